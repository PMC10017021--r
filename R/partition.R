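# Occupied-space SPADE partition and concentric localization of the
# virtual space.

#' SPADE occupied-orbital partition
#'
#' Splits the occupied orbitals of a converged mean-field solution between
#' an active subsystem (A) and its environment (B) by the subsystem
#' projected AO decomposition: the symmetrically orthogonalized occupied
#' coefficients are restricted to the rows of the basis functions centered
#' on the active atoms, an SVD of that block supplies a rotation of the
#' occupied space, and the split is placed at the largest gap of
#' consecutive singular values.
#'
#' @param mf a `qc_scf` from [run_mean_field()]
#' @param sys the `qc_system`
#' @param active_atoms integer vector of active-atom indices (1-based)
#' @param k_override optional explicit number of active occupied orbitals
#'   (required when the singular-value gap is degenerate)
#' @return list with `C_occ_A`, `C_occ_B`, `sigma` (singular values),
#'   `k`, `n_act_elec`
#' @export
spade_split <- function(mf, sys, active_atoms, k_override = NULL) {
  active_atoms <- sort(unique(as.integer(active_atoms)))
  natm <- length(sys$geometry$atoms)
  if (length(active_atoms) == 0) stop("active_atoms must be non-empty")
  if (any(active_atoms < 1 | active_atoms > natm))
    stop("active_atoms out of range")
  nocc <- mf$n_occ
  C_occ <- mf$C[, seq_len(nocc), drop = FALSE]
  if (length(active_atoms) == natm) {
    return(list(C_occ_A = C_occ,
                C_occ_B = C_occ[, 0, drop = FALSE],
                sigma = rep(1, nocc), k = nocc, n_act_elec = 2L * nocc))
  }
  es <- eigen(sys$S, symmetric = TRUE)
  Shalf <- es$vectors %*% diag(sqrt(es$values)) %*% t(es$vectors)
  X <- Shalf %*% C_occ
  rows <- which(sys$ao_atom %in% active_atoms)
  sv <- svd(X[rows, , drop = FALSE], nu = 0, nv = nocc)
  sigma <- c(sv$d, rep(0, nocc - length(sv$d)))
  C_rot <- C_occ %*% sv$v
  if (is.null(k_override)) {
    gaps <- sigma - c(sigma[-1], 0)
    k <- which.max(gaps)
    best <- sort(gaps, decreasing = TRUE)
    if (length(gaps) > 1 && best[1] - best[2] < 1e-8)
      stop("degenerate SPADE singular-value gap; supply k_override")
  } else {
    k <- as.integer(k_override)
    if (k < 1 || k > nocc) stop("k_override out of range")
  }
  list(C_occ_A = C_rot[, seq_len(k), drop = FALSE],
       C_occ_B = C_rot[, setdiff(seq_len(nocc), seq_len(k)), drop = FALSE],
       sigma = sigma, k = as.integer(k), n_act_elec = 2L * k)
}

#' Concentric localization of the virtual space
#'
#' Builds shells of virtual orbitals concentrated on the active fragment.
#' Shell 1 spans the projection of the full virtual space onto the
#' fragment AO subspace (rank of the fragment-AO/virtual overlap); each
#' following shell is obtained by applying the converged full-system Fock
#' matrix to the previous shell, projecting onto the remaining virtual
#' complement and keeping the span selected by SVD. All shells are
#' S-orthonormal, mutually S-orthogonal and S-orthogonal to the occupied
#' space. Shells are semicanonicalized (Fock-diagonal within each block).
#'
#' @param mf a `qc_scf`
#' @param sys the `qc_system`
#' @param occ_split result of [spade_split()]
#' @param active_atoms the active-atom indices used for the split
#' @param n_shells number of shells to retain (default 2)
#' @param tol singular-value threshold defining numerical rank
#' @return list with `shells` (list of coefficient blocks), `sizes`
#' @export
concentric_shells <- function(mf, sys, occ_split, active_atoms,
                              n_shells = 2, tol = 1e-8) {
  if (n_shells < 1) stop("n_shells must be >= 1")
  nocc <- mf$n_occ
  nao <- sys$nao
  C_virt <- mf$C[, setdiff(seq_len(nao), seq_len(nocc)), drop = FALSE]
  nvirt <- ncol(C_virt)
  rows <- which(sys$ao_atom %in% sort(unique(as.integer(active_atoms))))
  if (nvirt == 0) return(list(shells = list(), sizes = integer(0)))
  # shell 1: SVD of fragment-AO x virtual overlap
  M <- (sys$S %*% C_virt)[rows, , drop = FALSE]
  sv <- svd(M, nu = 0, nv = nvirt)
  r1 <- sum(sv$d > tol)
  shells <- list()
  cur <- C_virt %*% sv$v[, seq_len(r1), drop = FALSE]
  rest <- C_virt %*% sv$v[, setdiff(seq_len(nvirt), seq_len(r1)),
                          drop = FALSE]
  shells[[1]] <- cur
  F <- mf$fock
  t <- 1
  while (t < n_shells) {
    if (ncol(rest) == 0) {
      warning("requested shells exhaust the virtual space; truncating at ",
              t, " shell(s)")
      break
    }
    M2 <- t(rest) %*% F %*% cur
    sv2 <- svd(M2, nu = ncol(rest), nv = 0)
    r <- sum(sv2$d > tol)
    if (r == 0) {
      warning("Fock coupling to the virtual complement vanished; ",
              "truncating at ", t, " shell(s)")
      break
    }
    nxt <- rest %*% sv2$u[, seq_len(r), drop = FALSE]
    rest <- rest %*% sv2$u[, setdiff(seq_len(ncol(rest)), seq_len(r)),
                           drop = FALSE]
    shells[[t + 1]] <- nxt
    cur <- nxt
    t <- t + 1
  }
  # semicanonicalize each shell in the full-system Fock
  shells <- lapply(shells, function(B) {
    Fb <- t(B) %*% F %*% B
    ev <- .eigh_asc(0.5 * (Fb + t(Fb)))
    B %*% ev$vectors
  })
  list(shells = shells,
       sizes = vapply(shells, ncol, integer(1)))
}

#' Subsystem densities from an occupied split
#'
#' @param occ_split result of [spade_split()]
#' @return list with `gamma_A`, `gamma_B` (spin-summed AO densities)
#' @export
assemble_densities <- function(occ_split) {
  gA <- 2 * occ_split$C_occ_A %*% t(occ_split$C_occ_A)
  gB <- if (ncol(occ_split$C_occ_B) > 0)
    2 * occ_split$C_occ_B %*% t(occ_split$C_occ_B)
  else matrix(0, nrow(gA), nrow(gA))
  list(gamma_A = gA, gamma_B = gB)
}

#' Full subsystem partition
#'
#' Convenience wrapper running [spade_split()], [concentric_shells()] and
#' [assemble_densities()] in sequence.
#'
#' @inheritParams spade_split
#' @inheritParams concentric_shells
#' @return object of class `qc_partition` with the occupied split, the
#'   virtual shells, subsystem densities and counts
#' @export
build_partition <- function(mf, sys, active_atoms, n_shells = 2,
                            k_override = NULL, tol = 1e-8) {
  occ <- spade_split(mf, sys, active_atoms, k_override)
  cl <- concentric_shells(mf, sys, occ, active_atoms, n_shells, tol)
  dens <- assemble_densities(occ)
  structure(list(active_atoms = sort(unique(as.integer(active_atoms))),
                 C_occ_A = occ$C_occ_A, C_occ_B = occ$C_occ_B,
                 sigma = occ$sigma, k = occ$k,
                 n_act_elec = occ$n_act_elec,
                 C_virt_shells = cl$shells, shell_sizes = cl$sizes,
                 gamma_A = dens$gamma_A, gamma_B = dens$gamma_B,
                 n_act_orb = occ$k + sum(cl$sizes)),
            class = "qc_partition")
}

#' @export
print.qc_partition <- function(x, ...) {
  cat(sprintf(
    "<qc_partition: %d active electrons in %d orbitals (k = %d occ + shells %s)>\n",
    x$n_act_elec, x$n_act_orb, x$k, paste(x$shell_sizes, collapse = "+")))
  invisible(x)
}

#' Partition report
#'
#' JSON-serializable summary of a partition: singular values, chosen k,
#' shell sizes, active electron and orbital counts.
#'
#' @param part a `qc_partition`
#' @param path optional file to write JSON to
#' @return the report list, invisibly if written
#' @export
partition_report <- function(part, path = NULL) {
  rep <- list(sigma = part$sigma, k = part$k,
              shell_sizes = as.integer(part$shell_sizes),
              n_act_elec = as.integer(part$n_act_elec),
              n_act_orb = as.integer(part$n_act_orb),
              active_atoms = as.integer(part$active_atoms))
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = FALSE, digits = NA)
    return(invisible(rep))
  }
  rep
}
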