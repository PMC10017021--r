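# Projection-based embedding: level-shift projector, embedding potential,
# embedded mean-field, active-space Hamiltonian, and total-energy assembly.

#' Level-shift projector P^B = S gamma_B S
#'
#' @param S AO overlap matrix
#' @param gamma_B environment density matrix
#' @param mu level-shift scalar (default 1e6)
#' @return list with `P_B` and `muP_B`
#' @export
build_projector <- function(S, gamma_B, mu = 1e6) {
  if (!isTRUE(all.equal(dim(S), dim(gamma_B))))
    stop("dimension mismatch between S and gamma_B")
  if (max(abs(S - t(S))) > 1e-10 || max(abs(gamma_B - t(gamma_B))) > 1e-10)
    stop("S and gamma_B must be symmetric")
  P <- S %*% gamma_B %*% S
  P <- 0.5 * (P + t(P))
  list(P_B = P, muP_B = mu * P, mu = mu)
}

#' Embedding potential v_emb
#'
#' All interactions of the environment density with the active subsystem:
#' `v_emb = g[gamma_A + gamma_B] - g[gamma_A]` evaluated at the
#' environment level of theory (Coulomb, exact-exchange fraction and
#' exchange-correlation).
#'
#' @param sys a `qc_system`
#' @param gamma_A,gamma_B subsystem densities from [build_partition()]
#' @param level_env environment level (`"hf"` or functional)
#' @param grid optional precomputed quadrature grid
#' @return symmetric matrix v_emb
#' @export
build_embedding_potential <- function(sys, gamma_A, gamma_B, level_env,
                                      grid = NULL) {
  lv <- .lvl(level_env)
  if (lv$dft && is.null(grid)) grid <- build_grid(sys$geometry)
  g_tot <- two_electron_matrix(sys, gamma_A + gamma_B, level_env, grid)
  g_A <- two_electron_matrix(sys, gamma_A, level_env, grid)
  v <- g_tot - g_A
  0.5 * (v + t(v))
}

#' Embedding operator bundle
#'
#' Builds the projector, embedding potential and effective core
#' Hamiltonian `h_tilde = hcore + v_emb + mu * P_B` for a partition.
#'
#' @param sys a `qc_system`
#' @param part a `qc_partition`
#' @param level_env environment level
#' @param mu level shift (default 1e6)
#' @param grid optional quadrature grid
#' @return object of class `qc_embedding_ops`
#' @export
build_embedding_operators <- function(sys, part, level_env, mu = 1e6,
                                      grid = NULL) {
  lv <- .lvl(level_env)
  if (lv$dft && is.null(grid)) grid <- build_grid(sys$geometry)
  proj <- build_projector(sys$S, part$gamma_B, mu)
  v_emb <- build_embedding_potential(sys, part$gamma_A, part$gamma_B,
                                     level_env, grid)
  h_tilde <- sys$hcore + v_emb + proj$muP_B
  structure(list(P_B = proj$P_B, mu = mu, v_emb = v_emb,
                 h_tilde = 0.5 * (h_tilde + t(h_tilde)),
                 level_env = lv$name, grid = grid),
            class = "qc_embedding_ops")
}

#' Embedded mean-field calculation of subsystem A
#'
#' Self-consistently optimizes the embedded subsystem-A density under
#' `F_A = h_tilde + g[gamma_A_tilde]`, with the two-electron field at
#' `level_wf` (HF for the wavefunction path, or the environment functional
#' for same-level-in-same-level checks). The variational space is the full
#' AO basis by default (the level shift keeps environment-occupied
#' character out); a restricted S-orthonormal span may be supplied.
#'
#' @param sys a `qc_system`
#' @param ops a `qc_embedding_ops`
#' @param n_act_elec active electron count (even)
#' @param span optional AO x m matrix of S-orthonormal span vectors
#' @param level_wf level for the subsystem-A two-electron field
#' @param conv energy-change convergence (Hartree)
#' @param max_iter maximum iterations
#' @return object of class `qc_embedded_mf`: `gamma_A_tilde`, `C` (AO
#'   coefficients of embedded orbitals), `eps`, `n_occ`, `E_A_elec`
#'   (subsystem-A electronic energy with the effective core, level shift
#'   included)
#' @export
embedded_scf <- function(sys, ops, n_act_elec, span = NULL,
                         level_wf = "hf", conv = 1e-9, max_iter = 200) {
  lv <- .lvl(level_wf)
  if (n_act_elec %% 2 != 0) stop("active electron count must be even")
  nocc <- n_act_elec %/% 2
  n <- sys$nao
  if (is.null(span)) {
    B <- .sym_orth(sys$S) # columns S-orthonormal, full rank
  } else {
    B <- span
    dev <- max(abs(t(B) %*% sys$S %*% B - diag(ncol(B))))
    if (dev > 1e-8) stop("span is not S-orthonormal (deviation ",
                         format(dev), ")")
  }
  if (nocc > ncol(B)) stop("occupied count exceeds span dimension")
  grid <- ops$grid
  aoval <- NULL
  if (lv$dft) {
    if (is.null(grid)) grid <- build_grid(sys$geometry)
    aoval <- .cpp_eval_ao(sys$shells, grid$pts, TRUE)
  }
  eriJ <- matrix(sys$eri, n * n, n * n)
  eriK <- if (lv$hyb > 0) matrix(aperm(sys$eri, c(1, 3, 2, 4)), n * n, n * n)
          else NULL
  ht <- ops$h_tilde
  # initial guess from h_tilde in the span
  ev <- .eigh_asc(t(B) %*% ht %*% B)
  Co <- B %*% ev$vectors[, seq_len(nocc), drop = FALSE]
  D <- 2 * Co %*% t(Co)
  E_old <- 0
  focks <- list(); errs <- list()
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    fe <- .fock_two_electron(sys, D, lv, grid, aoval, eriJ, eriK)
    Fmat <- ht + fe$G
    E <- sum(D * ht) + fe$e2
    Fs <- t(B) %*% Fmat %*% B
    Ds <- t(B) %*% sys$S %*% D %*% sys$S %*% B
    err <- Fs %*% Ds - Ds %*% Fs
    focks[[length(focks) + 1]] <- Fs
    errs[[length(errs) + 1]] <- err
    if (length(focks) > 8) { focks <- focks[-1]; errs <- errs[-1] }
    Fuse <- Fs
    if (length(focks) >= 2) {
      Fd <- .diis_extrapolate(focks, errs)
      if (!is.null(Fd)) Fuse <- Fd
    }
    ev <- .eigh_asc(0.5 * (Fuse + t(Fuse)))
    Co <- B %*% ev$vectors[, seq_len(nocc), drop = FALSE]
    D <- 2 * Co %*% t(Co)
    dE <- E - E_old
    if (it > 1 && abs(dE) < conv && max(abs(err)) < 1e-6) {
      converged <- TRUE
      break
    }
    E_old <- E
  }
  if (!converged)
    stop("embedded SCF failed to converge; last dE = ", format(dE))
  fe <- .fock_two_electron(sys, D, lv, grid, aoval, eriJ, eriK)
  E <- sum(D * ht) + fe$e2
  Call <- B %*% ev$vectors
  structure(list(gamma_A_tilde = D, C = Call, eps = ev$values,
                 n_occ = nocc, E_A_elec = E, level_wf = lv$name,
                 converged = converged),
            class = "qc_embedded_mf")
}

# AO -> MO transform of the two-electron tensor into a span (AO x m)
.ao2mo_eri <- function(eri, B) {
  n <- dim(eri)[1]
  m <- ncol(B)
  A <- eri
  for (pass in 1:4) {
    d <- dim(A)
    M <- matrix(A, prod(d[1:3]), d[4]) %*% B
    A <- array(M, c(d[1:3], m))
    A <- aperm(A, c(4, 1, 2, 3))
  }
  A
}

#' Active-space Hamiltonian in the embedded orbital basis
#'
#' Transforms the effective core Hamiltonian and the two-electron
#' integrals into an S-orthonormal active span, producing the
#' second-quantized subsystem Hamiltonian consumed by the FCI and DMRG
#' solvers (and serializable as FCIDUMP).
#'
#' @param sys a `qc_system`
#' @param ops a `qc_embedding_ops` (or a plain symmetric matrix used as
#'   the one-electron operator)
#' @param span AO x m matrix of S-orthonormal orbitals
#' @param nelec active electron count
#' @param e_core scalar constant carried into the energy assembly
#' @return object of class `qc_active_ham`: `norb`, `nelec`, `h` (m x m),
#'   `eri` (m^4 array, chemist notation), `e_core`
#' @export
transform_active_integrals <- function(sys, ops, span, nelec,
                                       e_core = 0) {
  B <- span
  dev <- max(abs(t(B) %*% sys$S %*% B - diag(ncol(B))))
  if (dev > 1e-8)
    stop("active span is not S-orthonormal (deviation ", format(dev), ")")
  hmat <- if (inherits(ops, "qc_embedding_ops")) ops$h_tilde else ops
  h <- t(B) %*% hmat %*% B
  eri <- .ao2mo_eri(sys$eri, B)
  structure(list(norb = ncol(B), nelec = as.integer(nelec),
                 h = 0.5 * (h + t(h)), eri = eri, e_core = e_core),
            class = "qc_active_ham")
}

#' @export
print.qc_active_ham <- function(x, ...) {
  cat(sprintf("<qc_active_ham: %d electrons in %d orbitals, e_core %.8f>\n",
              x$nelec, x$norb, x$e_core))
  invisible(x)
}

#' Assemble the embedded total energy
#'
#' Combines the subsystem-A energy (computed with the effective core
#' Hamiltonian, so the embedding potential and level-shift penalty are
#' folded in) with the environment-level functional:
#' `E = E_A + E_DFT[gamma_A + gamma_B] - E_DFT[gamma_A] - tr(gamma_A
#' v_emb)`, where the subtracted functional value is electronic-only
#' (nuclear repulsion is carried once, in the full-density term). For the
#' same-level mean-field path this reduces exactly to the full-system
#' single-calculation energy.
#'
#' @param E_A_elec subsystem-A electronic energy evaluated with `h_tilde`
#'   (from [embedded_scf()], or correlated solver energy plus its core)
#' @param gamma_corr AO-basis 1-RDM of the subsystem-A state used for the
#'   level-shift report (for the mean-field path, `gamma_A_tilde`)
#' @param sys a `qc_system`
#' @param part a `qc_partition`
#' @param ops a `qc_embedding_ops`
#' @return list with `E_total` and the energy components
#' @export
assemble_total_energy <- function(E_A_elec, gamma_corr, sys, part, ops) {
  grid <- ops$grid
  E_full <- dft_energy(part$gamma_A + part$gamma_B, ops$level_env, sys,
                       include_enuc = TRUE, grid = grid)
  E_A_dft <- dft_energy(part$gamma_A, ops$level_env, sys,
                        include_enuc = FALSE, grid = grid)
  tr_v <- sum(part$gamma_A * ops$v_emb)
  shift <- ops$mu * sum(gamma_corr * ops$P_B)
  E_total <- E_A_elec + E_full - E_A_dft - tr_v
  list(E_total = E_total,
       components = list(E_A = E_A_elec,
                         E_dft_full = E_full,
                         E_dft_A = E_A_dft,
                         tr_gammaA_vemb = tr_v,
                         level_shift = shift))
}

#' Energy report
#'
#' JSON-serializable energy decomposition of an embedded calculation.
#'
#' @param assembly result of [assemble_total_energy()]
#' @param path optional JSON output path
#' @return report list
#' @export
energy_report <- function(assembly, path = NULL) {
  rep <- c(assembly$components, list(E_total = assembly$E_total))
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
    return(invisible(rep))
  }
  rep
}
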