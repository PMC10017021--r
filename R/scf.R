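# Restricted mean-field solver (RHF / RKS) with DIIS acceleration.
#
# Density convention throughout: gamma is the spin-summed AO density,
# gamma = 2 C_occ C_occ^T, tr(gamma S) = N_elec.

.eigh_asc <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  ord <- order(e$values)
  list(values = e$values[ord], vectors = e$vectors[, ord, drop = FALSE])
}

.sym_orth <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < 1e-10)
    warning("near-singular overlap matrix, smallest eigenvalue ",
            format(min(e$values)))
  e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
}

# two-electron part of the Fock matrix and its energy for density D
# returns list(G, e2): F = hcore + G; e2 = two-electron energy incl. Exc
.fock_two_electron <- function(sys, D, lv, grid = NULL, aoval = NULL,
                               eriJ = NULL, eriK = NULL) {
  n <- sys$nao
  vD <- as.vector(D)
  J <- if (is.null(eriJ)) coulomb_matrix(sys, D)
       else matrix(eriJ %*% vD, n, n)
  G <- J
  e2 <- 0.5 * sum(D * J)
  if (lv$hyb > 0) {
    K <- if (is.null(eriK)) exchange_matrix(sys, D)
         else matrix(eriK %*% vD, n, n)
    G <- G - 0.5 * lv$hyb * K
    e2 <- e2 - 0.25 * lv$hyb * sum(D * K)
  }
  if (lv$dft) {
    xc <- .xc_matrix(lv$name, sys, grid, aoval, D)
    G <- G + xc$V
    e2 <- e2 + xc$exc
  }
  list(G = G, e2 = e2)
}

#' Two-electron field matrix g[gamma]
#'
#' Groups all two-electron contributions for a given level of theory:
#' Coulomb, the level's exact-exchange fraction, and (for density
#' functionals) the exchange-correlation potential matrix.
#'
#' @param sys a `qc_system`
#' @param gamma spin-summed AO density matrix
#' @param level `"hf"` or a functional name
#' @param grid optional precomputed [build_grid()] result
#' @return symmetric matrix g
#' @export
two_electron_matrix <- function(sys, gamma, level, grid = NULL) {
  if (!isTRUE(all.equal(dim(gamma), c(sys$nao, sys$nao))))
    stop("gamma dimension mismatch")
  lv <- .lvl(level)
  aoval <- NULL
  if (lv$dft) {
    if (is.null(grid)) grid <- build_grid(sys$geometry)
    aoval <- .cpp_eval_ao(sys$shells, grid$pts, TRUE)
  }
  .fock_two_electron(sys, gamma, lv, grid, aoval)$G
}

#' Total energy functional evaluated at a given density
#'
#' Evaluates the HF or DFT energy expression at an arbitrary (not
#' necessarily self-consistent) spin-summed density matrix.
#'
#' @param gamma AO density matrix
#' @param level `"hf"` or functional name
#' @param sys a `qc_system`
#' @param include_enuc include nuclear repulsion (default TRUE)
#' @param grid optional precomputed grid
#' @return energy in Hartree
#' @export
dft_energy <- function(gamma, level, sys, include_enuc = TRUE, grid = NULL) {
  lv <- .lvl(level)
  aoval <- NULL
  if (lv$dft) {
    if (is.null(grid)) grid <- build_grid(sys$geometry)
    aoval <- .cpp_eval_ao(sys$shells, grid$pts, TRUE)
  }
  fe <- .fock_two_electron(sys, gamma, lv, grid, aoval)
  e <- sum(gamma * sys$hcore) + fe$e2
  if (include_enuc) e <- e + sys$enuc
  e
}

.diis_extrapolate <- function(focks, errs) {
  m <- length(focks)
  B <- matrix(0, m + 1, m + 1)
  for (i in seq_len(m)) for (j in seq_len(m))
    B[i, j] <- sum(errs[[i]] * errs[[j]])
  B[m + 1, seq_len(m)] <- -1
  B[seq_len(m), m + 1] <- -1
  rhs <- c(rep(0, m), -1)
  co <- tryCatch(solve(B, rhs), error = function(e) NULL)
  if (is.null(co)) return(NULL)
  Fm <- 0
  for (i in seq_len(m)) Fm <- Fm + co[i] * focks[[i]]
  Fm
}

#' Run a restricted mean-field (HF or KS-DFT) calculation
#'
#' Self-consistent field with DIIS, core-Hamiltonian initial guess and a
#' 1e-9 Hartree energy convergence threshold. Closed-shell only.
#'
#' @param sys a `qc_system` from [build_system()]
#' @param level `"hf"` or a functional name (`"lda"`, `"pbe"`, `"pbe0"`,
#'   `"b3lyp"`, `"b3lyp5"`)
#' @param conv energy convergence threshold (Hartree)
#' @param max_iter maximum SCF iterations
#' @param grid optional precomputed [build_grid()] quadrature
#' @param verbose print per-iteration energies
#' @return object of class `qc_scf`: `C` (MO coefficients, S-orthonormal),
#'   `eps` (orbital energies), `gamma` (AO density, tr(gamma S) = N),
#'   `E_total` (Hartree), `level`, `n_occ`, `converged`, `fock`
#' @export
run_mean_field <- function(sys, level = "hf", conv = 1e-9, max_iter = 200,
                           grid = NULL, verbose = FALSE) {
  lv <- .lvl(level)
  nelec <- n_electrons(sys$geometry)
  if (nelec %% 2 != 0) stop("closed-shell electron count required")
  nocc <- nelec %/% 2
  n <- sys$nao
  X <- .sym_orth(sys$S)
  aoval <- NULL
  if (lv$dft) {
    if (is.null(grid)) grid <- build_grid(sys$geometry)
    aoval <- .cpp_eval_ao(sys$shells, grid$pts, TRUE)
  }
  eriJ <- matrix(sys$eri, n * n, n * n)
  eriK <- matrix(aperm(sys$eri, c(1, 3, 2, 4)), n * n, n * n)
  # core guess
  Fo <- t(X) %*% sys$hcore %*% X
  ev <- .eigh_asc(Fo)
  C <- X %*% ev$vectors
  D <- 2 * C[, seq_len(nocc), drop = FALSE] %*%
           t(C[, seq_len(nocc), drop = FALSE])
  E_old <- 0
  energies <- numeric(0)
  focks <- list(); errs <- list()
  converged <- FALSE
  Fmat <- NULL
  for (it in seq_len(max_iter)) {
    fe <- .fock_two_electron(sys, D, lv, grid, aoval, eriJ, eriK)
    Fmat <- sys$hcore + fe$G
    E <- sum(D * sys$hcore) + fe$e2 + sys$enuc
    err <- t(X) %*% (Fmat %*% D %*% sys$S - sys$S %*% D %*% Fmat) %*% X
    focks[[length(focks) + 1]] <- Fmat
    errs[[length(errs) + 1]] <- err
    if (length(focks) > 8) { focks <- focks[-1]; errs <- errs[-1] }
    Fuse <- Fmat
    if (length(focks) >= 2) {
      Fd <- .diis_extrapolate(focks, errs)
      if (!is.null(Fd)) Fuse <- Fd
    }
    Fo <- t(X) %*% Fuse %*% X
    ev <- .eigh_asc(Fo)
    C <- X %*% ev$vectors
    D <- 2 * C[, seq_len(nocc), drop = FALSE] %*%
             t(C[, seq_len(nocc), drop = FALSE])
    dE <- E - E_old
    if (verbose)
      message(sprintf("scf iter %3d  E = %.12f  dE = %.3e  |err| = %.3e",
                      it, E, dE, max(abs(err))))
    energies <- c(energies, E)
    if (it > 1 && abs(dE) < conv && max(abs(err)) < 1e-6) {
      converged <- TRUE
      break
    }
    E_old <- E
  }
  if (!converged) {
    stop("SCF failed to converge in ", max_iter,
         " iterations; last energies: ",
         paste(sprintf("%.10f", utils::tail(energies, 3)), collapse = ", "))
  }
  # final energy at the converged density
  fe <- .fock_two_electron(sys, D, lv, grid, aoval, eriJ, eriK)
  Fmat <- sys$hcore + fe$G
  E <- sum(D * sys$hcore) + fe$e2 + sys$enuc
  structure(list(C = C, eps = ev$values, gamma = D, E_total = E,
                 level = lv$name, n_occ = nocc, converged = converged,
                 fock = Fmat, grid = grid, iterations = length(energies),
                 scf_energies = energies),
            class = "qc_scf")
}

#' @export
print.qc_scf <- function(x, ...) {
  cat(sprintf("<qc_scf: level %s, E_total %.10f Eh, %d iterations>\n",
              x$level, x$E_total, x$iterations))
  invisible(x)
}
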