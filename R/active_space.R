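# Conventional (frozen-core / orbital-window) active-space Hamiltonians
# from a converged mean-field solution.

#' Active-space Hamiltonian from an orbital window
#'
#' Builds the second-quantized Hamiltonian for a window of molecular
#' orbitals, freezing the lowest `n_frozen` doubly occupied orbitals into
#' an effective core (Coulomb + exchange mean field plus scalar energy).
#'
#' @param sys a `qc_system`
#' @param mf a `qc_scf`
#' @param n_frozen number of frozen doubly-occupied core orbitals
#' @param n_active number of active orbitals (default: all remaining)
#' @return a `qc_active_ham` with `e_core` carrying the frozen-core and
#'   nuclear-repulsion energy
#' @export
active_window_hamiltonian <- function(sys, mf, n_frozen = 0,
                                      n_active = NULL) {
  nmo <- ncol(mf$C)
  if (is.null(n_active)) n_active <- nmo - n_frozen
  if (n_frozen + n_active > nmo) stop("orbital window exceeds MO count")
  act <- mf$C[, n_frozen + seq_len(n_active), drop = FALSE]
  nelec_act <- 2L * (mf$n_occ - n_frozen)
  if (nelec_act < 0) stop("more frozen orbitals than occupied orbitals")
  if (n_frozen > 0) {
    Cc <- mf$C[, seq_len(n_frozen), drop = FALSE]
    gc <- 2 * Cc %*% t(Cc)
    Jc <- coulomb_matrix(sys, gc)
    Kc <- exchange_matrix(sys, gc)
    h_eff <- sys$hcore + Jc - 0.5 * Kc
    e_core <- sum(gc * sys$hcore) + 0.5 * sum(gc * (Jc - 0.5 * Kc)) +
      sys$enuc
  } else {
    h_eff <- sys$hcore
    e_core <- sys$enuc
  }
  transform_active_integrals(sys, h_eff, act, nelec_act, e_core = e_core)
}
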