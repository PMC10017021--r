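# Determinant full CI driver (the truth oracle for the DMRG solver and
# for embedding reductions). S_z = 0 sector, dense diagonalization.

.fci_dim <- function(norb, nelec) {
  na <- (nelec + nelec %% 2) %/% 2
  nb <- nelec - na
  choose(norb, na) * choose(norb, nb)
}

#' Solve the active-space Hamiltonian by determinant FCI
#'
#' Builds the S_z = 0 determinant Hamiltonian with Slater-Condon rules
#' and diagonalizes it densely. Intended as a brute-force oracle for
#' small spaces; refuses spaces beyond `max_dim` with a size report.
#'
#' @param ham a `qc_active_ham` (from [transform_active_integrals()] or
#'   [read_fcidump()])
#' @param max_dim largest determinant-space dimension accepted
#' @param n_states number of eigenstates returned (energies only beyond
#'   the first)
#' @return object of class `qc_fci`: `energy` (includes `e_core`),
#'   `ci_vector`, `one_rdm`, `strings_a`, `strings_b`, `dim`
#' @export
fci_solve <- function(ham, max_dim = 6000, n_states = 1) {
  norb <- ham$norb
  nelec <- ham$nelec
  if (norb > 16) stop("FCI oracle limited to 16 orbitals (got ", norb, ")")
  d <- .fci_dim(norb, nelec)
  if (d > max_dim)
    stop(sprintf(
      "determinant space too large for the dense oracle: dim %.0f > %d",
      d, max_dim))
  na <- (nelec + nelec %% 2) %/% 2
  nb <- nelec - na
  sa <- .cpp_fci_strings(norb, na)
  sb <- if (nb == na) sa else .cpp_fci_strings(norb, nb)
  H <- .cpp_fci_ham(norb, ham$h, as.vector(ham$eri), sa, sb)
  ev <- eigen(H, symmetric = TRUE)
  ord <- order(ev$values)
  ci <- ev$vectors[, ord[1]]
  # fix sign deterministically: largest-magnitude coefficient positive
  imax <- which.max(abs(ci))
  if (ci[imax] < 0) ci <- -ci
  G <- .cpp_fci_rdm1(norb, ci, sa, sb)
  structure(list(energy = ev$values[ord[1]] + ham$e_core,
                 energies = ev$values[ord[seq_len(min(n_states, d))]] +
                   ham$e_core,
                 ci_vector = ci, one_rdm = G,
                 strings_a = sa, strings_b = sb, dim = d),
            class = "qc_fci")
}

#' @export
print.qc_fci <- function(x, ...) {
  cat(sprintf("<qc_fci: E = %.10f Eh, dim %d>\n", x$energy, x$dim))
  invisible(x)
}

#' Hamiltonian expectation value of a CI vector
#'
#' `<c|H|c> + e_core` for a normalized determinant-space vector over the
#' same S_z = 0 determinant ordering as [fci_solve()].
#'
#' @param ci_vector normalized coefficient vector
#' @param ham a `qc_active_ham`
#' @return energy in Hartree
#' @export
fci_expectation <- function(ci_vector, ham) {
  norb <- ham$norb
  na <- (ham$nelec + ham$nelec %% 2) %/% 2
  nb <- ham$nelec - na
  sa <- .cpp_fci_strings(norb, na)
  sb <- if (nb == na) sa else .cpp_fci_strings(norb, nb)
  d <- length(sa) * length(sb)
  if (length(ci_vector) != d)
    stop("ci_vector length ", length(ci_vector), " != determinant space ", d)
  nrm <- sqrt(sum(ci_vector^2))
  if (abs(nrm - 1) > 1e-8) stop("ci_vector is not normalized")
  H <- .cpp_fci_ham(norb, ham$h, as.vector(ham$eri), sa, sb)
  sum(ci_vector * (H %*% ci_vector)) + ham$e_core
}

# index of the aufbau determinant (lowest orbitals doubly occupied) in
# the fci_solve determinant ordering
.aufbau_index <- function(norb, nelec) {
  na <- nelec %/% 2
  sa <- .cpp_fci_strings(norb, na)
  target <- sum(2^(seq_len(na) - 1))
  i <- which(sa == target)
  (i - 1) * length(sa) + i # ia + nA*ib with ia = ib = i (1-based combined)
}
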