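#' Build the AO integral representation of a molecule
#'
#' Computes overlap, core-Hamiltonian (kinetic + nuclear attraction) and
#' the full two-electron integral tensor for a geometry in a given basis,
#' using the built-in McMurchie-Davidson engine (s, p and spherical d
#' shells). The two-electron tensor is stored dense in chemist notation
#' `(pq|rs)` as a 4-way array; eight-fold permutational symmetry holds by
#' construction.
#'
#' @param geom a [geometry()] object
#' @param basis basis-set name (see [list_basis_sets()])
#' @return an object of class `qc_system` with elements `nao`, `S`,
#'   `hcore`, `Tkin`, `Vnuc`, `eri` (4-d array), `enuc`, `shells`,
#'   `ao_atom`, `geometry`, `basis`
#' @export
build_system <- function(geom, basis) {
  shells <- build_shells(geom, basis)
  Z <- unname(.element_Z[geom$atoms])
  one <- .cpp_one_electron(shells, geom$coords / .BOHR, Z)
  nao <- ao_count(shells)
  eri <- .cpp_eri(shells)
  dim(eri) <- c(nao, nao, nao, nao)
  sys <- list(nao = nao,
              S = one$S,
              Tkin = one$T,
              Vnuc = one$V,
              hcore = one$T + one$V,
              eri = eri,
              enuc = nuclear_repulsion(geom),
              shells = shells,
              ao_atom = ao_atom_map(shells),
              geometry = geom,
              basis = tolower(basis))
  class(sys) <- "qc_system"
  sys
}

#' @export
print.qc_system <- function(x, ...) {
  cat(sprintf("<qc_system: %d AOs, basis %s, %d atoms, enuc %.8f>\n",
              x$nao, x$basis, length(x$geometry$atoms), x$enuc))
  invisible(x)
}

# Coulomb matrix J[D]_pq = sum_rs (pq|rs) D_rs
coulomb_matrix <- function(sys, D) {
  n <- sys$nao
  J <- matrix(sys$eri, n * n, n * n) %*% as.vector(D)
  matrix(J, n, n)
}

# Exchange matrix K[D]_pq = sum_rs (pr|qs) D_rs
exchange_matrix <- function(sys, D) {
  n <- sys$nao
  e <- aperm(sys$eri, c(1, 3, 2, 4))
  K <- matrix(e, n * n, n * n) %*% as.vector(D)
  matrix(K, n, n)
}
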