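# Shell construction and normalization.
#
# Contraction coefficients in the library refer to normalized cartesian
# primitives of the (l,0,0) component; here they are folded together with
# the primitive norms and a final contracted renormalization so the C++
# layer works with raw cartesian Gaussians.

.double_factorial <- function(n) if (n <= 1) 1 else prod(seq(n, 1, by = -2))

# norm of primitive cartesian gaussian x^l exp(-a r^2)
.prim_norm <- function(a, l) {
  sqrt((2 * a / pi)^1.5 * (4 * a)^l / .double_factorial(2 * l - 1))
}

#' Available basis sets
#' @return character vector of basis-set names
#' @export
list_basis_sets <- function() names(.basis_library)

# Build the shell list for a geometry. Each shell: l, atom (1-based),
# center (bohr), exp, coef (fully normalized).
build_shells <- function(geom, basis) {
  basis <- tolower(basis)
  if (!basis %in% names(.basis_library))
    stop("unknown basis set: ", basis)
  lib <- .basis_library[[basis]]
  shells <- list()
  for (ia in seq_along(geom$atoms)) {
    el <- geom$atoms[ia]
    if (!el %in% names(lib))
      stop("basis ", basis, " has no parameters for element ", el)
    for (sh in lib[[el]]) {
      l <- sh$l
      cN <- sh$coef * vapply(sh$exp, .prim_norm, 0, l = l)
      # contracted self-overlap of the (l,0,0) component
      p <- outer(sh$exp, sh$exp, "+")
      ov <- (pi / p)^1.5 * .double_factorial(2 * l - 1) / (2 * p)^l
      s <- sqrt(sum(outer(cN, cN) * ov))
      shells[[length(shells) + 1]] <- list(
        l = as.integer(l), atom = as.integer(ia),
        center = geom$coords[ia, ] / .BOHR,
        exp = sh$exp, coef = cN / s)
    }
  }
  shells
}

# atom index owning each AO (1-based), matching the C++ AO ordering
ao_atom_map <- function(shells) {
  unlist(lapply(shells, function(s) rep(s$atom, 2 * s$l + 1)))
}

ao_count <- function(shells) {
  sum(vapply(shells, function(s) 2L * s$l + 1L, integer(1)))
}
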