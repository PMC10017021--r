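#' @useDynLib qcembed, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif
NULL

# bohr per angstrom (CODATA value used throughout)
.BOHR <- 0.52917721092
# Hartree to electron volt
.HARTREE_EV <- 27.211386245988

.element_Z <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
                F = 9, Ne = 10)

#' Molecular geometry
#'
#' Container for a molecular structure: element symbols, Cartesian
#' coordinates in angstrom, net charge and spin (2S). Only closed-shell
#' systems (`spin = 0`, even electron count) are supported by the
#' mean-field and embedding machinery.
#'
#' @param atoms character vector of element symbols
#' @param coords numeric matrix (n x 3) of coordinates in angstrom
#' @param charge integer net charge
#' @param spin integer 2S (must be 0)
#' @return object of class `qc_geometry`
#' @export
geometry <- function(atoms, coords, charge = 0L, spin = 0L) {
  atoms <- as.character(atoms)
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (length(atoms) != nrow(coords))
    stop("length(atoms) must equal nrow(coords)")
  if (!all(atoms %in% names(.element_Z)))
    stop("unknown element symbol(s): ",
         paste(setdiff(atoms, names(.element_Z)), collapse = ", "))
  ne <- sum(.element_Z[atoms]) - charge
  if (spin != 0L)
    stop("only closed-shell systems (spin = 0) are supported")
  if (ne %% 2 != 0)
    stop("odd electron count (", ne, "); closed-shell systems only")
  structure(list(atoms = atoms, coords = coords,
                 charge = as.integer(charge), spin = as.integer(spin)),
            class = "qc_geometry")
}

#' @export
print.qc_geometry <- function(x, ...) {
  cat(sprintf("<qc_geometry: %d atoms, charge %d, %d electrons>\n",
              length(x$atoms), x$charge, n_electrons(x)))
  invisible(x)
}

#' Number of electrons in a geometry
#' @param geom a `qc_geometry`
#' @return integer electron count
#' @export
n_electrons <- function(geom) {
  as.integer(sum(.element_Z[geom$atoms]) - geom$charge)
}

#' Nuclear repulsion energy (Hartree)
#' @param geom a `qc_geometry`
#' @return scalar, Hartree
#' @export
nuclear_repulsion <- function(geom) {
  Z <- .element_Z[geom$atoms]
  R <- geom$coords / .BOHR
  n <- length(Z)
  e <- 0
  if (n < 2) return(0)
  for (i in 2:n) for (j in 1:(i - 1)) {
    e <- e + Z[i] * Z[j] / sqrt(sum((R[i, ] - R[j, ])^2))
  }
  unname(e)
}

#' Read a geometry from an XYZ file
#'
#' Standard XYZ: first line atom count, second line comment (optionally
#' carrying `charge=INT spin=INT`), then one `element x y z` line per atom
#' (angstrom).
#'
#' @param path file path
#' @return a `qc_geometry`
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("malformed XYZ file: fewer than 2 lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ line 1: expected atom count")
  if (length(lines) < 2 + n)
    stop("malformed XYZ: expected ", n, " atom lines")
  comment <- lines[2]
  charge <- 0L; spin <- 0L
  m <- regmatches(comment, regexec("charge=(-?[0-9]+)", comment))[[1]]
  if (length(m) == 2) charge <- as.integer(m[2])
  m <- regmatches(comment, regexec("spin=(-?[0-9]+)", comment))[[1]]
  if (length(m) == 2) spin <- as.integer(m[2])
  atoms <- character(n)
  coords <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[2 + i]), "[[:space:]]+")[[1]]
    if (length(tok) < 4)
      stop("malformed XYZ line ", 2 + i, ": ", lines[2 + i])
    atoms[i] <- tok[1]
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(xyz)))
      stop("malformed XYZ line ", 2 + i, ": non-numeric coordinate")
    coords[i, ] <- xyz
  }
  geometry(atoms, coords, charge, spin)
}

#' Write a geometry to an XYZ file
#' @param geom a `qc_geometry`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_xyz <- function(geom, path) {
  lines <- c(
    as.character(length(geom$atoms)),
    sprintf("charge=%d spin=%d", geom$charge, geom$spin),
    sprintf("%-2s %20.12f %20.12f %20.12f", geom$atoms,
            geom$coords[, 1], geom$coords[, 2], geom$coords[, 3]))
  writeLines(lines, path)
  invisible(path)
}

.norm3 <- function(v) sqrt(sum(v^2))

# deterministic propionitrile (CH3CH2CN) frame: methylene carbon at the
# origin, nitrile axis along +z so that stretching r_CN displaces only N
.propionitrile_geometry <- function(r_cn = 1.157) {
  d_cc1 <- 1.540; d_cc2 <- 1.458; d_ch <- 1.091
  ang <- 111.5 * pi / 180
  C2 <- c(0, 0, 0)
  C3 <- c(0, 0, d_cc2)
  N <- C3 + c(0, 0, r_cn)
  C1 <- C2 + d_cc1 * c(sin(ang), 0, cos(ang))
  u1 <- (C3 - C2) / .norm3(C3 - C2)
  u2 <- (C1 - C2) / .norm3(C1 - C2)
  bis <- -(u1 + u2); bis <- bis / .norm3(bis)
  perp <- c(u1[2] * u2[3] - u1[3] * u2[2],
            u1[3] * u2[1] - u1[1] * u2[3],
            u1[1] * u2[2] - u1[2] * u2[1])
  perp <- perp / .norm3(perp)
  th <- (109.5 / 2) * pi / 180
  H1 <- C2 + d_ch * (bis * cos(th) + perp * sin(th))
  H2 <- C2 + d_ch * (bis * cos(th) - perp * sin(th))
  a1 <- (C2 - C1) / .norm3(C2 - C1)
  e1 <- c(a1[2] * perp[3] - a1[3] * perp[2],
          a1[3] * perp[1] - a1[1] * perp[3],
          a1[1] * perp[2] - a1[2] * perp[1])
  e1 <- e1 / .norm3(e1)
  e2 <- c(a1[2] * e1[3] - a1[3] * e1[2],
          a1[3] * e1[1] - a1[1] * e1[3],
          a1[1] * e1[2] - a1[2] * e1[1])
  tet <- (180 - 109.5) * pi / 180
  Hs <- lapply(0:2, function(k) {
    phi <- (60 + 120 * k) * pi / 180
    d <- -a1 * cos(tet) + sin(tet) * (e1 * cos(phi) + e2 * sin(phi))
    C1 + d_ch * d / .norm3(d)
  })
  atoms <- c("C", "C", "C", "N", "H", "H", "H", "H", "H")
  coords <- rbind(C1, C2, C3, N, H1, H2, Hs[[1]], Hs[[2]], Hs[[3]])
  geometry(atoms, coords)
}

#' Built-in deterministic test geometries
#'
#' Fixture generator for the systems used throughout the test-suite and
#' examples. All geometries are constructed from standard equilibrium
#' internal coordinates; no external files are required.
#'
#' Available fixtures:
#' \describe{
#'   \item{`h_chain`}{`n` collinear hydrogens, spacing `r` angstrom
#'     (defaults 4, 1.0)}
#'   \item{`n2`}{dinitrogen at bond length `r` (default 1.0977)}
#'   \item{`water`}{single water molecule}
#'   \item{`water_dimer`}{hydrogen-bonded water dimer}
#'   \item{`he2`}{two helium atoms separated by `r` (default 50)}
#'   \item{`h2`}{dihydrogen at bond length `r` (default 0.74)}
#'   \item{`propionitrile`}{CH3CH2CN with nitrile bond length
#'     `r_cn` (default 1.157); the nitrile axis is a coordinate axis so
#'     the returned C-N distance equals `r_cn` exactly}
#' }
#'
#' @param name fixture name (see details)
#' @param n chain length (`h_chain`)
#' @param r distance parameter in angstrom (`h_chain`, `h2`, `n2`, `he2`)
#' @param r_cn nitrile bond length in angstrom (`propionitrile`)
#' @return a `qc_geometry`
#' @export
fixture <- function(name, n = NULL, r = NULL, r_cn = NULL) {
  switch(name,
    h_chain = {
      if (is.null(n)) n <- 4L
      if (is.null(r)) r <- 1.0
      geometry(rep("H", as.integer(n)), cbind(0, 0, (seq_len(n) - 1) * r))
    },
    h2 = {
      if (is.null(r)) r <- 0.74
      geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, r)))
    },
    n2 = {
      if (is.null(r)) r <- 1.0977
      geometry(c("N", "N"), rbind(c(0, 0, 0), c(0, 0, r)))
    },
    he2 = {
      if (is.null(r)) r <- 50
      geometry(c("He", "He"), rbind(c(0, 0, 0), c(0, 0, r)))
    },
    water = {
      # r(OH) = 0.9572 A, HOH = 104.52 deg
      a <- 104.52 * pi / 180
      geometry(c("O", "H", "H"),
               rbind(c(0, 0, 0),
                     c(0.9572, 0, 0),
                     c(0.9572 * cos(a), 0.9572 * sin(a), 0)))
    },
    water_dimer = {
      # near-equilibrium hydrogen-bonded dimer, O..O about 2.91 A
      geometry(c("O", "H", "H", "O", "H", "H"),
               rbind(c(-1.551007, -0.114520, 0.000000),
                     c(-1.934259, 0.762503, 0.000000),
                     c(-0.599677, 0.040712, 0.000000),
                     c(1.350625, 0.111469, 0.000000),
                     c(1.680398, -0.373741, -0.758561),
                     c(1.680398, -0.373741, 0.758561)))
    },
    propionitrile = {
      if (is.null(r_cn)) r_cn <- 1.157
      .propionitrile_geometry(r_cn)
    },
    stop("unknown fixture: ", name)
  )
}
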