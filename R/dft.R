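# Exchange-correlation functionals and molecular quadrature grid.
#
# Closed-shell (spin-restricted) energy densities e(rho, sigma) with
# sigma = |grad rho|^2. Potentials vrho = de/drho and vsigma = de/dsigma
# are obtained by central finite differences of the analytic energy
# density; the SCF energy is variational, so potential-level truncation
# enters only at second order, and the embedding exactness identities
# hold because every code path shares these same functions.

.lvl <- function(level) {
  level <- tolower(level)
  known <- list(
    hf     = list(name = "hf", dft = FALSE, hyb = 1.0),
    lda    = list(name = "lda", dft = TRUE, hyb = 0.0),
    svwn   = list(name = "lda", dft = TRUE, hyb = 0.0),
    pbe    = list(name = "pbe", dft = TRUE, hyb = 0.0),
    pbe0   = list(name = "pbe0", dft = TRUE, hyb = 0.25),
    b3lyp  = list(name = "b3lyp", dft = TRUE, hyb = 0.20),
    b3lyp5 = list(name = "b3lyp5", dft = TRUE, hyb = 0.20))
  if (!level %in% names(known)) stop("unknown level/functional: ", level)
  known[[level]]
}

# --- LDA pieces ------------------------------------------------------------

.ex_slater <- function(rho) {
  cx <- 0.75 * (3 / pi)^(1 / 3)
  -cx * rho^(4 / 3)
}

# VWN correlation, paramagnetic channel; par = 5 (QMC fit) or 3 (RPA fit)
.ec_vwn <- function(rho, par = 5) {
  if (par == 5) {
    A <- 0.0310907; b <- 3.72744; c <- 12.9352; x0 <- -0.10498
  } else {
    A <- 0.0310907; b <- 13.0720; c <- 42.7198; x0 <- -0.409286
  }
  rho <- pmax(rho, 1e-250)
  rs <- (3 / (4 * pi * rho))^(1 / 3)
  x <- sqrt(rs)
  X <- x^2 + b * x + c
  X0 <- x0^2 + b * x0 + c
  Q <- sqrt(4 * c - b^2)
  eps <- A * (log(x^2 / X) + 2 * b / Q * atan(Q / (2 * x + b))
              - b * x0 / X0 * (log((x - x0)^2 / X)
                               + 2 * (b + 2 * x0) / Q * atan(Q / (2 * x + b))))
  rho * eps
}

# PW92 correlation energy per electron, zeta = 0
.eps_pw92 <- function(rs) {
  A <- 0.0310907; a1 <- 0.21370
  b1 <- 7.5957; b2 <- 3.5876; b3 <- 1.6382; b4 <- 0.49294
  srs <- sqrt(rs)
  den <- 2 * A * (b1 * srs + b2 * rs + b3 * rs * srs + b4 * rs^2)
  -2 * A * (1 + a1 * rs) * log(1 + 1 / den)
}

# --- GGA pieces ------------------------------------------------------------

# B88 exchange (full, includes the Slater part); closed shell
.ex_b88 <- function(rho, sigma) {
  beta <- 0.0042
  rs <- pmax(rho / 2, 1e-250)        # per-spin density
  ss <- pmax(sigma / 4, 0)           # per-spin |grad|^2
  x <- sqrt(ss) / rs^(4 / 3)
  cx <- 1.5 * (3 / (4 * pi))^(1 / 3) # per-spin LDA exchange constant
  e_s <- -rs^(4 / 3) * (cx + beta * x^2 / (1 + 6 * beta * x * asinh(x)))
  2 * e_s
}

# LYP correlation (Miehlich et al. reformulation), evaluated at the
# closed-shell point rho_a = rho_b = rho/2, sigma_aa = sigma_ab = sigma/4
.ec_lyp <- function(rho, sigma) {
  a <- 0.04918; b <- 0.132; c <- 0.2533; d <- 0.349
  rho <- pmax(rho, 1e-250)
  r13 <- rho^(-1 / 3)
  denom <- 1 + d * r13
  om <- exp(-c * r13) / denom * rho^(-11 / 3)
  del <- c * r13 + d * r13 / denom
  cf <- 0.3 * (3 * pi^2)^(2 / 3)
  ra <- rho / 2; rb <- rho / 2
  saa <- sigma / 4; sbb <- sigma / 4
  stot <- sigma
  t1 <- -a * 4 / denom * ra * rb / rho
  inner <- ra * rb * (2^(11 / 3) * cf * (ra^(8 / 3) + rb^(8 / 3))
                      + (47 / 18 - 7 * del / 18) * stot
                      - (5 / 2 - del / 18) * (saa + sbb)
                      - (del - 11) / 9 * (ra * saa + rb * sbb) / rho) -
           2 / 3 * rho^2 * stot +
           (2 / 3 * rho^2 - ra^2) * sbb +
           (2 / 3 * rho^2 - rb^2) * saa
  t1 - a * b * om * inner
}

# PBE exchange (full); closed shell
.ex_pbe <- function(rho, sigma) {
  kappa <- 0.804; mu <- 0.2195149727645171
  rho <- pmax(rho, 1e-250)
  kf <- (3 * pi^2 * rho)^(1 / 3)
  s2 <- pmax(sigma, 0) / (4 * kf^2 * rho^2)
  Fx <- 1 + kappa - kappa / (1 + mu * s2 / kappa)
  .ex_slater(rho) * Fx
}

# PBE correlation; closed shell
.ec_pbe <- function(rho, sigma) {
  gam <- (1 - log(2)) / pi^2
  beta <- 0.06672455060314922
  rho <- pmax(rho, 1e-250)
  rs <- (3 / (4 * pi * rho))^(1 / 3)
  eps <- .eps_pw92(rs)
  kf <- (3 * pi^2 * rho)^(1 / 3)
  ks <- sqrt(4 * kf / pi)
  t2 <- pmax(sigma, 0) / (4 * ks^2 * rho^2)
  expo <- exp(-eps / gam)
  A <- beta / gam / pmax(expo - 1, 1e-300)
  num <- 1 + A * t2
  den <- 1 + A * t2 + A^2 * t2^2
  H <- gam * log(1 + beta / gam * t2 * num / den)
  rho * (eps + H)
}

# combined XC energy density per functional tag
.exc_density <- function(name, rho, sigma) {
  switch(name,
    lda = .ex_slater(rho) + .ec_vwn(rho, 5),
    pbe = .ex_pbe(rho, sigma) + .ec_pbe(rho, sigma),
    pbe0 = 0.75 * .ex_pbe(rho, sigma) + .ec_pbe(rho, sigma),
    # B3LYP: 0.2 HF + 0.8 Slater + 0.72 (B88 - Slater) + 0.81 LYP
    #        + 0.19 VWN;  .ex_b88 returns the full B88 exchange
    b3lyp = 0.08 * .ex_slater(rho) + 0.72 * .ex_b88(rho, sigma)
          + 0.81 * .ec_lyp(rho, sigma) + 0.19 * .ec_vwn(rho, 3),
    b3lyp5 = 0.08 * .ex_slater(rho) + 0.72 * .ex_b88(rho, sigma)
           + 0.81 * .ec_lyp(rho, sigma) + 0.19 * .ec_vwn(rho, 5),
    stop("no XC density for ", name))
}

# potentials by central differences of the energy density
.xc_potentials <- function(name, rho, sigma) {
  hr <- pmax(1e-7 * rho, 1e-12)
  vrho <- (.exc_density(name, rho + hr, sigma)
           - .exc_density(name, rho - hr, sigma)) / (2 * hr)
  hs <- pmax(1e-7 * sigma, 1e-12)
  vsig <- (.exc_density(name, rho, sigma + hs)
           - .exc_density(name, rho, pmax(sigma - hs, 0))) /
          (hs + pmin(sigma, hs))
  list(vrho = vrho, vsigma = vsig)
}

# --- molecular quadrature grid --------------------------------------------

.bragg_radius <- c(H = 0.35, He = 0.28, Li = 1.45, Be = 1.05, B = 0.85,
                   C = 0.70, N = 0.65, O = 0.60, F = 0.50, Ne = 0.45)

# product angular grid: Gauss-Legendre in cos(theta) x uniform phi
.angular_grid <- function(ntheta) {
  gl <- .gauss_legendre(ntheta)
  nphi <- 2 * ntheta
  phi <- (seq_len(nphi) - 0.5) * 2 * pi / nphi
  ct <- gl$x
  st <- sqrt(pmax(1 - ct^2, 0))
  pts <- NULL
  wts <- NULL
  for (i in seq_len(ntheta)) {
    pts <- rbind(pts, cbind(st[i] * cos(phi), st[i] * sin(phi),
                            rep(ct[i], nphi)))
    wts <- c(wts, rep(gl$w[i] * 2 * pi / nphi, nphi))
  }
  list(pts = pts, w = wts / (4 * pi))
}

.gauss_legendre <- function(n) {
  # Golub-Welsch via symmetric tridiagonal eigenproblem
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(x = x[ord], w = w[ord])
}

# Becke smoothing function, 3 iterations
.becke_f <- function(mu) {
  p <- mu
  for (i in 1:3) p <- 1.5 * p - 0.5 * p^3
  p
}

#' Molecular integration grid
#'
#' Becke-partitioned atom-centered grid: Gauss-Chebyshev radial points with
#' the Becke radial map, a Gauss-Legendre x uniform-phi angular product
#' grid, and three-iteration Becke cell functions. Deterministic for a
#' fixed geometry, so embedded and full-system functional evaluations share
#' identical quadrature.
#'
#' @param geom a [geometry()]
#' @param nrad radial points per atom
#' @param ntheta polar angular points (azimuthal count is `2*ntheta`)
#' @return list with `pts` (n x 3, bohr) and `w` (weights)
#' @export
build_grid <- function(geom, nrad = 50, ntheta = 14) {
  ang <- .angular_grid(ntheta)
  natm <- length(geom$atoms)
  coords <- geom$coords / .BOHR
  allpts <- NULL
  allw <- NULL
  for (ia in seq_len(natm)) {
    Rb <- .bragg_radius[geom$atoms[ia]]
    if (geom$atoms[ia] != "H") Rb <- Rb  # Becke: half Bragg handled via map
    i <- seq_len(nrad)
    x <- cos(i * pi / (nrad + 1))
    r <- Rb * (1 + x) / (1 - x)
    wch <- pi / (nrad + 1) * sin(i * pi / (nrad + 1))^2
    # dr/dx = 2 Rb / (1-x)^2 ; quadrature in x with weight wch/sqrt(1-x^2)
    wr <- wch / sqrt(1 - x^2) * 2 * Rb / (1 - x)^2 * r^2
    keep <- r < 40
    r <- r[keep]; wr <- wr[keep]
    pts <- matrix(0, 0, 3)
    w <- numeric(0)
    for (k in seq_along(r)) {
      pts <- rbind(pts, sweep(ang$pts * r[k], 2, coords[ia, ], "+"))
      w <- c(w, ang$w * wr[k] * 4 * pi)
    }
    # Becke partition weights
    if (natm > 1) {
      d_at <- sapply(seq_len(natm), function(j)
        sqrt(rowSums(sweep(pts, 2, coords[j, ], "-")^2)))
      Rij <- as.matrix(dist(coords))
      P <- matrix(1, nrow(pts), natm)
      for (i1 in seq_len(natm)) for (j1 in seq_len(natm)) {
        if (i1 == j1) next
        mu <- (d_at[, i1] - d_at[, j1]) / Rij[i1, j1]
        P[, i1] <- P[, i1] * 0.5 * (1 - .becke_f(mu))
      }
      wb <- P[, ia] / rowSums(P)
      w <- w * wb
    }
    allpts <- rbind(allpts, pts)
    allw <- c(allw, w)
  }
  list(pts = allpts, w = allw)
}

# density and gradient on grid from AO values
.grid_density <- function(aoval, D) {
  ao <- aoval$ao
  rho <- rowSums((ao %*% D) * ao)
  dx <- 2 * rowSums((ao %*% D) * aoval$dx)
  dy <- 2 * rowSums((ao %*% D) * aoval$dy)
  dz <- 2 * rowSums((ao %*% D) * aoval$dz)
  list(rho = rho, sigma = dx^2 + dy^2 + dz^2, dx = dx, dy = dy, dz = dz)
}

# XC energy and potential matrix for density matrix D (spin-summed)
.xc_matrix <- function(name, sys, grid, aoval, D) {
  den <- .grid_density(aoval, D)
  rho <- pmax(den$rho, 0)
  ok <- rho > 1e-12
  exc <- sum(grid$w[ok] * .exc_density(name, rho[ok], den$sigma[ok]))
  pot <- .xc_potentials(name, rho[ok], den$sigma[ok])
  n <- ncol(aoval$ao)
  ao <- aoval$ao[ok, , drop = FALSE]
  wv <- grid$w[ok] * pot$vrho
  V <- crossprod(ao * wv, ao)
  # gradient part: 2 vsigma grad rho . (grad phi_p phi_q + phi_p grad phi_q)
  wgx <- grid$w[ok] * 2 * pot$vsigma * den$dx[ok]
  wgy <- grid$w[ok] * 2 * pot$vsigma * den$dy[ok]
  wgz <- grid$w[ok] * 2 * pot$vsigma * den$dz[ok]
  Gp <- crossprod(aoval$dx[ok, , drop = FALSE] * wgx, ao) +
        crossprod(aoval$dy[ok, , drop = FALSE] * wgy, ao) +
        crossprod(aoval$dz[ok, , drop = FALSE] * wgz, ao)
  V <- V + Gp + t(Gp)
  list(exc = exc, V = 0.5 * (V + t(V)))
}
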