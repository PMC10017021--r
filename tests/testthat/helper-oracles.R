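# Independent oracles used across the suite. These deliberately avoid the
# package's McMurchie-Davidson / Slater-Condon / MPO code paths.

# ---- Gauss-Hermite overlap quadrature oracle ------------------------------
# AO values evaluated directly from the shell data in plain R (polynomial
# times Gaussian, spherical-harmonic d transform), integrated on a product
# Gauss-Hermite grid exact for polynomial x Gaussian integrands.

.oracle_sph_d <- function(cart) {
  # cart: (xx, xy, xz, yy, yz, zz) -> (xy, yz, z2, xz, x2-y2)
  s3 <- sqrt(3)
  c(s3 * cart[2], s3 * cart[5],
    cart[6] - 0.5 * (cart[1] + cart[4]),
    s3 * cart[3], 0.5 * s3 * (cart[1] - cart[4]))
}

# value of every spherical component of one shell at a point (bohr)
.oracle_shell_value <- function(shell, p) {
  d <- p - shell$center
  r2 <- sum(d^2)
  g <- sum(shell$coef * exp(-shell$exp * r2))
  if (shell$l == 0) return(g)
  if (shell$l == 1) return(g * d)
  cart <- c(d[1]^2, d[1] * d[2], d[1] * d[3], d[2]^2, d[2] * d[3], d[3]^2)
  g * .oracle_sph_d(cart)
}

.gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

# numerical overlap of the AO blocks of two shells. The quadrature is
# applied primitive pair by primitive pair so the integrand divided by
# the pair's own Gaussian envelope is an exact polynomial: Gauss-Hermite
# is then exact (degree <= 4 polynomials, npts >= 5 is generous).
oracle_overlap_block <- function(sa, sb, npts = 8) {
  gh <- .gauss_hermite(npts)
  na <- 2 * sa$l + 1; nb <- 2 * sb$l + 1
  acc <- matrix(0, na, nb)
  prim_val <- function(center, l, pt) {
    d <- pt - center
    if (l == 0) return(1)
    if (l == 1) return(d)
    cart <- c(d[1]^2, d[1] * d[2], d[1] * d[3], d[2]^2, d[2] * d[3], d[3]^2)
    .oracle_sph_d(cart)
  }
  for (ia in seq_along(sa$exp)) for (ib in seq_along(sb$exp)) {
    a <- sa$exp[ia]; b <- sb$exp[ib]
    p <- a + b
    P <- (a * sa$center + b * sb$center) / p
    pref <- sa$coef[ia] * sb$coef[ib] *
      exp(-a * b / p * sum((sa$center - sb$center)^2))
    x <- gh$x / sqrt(p)
    w <- gh$w / sqrt(p)
    blk <- matrix(0, na, nb)
    for (i in seq_len(npts)) for (j in seq_len(npts))
      for (k in seq_len(npts)) {
        pt <- P + c(x[i], x[j], x[k])
        va <- prim_val(sa$center, sa$l, pt)
        vb <- prim_val(sb$center, sb$l, pt)
        blk <- blk + w[i] * w[j] * w[k] * outer(va, vb)
      }
    acc <- acc + pref * blk
  }
  acc
}

# ---- 2x2 symmetric Roothaan closed form for H2 ----------------------------
oracle_h2_rhf <- function(sys) {
  S12 <- sys$S[1, 2]
  c1 <- 1 / sqrt(2 * (1 + S12))
  C <- c(c1, c1)
  D <- 2 * outer(C, C)
  J <- matrix(0, 2, 2); K <- matrix(0, 2, 2)
  for (p in 1:2) for (q in 1:2) for (r in 1:2) for (s in 1:2) {
    J[p, q] <- J[p, q] + sys$eri[p, q, r, s] * D[r, s]
    K[p, q] <- K[p, q] + sys$eri[p, r, q, s] * D[r, s]
  }
  sum(D * sys$hcore) + 0.5 * sum(D * (J - 0.5 * K)) + sys$enuc
}

# ---- dense-loop two-electron contraction ----------------------------------
oracle_jk_dense <- function(eri, D) {
  n <- nrow(D)
  J <- matrix(0, n, n); K <- matrix(0, n, n)
  for (p in seq_len(n)) for (q in seq_len(n))
    for (r in seq_len(n)) for (s in seq_len(n)) {
      J[p, q] <- J[p, q] + eri[p, q, r, s] * D[r, s]
      K[p, q] <- K[p, q] + eri[p, r, q, s] * D[r, s]
    }
  list(J = J, K = K)
}

# ---- quadruple-loop AO->MO transform --------------------------------------
oracle_ao2mo <- function(eri, B) {
  n <- dim(eri)[1]; m <- ncol(B)
  out <- array(0, rep(m, 4))
  for (p in seq_len(m)) for (q in seq_len(m))
    for (r in seq_len(m)) for (s in seq_len(m)) {
      v <- 0
      for (a in seq_len(n)) for (b in seq_len(n))
        for (c in seq_len(n)) for (d in seq_len(n))
          v <- v + B[a, p] * B[b, q] * B[c, r] * B[d, s] * eri[a, b, c, d]
      out[p, q, r, s] <- v
    }
  out
}

# ---- dense Fock-space Hamiltonian via Jordan-Wigner kron ------------------
# Full 4^k-dimensional second-quantized Hamiltonian built from explicit
# creation/annihilation matrices; completely independent of the package's
# Slater-Condon and MPO code.
oracle_fock_space <- function(h, eri) {
  k <- nrow(h)
  n <- 2 * k # modes: 1up, 1dn, 2up, 2dn, ...
  dim <- 2^n
  sm <- matrix(c(0, 0, 1, 0), 2, 2) # annihilator |0><1|
  Z <- diag(c(1, -1))
  I2 <- diag(2)
  ann <- vector("list", n)
  for (m in seq_len(n)) {
    op <- 1
    for (j in seq_len(n)) {
      f <- if (j < m) Z else if (j == m) sm else I2
      op <- kronecker(op, f)
    }
    ann[[m]] <- op
  }
  cre <- lapply(ann, t)
  mode <- function(p, spin) 2 * (p - 1) + spin # spin 1 = up, 2 = dn
  H <- matrix(0, dim, dim)
  for (p in seq_len(k)) for (q in seq_len(k)) {
    if (h[p, q] == 0) next
    for (s in 1:2)
      H <- H + h[p, q] * cre[[mode(p, s)]] %*% ann[[mode(q, s)]]
  }
  for (p in seq_len(k)) for (q in seq_len(k))
    for (r in seq_len(k)) for (s in seq_len(k)) {
      v <- eri[p, q, r, s] # chemist (pq|rs)
      if (v == 0) next
      for (s1 in 1:2) for (s2 in 1:2) {
        H <- H + 0.5 * v * cre[[mode(p, s1)]] %*% cre[[mode(r, s2)]] %*%
          ann[[mode(s, s2)]] %*% ann[[mode(q, s1)]]
      }
    }
  H
}

# number and Sz operators in the same Fock space
oracle_fock_numbers <- function(k) {
  n <- 2 * k
  sm <- matrix(c(0, 0, 1, 0), 2, 2)
  Z <- diag(c(1, -1)); I2 <- diag(2)
  Nop <- 0; Szop <- 0
  for (m in seq_len(n)) {
    op <- 1
    for (j in seq_len(n)) op <- kronecker(op, if (j == m) t(sm) %*% sm else I2)
    Nop <- Nop + op
    Szop <- Szop + (if (m %% 2 == 1) 0.5 else -0.5) * op
  }
  list(N = Nop, Sz = Szop)
}

# ground-state energy in the (nelec, Sz=0) sector
oracle_sector_ground <- function(h, eri, nelec) {
  k <- nrow(h)
  H <- oracle_fock_space(h, eri)
  nums <- oracle_fock_numbers(k)
  nd <- diag(nums$N); sz <- diag(nums$Sz)
  sel <- which(abs(nd - nelec) < 1e-9 & abs(sz) < 1e-9)
  Hs <- H[sel, sel]
  min(eigen(0.5 * (Hs + t(Hs)), symmetric = TRUE, only.values = TRUE)$values)
}

# random 8-fold-symmetric two-electron tensor
random_sym_eri <- function(n, seed) {
  set.seed(seed)
  eri <- array(rnorm(n^4), rep(n, 4))
  sym <- array(0, rep(n, 4))
  for (p in 1:n) for (q in 1:n) for (r in 1:n) for (s in 1:n)
    sym[p, q, r, s] <- mean(c(
      eri[p, q, r, s], eri[q, p, r, s], eri[p, q, s, r], eri[q, p, s, r],
      eri[r, s, p, q], eri[s, r, p, q], eri[r, s, q, p], eri[s, r, q, p]))
  sym
}

random_active_ham <- function(norb, nelec, seed, e_core = 0) {
  set.seed(seed)
  h <- matrix(rnorm(norb^2), norb)
  h <- 0.5 * (h + t(h))
  structure(list(norb = norb, nelec = as.integer(nelec), h = h,
                 eri = random_sym_eri(norb, seed + 1), e_core = e_core),
            class = "qc_active_ham")
}
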