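# Matrix-product-state machinery over spatial-orbital sites with local
# dimension 4. Local basis order: |0>, |dn>, |up>, |updn>, with
# |updn> = a+_up a+_dn |0>; mode ordering interleaves up before down
# within each site along the chain.

# local occupation and 2*Sz per basis state
.LOC_N <- c(0L, 1L, 1L, 2L)
.LOC_SZ <- c(0L, -1L, 1L, 0L)

.mps <- function(tensors, center = 1L) {
  structure(list(tensors = tensors, center = as.integer(center)),
            class = "qc_mps")
}

#' @export
print.qc_mps <- function(x, ...) {
  bd <- mps_bond_dims(x)
  cat(sprintf("<qc_mps: %d sites, bond dims %s, center %d>\n",
              length(x$tensors), paste(bd, collapse = ","), x$center))
  invisible(x)
}

#' Bond dimensions of an MPS
#' @param mps a `qc_mps`
#' @return integer vector of the k-1 internal bond dimensions
#' @export
mps_bond_dims <- function(mps) {
  k <- length(mps$tensors)
  if (k < 2) return(integer(0))
  vapply(seq_len(k - 1), function(i) dim(mps$tensors[[i]])[3], integer(1))
}

#' Product-state MPS from local basis indices
#' @param states integer vector of local states (1 = empty, 2 = down,
#'   3 = up, 4 = doubly occupied)
#' @return a `qc_mps` with unit bond dimensions
#' @export
mps_product_state <- function(states) {
  tensors <- lapply(states, function(s) {
    a <- array(0, c(1, 4, 1))
    a[1, s, 1] <- 1
    a
  })
  .mps(tensors, center = length(states))
}

#' Recontract an MPS to the full occupation-basis tensor
#' @param mps a `qc_mps` (small systems only: 4^k coefficients)
#' @return numeric vector of length `4^k`, site-1 index fastest
#' @export
mps_contract_full <- function(mps) {
  k <- length(mps$tensors)
  v <- matrix(mps$tensors[[1]][1, , ], nrow = 4) # 4 x M1
  if (k == 1) return(as.vector(v))
  for (i in 2:k) {
    A <- mps$tensors[[i]]
    d <- dim(A)
    # v: (4^{i-1}) x Ml ; A: Ml x 4 x Mr -> result (4^i) x Mr
    M <- matrix(A, d[1], 4 * d[3])
    vn <- v %*% M # (4^{i-1}) x (4*Mr)
    v <- matrix(array(vn, c(nrow(v) * 4, d[3])), nrow(v) * 4, d[3])
  }
  as.vector(v)
}

#' Overlap of two MPS
#' @param m1,m2 `qc_mps` objects over the same chain
#' @return scalar overlap
#' @export
mps_overlap <- function(m1, m2) {
  k <- length(m1$tensors)
  E <- matrix(1, 1, 1)
  for (i in seq_len(k)) {
    A <- m1$tensors[[i]]; B <- m2$tensors[[i]]
    da <- dim(A); db <- dim(B)
    En <- matrix(0, da[3], db[3])
    for (s in 1:4)
      En <- En + t(matrix(A[, s, ], da[1], da[3])) %*% E %*%
                 matrix(B[, s, ], db[1], db[3])
    E <- En
  }
  E[1, 1]
}

#' Norm of an MPS
#' @param mps a `qc_mps`
#' @return scalar norm
#' @export
mps_norm <- function(mps) sqrt(abs(mps_overlap(mps, mps)))

# left-orthonormalize site i, pushing the remainder into site i+1
.mps_push_right <- function(mps, i) {
  A <- mps$tensors[[i]]
  d <- dim(A)
  M <- matrix(A, d[1] * 4, d[3])
  qr_ <- qr(M)
  r <- min(dim(M))
  Q <- qr.Q(qr_)[, seq_len(r), drop = FALSE]
  R <- qr.R(qr_)[seq_len(r), , drop = FALSE]
  mps$tensors[[i]] <- array(Q, c(d[1], 4, r))
  B <- mps$tensors[[i + 1]]
  db <- dim(B)
  Bn <- R %*% matrix(B, db[1], 4 * db[3])
  mps$tensors[[i + 1]] <- array(Bn, c(r, 4, db[3]))
  mps
}

# right-orthonormalize site i, pushing remainder into site i-1
.mps_push_left <- function(mps, i) {
  A <- mps$tensors[[i]]
  d <- dim(A)
  M <- matrix(A, d[1], 4 * d[3])
  qr_ <- qr(t(M))
  r <- min(dim(M))
  Q <- qr.Q(qr_)[, seq_len(r), drop = FALSE] # (4 Mr) x r
  R <- qr.R(qr_)[seq_len(r), , drop = FALSE] # r x Ml
  mps$tensors[[i]] <- array(t(Q), c(r, 4, d[3]))
  B <- mps$tensors[[i - 1]]
  db <- dim(B)
  Bn <- matrix(B, db[1] * 4, db[3]) %*% t(R)
  mps$tensors[[i - 1]] <- array(Bn, c(db[1], 4, r))
  mps
}

#' Bring an MPS to mixed-canonical form
#' @param mps a `qc_mps`
#' @param center canonical center site
#' @return a `qc_mps` with left/right orthonormal flanks
#' @export
mps_canonicalize <- function(mps, center = 1L) {
  k <- length(mps$tensors)
  if (center < 1 || center > k) stop("invalid center")
  if (center > 1)
    for (i in seq_len(center - 1)) mps <- .mps_push_right(mps, i)
  if (center < k)
    for (i in seq(k, center + 1)) mps <- .mps_push_left(mps, i)
  mps$center <- as.integer(center)
  mps
}

mps_normalize <- function(mps) {
  nrm <- mps_norm(mps)
  c0 <- mps$center
  mps$tensors[[c0]] <- mps$tensors[[c0]] / nrm
  mps
}

# direct-sum addition c1*m1 + c2*m2 (bond dims add)
mps_add <- function(m1, m2, c1 = 1, c2 = 1) {
  k <- length(m1$tensors)
  tensors <- vector("list", k)
  for (i in seq_len(k)) {
    A <- m1$tensors[[i]]; B <- m2$tensors[[i]]
    da <- dim(A); db <- dim(B)
    l1 <- if (i == 1) 1L else da[1] + db[1]
    r1 <- if (i == k) 1L else da[3] + db[3]
    Tn <- array(0, c(l1, 4, r1))
    if (i == 1) {
      Tn[1, , seq_len(da[3])] <- c1 * A[1, , ]
      Tn[1, , da[3] + seq_len(db[3])] <- c2 * B[1, , ]
    } else if (i == k) {
      Tn[seq_len(da[1]), , 1] <- A[, , 1]
      Tn[da[1] + seq_len(db[1]), , 1] <- B[, , 1]
    } else {
      Tn[seq_len(da[1]), , seq_len(da[3])] <- A
      Tn[da[1] + seq_len(db[1]), , da[3] + seq_len(db[3])] <- B
    }
    tensors[[i]] <- Tn
  }
  .mps(tensors, center = 1L)
}

#' Truncate a two-site tensor by dynamical block state selection
#'
#' SVD of the two-site wavefunction tensor; keeps the smallest bond
#' dimension in `[m_min, m_max]` whose discarded Schmidt weight does not
#' exceed the preset truncation error. If the target is unattainable at
#' `m_max`, `m_max` states are kept and the overrun is flagged (data, not
#' an error).
#'
#' @param W two-site tensor, dim `(Ml, 4, 4, Mr)`, assumed normalized
#' @param tre_target preset truncation error (discarded weight)
#' @param m_min,m_max bond-dimension bounds
#' @return list: `left` (Ml x 4 x m, left-orthonormal), `right`
#'   (m x 4 x Mr), `sv` (kept singular values, absorbed into `right`),
#'   `discarded` weight, `m`, `overrun` flag
#' @export
dbss_truncate <- function(W, tre_target, m_min = 1, m_max = Inf) {
  d <- dim(W)
  M <- matrix(W, d[1] * 4, 4 * d[4])
  sv <- svd(M)
  lam2 <- sv$d^2
  tot <- sum(lam2)
  rank_full <- sum(sv$d > 1e-14)
  discarded_at <- function(m) (tot - sum(lam2[seq_len(m)])) / tot
  m <- NA
  for (mm in seq_len(min(rank_full, m_max))) {
    if (mm >= m_min && discarded_at(mm) <= tre_target) { m <- mm; break }
  }
  overrun <- FALSE
  if (is.na(m)) {
    m <- min(rank_full, m_max)
    m <- max(m, min(m_min, rank_full))
    overrun <- discarded_at(m) > tre_target
  }
  disc <- discarded_at(m)
  U <- sv$u[, seq_len(m), drop = FALSE]
  SVt <- diag(sv$d[seq_len(m)], m, m) %*%
         t(sv$v[, seq_len(m), drop = FALSE])
  list(left = array(U, c(d[1], 4, m)),
       right = array(SVt / sqrt(max(1 - disc, 1e-300)), c(m, 4, d[4])),
       sv = sv$d[seq_len(m)],
       discarded = disc, m = m, overrun = overrun)
}

#' Exact MPS factorization of an FCI occupation tensor
#'
#' Factorizes a coefficient tensor over the occupation basis (index of
#' site 1 fastest) into matrix-product form by successive SVD. With no
#' truncation the MPS reconstructs every coefficient to machine
#' precision; with a bond-dimension cap the squared reconstruction error
#' equals the sum of discarded Schmidt weights.
#'
#' @param fci_tensor numeric vector of length `4^n_orb`
#' @param n_orb number of orbitals (sites), at most 8
#' @param m_max optional bond-dimension cap
#' @return a `qc_mps`; attribute `discarded` holds per-bond discarded
#'   Schmidt weights
#' @export
exact_mps_from_fci <- function(fci_tensor, n_orb, m_max = Inf) {
  if (length(fci_tensor) != 4^n_orb)
    stop("tensor length ", length(fci_tensor), " inconsistent with 4^",
         n_orb)
  if (n_orb > 8) stop("exact factorization limited to 8 orbitals")
  tensors <- vector("list", n_orb)
  rest <- matrix(fci_tensor, nrow = 4) # (Ml*4) x rest with Ml = 1
  Ml <- 1
  discarded <- numeric(0)
  for (i in seq_len(n_orb)) {
    if (i == n_orb) {
      tensors[[i]] <- array(rest, c(Ml, 4, 1))
      break
    }
    sv <- svd(rest)
    r <- sum(sv$d > 1e-14)
    m <- min(r, m_max)
    lam2 <- sv$d^2
    discarded <- c(discarded, (sum(lam2) - sum(lam2[seq_len(m)])) /
                     max(sum(lam2), 1e-300))
    U <- sv$u[, seq_len(m), drop = FALSE]
    tensors[[i]] <- array(U, c(Ml, 4, m))
    SVt <- diag(sv$d[seq_len(m)], m, m) %*%
           t(sv$v[, seq_len(m), drop = FALSE])
    # reshape remainder: (m) x 4^{n-i} -> (m*4) x 4^{n-i-1}
    ncolr <- ncol(SVt)
    rest <- matrix(array(aperm(array(SVt, c(m, 4, ncolr / 4)),
                               c(1, 2, 3)), c(m * 4, ncolr / 4)),
                   m * 4, ncolr / 4)
    Ml <- m
  }
  out <- .mps(tensors, center = n_orb)
  attr(out, "discarded") <- discarded
  out
}

#' Map a determinant CI vector to an occupation-basis tensor
#'
#' Converts `(alpha string, beta string)` determinant amplitudes into
#' the interleaved-mode occupation tensor consumed by
#' [exact_mps_from_fci()], including the fermionic reordering signs.
#'
#' @param ci CI coefficient vector from [fci_solve()]
#' @param strings_a,strings_b bitmask string lists from [fci_solve()]
#' @param norb orbital count
#' @return numeric vector of length `4^norb`
#' @export
fci_vector_to_occ_tensor <- function(ci, strings_a, strings_b, norb) {
  nA <- length(strings_a); nB <- length(strings_b)
  tens <- numeric(4^norb)
  bitsof <- function(s) which(bitwAnd(s, 2^(seq_len(norb) - 1)) != 0)
  for (ib in seq_len(nB)) {
    occ_b <- bitsof(strings_b[ib])
    for (ia in seq_len(nA)) {
      cval <- ci[(ib - 1) * nA + ia]
      if (abs(cval) < 1e-300) next
      occ_a <- bitsof(strings_a[ia])
      # local states: 1=|0>,2=|dn>,3=|up>,4=|updn>
      loc <- rep(1L, norb)
      loc[occ_a] <- loc[occ_a] + 2L
      loc[occ_b] <- loc[occ_b] + 1L
      # sign: reorder (alpha asc)(beta asc) -> interleaved per site
      sgn <- 1
      for (j in occ_b) {
        crossings <- sum(occ_a > j)
        if (crossings %% 2 == 1) sgn <- -sgn
      }
      idx <- 1 + sum((loc - 1L) * 4^(seq_len(norb) - 1))
      tens[idx] <- tens[idx] + sgn * cval
    }
  }
  tens
}
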