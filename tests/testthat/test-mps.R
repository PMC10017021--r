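# MPS factorization and DBSS truncation.

test_that("a product determinant factorizes with unit bond dimensions", {
  # |updn, 0, updn> occupation tensor
  tens <- numeric(4^3)
  idx <- 1 + (4 - 1) * 1 + (1 - 1) * 4 + (4 - 1) * 16
  tens[idx] <- 1
  mps <- exact_mps_from_fci(tens, 3)
  expect_equal(mps_bond_dims(mps), c(1L, 1L))
  expect_equal(mps_contract_full(mps), tens, tolerance = 1e-14)
})

test_that("random 2-orbital tensors reconstruct exactly", {
  set.seed(5)
  t2 <- rnorm(16)
  t2 <- t2 / sqrt(sum(t2^2))
  mps <- exact_mps_from_fci(t2, 2)
  expect_lte(max(mps_bond_dims(mps)), 4L)
  expect_equal(mps_contract_full(mps), t2, tolerance = 1e-12)
})

test_that("truncation error follows the Eckart-Young identity", {
  set.seed(6)
  t4 <- rnorm(256)
  t4 <- t4 / sqrt(sum(t4^2))
  # with m_max >= 4 only the central bond (Schmidt rank up to 16) is
  # truncated, so the squared reconstruction error equals the discarded
  # Schmidt weight exactly (Eckart-Young)
  for (m in c(4, 8, 12)) {
    mps <- exact_mps_from_fci(t4, 4, m_max = m)
    rec <- mps_contract_full(mps)
    err2 <- sum((rec - t4)^2)
    disc <- attr(mps, "discarded")
    expect_equal(err2, sum(disc), tolerance = 1e-10)
  }
  # no truncation: machine-precision reconstruction
  mps <- exact_mps_from_fci(t4, 4)
  expect_equal(mps_contract_full(mps), t4, tolerance = 1e-12)
  expect_error(exact_mps_from_fci(t4[-1], 4), "inconsistent")
})

test_that("dbss_truncate selects the smallest compliant rank", {
  # hand-built Schmidt weights {0.6, 0.3, 0.09, 0.01}
  lam <- sqrt(c(0.6, 0.3, 0.09, 0.01))
  U <- qr.Q(qr(matrix(rnorm(16), 4)))
  V <- qr.Q(qr(matrix(rnorm(16), 4)))
  M <- U %*% diag(lam) %*% t(V)
  W <- array(M, c(1, 4, 4, 1))
  tr <- dbss_truncate(W, tre_target = 0.05)
  expect_equal(tr$m, 3L)
  expect_equal(tr$discarded, 0.01, tolerance = 1e-10)
  expect_false(tr$overrun)
  # lossless limit keeps the full Schmidt rank
  tr0 <- dbss_truncate(W, tre_target = 0)
  expect_equal(tr0$m, 4L)
  # m_max overrun is data, not an error
  trx <- dbss_truncate(W, tre_target = 0, m_max = 2)
  expect_equal(trx$m, 2L)
  expect_true(trx$overrun)
  expect_equal(trx$discarded, 0.1, tolerance = 1e-10)
  # normalization identity: discarded = 1 - sum of kept weights
  expect_equal(trx$discarded, 1 - sum(trx$sv^2), tolerance = 1e-12)
})

test_that("determinant vectors map to occupation tensors consistently", {
  # FCI ground state of H2 -> occupation tensor -> MPS expectation
  f <- fci_h2()
  tens <- fci_vector_to_occ_tensor(f$ci_vector, f$strings_a,
                                   f$strings_b, 2)
  expect_equal(sum(tens^2), 1, tolerance = 1e-12)
  mps <- exact_mps_from_fci(tens, 2)
  expect_equal(mps_norm(mps), 1, tolerance = 1e-10)
})
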