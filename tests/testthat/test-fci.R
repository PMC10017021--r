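# Determinant FCI oracle.

test_that("one electron in two orbitals reduces to the h eigenvalue", {
  ham <- random_active_ham(2, 1, seed = 21, e_core = 0.7)
  ham$eri[] <- 0 # one electron: no two-body part contributes anyway
  f <- fci_solve(ham)
  expect_equal(f$energy,
               min(eigen(ham$h, symmetric = TRUE)$values) + 0.7,
               tolerance = 1e-10)
})

test_that("H2 FCI matches an explicit 4x4 CI matrix", {
  ham <- ham_h2()
  # determinant basis (Sz=0, 2 orbitals): |11>, |12>, |21>, |22> as
  # (alpha-string, beta-string) pairs; build H by hand from integrals
  h <- ham$h; eri <- ham$eri
  E1 <- function(i, j) 2 * h[i, i] * (i == j)
  diag_e <- function(ia, ib) {
    h[ia, ia] + h[ib, ib] + eri[ia, ia, ib, ib]
  }
  H <- matrix(0, 4, 4)
  occ <- list(c(1, 1), c(1, 2), c(2, 1), c(2, 2))
  for (i in 1:4) H[i, i] <- diag_e(occ[[i]][1], occ[[i]][2])
  # single excitations (alpha or beta hop), Slater-Condon
  sc1 <- function(p, q, other) h[p, q] + eri[p, q, other, other]
  H[1, 2] <- sc1(1, 2, 1); H[1, 3] <- sc1(1, 2, 1)
  H[2, 4] <- sc1(1, 2, 2); H[3, 4] <- sc1(1, 2, 2)
  H[1, 4] <- eri[1, 2, 1, 2]
  H[2, 3] <- eri[1, 2, 2, 1]
  H[lower.tri(H)] <- t(H)[lower.tri(H)]
  e_ref <- min(eigen(H, symmetric = TRUE)$values) + ham$e_core
  expect_equal(fci_h2()$energy, e_ref, tolerance = 1e-10)
})

test_that("FCI agrees with the dense Fock-space Jordan-Wigner oracle", {
  ham <- random_active_ham(3, 4, seed = 31, e_core = -0.2)
  f <- fci_solve(ham)
  e_ref <- oracle_sector_ground(ham$h, ham$eri, 4) + ham$e_core
  expect_equal(f$energy, e_ref, tolerance = 1e-9)
  # 1-RDM sanity: trace and eigenvalue range
  expect_equal(sum(diag(f$one_rdm)), 4, tolerance = 1e-9)
  evs <- eigen(f$one_rdm, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(evs > -1e-10 & evs < 2 + 1e-10))
})

test_that("expectation values follow the variational structure", {
  ham <- ham_h4()
  f <- fci_h4()
  # eigenvector reproduces its eigenvalue
  expect_equal(fci_expectation(f$ci_vector, ham), f$energy,
               tolerance = 1e-10)
  # aufbau determinant gives the mean-field energy in the active space
  d <- f$dim
  v <- numeric(d)
  v[qcembed:::.aufbau_index(ham$norb, ham$nelec)] <- 1
  e_det <- fci_expectation(v, ham)
  nocc <- ham$nelec %/% 2
  e_hand <- ham$e_core
  for (i in seq_len(nocc)) e_hand <- e_hand + 2 * ham$h[i, i]
  for (i in seq_len(nocc)) for (j in seq_len(nocc))
    e_hand <- e_hand + 2 * ham$eri[i, i, j, j] - ham$eri[i, j, j, i]
  expect_equal(e_det, e_hand, tolerance = 1e-10)
  # any normalized vector sits at or above the ground state
  set.seed(77)
  r <- rnorm(d); r <- r / sqrt(sum(r^2))
  expect_gte(fci_expectation(r, ham), f$energy - 1e-12)
  expect_error(fci_expectation(r[-1], ham), "determinant space")
  expect_error(fci_expectation(2 * r, ham), "normalized")
})

test_that("energy is invariant under orbital reordering", {
  ham <- random_active_ham(4, 4, seed = 41)
  perm <- c(3, 1, 4, 2)
  ham2 <- ham
  ham2$h <- ham$h[perm, perm]
  ham2$eri <- ham$eri[perm, perm, perm, perm]
  expect_equal(fci_solve(ham)$energy, fci_solve(ham2)$energy,
               tolerance = 1e-10)
})

test_that("oversized determinant spaces are refused with a size report", {
  ham <- random_active_ham(4, 4, seed = 51)
  expect_error(fci_solve(ham, max_dim = 10), "too large")
  expect_error(fci_solve(ham, max_dim = 10), "36")
})
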