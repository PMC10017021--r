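# MPO compiler, sweeps, DBSS behavior, observables, Fiedler ordering.

test_that("one-orbital MPO reproduces the local 4x4 Hamiltonian", {
  ham <- random_active_ham(1, 2, seed = 61)
  mpo <- build_mpo(ham)
  # expectation on each local basis state: n(h11) pattern + (11|11) n_up n_dn
  h11 <- ham$h[1, 1]; v <- ham$eri[1, 1, 1, 1]
  exp_ref <- c(0, h11, h11, 2 * h11 + v)
  for (s in 1:4) {
    mps <- qcembed:::mps_product_state(s)
    expect_equal(mpo_expectation(mpo, mps), exp_ref[s], tolerance = 1e-12)
  }
})

test_that("MPO expectations equal determinant-space expectations", {
  # random CI vectors on a random 3-orbital Hamiltonian
  ham <- random_active_ham(3, 4, seed = 62)
  f <- fci_solve(ham)
  set.seed(63)
  for (rep in 1:3) {
    v <- rnorm(f$dim); v <- v / sqrt(sum(v^2))
    e_det <- fci_expectation(v, ham)
    tens <- fci_vector_to_occ_tensor(v, f$strings_a, f$strings_b, 3)
    mps <- exact_mps_from_fci(tens, 3)
    e_mpo <- mpo_expectation(build_mpo(ham), mps) + ham$e_core
    expect_equal(e_mpo, e_det, tolerance = 1e-9)
  }
})

test_that("H2 ground state: DMRG = dense CI oracle", {
  d <- run_dmrg(ham_h2(), sweep_config(tre_target = 1e-12, m_max = 8,
                                       seed = 2))
  expect_equal(d$energy, fci_h2()$energy, tolerance = 1e-8)
})

test_that("chain order does not change the ground-state energy", {
  ham <- ham_h4()
  cfg <- sweep_config(tre_target = 1e-10, m_max = 32, seed = 2,
                      davidson_tol = 1e-7)
  d1 <- run_dmrg(ham, cfg)
  cfg$ordering <- rev(seq_len(4))
  d2 <- run_dmrg(ham, cfg)
  expect_equal(d1$energy, d2$energy, tolerance = 1e-9)
  # back-permuted observables agree too
  expect_equal(d1$one_rdm, d2$one_rdm, tolerance = 1e-6)
})

test_that("H4: DMRG matches FCI in energy and 1-RDM", {
  d <- run_dmrg(ham_h4(), sweep_config(tre_target = 1e-11, m_max = 32,
                                       e_conv = 1e-9, seed = 2,
                                       davidson_tol = 1e-7))
  f <- fci_h4()
  expect_equal(d$energy, f$energy, tolerance = 1e-7)
  expect_lt(max(abs(d$one_rdm - f$one_rdm)), 1e-6)
  expect_equal(sum(diag(d$one_rdm)), 4, tolerance = 1e-8)
})

test_that("DMRG is variational and converges monotonically in m_max", {
  # stretched H4: strong correlation, truncation bites at small m
  sys <- build_system(fixture("h_chain", n = 4, r = 1.8), "sto-3g")
  mf <- run_mean_field(sys, "hf")
  ham <- transform_active_integrals(sys, sys$hcore, mf$C, 4,
                                    e_core = sys$enuc)
  f <- fci_solve(ham)
  gaps <- vapply(c(2, 4, 16), function(m) {
    d <- run_dmrg(ham, sweep_config(tre_target = 0, m_min = 1,
                                    m_max = m, seed = 2,
                                    max_sweeps = 8))
    d$energy - f$energy
  }, numeric(1))
  expect_true(all(gaps > -1e-9)) # variational bound
  expect_true(all(diff(gaps) <= 1e-9)) # monotone improvement
  expect_lt(gaps[3], 1e-7)
})

test_that("DBSS honors the preset truncation error or flags overruns", {
  d <- run_dmrg(ham_h4(), sweep_config(tre_target = 1e-6, m_max = 4,
                                       seed = 2))
  for (rec in d$discarded)
    expect_true(rec$discarded <= 1e-6 + 1e-12 || rec$overrun)
  # with a generous cap nothing may overrun
  d2 <- run_dmrg(ham_h4(), sweep_config(tre_target = 1e-8, m_max = 64,
                                        seed = 2))
  expect_false(any(vapply(d2$discarded, function(r) r$overrun,
                          logical(1))))
})

test_that("runs are bitwise reproducible for a fixed seed", {
  cfg <- sweep_config(tre_target = 1e-8, m_max = 16, seed = 7)
  d1 <- run_dmrg(ham_h4(), cfg)
  d2 <- run_dmrg(ham_h4(), cfg)
  expect_identical(d1$sweep_energies, d2$sweep_energies)
  expect_identical(d1$energy, d2$energy)
  m1 <- warmup_mps(ham_h4(), cfg)
  m2 <- warmup_mps(ham_h4(), cfg)
  expect_identical(m1$tensors, m2$tensors)
})

test_that("warm-up states are quantum-number valid and overlap the truth", {
  cfg <- sweep_config(m_min = 2, seed = 3)
  m <- warmup_mps(ham_h2(), cfg)
  expect_lte(max(mps_bond_dims(m)), 2L)
  expect_equal(mps_norm(m), 1, tolerance = 1e-10)
  # overlap with the FCI ground state at equilibrium exceeds 0.9
  f <- fci_h2()
  tens <- fci_vector_to_occ_tensor(f$ci_vector, f$strings_a,
                                   f$strings_b, 2)
  fmps <- exact_mps_from_fci(tens, 2)
  expect_gt(abs(qcembed:::mps_overlap(m, fmps)), 0.9)
  # both strategies land on the same variational fixed point
  e_det <- run_dmrg(ham_h4(), sweep_config(tre_target = 1e-10, m_max = 32,
                                           warmup = "determinant",
                                           seed = 3))$energy
  e_ent <- run_dmrg(ham_h4(), sweep_config(tre_target = 1e-10, m_max = 32,
                                           warmup = "entropy",
                                           seed = 3))$energy
  expect_equal(e_det, e_ent, tolerance = 1e-7)
})

test_that("canonical form and quantum numbers are conserved", {
  d <- run_dmrg(ham_h4(), sweep_config(tre_target = 1e-10, m_max = 32,
                                       seed = 2))
  psi <- d$mps
  k <- length(psi$tensors)
  psi <- qcembed:::mps_canonicalize(psi, k)
  for (i in seq_len(k - 1)) { # left-orthonormality
    A <- psi$tensors[[i]]
    dd <- dim(A)
    M <- matrix(A, dd[1] * 4, dd[3])
    expect_equal(crossprod(M), diag(dd[3]), tolerance = 1e-10)
  }
  expect_equal(mps_norm(psi), 1, tolerance = 1e-10)
  # bond quantum numbers are sharp integers; total flux = (nelec, 0)
  qn <- d$qnums
  for (b in seq_along(qn)) {
    expect_lt(max(abs(qn[[b]]$N - round(qn[[b]]$N))), 1e-6)
    expect_lt(max(abs(qn[[b]]$Sz - round(qn[[b]]$Sz))), 1e-6)
  }
  # weighted block particle numbers sum to the total across the chain
  expect_equal(sum(diag(d$one_rdm)), 4, tolerance = 1e-8)
})

test_that("sweep energies are non-increasing within solver tolerance", {
  d <- run_dmrg(ham_h4(), sweep_config(tre_target = 1e-10, m_max = 32,
                                       seed = 2))
  expect_true(all(diff(d$sweep_energies) < 1e-6))
})

test_that("one-particle RDM of simple states behaves correctly", {
  # single determinant: occupations exactly 0 or 2
  m <- qcembed:::mps_product_state(c(4L, 4L, 1L, 1L))
  G <- mps_one_rdm(m)
  expect_equal(diag(G), c(2, 2, 0, 0), tolerance = 1e-12)
  expect_equal(G[lower.tri(G)], rep(0, 6), tolerance = 1e-12)
  # dissociated H2: natural occupations near 1,1
  d <- run_dmrg(ham_h2_far(), sweep_config(tre_target = 1e-12,
                                           m_max = 8, seed = 2))
  occs <- eigen(d$one_rdm, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(occs, c(1, 1), tolerance = 0.05)
})

test_that("entropies and mutual information capture entanglement", {
  # product determinant: all zero
  m <- qcembed:::mps_product_state(c(4L, 1L, 4L))
  ent <- mps_entropies(m)
  expect_equal(ent$s1, rep(0, 3), tolerance = 1e-12)
  expect_equal(max(abs(ent$I)), 0, tolerance = 1e-12)
  # dissociated H2: the two sigma orbitals are maximally entangled
  d <- run_dmrg(ham_h2_far(), sweep_config(tre_target = 1e-12,
                                           m_max = 8, seed = 2))
  expect_gt(d$mutual_information[1, 2], 1.0)
  # H4: I symmetric and non-negative, s_i subadditive vs bond entropy
  d4 <- run_dmrg(ham_h4(), sweep_config(tre_target = 1e-10, m_max = 32,
                                        seed = 2))
  I <- d4$mutual_information
  expect_equal(I, t(I), tolerance = 1e-9)
  expect_true(all(I >= -1e-10))
  # subadditivity: sum_i s_i bounds the 1|234 bipartition entropy
  psi <- qcembed:::mps_canonicalize(d4$mps, 1)
  A1 <- psi$tensors[[1]]
  lam <- svd(matrix(A1, 4, dim(A1)[3]))$d^2
  lam <- lam[lam > 1e-14]
  s_cut <- -sum(lam * log(lam))
  expect_gte(sum(d4$entropies) + 1e-10, s_cut)
})

test_that("Fiedler ordering solves chains and respects components", {
  expect_equal(fiedler_ordering(matrix(0, 4, 4)), 1:4)
  # shuffled path graph: recovered up to global reversal
  k <- 6
  set.seed(8)
  perm <- sample(k)
  I <- matrix(0, k, k)
  for (i in 1:(k - 1)) {
    a <- perm[i]; b <- perm[i + 1]
    I[a, b] <- 1; I[b, a] <- 1
  }
  ord <- fiedler_ordering(I)
  expect_true(identical(ord, as.integer(perm)) ||
              identical(ord, as.integer(rev(perm))))
  # two decoupled blocks stay contiguous
  Ib <- matrix(0, 6, 6)
  blocks <- list(c(1, 3, 5), c(2, 4, 6))
  for (bl in blocks)
    for (i in bl) for (j in bl) if (i != j) Ib[i, j] <- 0.5
  ordb <- fiedler_ordering(Ib)
  pos <- match(blocks[[1]], ordb)
  expect_equal(diff(range(pos)), 2)
  expect_error(fiedler_ordering(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})
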