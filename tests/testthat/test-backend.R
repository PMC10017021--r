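# Integral engine and mean-field backend.

test_that("build_system produces valid AO systems", {
  sys <- sys_h2()
  expect_equal(sys$nao, 2L)
  expect_gt(sys$S[1, 2], 0)
  expect_lt(sys$S[1, 2], 1)
  expect_equal(sys$S, t(sys$S))
  expect_equal(sys$hcore, t(sys$hcore), tolerance = 1e-12)
  expect_true(all(eigen(sys$S, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
  # determinism
  sys2 <- build_system(fixture("h2"), "sto-3g")
  expect_identical(sys$S, sys2$S)
  expect_identical(sys$eri, sys2$eri)
})

test_that("cc-pVDZ AO counts match published contraction sizes", {
  # 4 heavy atoms x 14 + 5 H x 5 = 81 for propionitrile; the cheaper N2
  # case checks the same contraction bookkeeping (2 x 14 = 28)
  sysn <- build_system(fixture("n2"), "cc-pvdz")
  expect_equal(sysn$nao, 28L)
  shn <- build_shells(fixture("propionitrile"), "cc-pvdz")
  expect_equal(qcembed:::ao_count(shn), 81L)
})

test_that("overlap matches independent Gauss-Hermite quadrature", {
  sys <- build_system(fixture("n2"), "cc-pvdz")
  shells <- sys$shells
  nsph <- vapply(shells, function(s) 2L * s$l + 1L, integer(1))
  off <- c(0L, cumsum(nsph))
  # three sampled shell pairs covering s-s, p-p (cross-atom) and d-d
  ls <- vapply(shells, function(s) s$l, integer(1))
  atoms <- vapply(shells, function(s) s$atom, integer(1))
  pick <- list(
    c(which(ls == 0)[1], which(ls == 0 & atoms == 2)[1]),
    c(which(ls == 1)[1], which(ls == 1 & atoms == 2)[1]),
    c(which(ls == 2)[1], which(ls == 2 & atoms == 2)[1]))
  for (pr in pick) {
    i <- pr[1]; j <- pr[2]
    num <- oracle_overlap_block(shells[[i]], shells[[j]])
    ana <- sys$S[off[i] + seq_len(nsph[i]), off[j] + seq_len(nsph[j]),
                 drop = FALSE]
    expect_equal(unname(ana), unname(num), tolerance = 1e-9)
  }
})

test_that("RHF matches the hand-coded two-orbital Roothaan oracle", {
  sys <- sys_h2()
  mf <- mf_h2()
  expect_equal(mf$E_total, oracle_h2_rhf(sys), tolerance = 1e-8)
  # reference value from an independent electronic-structure engine
  expect_equal(mf$E_total, -1.11675930, tolerance = 1e-6)
})

test_that("single-pair helium closed form holds", {
  sys <- build_system(geometry("He", matrix(c(0, 0, 0), 1, 3)), "sto-3g")
  mf <- run_mean_field(sys, "hf")
  # one occupied orbital c: E = 2 h_11 + (11|11) in the MO basis
  C <- mf$C[, 1]
  hmo <- sum(C * (sys$hcore %*% C))
  jmo <- 0
  n <- sys$nao
  for (p in seq_len(n)) for (q in seq_len(n))
    for (r in seq_len(n)) for (s in seq_len(n))
      jmo <- jmo + C[p] * C[q] * C[r] * C[s] * sys$eri[p, q, r, s]
  expect_equal(mf$E_total, 2 * hmo + jmo, tolerance = 1e-9)
})

test_that("mean-field solution invariants hold across fixtures/levels", {
  for (case in list(list(sys_h2(), mf_h2()),
                    list(sys_water(), mf_water()))) {
    sys <- case[[1]]; mf <- case[[2]]
    N <- n_electrons(sys$geometry)
    expect_equal(sum(mf$gamma * sys$S), N, tolerance = 1e-8)
    gSg <- mf$gamma %*% sys$S %*% mf$gamma
    expect_equal(gSg, 2 * mf$gamma, tolerance = 1e-7)
    orth <- t(mf$C) %*% sys$S %*% mf$C
    expect_equal(orth, diag(ncol(mf$C)), tolerance = 1e-8)
    Co <- mf$C[, seq_len(mf$n_occ), drop = FALSE]
    expect_equal(2 * Co %*% t(Co), mf$gamma, tolerance = 1e-10)
  }
})

test_that("hybrid-functional total energy is self-consistent", {
  sys <- sys_water()
  grid <- lean_grid(sys$geometry)
  mf <- run_mean_field(sys, "b3lyp", grid = grid)
  expect_equal(dft_energy(mf$gamma, "b3lyp", sys, grid = grid),
               mf$E_total, tolerance = 1e-9)
})

test_that("two_electron_matrix behaves as a two-electron field", {
  sys <- sys_h2()
  g0 <- two_electron_matrix(sys, matrix(0, 2, 2), "hf")
  expect_equal(g0, matrix(0, 2, 2))
  set.seed(4)
  D1 <- matrix(rnorm(4), 2); D1 <- D1 + t(D1)
  D2 <- matrix(rnorm(4), 2); D2 <- D2 + t(D2)
  # Coulomb linearity at HF level
  J1 <- coulomb_matrix(sys, D1); J2 <- coulomb_matrix(sys, D2)
  expect_equal(coulomb_matrix(sys, D1 + D2), J1 + J2, tolerance = 1e-10)
  # dense-loop contraction oracle
  jk <- oracle_jk_dense(sys$eri, D1)
  expect_equal(two_electron_matrix(sys, D1, "hf"),
               jk$J - 0.5 * jk$K, tolerance = 1e-10)
  expect_error(two_electron_matrix(sys, matrix(0, 3, 3), "hf"),
               "dimension")
})

test_that("dft_energy evaluates the stated functional of the density", {
  sys <- sys_h2()
  expect_equal(dft_energy(matrix(0, 2, 2), "hf", sys), sys$enuc)
  mf <- mf_h2()
  expect_equal(dft_energy(mf$gamma, "hf", sys), mf$E_total,
               tolerance = 1e-9)
  # idempotent trial density, closed-form HF energy oracle
  X <- qcembed:::.sym_orth(sys$S)
  v <- X[, 1] / sqrt(sum(X[, 1] * (sys$S %*% X[, 1])))
  gam <- 2 * outer(v, v)
  jk <- oracle_jk_dense(sys$eri, gam)
  eo <- sum(gam * sys$hcore) + 0.5 * sum(gam * (jk$J - 0.5 * jk$K)) +
    sys$enuc
  expect_equal(dft_energy(gam, "hf", sys), eo, tolerance = 1e-10)
  # variational bound for the trial density
  expect_gte(eo, mf$E_total - 1e-10)
  expect_error(dft_energy(mf$gamma, "nosuchfunctional", sys), "unknown")
})

test_that("rigid translation leaves the energy invariant", {
  g <- fixture("water")
  g2 <- geometry(g$atoms, g$coords + matrix(rep(c(1.3, -0.7, 2.1),
                                                each = 3), 3, 3))
  sys2 <- build_system(g2, "sto-3g")
  mf2 <- run_mean_field(sys2, "hf")
  expect_equal(mf2$E_total, mf_water()$E_total, tolerance = 1e-8)
})

test_that("SCF reports convergence failure with diagnostics", {
  sys <- sys_h2()
  expect_error(run_mean_field(sys, "hf", max_iter = 1),
               "failed to converge")
})
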