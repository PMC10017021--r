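# Embedding operators, embedded SCF and total-energy assembly.

test_that("level-shift projector is the exact triple product", {
  sys <- sys_h2()
  pr0 <- build_projector(sys$S, matrix(0, 2, 2))
  expect_equal(pr0$P_B, matrix(0, 2, 2))
  # orthonormal AO limit: S = identity, idempotent-normalized gamma_B
  gb <- diag(c(1, 0))
  pr1 <- build_projector(diag(2), gb, mu = 10)
  expect_equal(pr1$P_B, gb)
  expect_equal(pr1$muP_B, 10 * gb)
  # random SPD S and symmetric gamma_B vs dense loop
  set.seed(12)
  A <- matrix(rnorm(9), 3)
  S <- crossprod(A) + diag(3)
  gB <- matrix(rnorm(9), 3); gB <- gB + t(gB)
  pr <- build_projector(S, gB)
  ref <- matrix(0, 3, 3)
  for (p in 1:3) for (q in 1:3)
    for (r in 1:3) for (s in 1:3)
      ref[p, q] <- ref[p, q] + S[p, r] * gB[r, s] * S[s, q]
  expect_equal(pr$P_B, ref, tolerance = 1e-10)
  expect_error(build_projector(S, matrix(rnorm(9), 3)), "symmetric")
})

test_that("embedding potential reduces to the environment's J and K", {
  sys <- sys_dimer()
  mf <- mf_dimer_hf()
  part <- suppressWarnings(build_partition(mf, sys, active_atoms = 1:3))
  # empty environment
  v0 <- build_embedding_potential(sys, part$gamma_A,
                                  0 * part$gamma_B, "hf")
  expect_equal(max(abs(v0)), 0, tolerance = 1e-12)
  # HF level: v_emb = J[gamma_B] - 0.5 K[gamma_B] by linearity
  v <- build_embedding_potential(sys, part$gamma_A, part$gamma_B, "hf")
  jk <- list(J = coulomb_matrix(sys, part$gamma_B),
             K = exchange_matrix(sys, part$gamma_B))
  expect_equal(v, jk$J - 0.5 * jk$K, tolerance = 1e-9)
})

test_that("whole-system-active embedding reproduces the full mean field", {
  sys <- sys_water()
  mf <- mf_water()
  part <- suppressWarnings(build_partition(mf, sys, active_atoms = 1:3))
  ops <- build_embedding_operators(sys, part, "hf")
  emb <- embedded_scf(sys, ops, part$n_act_elec, level_wf = "hf")
  expect_equal(emb$E_A_elec + sys$enuc, mf$E_total, tolerance = 1e-8)
  expect_equal(emb$gamma_A_tilde, mf$gamma, tolerance = 1e-6)
})

test_that("level shift keeps environment character out of subsystem A", {
  sys <- sys_dimer()
  mf <- mf_dimer_hf()
  part <- suppressWarnings(build_partition(mf, sys, active_atoms = 1:3))
  ops <- build_embedding_operators(sys, part, "hf", mu = 1e6)
  emb <- embedded_scf(sys, ops, part$n_act_elec, level_wf = "hf")
  tr1 <- sum(emb$gamma_A_tilde * ops$P_B)
  expect_lt(tr1, 1e-6)
  # penalty-method scaling: doubling mu divides the trace by ~4 (the
  # second-order 1/mu^2 law; the energy term mu*tr scales as 1/mu)
  ops2 <- build_embedding_operators(sys, part, "hf", mu = 2e6)
  emb2 <- embedded_scf(sys, ops2, part$n_act_elec, level_wf = "hf")
  tr2 <- sum(emb2$gamma_A_tilde * ops2$P_B)
  expect_gt(tr1 / tr2, 3.0)
  expect_lt(tr1 / tr2, 5.0)
  expect_gt((1e6 * tr1) / (2e6 * tr2), 1.5)
  expect_lt((1e6 * tr1) / (2e6 * tr2), 2.5)
})

test_that("same-level-in-same-level assembly is exact (HF and PBE)", {
  sys <- sys_dimer()
  grid <- lean_grid(sys$geometry)
  for (lev in c("hf", "pbe")) {
    mf <- if (lev == "hf") mf_dimer_hf()
          else run_mean_field(sys, lev, grid = grid)
    part <- suppressWarnings(build_partition(mf, sys, active_atoms = 1:3))
    ops <- build_embedding_operators(sys, part, lev, grid = mf$grid)
    emb <- embedded_scf(sys, ops, part$n_act_elec, level_wf = lev)
    asm <- assemble_total_energy(emb$E_A_elec, emb$gamma_A_tilde,
                                 sys, part, ops)
    expect_equal(asm$E_total, mf$E_total, tolerance = 1e-6)
  }
})

test_that("total energy is robust to the level-shift magnitude", {
  sys <- sys_dimer()
  mf <- mf_dimer_hf()
  part <- suppressWarnings(build_partition(mf, sys, active_atoms = 1:3))
  es <- vapply(c(1e5, 1e7), function(mu) {
    ops <- build_embedding_operators(sys, part, "hf", mu = mu)
    emb <- embedded_scf(sys, ops, part$n_act_elec, level_wf = "hf")
    assemble_total_energy(emb$E_A_elec, emb$gamma_A_tilde, sys, part,
                          ops)$E_total
  }, numeric(1))
  expect_lt(abs(es[1] - es[2]), 1e-6)
})

test_that("active-space integral transform matches dense loops", {
  sys <- sys_h2()
  # identity-span toy: S-orthonormal span in an orthonormalized AO basis
  X <- qcembed:::.sym_orth(sys$S)
  ham <- transform_active_integrals(sys, sys$hcore, X, 2)
  expect_equal(ham$h, t(X) %*% sys$hcore %*% X, tolerance = 1e-12)
  expect_equal(ham$eri, oracle_ao2mo(sys$eri, X), tolerance = 1e-10)
  # 2-orbital span of a 4-AO system vs the quadruple dense loop
  sys4 <- sys_h4()
  mf4 <- mf_h4()
  B <- mf4$C[, 1:2]
  ham2 <- transform_active_integrals(sys4, sys4$hcore, B, 2)
  expect_equal(ham2$eri, oracle_ao2mo(sys4$eri, B), tolerance = 1e-10)
  expect_error(
    transform_active_integrals(sys4, sys4$hcore, 2 * B, 2),
    "S-orthonormal")
})

test_that("empty-environment reduction: embedded FCI equals plain FCI", {
  sys <- sys_h4()
  mf <- mf_h4()
  run <- suppressWarnings(
    embed_system(sys = sys, mf = mf, active_atoms = 1:4,
                 env_level = "hf", wf_solver = "fci"))
  plain <- fci_h4()
  expect_equal(run$E_total, plain$energy, tolerance = 1e-8)
})

test_that("adding a concentric shell never raises the embedded energy", {
  sys <- sys_h4()
  mf <- mf_h4()
  es <- vapply(1:2, function(ns) {
    suppressWarnings(
      embed_system(sys = sys, mf = mf, active_atoms = 1:2,
                   env_level = "hf", wf_solver = "fci",
                   n_shells = ns))$E_total
  }, numeric(1))
  expect_lte(es[2], es[1] + 1e-10)
})

test_that("FCIDUMP round-trips the active Hamiltonian", {
  ham <- ham_h4()
  path <- tempfile(fileext = ".fcidump")
  write_fcidump(ham, path)
  back <- read_fcidump(path)
  expect_equal(back$norb, ham$norb)
  expect_equal(back$nelec, ham$nelec)
  expect_equal(back$e_core, ham$e_core, tolerance = 1e-12)
  expect_equal(back$h, unname(ham$h), tolerance = 1e-12)
  expect_equal(back$eri, ham$eri, tolerance = 1e-12)
  hdr <- readLines(path, n = 1)
  expect_match(hdr, "NORB=4")
  expect_match(hdr, "NELEC=4")
  expect_match(hdr, "MS2=0")
})
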