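# SPADE occupied split and concentric virtual localization.

test_that("whole-system-active assigns everything to subsystem A", {
  part <- suppressWarnings(
    build_partition(mf_water(), sys_water(), active_atoms = 1:3))
  expect_equal(part$k, mf_water()$n_occ)
  expect_equal(part$n_act_elec, 2L * mf_water()$n_occ)
  expect_equal(max(abs(part$gamma_B)), 0)
  expect_equal(part$gamma_A, mf_water()$gamma, tolerance = 1e-10)
})

test_that("far-separated helium dimer splits with a binary spectrum", {
  sys <- build_system(fixture("he2", r = 50), "sto-3g")
  mf <- run_mean_field(sys, "hf")
  sp <- spade_split(mf, sys, active_atoms = 1)
  expect_equal(sp$sigma, c(1, 0), tolerance = 1e-6)
  expect_equal(sp$k, 1L)
  expect_equal(sp$n_act_elec, 2L)
  # minimal-basis He2 has no virtuals at all: empty shell list
  cl <- concentric_shells(mf, sys, sp, active_atoms = 1, n_shells = 1)
  expect_length(cl$sizes, 0)
  # shell-1 size bounded by the fragment AO count (projection rank)
  sysd <- sys_dimer()
  mfd <- mf_dimer_hf()
  spd <- spade_split(mfd, sysd, active_atoms = 1:3)
  cld <- suppressWarnings(
    concentric_shells(mfd, sysd, spd, active_atoms = 1:3, n_shells = 1))
  n_frag_ao <- sum(qcembed:::ao_atom_map(sysd$shells) %in% 1:3)
  expect_lte(cld$sizes[1], n_frag_ao)
})

test_that("SPADE rotation preserves the occupied density", {
  sys <- sys_dimer()
  mf <- mf_dimer_hf()
  sp <- spade_split(mf, sys, active_atoms = 1:3)
  g_before <- mf$gamma
  g_after <- 2 * (sp$C_occ_A %*% t(sp$C_occ_A) +
                  sp$C_occ_B %*% t(sp$C_occ_B))
  expect_lt(max(abs(g_before - g_after)), 1e-10)
  expect_true(all(diff(sp$sigma) <= 1e-12))
  expect_equal(sp$sigma, sort(sp$sigma, decreasing = TRUE))
})

test_that("partition invariants hold (orthonormality, additivity)", {
  sys <- sys_dimer()
  mf <- mf_dimer_hf()
  part <- suppressWarnings(build_partition(mf, sys, active_atoms = 1:3))
  expect_equal(part$gamma_A + part$gamma_B, mf$gamma, tolerance = 1e-8)
  expect_equal(sum(part$gamma_A * sys$S), part$n_act_elec,
               tolerance = 1e-8)
  expect_lt(max(abs(part$gamma_A %*% sys$S %*% part$gamma_B)), 1e-8)
  allC <- cbind(part$C_occ_A, part$C_occ_B,
                do.call(cbind, part$C_virt_shells))
  orth <- t(allC) %*% sys$S %*% allC
  expect_equal(orth, diag(ncol(allC)), tolerance = 1e-8)
})

test_that("shell construction is idempotent under re-orthogonalization", {
  sys <- sys_dimer()
  mf <- mf_dimer_hf()
  part <- suppressWarnings(build_partition(mf, sys, active_atoms = 1:3))
  for (B in part$C_virt_shells) {
    M <- t(B) %*% sys$S %*% B
    ev <- eigen(0.5 * (M + t(M)), symmetric = TRUE)
    B2 <- B %*% ev$vectors %*% diag(1 / sqrt(ev$values), ncol(B)) %*%
      t(ev$vectors)
    expect_lt(max(abs(B2 - B)), 1e-10)
  }
})

test_that("shells covering all virtuals reproduce the full virtual count", {
  sys <- sys_h4()
  mf <- mf_h4()
  sp <- spade_split(mf, sys, active_atoms = 1:2)
  cl <- suppressWarnings(
    concentric_shells(mf, sys, sp, active_atoms = 1:2, n_shells = 10))
  expect_equal(sum(cl$sizes), sys$nao - mf$n_occ)
})

test_that("density assembly adds traces over a random orthonormal split", {
  sys <- sys_dimer()
  mf <- mf_dimer_hf()
  nocc <- mf$n_occ
  set.seed(9)
  Q <- qr.Q(qr(matrix(rnorm(nocc^2), nocc)))
  Crot <- mf$C[, seq_len(nocc)] %*% Q
  split <- list(C_occ_A = Crot[, 1:4, drop = FALSE],
                C_occ_B = Crot[, 5:nocc, drop = FALSE])
  dens <- assemble_densities(split)
  expect_equal(sum(dens$gamma_A * sys$S) + sum(dens$gamma_B * sys$S),
               2 * nocc, tolerance = 1e-8)
  expect_equal(dens$gamma_A + dens$gamma_B, mf$gamma, tolerance = 1e-8)
})

test_that("degenerate SPADE gaps demand an explicit override", {
  sys <- sys_h2()
  mf <- mf_h2()
  # one occupied orbital: sigma has a single entry, gap list length 1 --
  # force the degenerate path with a hand-built symmetric case instead
  sp <- spade_split(mf, sys, active_atoms = 1)
  expect_equal(sp$k, 1L)
  # k_override honored and validated
  expect_error(spade_split(mf, sys, active_atoms = 1, k_override = 5),
               "k_override")
  expect_error(spade_split(mf, sys, active_atoms = integer(0)),
               "non-empty")
})
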