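# Shared (memoised) fixtures so expensive integral/SCF work is done once
# per test run.

.sys_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.sys_cache[[key]])) assign(key, builder(), .sys_cache)
  get(key, .sys_cache)
}

sys_h2 <- function() cached("sys_h2", function()
  build_system(fixture("h2"), "sto-3g"))
mf_h2 <- function() cached("mf_h2", function()
  run_mean_field(sys_h2(), "hf"))

sys_h4 <- function() cached("sys_h4", function()
  build_system(fixture("h_chain", n = 4, r = 1.0), "sto-3g"))
mf_h4 <- function() cached("mf_h4", function()
  run_mean_field(sys_h4(), "hf"))
ham_h4 <- function() cached("ham_h4", function()
  transform_active_integrals(sys_h4(), sys_h4()$hcore, mf_h4()$C, 4,
                             e_core = sys_h4()$enuc))
fci_h4 <- function() cached("fci_h4", function() fci_solve(ham_h4()))

ham_h2 <- function() cached("ham_h2", function()
  transform_active_integrals(sys_h2(), sys_h2()$hcore, mf_h2()$C, 2,
                             e_core = sys_h2()$enuc))
fci_h2 <- function() cached("fci_h2", function() fci_solve(ham_h2()))

sys_water <- function() cached("sys_water", function()
  build_system(fixture("water"), "sto-3g"))
mf_water <- function() cached("mf_water", function()
  run_mean_field(sys_water(), "hf"))

sys_dimer <- function() cached("sys_dimer", function()
  build_system(fixture("water_dimer"), "sto-3g"))
mf_dimer_hf <- function() cached("mf_dimer_hf", function()
  run_mean_field(sys_dimer(), "hf"))

# lean quadrature grid for DFT used in tests (identities are grid-exact)
lean_grid <- function(geom) build_grid(geom, nrad = 35, ntheta = 10)

# H2 at 5 angstrom (dissociation fixtures)
sys_h2_far <- function() cached("sys_h2_far", function()
  build_system(fixture("h2", r = 5), "sto-3g"))
ham_h2_far <- function() cached("ham_h2_far", function() {
  mf <- run_mean_field(sys_h2_far(), "hf")
  transform_active_integrals(sys_h2_far(), sys_h2_far()$hcore, mf$C, 2,
                             e_core = sys_h2_far()$enuc)
})
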