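# Shared fixtures. Heavy simulations are computed once per test run and
# cached; everything is generated in code (no stored data).

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

ref_phys <- function() cached("phys", build_reference_human())
ref_sub <- function() cached("sub", substance_retrorsine())

# single oral 100-nmol dose, dense output
single_dose_sim <- function() cached("single_dose", {
  simulate_pbtk(dose_regimen("retrorsine", 100, 0), ref_sub(), ref_phys(),
                t_end = 48, dt_out = 0.05)
})

# short (6-day) tea regimen used by window/steady-state tests
short_tea_sim <- function() cached("short_tea", {
  reg <- dose_regimen("retrorsine", 3.947, seq(0, by = 24, length.out = 6))
  simulate_pbtk(reg, ref_sub(), ref_phys(), t_end = 6 * 24, dt_out = 0.05)
})

# microsomal end-product-inhibition truth (assay-scale parameters)
micro_truth <- function() list(vmax_invitro = 0.817, km = 25.5, ic50 = 5.18e-4)
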