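# Whole-body PBTK model: physiology, clearances, mass balance, kinetics.

test_that("reference-human physiology satisfies its anatomical invariants", {
  phys <- ref_phys()
  expect_equal(phys$body_weight, 73)
  expect_equal(phys$tissue_volumes[["liver_cell"]], 1.30)
  expect_equal(phys$tissue_volumes[["gut"]], 1.02)
  expect_equal(sum(phys$blood_flows), phys$cardiac_output)
  expect_true(all(phys$tissue_volumes > 0) && all(phys$blood_flows > 0))
  expect_true(phys$f_si > 0 && phys$f_si <= 1)
  # intestinal metabolic clearance implied by the defaults, mL/min/kg
  sub <- ref_sub()
  cl_gut <- sub$vmax_gut / sub$km_gut * phys$f_si *
    phys$tissue_volumes[["gut"]] * 1000 / phys$body_weight
  expect_equal(cl_gut, 1.35, tolerance = 0.005)
  # renal clearance consistency: GFR x fu = 1.5 * 0.6
  expect_equal(sub$cl_renal, 1.5 * sub$fu_plasma)
})

test_that("unit conversions round-trip between assay and organ scales", {
  phys <- ref_phys(); sub <- ref_sub()
  r <- retrotox:::model_rates(sub, phys)
  # L/h organ clearance back to mL/min/g liver
  expect_equal(r$cl_act_in / phys$liver_mass * 1000 / 60, sub$cl_act_in)
  expect_equal(r$ps_diff / phys$liver_mass * 1000 / 60, sub$ps_diff)
  # nmol/h organ Vmax back to nmol/min/g
  expect_equal(r$vmax_liv / phys$liver_mass / 60, sub$vmax_liv)
  # Km in nmol/L back to uM
  expect_equal(r$km_liv / 1000, sub$km_liv)
  # renal L/h back to mL/min/kg
  expect_equal(r$cl_renal * 1000 / 60 / phys$body_weight, sub$cl_renal)
})

test_that("extended liver clearance matches its closed form and limits", {
  sub <- ref_sub(); phys <- ref_phys()
  expect_equal(extended_liver_clearance(sub, phys), 9.08, tolerance = 0.002)
  # no active uptake, no clearance
  sub0 <- substance_retrorsine(cl_act_in = 0)
  expect_equal(extended_liver_clearance(sub0, phys), 0)
  # flow-limited upper bound as uptake saturates the sinusoid
  subi <- substance_retrorsine(cl_act_in = 1.02e6)
  q_per_kg <- phys$blood_flows[["liver"]] * 1000 / 60 / phys$body_weight
  expect_equal(extended_liver_clearance(subi, phys), q_per_kg, tolerance = 1e-3)
})

test_that("the vector field vanishes at the origin and rejects bad states", {
  d0 <- retrorsine_rhs(0, c(lumen = 0))
  expect_true(all(d0 == 0))
  expect_error(retrorsine_rhs(0, c(lumen = -1)), "non-negative")
  expect_error(retrorsine_rhs(0, c(lumen = NaN)), "non-negative")
})

test_that("a single oral dose conserves mass and stays in the physical cone", {
  sim <- single_dose_sim()
  expect_lt(mass_balance_error(sim), 1e-6)
  expect_true(all(sim$amounts >= -1e-9))
  for (cum in c("cmet_3a4_liv", "cmet_oth_liv", "cmet_3a4_gut",
                "cmet_oth_gut", "cren")) {
    expect_true(all(diff(sim$amounts[, cum]) >= -1e-12))
  }
})

test_that("exposure is dose-proportional in the linear range", {
  sub <- ref_sub(); phys <- ref_phys()
  s1 <- simulate_pbtk(dose_regimen("retrorsine", 10, 0), sub, phys,
                      t_end = 36, dt_out = 0.1)
  s2 <- simulate_pbtk(dose_regimen("retrorsine", 5, 0), sub, phys,
                      t_end = 36, dt_out = 0.1)
  for (mx in colnames(s1$conc)) {
    auc1 <- retrotox:::trapz(s1$time, s1$conc[, mx])
    auc2 <- retrotox:::trapz(s2$time, s2$conc[, mx])
    expect_equal(auc1 / auc2, 2, tolerance = 1e-3)
    expect_equal(max(s1$conc[, mx]) / max(s2$conc[, mx]), 2, tolerance = 1e-3)
  }
})

test_that("simulated hepatic clearance agrees with the closed-form organ model", {
  sub <- ref_sub(); phys <- ref_phys()
  ivs <- simulate_pbtk(dose_regimen("retrorsine", 100, 0), sub, phys,
                       t_end = 96, dt_out = 0.1, iv = TRUE)
  cl_sim <- retrotox:::last(ivs$amounts[, "cmet_3a4_liv"] +
                              ivs$amounts[, "cmet_oth_liv"]) /
    retrotox:::last(ivs$amounts[, "cauc_art"]) # L/h
  cl_eq <- extended_liver_clearance(sub, phys) * phys$body_weight * 60 / 1000
  expect_equal(cl_sim, cl_eq, tolerance = 0.02)
})

test_that("an empty regimen yields an identically zero trajectory", {
  sim <- simulate_pbtk(dose_regimen("retrorsine", 1, numeric(0)),
                       t_end = 5, dt_out = 0.5)
  expect_true(all(sim$amounts[, 1:19] == 0))
  expect_true(all(sim$enzyme == 1))
})

test_that("dosing beyond the simulated horizon is rejected", {
  expect_error(
    simulate_pbtk(dose_regimen("retrorsine", 1, c(0, 48)), t_end = 24),
    "beyond the last dose")
})

test_that("bioavailability decomposes multiplicatively into Fa, Fg, Fh", {
  f <- cached("bioavail", bioavailability_decomposition(ref_sub(), ref_phys()))
  expect_equal(f$F, f$F_a * f$F_g * f$F_h, tolerance = 1e-12)
  expect_equal(f$F_a, 0.783)
  expect_true(f$F_g > f$F_h) # gut first pass is milder than hepatic
})

test_that("biodistribution report is complete and consistent", {
  bd <- cached("biodist", biodistribution_report(single_dose_sim()))
  expect_equal(sum(bd$route_shares), 100, tolerance = 1e-9)
  expect_true(all(bd$route_shares > 0))
  expect_true(bd$peak_fraction[["muscle"]] == max(bd$peak_fraction))
  expect_true(all(bd$peak_fraction[c("spleen", "kidney", "heart")] < 0.3))
  expect_true(bd$t9999 > 5 && bd$t9999 < 48)
})
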