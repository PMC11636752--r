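# Rifampicin exposure, CYP3A4 turnover/inhibition, fm derivation, coupling.

unit_central_amount_wrap <- function(p, t) retrotox:::unit_central_amount(p, t)

test_that("two-compartment solution matches a numerical integration oracle", {
  p <- rifampicin_2comp_params("liver")
  # no dose: zero forever
  expect_true(all(rif_conc_profile(p, seq(0, 48, 1), dose_mg = 600,
                                   dose_times = numeric(0)) == 0))
  # single dose: closed form vs lsoda on the raw right-hand side
  tt <- seq(0, 72, by = 0.5)
  ode <- deSolve::ode(
    y = c(dep = 1, cen = 0, per = 0), times = tt,
    func = function(t, y, pp) list(rifampicin_2comp_rhs(t, y, pp)),
    parms = p, rtol = 1e-10, atol = 1e-12)
  expect_equal(unit_central_amount_wrap(p, tt), unname(ode[, "cen"]),
               tolerance = 1e-7)
  expect_error(rifampicin_2comp_rhs(0, c(-1, 0, 0), p), "non-negative")
})

test_that("enzyme turnover has the Emax fixed points and closed-form de-induction", {
  ip <- induction_params()
  # baseline is a steady state in the absence of inducer
  expect_equal(cyp3a4_turnover_rhs(1, 0, ip, "liver"), 0)
  # saturating inducer drives the level to 1 + emax
  expect_equal(cyp3a4_turnover_rhs(1 + ip$emax, 1e6, ip, "liver"), 0,
               tolerance = 1e-4)
  # washout from the induced state: E(t) = 1 + 9 exp(-k_deg t)
  tt <- seq(0, 240, by = 1)
  sol <- deSolve::ode(
    y = c(E = 10), times = tt,
    func = function(t, y, pp) list(cyp3a4_turnover_rhs(y, 0, pp, "liver")),
    parms = ip, rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(sol[, "E"]), 1 + 9 * exp(-ip$k_deg_liv * tt),
               tolerance = 1e-6)
})

test_that("competitive inhibition multiplies K_M by 1 + I/Ki", {
  expect_equal(competitive_inhibition_factor(0, 18.5), 1)
  expect_equal(competitive_inhibition_factor(18.5, 18.5), 2)
  expect_error(competitive_inhibition_factor(-1, 18.5), ">= 0")
  # in the linear range the CYP3A4 pathway slows by exactly 1/(1 + I/Ki)
  sub <- ref_sub()
  d0 <- retrorsine_rhs(0, c(liv_cell = 1), rif_conc = c(0, 0))
  d1 <- retrorsine_rhs(0, c(liv_cell = 1), rif_conc = c(18.5, 0))
  v3a4 <- function(d) d[["cmet_3a4_liv"]]
  expect_equal(v3a4(d1) / v3a4(d0), 0.5, tolerance = 1e-4)
  # the non-CYP3A4 pathway is untouched
  expect_equal(d1[["cmet_oth_liv"]], d0[["cmet_oth_liv"]])
})

test_that("CYP3A4-metabolized fraction follows the abundance-scaled adduct weights", {
  ref <- supersome_reference()
  fm <- compute_fm_cyp3a4(ref$adduct_conc, ref$abundance)
  expect_equal(fm, 0.527, tolerance = 0.02) # known ~1.3% low, see vignette
  only <- ref$adduct_conc * 0; only[["CYP3A4"]] <- 1
  expect_equal(compute_fm_cyp3a4(only, ref$abundance), 1.0)
  eq <- setNames(rep(1, 10), names(ref$adduct_conc))
  expect_equal(compute_fm_cyp3a4(eq, eq), 0.1)
  expect_error(compute_fm_cyp3a4(eq * 0, eq), "zero")
  expect_error(compute_fm_cyp3a4(eq[-1], eq), "same isoform")
})

test_that("rifampicin fit recovers generating rate constants", {
  p <- rifampicin_2comp_params("liver")
  prof <- gen_rifampicin_profiles(noise = noise_spec(0, 1),
                                  times = seq(1, 384, by = 4))
  liver_prof <- prof[prof$tissue == "liver", ]
  fit <- fit_rifampicin_2comp(liver_prof, p, n_iter = 2000, seed = 9)
  # noise-free data: posterior concentrates on the truth
  truth <- c(k_depot = p$k_depot, k12 = p$k12, k21 = p$k21, k_e = p$k_e)
  for (nm in names(truth)) {
    est <- fit$summary$mode[fit$summary$parameter == nm]
    expect_equal(est, unname(truth[[nm]]), tolerance = 0.05)
  }
  expect_error(fit_rifampicin_2comp(liver_prof[1:5, ], p), ">= 10 points")
})

test_that("the coupled system reduces to the uncoupled one without rifampicin", {
  sub <- ref_sub(); phys <- ref_phys()
  tea <- dose_regimen("retrorsine", 3.947, seq(0, by = 24, length.out = 3))
  rif0 <- dose_regimen("rifampicin", 600, numeric(0))
  a <- simulate_pbtk(tea, sub, phys, t_end = 96, dt_out = 0.25)
  b <- coupled_simulate(tea, rif0, sub, phys, t_end = 96, dt_out = 0.25)
  expect_identical(a$amounts, b$amounts) # bit-for-bit: same joint system
  # emax = 0 and Ki = Inf neutralize an actually dosed perpetrator
  rif <- dose_regimen("rifampicin", 600, c(0, 24))
  ip0 <- induction_params(emax = 0, ki = Inf)
  c0 <- coupled_simulate(tea, rif, sub, phys, ip = ip0, t_end = 96, dt_out = 0.25)
  expect_equal(c0$amounts[, 1:19], a$amounts[, 1:19], tolerance = 1e-8)
  expect_true(all(c0$enzyme == 1))
})

test_that("enzyme dynamics stay within [1, 1 + Emax] and de-induce monotonically", {
  sub <- ref_sub(); phys <- ref_phys()
  ip <- induction_params()
  tea <- dose_regimen("retrorsine", 3.947, seq(0, by = 24, length.out = 4))
  rif <- dose_regimen("rifampicin", 600, seq(0, by = 24, length.out = 4))
  sim <- coupled_simulate(tea, rif, sub, phys, t_end = 24 * 20, dt_out = 0.25)
  expect_true(all(sim$enzyme >= 1 - 1e-9))
  expect_true(all(sim$enzyme <= 1 + ip$emax + 1e-9))
  # after washout the decline toward baseline is monotone
  for (k in 1:2) {
    e <- sim$enzyme[, k]
    ipk <- which.max(e)
    expect_true(all(diff(e[ipk:length(e)]) <= 1e-9))
  }
})
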