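# Scenario construction, exposure metrics, ratios, sensitivity.

test_that("scenario regimens implement the study dosing arithmetic", {
  reg <- make_scenario(scenario_spec("herbal_tea"), ref_sub(), ref_phys())
  total <- sum(rep(reg$tea$dose_amount, length(reg$tea$dose_times)))
  expect_equal(total, 138, tolerance = 0.002)
  expect_equal(reg$tea$dose_amount, 138 / 35, tolerance = 0.005)
  expect_length(reg$rif$dose_times, 0)

  both <- make_scenario(scenario_spec("herbal_tea_plus_rifampicin"))
  expect_equal(both$rif$dose_times[1], 3 * 24) # start at day 4
  expect_length(both$rif$dose_times, 14)
  expect_error(scenario_spec("herbal_tea_plus_rifampicin", tea_days = 10),
               "within the tea window")
})

test_that("windowed AUC and Cmax match closed forms", {
  # constant signal: AUC24 = 24 * level, Cmax = level
  fake <- structure(list(
    time = seq(0, 48, by = 0.02),
    conc = cbind(plasma = rep(1, 2401), liver_cell = rep(2, 2401),
                 gut_tissue = rep(0.5, 2401))), class = "sim_output")
  m <- auc_cmax_by_day(fake, c(d1 = 0))
  expect_equal(m$auc24, c(24, 48, 12))
  expect_equal(m$cmax, c(1, 2, 0.5))
  # exponential decay: trapezoid vs analytic integral to 0.01%
  tt <- seq(0, 24, by = 0.02)
  ke <- 0.3
  fake2 <- structure(list(time = tt, conc = cbind(plasma = exp(-ke * tt))),
                     class = "sim_output")
  m2 <- auc_cmax_by_day(fake2, c(d1 = 0))
  expect_equal(m2$auc24, (1 - exp(-ke * 24)) / ke, tolerance = 1e-4)
  expect_error(auc_cmax_by_day(fake2, c(late = 10)), "beyond simulated span")
})

test_that("tea-only exposure is at steady state from day 3 on", {
  sim <- short_tea_sim()
  m <- auc_cmax_by_day(sim, c(d3 = 48, d5 = 96))
  for (mx in unique(m$matrix)) {
    a <- m[m$matrix == mx, ]
    expect_equal(a$auc24[1], a$auc24[2], tolerance = 1e-3)
  }
})

test_that("metabolite formation bookkeeping is additive and mass-consistent", {
  sim <- short_tea_sim()
  rep6 <- metabolite_formation_report(sim)
  # daily amounts sum to the cumulative totals
  for (nm in names(rep6$cumulative)) {
    parts <- strsplit(nm, "_")[[1]]
    daily_sum <- sum(rep6$daily$amount_nmol[rep6$daily$pathway == parts[1] &
                                              rep6$daily$tissue == parts[2]])
    expect_equal(daily_sum, unname(rep6$cumulative[[nm]]), tolerance = 1e-6)
  }
  # pathway totals + renal + residual body burden = administered
  a <- sim$amounts[nrow(sim$amounts), ]
  body <- sum(a[c("lumen", "gut", "liv_ext", "liv_cell", "art", "ven", "lung",
                  "adipose", "bone", "muscle", "spleen", "kidney", "heart",
                  "rest")])
  expect_equal(sum(rep6$cumulative) + a[["cren"]] + body, sim$dosed,
               tolerance = 1e-6 * sim$dosed)
})

test_that("interaction ratios are elementwise percentages with guarded zeros", {
  m <- data.frame(day_label = "d", matrix = c("a", "b"), auc24 = c(1, 2),
                  cmax = c(3, 4))
  expect_equal(interaction_ratio_table(m, m)$auc24, c(100, 100))
  half <- m; half$auc24 <- half$auc24 / 2
  expect_equal(interaction_ratio_table(half, m)$auc24, c(50, 50))
  zero <- m; zero$auc24[1] <- 0
  expect_error(interaction_ratio_table(m, zero), "zero reference")
})

test_that("sensitivity coefficients are exact for multiplicative and inactive parameters", {
  # short tea-only course: the CYP3A4 metabolite amount is exactly
  # proportional to fm (total metabolism is fm-independent at baseline),
  # and Ki is inactive without the perpetrator
  spec <- scenario_spec("herbal_tea", tea_days = 3)
  sens <- sensitivity_coefficients(spec, ref_sub(), ref_phys(),
                                   params = c("fm_cyp3a4", "ki"),
                                   dt_out = 0.5)
  fm <- sens[sens$parameter == "fm_cyp3a4", ]
  expect_equal(fm$coefficient, rep(1, 4), tolerance = 1e-6)
  ki <- sens[sens$parameter == "ki", ]
  expect_equal(ki$coefficient, rep(0, 4), tolerance = 1e-10)
  # +/- perturbations agree in sign and magnitude for a linear response
  expect_equal(fm$coefficient[fm$direction == "+10%"],
               fm$coefficient[fm$direction == "-10%"], tolerance = 1e-6)
})
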