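# In-vitro depletion models and IVIVE scaling.

test_that("monoexponential depletion obeys its closed form and rejects bad input", {
  # zero-rate identity
  expect_equal(monoexponential_depletion(0, c0 = 5, t = 100), 5)
  # half-life identity at the 4C rate constant
  lam <- 0.00754
  expect_equal(monoexponential_depletion(lam, 1, log(2) / lam), 0.5,
               tolerance = 1e-12)
  # strictly decreasing for positive rate
  tt <- seq(0, 24, by = 0.5)
  cc <- monoexponential_depletion(0.0696, 1, tt)
  expect_true(all(diff(cc) < 0))
  expect_equal(cc[length(cc)], exp(-1.6704), tolerance = 1e-12)

  expect_error(monoexponential_depletion(-0.1, 1, 1), "lambda")
  expect_error(monoexponential_depletion(0.1, 1, -1), "t must")
  expect_error(monoexponential_depletion(0.1, 0, 1), "c0")
})

test_that("end-product inhibition kinetics conserve mass and have the right limits", {
  p <- micro_truth()
  # no substrate, no flux
  expect_equal(end_product_inhibition_rhs(c(0, 3), p), c(0, 0))
  # exact conservation of substrate + product for arbitrary states
  for (s in list(c(1, 0), c(50, 2), c(200, 7), c(0.01, 0.3))) {
    d <- end_product_inhibition_rhs(s, p)
    expect_identical(sum(d), 0)
  }
  # first-order limit: S << km and P << ic50 gives v ~ (vmax/km) S
  s0 <- 1e-6
  d <- end_product_inhibition_rhs(c(s0, 0), p)
  expect_equal(-d[1], p$vmax_invitro / p$km * s0, tolerance = 1e-6)
  # negative state rejected
  expect_error(end_product_inhibition_rhs(c(-1, 0), p), "non-negative")
})

test_that("ic50 -> Inf reduces the depletion model to first-order decay in the linear range", {
  p <- micro_truth()
  p$ic50 <- Inf
  times <- seq(0, 60, by = 5)
  sim <- simulate_microsomal_depletion(p, c0 = 0.05, times = times)
  # S << km: closed-form exponential with rate vmax/km (per minute)
  oracle <- 0.05 * exp(-p$vmax_invitro / p$km * times)
  expect_equal(sim$substrate_uM, oracle, tolerance = 2e-3)
  # finite ic50 flattens the curve (less depletion at late times)
  sim_inh <- simulate_microsomal_depletion(micro_truth(), c0 = 0.05, times = times)
  expect_true(all(sim_inh$substrate_uM[-1] > sim$substrate_uM[-1]))
})

test_that("microsomal depletion curves flatten with accumulating product", {
  # Table-1-scale parameters, the four assay concentrations
  for (c0 in c(1, 15, 50, 200)) {
    sim <- simulate_microsomal_depletion(micro_truth(), c0,
                                         times = seq(0, 60, by = 2))
    expect_true(all(diff(sim$substrate_uM) < 0))
    # depletion rate decreases in time (strong early loss, flattening)
    rate <- -diff(sim$substrate_uM)
    expect_true(all(diff(rate) < 1e-10))
    # conservation through the integrator
    expect_equal(sim$substrate_uM + sim$product_uM, rep(c0, nrow(sim)),
                 tolerance = 1e-8)
  }
})

test_that("hepatic-transport IVIVE reproduces the reference clearances", {
  tr <- ivive_hepatic_transport(0.00754, 0.0696)
  expect_equal(tr$ps_diff, 0.124, tolerance = 0.005)
  expect_equal(tr$cl_act_in, 1.02, tolerance = 0.005)
  # identical rate constants: no temperature-dependent (active) component
  expect_equal(ivive_hepatic_transport(0.01, 0.01)$cl_act_in, 0)
  # scaling-independent ratio identity
  expect_equal(tr$cl_act_in / tr$ps_diff, (0.0696 - 0.00754) / 0.00754,
               tolerance = 1e-12)
  expect_error(ivive_hepatic_transport(0.07, 0.01), "active uptake")
})

test_that("metabolic-vmax IVIVE is linear and matches the reference pair", {
  expect_equal(ivive_metabolic_vmax(0.817), 26.2, tolerance = 0.005)
  expect_equal(ivive_metabolic_vmax(0), 0)
  # degree-1 positive homogeneity of all IVIVE maps
  for (a in c(0.5, 2, 10)) {
    expect_equal(ivive_metabolic_vmax(a * 0.817), a * ivive_metabolic_vmax(0.817))
    tr1 <- ivive_hepatic_transport(0.00754, 0.0696)
    tra <- ivive_hepatic_transport(a * 0.00754, a * 0.0696)
    expect_equal(tra$ps_diff, a * tr1$ps_diff)
    expect_equal(tra$cl_act_in, a * tr1$cl_act_in)
  }
  expect_error(ivive_scaling(mppgl = -1), "positive")
})

test_that("tidy in-vitro CSV round-trips", {
  d <- gen_medium_loss_dataset(0.0696, 1, noise = noise_spec(0.1, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_invitro_csv(d, path)
  d2 <- read_invitro_csv(path)
  expect_equal(d2$concentration_uM, d$concentration_uM)
  expect_equal(names(d2), names(d))
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_invitro_csv(bad), "missing column")
})
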