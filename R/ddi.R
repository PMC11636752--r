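# Rifampicin exposure models, CYP3A4 turnover/inhibition, and the
# CYP3A4-metabolized fraction derived from supersome adduct data.

#' Rifampicin two-compartment right-hand side
#'
#' First-order absorption from a depot into a central (intracellular)
#' compartment exchanging with a peripheral compartment:
#' `d(depot) = -k_depot*depot`;
#' `d(central) = k_depot*depot - (k12 + k_e)*central + k21*peripheral`;
#' `d(peripheral) = k12*central - k21*peripheral`.
#'
#' @param t time (h), unused (autonomous system).
#' @param state numeric length-3 `c(depot, central, peripheral)`, amounts.
#' @param params a [rifampicin_2comp_params()] object (single tissue).
#' @return derivative vector (amount/h).
#' @export
rifampicin_2comp_rhs <- function(t, state, params) {
  if (any(state < -1e-8) || any(!is.finite(state))) {
    stop("state must be non-negative and finite", call. = FALSE)
  }
  state <- pmax(state, 0) # absorb solver-scale undershoot
  c(-params$k_depot * state[[1]],
    params$k_depot * state[[1]] - (params$k12 + params$k_e) * state[[2]] +
      params$k21 * state[[3]],
    params$k12 * state[[2]] - params$k21 * state[[3]])
}

# Bateman solution for the central amount after a unit depot dose.
unit_central_amount <- function(p, t) {
  ksum <- p$k12 + p$k21 + p$k_e
  disc <- sqrt(ksum^2 - 4 * p$k21 * p$k_e)
  alpha <- (ksum + disc) / 2
  beta <- (ksum - disc) / 2
  kd <- p$k_depot
  # guard against degeneracy with the disposition exponents
  if (min(abs(kd - alpha), abs(kd - beta)) < 1e-8 * kd) kd <- kd * (1 + 1e-6)
  term <- function(lam, l2, l3) {
    (p$k21 - lam) / ((l2 - lam) * (l3 - lam)) * exp(-lam * pmax(t, 0))
  }
  out <- kd * (term(alpha, beta, kd) + term(beta, alpha, kd) + term(kd, alpha, beta))
  out[t < 0] <- 0
  out
}

#' Intracellular rifampicin concentration profile
#'
#' Closed-form multi-dose solution of the two-compartment model; used both
#' as the coupled model's reference and as the synthetic-profile truth.
#'
#' @param params single-tissue [rifampicin_2comp_params()].
#' @param times output times (h).
#' @param dose_mg per-dose amount (mg).
#' @param dose_times dosing times (h).
#' @return concentration (umol/L) in the central compartment.
#' @export
rif_conc_profile <- function(params, times, dose_mg = 600,
                             dose_times = seq(0, by = 24, length.out = 14)) {
  dose_umol <- dose_mg / RIFAMPICIN_MW * 1000 * params$dose_fraction
  amt <- rowSums(vapply(dose_times,
                        function(tau) unit_central_amount(params, times - tau),
                        numeric(length(times))))
  amt * dose_umol / params$central_volume
}

#' CYP3A4 turnover with Emax induction (right-hand side)
#'
#' Relative enzyme level `E` (baseline 1) with synthesis induced by the
#' inducer concentration: `dE/dt = k_deg*(1 + emax*C/(ec50 + C)) - k_deg*E`.
#' Fixed point: `E = 1 + emax*C/(ec50 + C)`, bounded by `1 + emax`.
#'
#' @param enzyme_level relative CYP3A4 level (> 0).
#' @param rif_conc inducer concentration (uM).
#' @param p an [induction_params()] object.
#' @param tissue `"liver"` or `"gut"` (selects `k_deg`).
#' @return `dE/dt` (1/h).
#' @export
cyp3a4_turnover_rhs <- function(enzyme_level, rif_conc, p = induction_params(),
                                tissue = c("liver", "gut")) {
  tissue <- match.arg(tissue)
  kdeg <- if (tissue == "liver") p$k_deg_liv else p$k_deg_gut
  kdeg * (1 + p$emax * rif_conc / (p$ec50 + rif_conc)) - kdeg * enzyme_level
}

#' Competitive inhibition factor on the Michaelis constant
#'
#' @param rif_conc inhibitor concentration (uM), >= 0.
#' @param ki inhibition constant (uM).
#' @return multiplier `1 + rif_conc/ki` applied to `K_M` of the
#'   CYP3A4-dependent pathway.
#' @export
competitive_inhibition_factor <- function(rif_conc, ki) {
  if (any(rif_conc < 0)) stop("rif_conc must be >= 0", call. = FALSE)
  1 + rif_conc / ki
}

#' Hepatic CYP isoform reference data for the adduct-scaling calculation
#'
#' Protein-adduct concentrations (nM) measured in recombinant CYP
#' supersome incubations, and hepatic isoform abundances (pmol/mg
#' microsomal protein), for the ten isoforms involved in pyrrolizidine
#' alkaloid oxidation.
#'
#' @return list with numeric named vectors `adduct_conc` and `abundance`.
#' @export
supersome_reference <- function() {
  iso <- c("CYP1A1", "CYP1A2", "CYP2A6", "CYP3A4", "CYP3A5",
           "CYP2B6", "CYP2C9", "CYP2C19", "CYP2D6", "CYP2E1")
  list(
    adduct_conc = stats::setNames(
      c(34.2, 47.4, 451, 387, 292, 132, 71.1, 123, 153, 63.6), iso),
    abundance = stats::setNames(
      c(10, 39, 27, 93, 17, 16, 61, 11, 12.6, 64.5), iso)
  )
}

#' Fraction of metabolism attributable to CYP3A4
#'
#' Scales per-isoform adduct formation linearly with hepatic isoform
#' abundance (`weight_i = adduct_i * abundance_i`) and returns the CYP3A4
#' share of the total.
#'
#' @param adduct_conc named vector of adduct concentrations (nM), must
#'   include `CYP3A4`.
#' @param abundance named vector of hepatic abundances (pmol/mg), same
#'   names.
#' @return fraction in (0, 1].
#' @examples
#' ref <- supersome_reference()
#' compute_fm_cyp3a4(ref$adduct_conc, ref$abundance)
#' @export
compute_fm_cyp3a4 <- function(adduct_conc, abundance) {
  if (!setequal(names(adduct_conc), names(abundance))) {
    stop("adduct_conc and abundance must share the same isoform names", call. = FALSE)
  }
  if (any(adduct_conc < 0) || any(abundance < 0)) {
    stop("negative adduct or abundance values", call. = FALSE)
  }
  w <- adduct_conc * abundance[names(adduct_conc)]
  if (sum(w) == 0) stop("all scaled weights are zero", call. = FALSE)
  unname(w[["CYP3A4"]] / sum(w))
}

#' Fit the rifampicin two-compartment model by MCMC
#'
#' Estimates the four rate constants (and noise SD) of a tissue's
#' two-compartment model from an intracellular concentration-time profile
#' under a known regimen; volume and dose fraction are held at their
#' configured values.
#'
#' @param profile data.frame with `time_h`, `concentration_uM` for one tissue.
#' @param params tissue [rifampicin_2comp_params()] providing volume,
#'   dose fraction and initial rates.
#' @param dose_mg,dose_times regimen (defaults: 600 mg/day for 14 days).
#' @param n_iter,seed passed to [run_metropolis()].
#' @return list with `chains`, `summary` and `params` (modes inserted).
#' @export
fit_rifampicin_2comp <- function(profile, params,
                                 dose_mg = 600,
                                 dose_times = seq(0, by = 24, length.out = 14),
                                 n_iter = 3000, seed = 20240325) {
  profile <- profile[profile$concentration_uM > 0, ]
  if (nrow(profile) < 10) stop("need >= 10 points spanning absorption and elimination",
                               call. = FALSE)
  init <- c(k_depot = params$k_depot, k12 = params$k12, k21 = params$k21,
            k_e = params$k_e, sigma = 0.2)
  pred_fun <- function(theta) {
    p <- params
    p$k_depot <- theta[[1]]; p$k12 <- theta[[2]]
    p$k21 <- theta[[3]]; p$k_e <- theta[[4]]
    rif_conc_profile(p, profile$time_h, dose_mg, dose_times)
  }
  ll <- loglik_lognormal(profile$concentration_uM, pred_fun)
  chains <- run_metropolis(ll, log_uniform_prior(init, decades = 2), init,
                           n_iter = n_iter, seed = seed)
  summ <- summarize_posterior(chains)
  fitted <- params
  fitted$k_depot <- summ$mode[summ$parameter == "k_depot"]
  fitted$k12 <- summ$mode[summ$parameter == "k12"]
  fitted$k21 <- summ$mode[summ$parameter == "k21"]
  fitted$k_e <- summ$mode[summ$parameter == "k_e"]
  list(chains = chains, summary = summ, params = fitted)
}

#' Coupled retrorsine-rifampicin simulation
#'
#' Convenience wrapper: simulates the joint ODE system for a retrorsine
#' regimen plus a rifampicin regimen (both oral).
#'
#' @param tea retrorsine [dose_regimen()].
#' @param rif rifampicin [dose_regimen()] (empty `dose_times` disables the
#'   interaction).
#' @param sub,phys,rifp,ip parameter objects (defaults used if `NULL`).
#' @param t_end,dt_out passed to [simulate_pbtk()].
#' @return `sim_output`.
#' @export
coupled_simulate <- function(tea, rif, sub = substance_retrorsine(),
                             phys = build_reference_human(),
                             rifp = NULL, ip = NULL,
                             t_end, dt_out = 0.1) {
  simulate_pbtk(list(tea, rif), sub, phys, interaction = ip, rifp = rifp,
                t_end = t_end, dt_out = dt_out)
}

#' Retrorsine PBTK derivatives at given enzyme and inhibitor levels
#'
#' Exposes the retrorsine part of the joint right-hand side for a state of
#' retrorsine amounts, fixed relative CYP3A4 levels and fixed intracellular
#' rifampicin concentrations. Mainly for testing and inspection.
#'
#' @param t time (h).
#' @param state named retrorsine amounts (nmol) over the 19 retrorsine and
#'   cumulative states (missing names default to 0).
#' @param sub,phys parameter objects.
#' @param enzyme_level length-2 `c(liver, gut)` relative CYP3A4.
#' @param rif_conc length-2 `c(liver, gut)` rifampicin (uM).
#' @param ip,rifp interaction parameter objects.
#' @return named derivative vector over the retrorsine states (nmol/h).
#' @export
retrorsine_rhs <- function(t, state, sub = substance_retrorsine(),
                           phys = build_reference_human(),
                           enzyme_level = c(1, 1), rif_conc = c(0, 0),
                           ip = induction_params(),
                           rifp = rifampicin_2comp_params()) {
  if (any(!is.finite(state)) || any(state < 0)) {
    stop("state must be non-negative and finite", call. = FALSE)
  }
  ret_states <- .state_names[1:19]
  y <- stats::setNames(numeric(29), .state_names)
  y[names(state)] <- state
  y[["e_liv"]] <- enzyme_level[[1]]
  y[["e_gut"]] <- enzyme_level[[2]]
  y[["rifc_liv"]] <- rif_conc[[1]] * rifp$liver$central_volume * 1000
  y[["rifc_gut"]] <- rif_conc[[2]] * rifp$gut$central_volume * 1000
  rhs <- build_rhs(sub, phys, ip, rifp)
  d <- rhs(t, y, NULL)[[1]]
  stats::setNames(d[seq_along(ret_states)], ret_states)
}
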