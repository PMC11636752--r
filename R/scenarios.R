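# Exposure scenarios, 24-h exposure metrics, interaction ratios and local
# sensitivity analysis.

#' Exposure-scenario specification
#'
#' The two study scenarios: daily herbal-tea consumption delivering a fixed
#' retrorsine dose for five weeks, optionally combined with a two-week
#' daily therapeutic rifampicin course starting on day 4.
#'
#' @param name `"herbal_tea"` or `"herbal_tea_plus_rifampicin"`.
#' @param tea_dose retrorsine dose (ug/kg body weight/day).
#' @param tea_days number of daily tea doses.
#' @param rif_dose rifampicin dose (mg/day).
#' @param rif_start_day 1-based day index of the first rifampicin dose.
#' @param rif_days number of daily rifampicin doses.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(name = c("herbal_tea", "herbal_tea_plus_rifampicin"),
                          tea_dose = 0.019, tea_days = 35,
                          rif_dose = 600, rif_start_day = 4, rif_days = 14) {
  name <- match.arg(name)
  if (name == "herbal_tea_plus_rifampicin" &&
      rif_start_day + rif_days - 1 > tea_days) {
    stop("rifampicin window must lie within the tea window", call. = FALSE)
  }
  structure(list(name = name, tea_dose = tea_dose, tea_days = tea_days,
                 rif_dose = rif_dose, rif_start_day = rif_start_day,
                 rif_days = rif_days),
            class = "scenario_spec")
}

#' Build dose regimens for a scenario
#'
#' Converts the tea dose to nmol per administration
#' (`ug/kg/day * body_weight / mol_weight * 1e3`) and lays out the daily
#' schedules; rifampicin (if present) runs daily from `rif_start_day`.
#'
#' @param spec a [scenario_spec()].
#' @param sub,phys parameter objects.
#' @return list with `tea` and `rif` [dose_regimen()] objects (the `rif`
#'   regimen has no dose times for the tea-only scenario).
#' @examples
#' reg <- make_scenario(scenario_spec("herbal_tea"))
#' sum(rep(reg$tea$dose_amount, length(reg$tea$dose_times))) # ~138 nmol
#' @export
make_scenario <- function(spec, sub = substance_retrorsine(),
                          phys = build_reference_human()) {
  tea_nmol <- spec$tea_dose * phys$body_weight / sub$mol_weight * 1e3
  tea <- dose_regimen("retrorsine", tea_nmol,
                      seq(0, by = 24, length.out = spec$tea_days))
  rif_times <- if (spec$name == "herbal_tea_plus_rifampicin") {
    seq((spec$rif_start_day - 1) * 24, by = 24, length.out = spec$rif_days)
  } else {
    numeric(0)
  }
  rif <- dose_regimen("rifampicin", spec$rif_dose, rif_times)
  list(tea = tea, rif = rif)
}

#' Simulate a scenario
#'
#' @param spec a [scenario_spec()].
#' @param sub,phys,rifp,ip parameter objects.
#' @param extra_days days simulated beyond the last tea dose.
#' @param dt_out output grid (h).
#' @return `sim_output`.
#' @export
run_scenario <- function(spec, sub = substance_retrorsine(),
                         phys = build_reference_human(),
                         rifp = NULL, ip = NULL, extra_days = 1,
                         dt_out = 0.1) {
  reg <- make_scenario(spec, sub, phys)
  simulate_pbtk(list(reg$tea, reg$rif), sub, phys, interaction = ip,
                rifp = rifp, t_end = (spec$tea_days + extra_days) * 24,
                dt_out = dt_out)
}

#' AUC and Cmax over 24-h windows
#'
#' Trapezoidal 24-h area-under-the-curve and window maximum of the three
#' reported matrices (venous plasma, liver cellular space, gut tissue).
#'
#' @param simout `sim_output` with dense output (<= 0.1 h spacing).
#' @param window_starts named vector of window start times (h); each window
#'   is `[t0, t0 + 24)` and must lie within the simulated span.
#' @return data.frame with `day_label`, `matrix`, `auc24` (nmol/L*h),
#'   `cmax` (nmol/L).
#' @export
auc_cmax_by_day <- function(simout, window_starts) {
  if (is.null(names(window_starts))) {
    names(window_starts) <- paste0("window_", seq_along(window_starts))
  }
  rows <- list()
  for (i in seq_along(window_starts)) {
    t0 <- window_starts[[i]]
    sel <- simout$time >= t0 & simout$time <= t0 + 24
    if (t0 < 0 || t0 + 24 > max(simout$time) + 1e-9) {
      stop("window beyond simulated span: ", names(window_starts)[i], call. = FALSE)
    }
    tt <- simout$time[sel]
    for (mx in colnames(simout$conc)) {
      yy <- simout$conc[sel, mx]
      rows[[length(rows) + 1]] <- data.frame(
        day_label = names(window_starts)[i], matrix = mx,
        auc24 = trapz(tt, yy), cmax = max(yy))
    }
  }
  do.call(rbind, rows)
}

# Window start times for the scenario's reporting days.
scenario_windows <- function(spec, ref_day = 3) {
  if (spec$name == "herbal_tea") {
    return(c(reference = (ref_day - 1) * 24))
  }
  t_first <- (spec$rif_start_day - 1) * 24
  t_last <- t_first + (spec$rif_days - 1) * 24
  c(first_1 = t_first, first_3 = t_first + 2 * 24, first_14 = t_first + 13 * 24,
    last_2 = t_last + 2 * 24, last_6 = t_last + 6 * 24, last_14 = t_last + 14 * 24)
}

#' Table of scenario exposure metrics
#'
#' For the tea-only scenario: the steady-state reference day (day 3 of
#' dosing). For the combined scenario: days 1, 3 and 14 after the first
#' rifampicin dose (windows starting at the dose time) and days 2, 6 and
#' 14 after the last dose (windows starting 24 h after the final
#' administration, so `last_2` covers 48-72 h post-dose).
#'
#' @param simout `sim_output` from [run_scenario()].
#' @param spec the matching [scenario_spec()].
#' @return data.frame as in [auc_cmax_by_day()].
#' @export
scenario_metrics <- function(simout, spec) {
  w <- scenario_windows(spec)
  w <- w[w + 24 <= max(simout$time) + 1e-9] # shortened runs report fewer days
  auc_cmax_by_day(simout, w)
}

#' Daily and cumulative pathway-resolved metabolite formation
#'
#' Daily amounts are differences of the cumulative CYP3A4 / non-CYP3A4
#' metabolite integrals at day bounds; cumulative amounts are reported at
#' the end of the simulation.
#'
#' @param simout `sim_output`.
#' @return list with `daily` (data.frame: day, pathway, tissue,
#'   amount_nmol) and `cumulative` (named vector at the last output time).
#' @export
metabolite_formation_report <- function(simout) {
  cols <- c(cyp3a4_liver = "cmet_3a4_liv", other_liver = "cmet_oth_liv",
            cyp3a4_gut = "cmet_3a4_gut", other_gut = "cmet_oth_gut")
  n_days <- floor(max(simout$time) / 24)
  bounds <- vapply(0:n_days * 24, function(tb) which.min(abs(simout$time - tb)),
                   integer(1))
  daily <- do.call(rbind, lapply(names(cols), function(nm) {
    cum <- simout$amounts[bounds, cols[[nm]]]
    data.frame(day = seq_len(n_days),
               pathway = sub("_.*", "", nm),
               tissue = sub(".*_", "", nm),
               amount_nmol = diff(cum))
  }))
  cumulative <- stats::setNames(
    simout$amounts[nrow(simout$amounts), cols], names(cols))
  list(daily = daily, cumulative = cumulative)
}

#' Interaction ratios as percent of reference
#'
#' Elementwise `100 * test / ref` over the numeric columns of two matching
#' metric tables.
#'
#' @param test,ref data.frames with identical layout (e.g. rows of
#'   [auc_cmax_by_day()] for matching windows).
#' @return data.frame with ratios in percent.
#' @export
interaction_ratio_table <- function(test, ref) {
  num <- vapply(test, is.numeric, logical(1))
  if (any(vapply(ref[num], function(x) any(x == 0), logical(1)))) {
    stop("zero reference value in ratio computation", call. = FALSE)
  }
  out <- test
  out[num] <- 100 * test[num] / ref[num]
  out
}

#' Local sensitivity coefficients of the interaction parameters
#'
#' Normalized sensitivity of the five-week cumulative CYP3A4 metabolite
#' amounts (liver, gut) in the combined scenario to +-10% perturbations of
#' the interaction parameters: `S = (dA/A0) / (dp/p0)`.
#'
#' @param spec combined-scenario [scenario_spec()].
#' @param sub,phys,rifp,ip parameter objects.
#' @param params character subset of
#'   `c("fm_cyp3a4", "ec50", "emax", "ki")`.
#' @param perturbation relative perturbation (default 0.1).
#' @param dt_out output grid (h); the endpoint is insensitive to it.
#' @return data.frame with `parameter`, `direction`, `tissue`,
#'   `coefficient`.
#' @export
sensitivity_coefficients <- function(spec = scenario_spec("herbal_tea_plus_rifampicin"),
                                     sub = substance_retrorsine(),
                                     phys = build_reference_human(),
                                     rifp = NULL, ip = NULL,
                                     params = c("fm_cyp3a4", "ec50", "emax", "ki"),
                                     perturbation = 0.1, dt_out = 0.5) {
  params <- match.arg(params, several.ok = TRUE)
  if (is.null(ip)) ip <- induction_params()
  endpoint <- function(sub_i, ip_i) {
    sim <- run_scenario(spec, sub_i, phys, rifp = rifp, ip = ip_i,
                        extra_days = 0, dt_out = dt_out)
    # cumulative CYP3A4 metabolites at exactly 5 weeks
    i5 <- which.min(abs(sim$time - spec$tea_days * 24))
    c(liver = unname(sim$amounts[i5, "cmet_3a4_liv"]),
      gut = unname(sim$amounts[i5, "cmet_3a4_gut"]))
  }
  a0 <- endpoint(sub, ip)
  rows <- list()
  for (p in params) {
    for (dir in c(-1, 1)) {
      sub_i <- sub; ip_i <- ip
      if (p == "fm_cyp3a4") {
        sub_i$fm_cyp3a4 <- sub$fm_cyp3a4 * (1 + dir * perturbation)
      } else {
        ip_i[[p]] <- ip[[p]] * (1 + dir * perturbation)
      }
      a1 <- endpoint(sub_i, ip_i)
      coef <- (a1 - a0) / a0 / (dir * perturbation)
      rows[[length(rows) + 1]] <- data.frame(
        parameter = p, direction = ifelse(dir > 0, "+10%", "-10%"),
        tissue = names(coef), coefficient = unname(coef))
    }
  }
  do.call(rbind, rows)
}
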