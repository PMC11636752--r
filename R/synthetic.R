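# Seeded synthetic-data generators emulating the study's raw inputs:
# medium-loss depletion, microsomal depletion, and intracellular
# rifampicin profiles. All generators are pure functions of
# (truth, design, seed) with multiplicative lognormal noise.

#' Noise specification for synthetic datasets
#'
#' Multiplicative lognormal noise: an observation is
#' `truth * exp(rnorm(1, 0, sdlog))` with `sdlog = sqrt(log(1 + cv^2))`.
#'
#' @param cv coefficient of variation (>= 0; default 0.1, a typical
#'   bioanalytical assay CV).
#' @param seed integer RNG seed.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(cv = 0.1, seed = 20240325) {
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  structure(list(cv = cv, seed = as.integer(seed)), class = "noise_spec")
}

with_noise <- function(truth, noise, n_stream = 0L) {
  if (noise$cv == 0) return(truth)
  old_seed_state <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed_state)) assign(".Random.seed", old_seed_state, globalenv()))
  set.seed(noise$seed + n_stream)
  sdlog <- sqrt(log(1 + noise$cv^2))
  truth * exp(stats::rnorm(length(truth), 0, sdlog))
}

#' Synthetic medium-loss dataset
#'
#' Replicate design of the hepatocyte medium-loss assay: `n_bio`
#' biological x `n_tech` technical replicates observed at `times` around a
#' monoexponential depletion truth.
#'
#' @param lambda_rate depletion rate constant (1/h).
#' @param c0 initial concentration (uM).
#' @param times sampling times (h).
#' @param n_bio,n_tech replicate counts (defaults 4 and 2).
#' @param noise a [noise_spec()].
#' @param condition label stored in the `condition` column (e.g. 37).
#' @return tidy in-vitro data.frame (`|times| * n_bio * n_tech` rows).
#' @export
gen_medium_loss_dataset <- function(lambda_rate, c0, times = c(0, 0.5, 1, 2, 4, 6, 24),
                                    n_bio = 4, n_tech = 2,
                                    noise = noise_spec(), condition = 37) {
  design <- expand.grid(bio = seq_len(n_bio), tech = seq_len(n_tech),
                        time_h = times)
  truth <- monoexponential_depletion(lambda_rate, c0, design$time_h)
  data.frame(
    assay_id = "medium_loss",
    condition = condition,
    replicate_id = paste0("b", design$bio, "t", design$tech),
    time_h = design$time_h,
    concentration_uM = with_noise(truth, noise)
  )
}

#' Synthetic microsomal depletion dataset
#'
#' End-product inhibition depletion trajectories at the assay's initial
#' concentrations, in technical duplicate, with multiplicative noise.
#'
#' @param params list with `vmax_invitro` (uM/min), `km` (uM), `ic50` (uM).
#' @param c0_list initial concentrations (uM).
#' @param times sampling times (h; converted to minutes internally).
#' @param n_tech technical replicates.
#' @param noise a [noise_spec()].
#' @return tidy in-vitro data.frame (`condition` = initial concentration).
#' @export
gen_microsomal_dataset <- function(params, c0_list = c(1, 15, 50, 200),
                                   times = c(0, 5, 10, 20, 30, 45, 60) / 60,
                                   n_tech = 2, noise = noise_spec()) {
  out <- list()
  for (i in seq_along(c0_list)) {
    sim <- simulate_microsomal_depletion(params, c0_list[i], times * 60)
    for (r in seq_len(n_tech)) {
      out[[length(out) + 1]] <- data.frame(
        assay_id = "microsomal",
        condition = c0_list[i],
        replicate_id = paste0("t", r),
        time_h = times,
        concentration_uM = with_noise(sim$substrate_uM, noise,
                                      n_stream = i * 10L + r)
      )
    }
  }
  do.call(rbind, out)
}

#' Synthetic intracellular rifampicin profiles
#'
#' Noisy observations of the two-compartment solution in liver and gut
#' under a daily oral regimen.
#'
#' @param rifp [rifampicin_2comp_params()] pair (`liver`, `gut`).
#' @param dose_mg per-dose amount (mg); 0 gives a zero profile.
#' @param dose_times dosing times (h).
#' @param times sampling grid (h).
#' @param noise a [noise_spec()].
#' @return data.frame with `tissue`, `time_h`, `concentration_uM`.
#' @export
gen_rifampicin_profiles <- function(rifp = rifampicin_2comp_params(),
                                    dose_mg = 600,
                                    dose_times = seq(0, by = 24, length.out = 14),
                                    times = seq(0, 384, by = 2),
                                    noise = noise_spec()) {
  out <- lapply(c("liver", "gut"), function(tt) {
    truth <- if (dose_mg == 0) numeric(length(times)) else {
      rif_conc_profile(rifp[[tt]], times, dose_mg, dose_times)
    }
    data.frame(tissue = tt, time_h = times,
               concentration_uM = with_noise(truth, noise,
                                             n_stream = ifelse(tt == "liver", 1L, 2L)))
  })
  do.call(rbind, out)
}
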