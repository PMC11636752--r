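# In-vitro depletion models and IVIVE scaling.

#' Monoexponential medium-loss model
#'
#' Depletion of parent compound from incubation medium over cultured
#' hepatocytes, `C(t) = c0 * exp(-lambda * t)`. At 4 C the rate constant
#' reflects passive diffusion only; at 37 C passive plus active transport.
#'
#' @param lambda_rate first-order depletion rate constant (1/h), >= 0.
#' @param c0 initial medium concentration (uM), > 0.
#' @param t time (h), vectorized, >= 0.
#' @return concentration (uM) at `t`.
#' @examples
#' monoexponential_depletion(0.0696, c0 = 1, t = c(0, 12, 24))
#' @export
monoexponential_depletion <- function(lambda_rate, c0, t) {
  if (lambda_rate < 0) stop("lambda_rate must be >= 0", call. = FALSE)
  stopifnot_positive(c0, "c0")
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  c0 * exp(-lambda_rate * t)
}

#' End-product inhibition depletion kinetics (right-hand side)
#'
#' Substrate depletion in a closed microsomal incubation where the reactive
#' product irreversibly inhibits the metabolizing enzymes:
#' `v = vmax * S / ((km + S) * (1 + P / ic50))`, `dS/dt = -v`, `dP/dt = +v`.
#' Substrate plus product is conserved exactly. Time unit: minutes.
#'
#' @param state numeric length-2, `c(substrate, product)` in uM, non-negative.
#' @param params list/object with `vmax_invitro` (uM/min), `km` (uM),
#'   `ic50` (uM), all > 0 (`ic50 = Inf` recovers plain Michaelis-Menten).
#' @return derivatives `c(dS, dP)` in uM/min.
#' @export
end_product_inhibition_rhs <- function(state, params) {
  if (any(!is.finite(state)) || any(state < 0)) {
    stop("state must be non-negative and finite", call. = FALSE)
  }
  stopifnot_positive(c(params$vmax_invitro, params$km), "end-product inhibition params")
  if (params$ic50 <= 0) stop("ic50 must be > 0", call. = FALSE)
  s <- state[[1]]; p <- state[[2]]
  v <- params$vmax_invitro * s / ((params$km + s) * (1 + p / params$ic50))
  c(-v, v)
}

#' Integrate the microsomal end-product inhibition model
#'
#' @param params see [end_product_inhibition_rhs()].
#' @param c0 initial substrate concentration (uM).
#' @param times output times (min).
#' @param p0 initial product concentration (uM), default 0.
#' @return data.frame with `time_min`, `substrate_uM`, `product_uM`.
#' @export
simulate_microsomal_depletion <- function(params, c0, times, p0 = 0) {
  stopifnot_positive(c0, "c0")
  rhs <- function(t, y, p) list(end_product_inhibition_rhs(y, p))
  out <- deSolve::ode(
    y = c(S = c0, P = p0), times = sort(unique(c(0, times))), func = rhs,
    parms = params, method = "lsoda", rtol = 1e-10, atol = 1e-12
  )
  out <- as.data.frame(out)
  out <- out[match(times, out$time), , drop = FALSE]
  data.frame(time_min = times, substrate_uM = out$S, product_uM = out$P,
             row.names = NULL)
}

#' IVIVE of hepatic transport clearances
#'
#' Scales the 4 C and 37 C medium-loss rate constants to whole-liver
#' passive diffusion and active uptake clearances. The composite per-rate
#' factor is `medium_volume * hepatocellularity / (cells_per_well * 60)`
#' (mL/g liver per 1/h). Passive diffusion scales with the 4 C rate; active
#' uptake with the temperature-dependent difference (37 C minus 4 C), so
#' the ratio `cl_act_in/ps_diff = (l37 - l4)/l4` independent of scaling.
#'
#' @param lambda_4c,lambda_37c depletion rate constants (1/h),
#'   `lambda_37c >= lambda_4c >= 0`.
#' @param scaling an [ivive_scaling()] object.
#' @return list with `ps_diff`, `cl_act_in` (mL/min/g liver).
#' @examples
#' ivive_hepatic_transport(0.00754, 0.0696)
#' @export
ivive_hepatic_transport <- function(lambda_4c, lambda_37c,
                                    scaling = ivive_scaling()) {
  if (lambda_4c < 0) stop("lambda_4c must be >= 0", call. = FALSE)
  if (lambda_37c < lambda_4c) {
    stop("lambda_37c < lambda_4c: active uptake would be negative", call. = FALSE)
  }
  factor_ml_g <- scaling$medium_volume * scaling$hepatocellularity /
    (scaling$cells_per_well * 60)
  list(
    ps_diff = lambda_4c * factor_ml_g,
    cl_act_in = (lambda_37c - lambda_4c) * factor_ml_g
  )
}

#' IVIVE of the maximum metabolic velocity
#'
#' Scales the in-vitro maximum depletion velocity (uM/min, i.e.
#' nmol/mL/min) to the whole-liver maximum velocity per gram using
#' microsomal protein content: `vmax_liv = vmax_invitro * mppgl /
#' microsomal_protein_conc` (nmol/min/g liver).
#'
#' @param vmax_invitro in-vitro maximum velocity (uM/min), >= 0.
#' @param scaling an [ivive_scaling()] object.
#' @return `vmax_liv` (nmol/min/g liver).
#' @examples
#' ivive_metabolic_vmax(0.817) # ~26.2
#' @export
ivive_metabolic_vmax <- function(vmax_invitro, scaling = ivive_scaling()) {
  if (vmax_invitro < 0) stop("vmax_invitro must be >= 0", call. = FALSE)
  vmax_invitro * scaling$mppgl / scaling$microsomal_protein_conc
}

#' Read/write tidy in-vitro depletion datasets
#'
#' CSV dialect: columns `assay_id`, `condition` (temperature in C or
#' initial concentration in uM), `replicate_id`, `time_h`,
#' `concentration_uM`.
#'
#' @param path file path.
#' @param data data.frame in the tidy in-vitro layout.
#' @return `read_invitro_csv`: the data.frame; `write_invitro_csv`: `path`,
#'   invisibly.
#' @export
read_invitro_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("assay_id", "condition", "replicate_id", "time_h", "concentration_uM")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' @rdname read_invitro_csv
#' @export
write_invitro_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}
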