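#' Predict racemization risk from a deprotonation energy
#'
#' The core prediction pipeline: a calibration line maps the energy to
#' log10 k_gb, the line's residual scatter gives multiplicative bounds, and
#' an exposure scenario converts the rate constant into a pseudo-first-order
#' k_obs, half-life and fraction racemized, finally binned into a risk
#' class.
#'
#' @param x deprotonation energy in kcal/mol: Sigma-DDG for the
#'   group-contribution lines, DDG(R1,R2,R3) for the QM line.
#' @param line a [calibration_line()]; default the non-aromatic
#'   group-contribution line.
#' @param scenario an [exposure_scenario()]; default blood-equivalent
#'   buffer, 24 h.
#' @param thresholds a [risk_thresholds()].
#' @return a `racemization_prediction` with fields `x_kcal_mol`, `domain`,
#'   `log_kgb`, `kgb_bounds` (named low/point/high, M^-1 s^-1), `k_obs`
#'   (s^-1), `half_life_s`, `fraction_racemized`, `risk_class`.
#' @examples
#' predict_racemization(-48.8)  # ~28% racemized in 24 h
#' @export
predict_racemization <- function(x,
                                 line = calibration_lines()$gc_nonaromatic,
                                 scenario = exposure_scenario(),
                                 thresholds = risk_thresholds()) {
  stopifnot(length(x) == 1L)
  log_kgb <- predict_log_kgb(x, line)
  bounds <- prediction_interval(log_kgb, line)
  k_obs <- .scenario_k_obs(10^log_kgb, scenario)
  fraction <- 1 - exp(-k_obs * scenario$duration_s)
  structure(
    list(
      x_kcal_mol = x,
      domain = line$domain,
      log_kgb = log_kgb,
      kgb_bounds = bounds,
      k_obs = k_obs,
      half_life_s = if (k_obs > 0) log(2) / k_obs else Inf,
      fraction_racemized = fraction,
      risk_class = classify_risk(fraction, thresholds),
      scenario = scenario
    ),
    class = "racemization_prediction"
  )
}

#' @export
print.racemization_prediction <- function(x, ...) {
  cat("<racemization_prediction> [", x$domain, "]\n", sep = "")
  cat(sprintf("  input energy:     %.4g kcal/mol\n", x$x_kcal_mol))
  cat(sprintf("  log10 kgb:        %.4g  (kgb %.3g [%.3g, %.3g] M^-1 s^-1)\n",
              x$log_kgb, x$kgb_bounds[["k_point"]],
              x$kgb_bounds[["k_low"]], x$kgb_bounds[["k_high"]]))
  cat(sprintf("  k_obs:            %.4g s^-1\n", x$k_obs))
  cat(sprintf("  half-life:        %.4g h\n", x$half_life_s / 3600))
  cat(sprintf("  racemized in %.3g h: %.1f%%  ->  risk %s\n",
              x$scenario$duration_s / 3600, 100 * x$fraction_racemized,
              x$risk_class))
  invisible(x)
}

#' @export
as.data.frame.racemization_prediction <- function(x, ...) {
  data.frame(
    x_kcal_mol = x$x_kcal_mol,
    domain = x$domain,
    log_kgb = x$log_kgb,
    k_low = x$kgb_bounds[["k_low"]],
    k_high = x$kgb_bounds[["k_high"]],
    k_obs = x$k_obs,
    half_life_h = x$half_life_s / 3600,
    frac_racemized = x$fraction_racemized,
    percent_racemized = round(100 * x$fraction_racemized, 1),
    risk = x$risk_class,
    stringsAsFactors = FALSE
  )
}
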