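# Kinetic observables and physiological predictions.
#
# Racemization here means loss of enantiomeric excess: ee(t) = ee0 *
# exp(-k_obs t), so fraction racemized = 1 - exp(-k_obs t) and half-life =
# ln(2)/k_obs. k_gb is the second-order rate constant for the ee-loss
# process, and k_obs = k_gb x [catalytic base].

#' Buffer specification
#'
#' @param total_concentration total buffer concentration, molar (> 0).
#' @param ph solution pH (0 < pH < 14).
#' @param pka pKa of the conjugate acid of the catalytic base (for
#'   phosphate, pKa2 of H2PO4-).
#' @param temperature_K absolute temperature, kelvin.
#' @return a `buffer_spec` object.
#' @export
buffer_spec <- function(total_concentration, ph, pka,
                        temperature_K = 310.15) {
  if (!is.numeric(total_concentration) || total_concentration <= 0) {
    stop("total_concentration must be > 0")
  }
  if (!is.numeric(ph) || ph <= 0 || ph >= 14) {
    stop("ph must be strictly between 0 and 14")
  }
  stopifnot(is.numeric(pka), is.numeric(temperature_K), temperature_K > 0)
  structure(list(total_concentration = total_concentration, ph = ph,
                 pka = pka, temperature_K = temperature_K),
            class = "buffer_spec")
}

#' Blood-equivalent phosphate buffer
#'
#' In terms of availability of catalytically active general base, blood
#' behaves like a 0.15 M phosphate buffer at pH 7.2. With pKa2 = 6.80
#' (physiological ionic strength) that is about 0.107 M dibasic phosphate
#' at 310.15 K.
#'
#' @return a `buffer_spec`.
#' @export
blood_buffer <- function() {
  buffer_spec(0.15, 7.2, 6.80, 310.15)
}

#' @export
print.buffer_spec <- function(x, ...) {
  cat(sprintf(
    "<buffer_spec> %.3g M total, pH %.2f, pKa %.2f, %.2f K (base: %.4g M)\n",
    x$total_concentration, x$ph, x$pka, x$temperature_K,
    base_concentration(x)))
  invisible(x)
}

#' Concentration of the catalytic (basic) buffer species
#'
#' Henderson-Hasselbalch with a single relevant ionization:
#' `[base] = total / (1 + 10^(pKa - pH))`.
#'
#' @param buffer a [buffer_spec()].
#' @return molar concentration of the basic species.
#' @examples
#' base_concentration(blood_buffer())  # ~0.1073 M
#' @export
base_concentration <- function(buffer) {
  stopifnot(inherits(buffer, "buffer_spec"))
  buffer$total_concentration / (1 + 10^(buffer$pka - buffer$ph))
}

#' Acid/base speciation of a buffer
#'
#' @param buffer a [buffer_spec()].
#' @return named numeric `c(acid, base)` in molar; sums to the total.
#' @export
buffer_speciation <- function(buffer) {
  b <- base_concentration(buffer)
  c(acid = buffer$total_concentration - b, base = b)
}

#' Kinetic trace container
#'
#' @param times_s strictly increasing times in seconds (>= 0), length >= 5.
#' @param signal observed signal: ellipticity (millidegrees) for
#'   `"cd_decay"`, deuterium fraction in `[0, 1]` for `"hd_exchange"`.
#' @param kind `"cd_decay"` or `"hd_exchange"`.
#' @return a `kinetic_trace` object.
#' @export
kinetic_trace <- function(times_s, signal,
                          kind = c("cd_decay", "hd_exchange")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(times_s), is.numeric(signal),
            length(times_s) == length(signal))
  if (length(times_s) < 5L) stop("a kinetic trace needs at least 5 points")
  if (any(times_s < 0) || any(diff(times_s) <= 0)) {
    stop("times must be non-negative and strictly increasing")
  }
  structure(list(times_s = times_s, signal = signal, kind = kind),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat("<kinetic_trace> ", x$kind, ", ", length(x$times_s), " points over ",
      format(max(x$times_s)), " s\n", sep = "")
  invisible(x)
}

#' Fit a pseudo-first-order rate constant to a kinetic trace
#'
#' Nonlinear least squares of
#' `signal = baseline + amplitude * exp(-k_obs * t)` (CD decay) or
#' `signal = plateau * (1 - exp(-k_obs * t))` (H/D exchange), with
#' `k_obs >= 0` enforced. Initial guesses are seeded analytically by
#' log-linear regression on the baseline-subtracted signal, which makes
#' convergence reproducible.
#'
#' @param trace a [kinetic_trace()].
#' @return a `first_order_fit` with fields `k_obs`, `amplitude`, `baseline`
#'   (for H/D exchange the plateau is returned as `amplitude` and the
#'   baseline is 0), `k_obs_se`, `kind`, and the fitted `nls` object.
#' @export
fit_first_order <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  t <- trace$times_s
  y <- trace$signal
  if (sd(y) == 0) stop("signal is constant; no decay to fit")

  if (trace$kind == "cd_decay") {
    b0 <- y[length(y)]
    a0 <- y[1] - b0
    if (a0 == 0) a0 <- (max(y) - min(y)) * sign(y[1] - mean(y) + 1e-300)
    k0 <- .seed_rate(t, y - b0, a0)
    fml <- y ~ baseline + amplitude * exp(-k_obs * t)
    start <- list(k_obs = k0, amplitude = a0, baseline = b0)
    lower <- c(k_obs = 0, amplitude = -Inf, baseline = -Inf)
  } else {
    a0 <- max(y) * 1.02 + 1e-12
    k0 <- .seed_rate(t, a0 - y, a0)
    fml <- y ~ amplitude * (1 - exp(-k_obs * t))
    start <- list(k_obs = k0, amplitude = a0)
    lower <- c(k_obs = 0, amplitude = -Inf)
  }

  df <- data.frame(t = t, y = y)
  fit <- tryCatch(
    nls(fml, data = df, start = start, algorithm = "port",
        lower = lower, control = stats::nls.control(maxiter = 200,
                                                    warnOnly = FALSE)),
    error = function(e) e
  )
  if (inherits(fit, "error") &&
      requireNamespace("minpack.lm", quietly = TRUE)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, data = df, start = start, lower = lower,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e
    )
  }
  if (inherits(fit, "error")) {
    stop("first-order fit did not converge (initial guesses: k_obs = ",
         format(k0), ", amplitude = ", format(start$amplitude),
         if (trace$kind == "cd_decay") paste0(", baseline = ", format(b0)),
         "): ", conditionMessage(fit))
  }
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit)))[["k_obs"]],
                 error = function(e) NA_real_)
  structure(
    list(k_obs = unname(est[["k_obs"]]),
         amplitude = unname(est[["amplitude"]]),
         baseline = if (trace$kind == "cd_decay") {
           unname(est[["baseline"]])
         } else 0,
         k_obs_se = se, kind = trace$kind, n = length(t), fit = fit),
    class = "first_order_fit"
  )
}

# log-linear seed for the decay rate from points where the decaying
# component is still resolved
.seed_rate <- function(t, decaying, a0) {
  z <- decaying / a0
  keep <- is.finite(z) & z > 1e-6
  if (sum(keep) >= 3L) {
    sl <- unname(coef(lm(log(z[keep]) ~ t[keep]))[2])
    if (is.finite(sl) && sl < 0) return(-sl)
  }
  1 / max(stats::median(t[t > 0]), 1e-12)
}

#' @export
print.first_order_fit <- function(x, ...) {
  cat(sprintf(
    "<first_order_fit> %s: k_obs = %.6g +/- %.2g s^-1 (n = %d)\n",
    x$kind, x$k_obs, x$k_obs_se, x$n))
  invisible(x)
}

#' @export
coef.first_order_fit <- function(object, ...) {
  c(k_obs = object$k_obs, amplitude = object$amplitude,
    baseline = object$baseline)
}

#' Correct an observed rate constant for a hydrolysis side reaction
#'
#' Racemization/exchange and hydrolysis are parallel first-order loss
#' channels, so the racemization component is `k_obs_total - k_hydrolysis`.
#' A slightly negative difference (within `2 * sqrt(se_total^2 + se_hyd^2)`)
#' is floored at 0 with a warning; a difference more negative than that is
#' unphysical and raises an error.
#'
#' @param k_obs_total total observed rate constant, s^-1 (>= 0).
#' @param k_hydrolysis hydrolysis rate constant, s^-1 (>= 0).
#' @param se_total,se_hydrolysis reported standard errors (>= 0).
#' @return corrected rate constant, s^-1.
#' @export
correct_hydrolysis <- function(k_obs_total, k_hydrolysis,
                               se_total = 0, se_hydrolysis = 0) {
  stopifnot(k_obs_total >= 0, k_hydrolysis >= 0,
            se_total >= 0, se_hydrolysis >= 0)
  diff <- k_obs_total - k_hydrolysis
  if (diff >= 0) return(diff)
  tol <- 2 * sqrt(se_total^2 + se_hydrolysis^2)
  if (-diff <= tol) {
    warning("k_hydrolysis exceeds k_obs_total within uncertainty; ",
            "flooring corrected rate at 0")
    return(0)
  }
  stop("k_hydrolysis (", format(k_hydrolysis),
       ") exceeds k_obs_total (", format(k_obs_total),
       ") by more than the combined uncertainty")
}

#' Extract the second-order rate constant from a buffer-dilution series
#'
#' Ordinary least squares of k_obs against the concentration of the basic
#' buffer component: the slope is k_gb and the intercept collects
#' buffer-independent contributions (water, hydroxide). A negative slope is
#' returned as-is with a warning flag rather than clamped.
#'
#' @param measurements a data.frame with columns `base_concentration`
#'   (molar) and `k_obs` (s^-1), optionally `k_obs_se`; at least 3 rows with
#'   at least 2 distinct concentrations.
#' @return a `buffer_series_fit` with fields `kgb`, `kgb_se`, `intercept`,
#'   `intercept_se`, `r2`, `negative_slope`.
#' @export
extract_kgb <- function(measurements) {
  m <- as.data.frame(measurements)
  if (!all(c("base_concentration", "k_obs") %in% names(m))) {
    stop("measurements must have columns 'base_concentration' and 'k_obs'")
  }
  if (nrow(m) < 3L) stop("at least 3 measurements are required")
  if (length(unique(m$base_concentration)) < 2L) {
    stop("at least 2 distinct base concentrations are required")
  }
  fit <- lm(k_obs ~ base_concentration, data = m)
  # noiseless series fit exactly; the "perfect fit" note is not informative
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- unname(coef(fit)[["base_concentration"]])
  neg <- slope < 0
  if (neg) {
    warning("negative slope: no detectable general-base catalysis ",
            "(or an inconsistent series)")
  }
  structure(
    list(kgb = slope,
         kgb_se = unname(sm["base_concentration", "Std. Error"]),
         intercept = unname(coef(fit)[["(Intercept)"]]),
         intercept_se = unname(sm["(Intercept)", "Std. Error"]),
         r2 = suppressWarnings(summary(fit))$r.squared, n = nrow(m),
         negative_slope = neg, fit = fit),
    class = "buffer_series_fit"
  )
}

#' @export
print.buffer_series_fit <- function(x, ...) {
  cat(sprintf(
    "<buffer_series_fit> kgb = %.6g +/- %.2g M^-1 s^-1, intercept = %.3g s^-1 (n = %d)\n",
    x$kgb, x$kgb_se, x$intercept, x$n))
  if (x$negative_slope) cat("  WARNING: negative slope\n")
  invisible(x)
}

#' @export
coef.buffer_series_fit <- function(object, ...) {
  c(kgb = object$kgb, intercept = object$intercept)
}

#' Correct an apparent rate constant for substrate protonation state
#'
#' When only a fraction of the substrate is in the reactive protonation
#' state, the intrinsic rate constant is the apparent one divided by that
#' fraction.
#'
#' @param kgb_apparent apparent second-order rate constant, M^-1 s^-1.
#' @param reactive_fraction fraction of substrate in the reactive state,
#'   in `(0, 1]`.
#' @return corrected rate constant, M^-1 s^-1.
#' @export
protonation_correction <- function(kgb_apparent, reactive_fraction) {
  if (!is.numeric(reactive_fraction) || reactive_fraction <= 0 ||
      reactive_fraction > 1) {
    stop("reactive_fraction must be in (0, 1]")
  }
  kgb_apparent / reactive_fraction
}

#' Arrhenius temperature correction of a rate constant
#'
#' `k(T_ref) = k(T_obs) * exp((Ea/R) * (1/T_obs - 1/T_ref))` with R in
#' kcal/(mol K). Identity when the two temperatures coincide or Ea is 0.
#'
#' @param k rate constant at `t_obs_K`.
#' @param t_obs_K temperature at which `k` was measured, kelvin.
#' @param t_ref_K target temperature, kelvin.
#' @param ea_kcal_mol activation energy, kcal/mol.
#' @return rate constant corrected to `t_ref_K`.
#' @export
temperature_correction <- function(k, t_obs_K, t_ref_K, ea_kcal_mol) {
  stopifnot(t_obs_K > 0, t_ref_K > 0, is.finite(ea_kcal_mol))
  R <- 1.987204259e-3  # kcal / (mol K)
  k * exp((ea_kcal_mol / R) * (1 / t_obs_K - 1 / t_ref_K))
}

#' Exposure scenario for physiological predictions
#'
#' @param buffer a [buffer_spec()]; defaults to the blood-equivalent
#'   phosphate buffer.
#' @param duration_s exposure time in seconds (default 24 h).
#' @param temperature_correction `NULL` (none; the calibration is used
#'   as-is) or a list `list(ea_kcal_mol =, t_obs_K =)` Arrhenius-correcting
#'   the predicted rate constant from `t_obs_K` to the buffer temperature.
#' @return an `exposure_scenario` object.
#' @export
exposure_scenario <- function(buffer = blood_buffer(), duration_s = 86400,
                              temperature_correction = NULL) {
  stopifnot(inherits(buffer, "buffer_spec"),
            is.numeric(duration_s), duration_s >= 0, is.finite(duration_s))
  if (!is.null(temperature_correction)) {
    stopifnot(is.list(temperature_correction),
              !is.null(temperature_correction$ea_kcal_mol),
              !is.null(temperature_correction$t_obs_K))
  }
  structure(list(buffer = buffer, duration_s = duration_s,
                 temperature_correction = temperature_correction),
            class = "exposure_scenario")
}

# k_obs for a given kgb under a scenario, applying the optional Arrhenius
# correction
.scenario_k_obs <- function(kgb, scenario) {
  k <- kgb * base_concentration(scenario$buffer)
  tc <- scenario$temperature_correction
  if (!is.null(tc)) {
    k <- temperature_correction(k, t_obs_K = tc$t_obs_K,
                                t_ref_K = scenario$buffer$temperature_K,
                                ea_kcal_mol = tc$ea_kcal_mol)
  }
  k
}

#' Fraction racemized under an exposure scenario
#'
#' `fraction = 1 - exp(-k_obs * duration)` with
#' `k_obs = k_gb x [catalytic base]`.
#'
#' @param kgb second-order rate constant for racemization (ee loss),
#'   M^-1 s^-1 (>= 0).
#' @param scenario an [exposure_scenario()].
#' @return fraction racemized in `[0, 1]`.
#' @examples
#' racemized_fraction(10^-4.442, exposure_scenario())  # ~0.285
#' @export
racemized_fraction <- function(kgb, scenario = exposure_scenario()) {
  if (!is.numeric(kgb) || any(kgb < 0)) stop("kgb must be >= 0")
  stopifnot(inherits(scenario, "exposure_scenario"))
  k_obs <- .scenario_k_obs(kgb, scenario)
  1 - exp(-k_obs * scenario$duration_s)
}

#' Risk-class thresholds on the 24-hour racemized fraction
#'
#' @param low upper bound (exclusive) of the low-risk class.
#' @param high upper bound (inclusive) of the medium-risk class; fractions
#'   strictly above it are high risk.
#' @return a `risk_thresholds` object.
#' @export
risk_thresholds <- function(low = 0.01, high = 0.10) {
  if (!is.numeric(low) || !is.numeric(high) || is.na(low) || is.na(high) ||
      low < 0 || high > 1 || low >= high) {
    stop("thresholds must satisfy 0 <= low < high <= 1")
  }
  structure(list(low = low, high = high), class = "risk_thresholds")
}

#' Classify a racemized fraction into a risk class
#'
#' Defaults: fraction < 0.01 is `"low"`, 0.01 to 0.10 (upper bound closed)
#' is `"medium"`, above 0.10 is `"high"`.
#'
#' @param fraction fraction racemized in `[0, 1]`, or a
#'   `racemization_prediction`.
#' @param thresholds a [risk_thresholds()].
#' @return `"low"`, `"medium"` or `"high"` (vectorized over `fraction`).
#' @export
classify_risk <- function(fraction, thresholds = risk_thresholds()) {
  if (inherits(fraction, "racemization_prediction")) {
    fraction <- fraction$fraction_racemized
  }
  stopifnot(inherits(thresholds, "risk_thresholds"))
  if (any(fraction < 0 | fraction > 1)) {
    stop("fraction must be in [0, 1]")
  }
  ifelse(fraction < thresholds$low, "low",
         ifelse(fraction <= thresholds$high, "medium", "high"))
}
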