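# Calibrated linear free-energy relationships: log10(k_gb) as an affine
# function of a deprotonation energy (kcal/mol), one line per domain:
#   qm             - quantum-chemical DDG(R1,R2,R3)
#   gc_nonaromatic - Sigma-DDG, centers whose anion is not cyclically aromatic
#   gc_aromatic    - Sigma-DDG, centers giving a potentially aromatic anion

#' Construct a calibration line
#'
#' @param domain one of `"qm"`, `"gc_nonaromatic"`, `"gc_aromatic"` or a
#'   free-text tag for user-fitted lines.
#' @param slope slope in log10(M^-1 s^-1) per kcal/mol.
#' @param intercept intercept in log10(M^-1 s^-1).
#' @param rmse root-mean-square residual of the fit, log10 units (>= 0).
#' @param r2 coefficient of determination in `[0, 1]` (may be `NA`).
#' @return a `calibration_line` object.
#' @export
calibration_line <- function(domain, slope, intercept, rmse = NA_real_,
                             r2 = NA_real_) {
  stopifnot(is.character(domain), length(domain) == 1L)
  for (v in list(slope, intercept)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("slope and intercept must be finite numbers")
    }
  }
  if (!is.na(rmse) && rmse < 0) stop("rmse must be >= 0")
  if (!is.na(r2) && (r2 < 0 || r2 > 1)) stop("r2 must be in [0, 1]")
  structure(list(domain = domain, slope = slope, intercept = intercept,
                 rmse = rmse, r2 = r2),
            class = "calibration_line")
}

#' Shipped calibration lines
#'
#' The three calibrated relationships mapping deprotonation energies to
#' log10 k_gb:
#' \describe{
#'   \item{qm}{log10(k_gb) = -0.20 x DDG(R1,R2,R3) - 14.28 (RMSE 0.61,
#'     R^2 0.68)}
#'   \item{gc_nonaromatic}{log10(k_gb) = -0.11 x Sigma-DDG - 9.81 (RMSE 0.40,
#'     R^2 0.78)}
#'   \item{gc_aromatic}{log10(k_gb) = -0.26 x Sigma-DDG - 16.95 (RMSE 0.39,
#'     R^2 0.92)}
#' }
#'
#' @return a named list of `calibration_line` objects.
#' @export
calibration_lines <- function() {
  list(
    qm = calibration_line("qm", -0.20, -14.28, 0.61, 0.68),
    gc_nonaromatic = calibration_line("gc_nonaromatic", -0.11, -9.81,
                                      0.40, 0.78),
    gc_aromatic = calibration_line("gc_aromatic", -0.26, -16.95, 0.39, 0.92)
  )
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf("<calibration_line> %s: log10(kgb) = %s x + %s\n",
              x$domain, format(x$slope), format(x$intercept)))
  if (!is.na(x$rmse) || !is.na(x$r2)) {
    cat(sprintf("  RMSE = %s log units, R^2 = %s\n",
                format(x$rmse), format(x$r2)))
  }
  invisible(x)
}

#' @export
coef.calibration_line <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict log10 k_gb from a deprotonation energy
#'
#' @param x deprotonation energy in kcal/mol (Sigma-DDG for the
#'   group-contribution lines, DDG(R1,R2,R3) for the QM line); vectorized.
#' @param line a `calibration_line`.
#' @return log10 k_gb in log10(M^-1 s^-1).
#' @examples
#' predict_log_kgb(-54.1, calibration_lines()$gc_nonaromatic)  # -3.859
#' @export
predict_log_kgb <- function(x, line) {
  stopifnot(inherits(line, "calibration_line"))
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("'x' must be finite numeric (kcal/mol)")
  }
  line$slope * x + line$intercept
}

#' @export
predict.calibration_line <- function(object, newdata, ...) {
  predict_log_kgb(newdata, object)
}

#' Multiplicative prediction interval around a predicted rate constant
#'
#' The residual scatter of a calibration line, expressed in log10 units,
#' translates into a multiplicative uncertainty factor `f = 10^rmse` on the
#' rate constant: bounds are `k/f` and `k*f`. The shipped QM line (RMSE
#' 0.61) gives f of about 4.
#'
#' @param log_kgb predicted log10 k_gb.
#' @param line a `calibration_line` with non-missing `rmse`.
#' @return named numeric `c(k_low, k_point, k_high)` in M^-1 s^-1.
#' @export
prediction_interval <- function(log_kgb, line) {
  stopifnot(inherits(line, "calibration_line"))
  rmse <- if (is.na(line$rmse)) 0 else line$rmse
  if (rmse < 0) stop("line rmse must be >= 0")
  k <- 10^log_kgb
  f <- 10^rmse
  c(k_low = k / f, k_point = k, k_high = k * f)
}

#' Fit a calibration line by ordinary least squares
#'
#' Points flagged `excluded` never enter the fit. With
#' `aggregate_by_class = TRUE` all points sharing a `class_label` are first
#' replaced by their class mean (mean x, mean log k_gb), so that heavily
#' represented center types cannot dominate the fit.
#'
#' @param data a data.frame with columns `x_kcal_mol`, `log_kgb` and
#'   optionally `class_label` (default: each point its own class) and
#'   `excluded` (default `FALSE`).
#' @param aggregate_by_class collapse points to class means before fitting.
#' @param rmse_denominator `"n"` (default, root mean square of residuals) or
#'   `"n-2"` (residual standard error).
#' @param domain tag recorded on the fitted line.
#' @return a `calibration_fit` object: a `calibration_line` plus
#'   diagnostics (`n_points`, `n_fit`, fitted values, residuals).
#' @export
fit_line <- function(data, aggregate_by_class = TRUE,
                     rmse_denominator = c("n", "n-2"), domain = "user") {
  rmse_denominator <- match.arg(rmse_denominator)
  data <- as.data.frame(data)
  if (!all(c("x_kcal_mol", "log_kgb") %in% names(data))) {
    stop("data must have columns 'x_kcal_mol' and 'log_kgb'")
  }
  if (is.null(data$class_label)) {
    data$class_label <- paste0("p", seq_len(nrow(data)))
  }
  if (is.null(data$excluded)) data$excluded <- FALSE
  data <- data[!as.logical(data$excluded), , drop = FALSE]
  if (nrow(data) < 2L) stop("at least 2 non-excluded points are required")

  if (aggregate_by_class) {
    xs <- tapply(data$x_kcal_mol, data$class_label, mean)
    ys <- tapply(data$log_kgb, data$class_label, mean)
    fit_df <- data.frame(x = as.numeric(xs), y = as.numeric(ys))
  } else {
    fit_df <- data.frame(x = data$x_kcal_mol, y = data$log_kgb)
  }
  if (nrow(fit_df) < 2L) {
    stop("fewer than 2 distinct classes after aggregation")
  }
  if (sd(fit_df$x) == 0) stop("zero variance in x; cannot fit a line")

  fit <- lm(y ~ x, data = fit_df)
  res <- stats::residuals(fit)
  n <- nrow(fit_df)
  rmse <- if (rmse_denominator == "n") {
    sqrt(mean(res^2))
  } else {
    if (n <= 2L) stop("rmse denominator n-2 needs more than 2 points")
    sqrt(sum(res^2) / (n - 2L))
  }
  tss <- sum((fit_df$y - mean(fit_df$y))^2)
  r2 <- if (tss == 0) NA_real_ else 1 - sum(res^2) / tss
  line <- calibration_line(domain,
                           slope = unname(coef(fit)[["x"]]),
                           intercept = unname(coef(fit)[["(Intercept)"]]),
                           rmse = rmse,
                           r2 = if (!is.na(r2)) max(0, min(1, r2))
                                else NA_real_)
  line$n_points <- nrow(data)
  line$n_fit <- n
  line$fitted <- unname(stats::fitted(fit))
  line$residuals <- unname(res)
  line$aggregated <- aggregate_by_class
  class(line) <- c("calibration_fit", "calibration_line")
  line
}

#' @export
print.calibration_fit <- function(x, ...) {
  NextMethod()
  cat("  fitted on ", x$n_fit,
      if (x$aggregated) " class means" else " points",
      " (", x$n_points, " data points)\n", sep = "")
  invisible(x)
}

#' Compare Hammett correlations against sigma and sigma-minus
#'
#' Fits log k against both substituent-constant scales by ordinary least
#' squares and reports which correlates better (higher R^2). A better
#' correlation with sigma-minus indicates negative charge conjugated into
#' the aryl ring in the rate-determining step, as expected for an SE1
#' racemization. Exact ties prefer sigma-minus, with a warning.
#'
#' @param series a data.frame with columns `substituent`, `sigma`,
#'   `sigma_minus`, `log_k`; at least 3 rows.
#' @return a `hammett_fit` object with fields `rho_sigma`, `r2_sigma`,
#'   `rho_sigma_minus`, `r2_sigma_minus`, `preferred`.
#' @export
fit_hammett <- function(series) {
  series <- as.data.frame(series)
  need <- c("sigma", "sigma_minus", "log_k")
  if (!all(need %in% names(series))) {
    stop("series must have columns: substituent, sigma, sigma_minus, log_k")
  }
  if (nrow(series) < 3L) {
    stop("at least 3 substituent entries are required for a Hammett fit")
  }
  one <- function(x, y) {
    fit <- lm(y ~ x)
    tss <- sum((y - mean(y))^2)
    r2 <- if (tss == 0) NA_real_ else
      1 - sum(stats::residuals(fit)^2) / tss
    list(rho = unname(coef(fit)[["x"]]), r2 = r2)
  }
  fs <- one(series$sigma, series$log_k)
  fm <- one(series$sigma_minus, series$log_k)
  if (isTRUE(all.equal(fs$r2, fm$r2))) {
    warning("sigma and sigma-minus correlate equally well; ",
            "preferring sigma-minus by convention")
    preferred <- "sigma_minus"
  } else {
    preferred <- if (fm$r2 > fs$r2) "sigma_minus" else "sigma"
  }
  structure(
    list(rho_sigma = fs$rho, r2_sigma = fs$r2,
         rho_sigma_minus = fm$rho, r2_sigma_minus = fm$r2,
         preferred = preferred, n = nrow(series)),
    class = "hammett_fit"
  )
}

#' @export
print.hammett_fit <- function(x, ...) {
  cat("<hammett_fit> n = ", x$n, "\n", sep = "")
  cat(sprintf("  sigma:       rho = %s, R^2 = %s\n",
              format(x$rho_sigma), format(x$r2_sigma)))
  cat(sprintf("  sigma-minus: rho = %s, R^2 = %s\n",
              format(x$rho_sigma_minus), format(x$r2_sigma_minus)))
  cat("  preferred scale: ", x$preferred, "\n", sep = "")
  invisible(x)
}
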