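# Seeded synthetic-data generators with embedded ground truth. All
# generators are pure functions of (parameters, seed): the RNG state of the
# session is saved and restored, and the same spec always produces the same
# output.

#' Specification for a synthetic fixture
#'
#' @param seed integer RNG seed.
#' @param n_points number of points to generate.
#' @param noise `"gaussian"` or `"none"`.
#' @param sigma noise scale; for [gen_trace()] it is additive (signal
#'   units), for [gen_buffer_series()] it is the relative (fractional) error
#'   on k_obs, for [gen_calibration_dataset()] additive in log10 units.
#' @return a `fixture_spec` object.
#' @export
fixture_spec <- function(seed, n_points = 50L, noise = c("gaussian", "none"),
                         sigma = 0) {
  noise <- match.arg(noise)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  if (!is.numeric(n_points) || n_points < 1L) stop("invalid n_points")
  if (!is.numeric(sigma) || sigma < 0) stop("sigma must be >= 0")
  if (noise == "none") sigma <- 0
  structure(list(seed = as.integer(seed), n_points = as.integer(n_points),
                 noise = noise, sigma = sigma),
            class = "fixture_spec")
}

# run code under the fixture's seed without disturbing the caller's RNG
.with_fixture_seed <- function(spec, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(spec$seed)
  force(code)
}

#' Generate a synthetic exponential-decay trace
#'
#' Times are log-spaced over `[0, 5/k_obs]` (dense early sampling gives the
#' decay and the tail comparable weight); the signal is
#' `baseline + amplitude * exp(-k_obs t)` for `"cd_decay"` or
#' `amplitude * (1 - exp(-k_obs t))` for `"hd_exchange"`, plus optional
#' Gaussian noise. The generating parameters are attached as the
#' `ground_truth` attribute.
#'
#' @param k_obs true rate constant, s^-1 (> 0).
#' @param amplitude signal amplitude (plateau for H/D exchange).
#' @param baseline signal baseline (CD decay only).
#' @param spec a [fixture_spec()] (`n_points >= 5`).
#' @param kind trace kind, `"cd_decay"` (default) or `"hd_exchange"`.
#' @return a [kinetic_trace()] with a `ground_truth` attribute.
#' @export
gen_trace <- function(k_obs, amplitude, baseline = 0,
                      spec = fixture_spec(1), kind = "cd_decay") {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!is.numeric(k_obs) || k_obs <= 0) stop("k_obs must be > 0")
  if (spec$n_points < 5L) stop("a trace needs n_points >= 5")
  t_max <- 5 / k_obs
  times <- c(0, exp(seq(log(t_max / 200), log(t_max),
                        length.out = spec$n_points - 1L)))
  clean <- if (kind == "cd_decay") {
    baseline + amplitude * exp(-k_obs * times)
  } else {
    amplitude * (1 - exp(-k_obs * times))
  }
  noise <- if (spec$sigma > 0) {
    .with_fixture_seed(spec, rnorm(length(times), 0, spec$sigma))
  } else {
    numeric(length(times))
  }
  tr <- kinetic_trace(times, clean + noise, kind)
  attr(tr, "ground_truth") <- list(k_obs = k_obs, amplitude = amplitude,
                                   baseline = baseline, spec = spec)
  tr
}

#' Generate a synthetic buffer-dilution series
#'
#' `k_obs = intercept + kgb * [base]`, with optional relative Gaussian noise
#' (`spec$sigma` is the fractional error).
#'
#' @param kgb true second-order rate constant, M^-1 s^-1.
#' @param intercept buffer-independent rate, s^-1.
#' @param concentrations base concentrations, molar; at least 2 distinct.
#' @param spec a [fixture_spec()].
#' @return a data.frame (`base_concentration`, `k_obs`, `k_obs_se`) with a
#'   `ground_truth` attribute, ready for [extract_kgb()].
#' @export
gen_buffer_series <- function(kgb, intercept, concentrations,
                              spec = fixture_spec(1)) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (length(unique(concentrations)) < 2L) {
    stop("at least 2 distinct concentrations are required")
  }
  clean <- intercept + kgb * concentrations
  k_obs <- if (spec$sigma > 0) {
    clean * (1 + .with_fixture_seed(
      spec, rnorm(length(concentrations), 0, spec$sigma)))
  } else {
    clean
  }
  out <- data.frame(base_concentration = concentrations, k_obs = k_obs,
                    k_obs_se = abs(clean) * spec$sigma)
  attr(out, "ground_truth") <- list(kgb = kgb, intercept = intercept,
                                    spec = spec)
  out
}

#' Generate a synthetic calibration dataset
#'
#' Emulates the structure of a rate-constant-versus-energy calibration: each
#' stereocenter class has one energy value x (uniform over `x_range`) and
#' `members_per_class` replicate log k_gb values scattered around
#' `slope * x + intercept` with Gaussian noise in log10 units.
#'
#' @param line a [calibration_line()] supplying the true slope/intercept.
#' @param n_classes number of classes (>= 2).
#' @param members_per_class replicates per class.
#' @param noise_sigma log10-unit scatter of individual members.
#' @param spec a [fixture_spec()] (its `n_points`/`sigma` fields are
#'   ignored; `seed` drives everything).
#' @param x_range energy range the class x values are drawn from, kcal/mol.
#' @return a data.frame (`x_kcal_mol`, `log_kgb`, `class_label`, `excluded`)
#'   with a `ground_truth` attribute, ready for [fit_line()].
#' @export
gen_calibration_dataset <- function(line, n_classes, members_per_class = 1L,
                                    noise_sigma = 0,
                                    spec = fixture_spec(1),
                                    x_range = c(-65, -40)) {
  stopifnot(inherits(line, "calibration_line"),
            inherits(spec, "fixture_spec"))
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (members_per_class < 1L) stop("members_per_class must be >= 1")
  dat <- .with_fixture_seed(spec, {
    xs <- runif(n_classes, x_range[1], x_range[2])
    do.call(rbind, lapply(seq_len(n_classes), function(ci) {
      y <- line$slope * xs[ci] + line$intercept +
        if (noise_sigma > 0) rnorm(members_per_class, 0, noise_sigma)
        else numeric(members_per_class)
      data.frame(x_kcal_mol = xs[ci], log_kgb = y,
                 class_label = sprintf("class%02d", ci), excluded = FALSE,
                 stringsAsFactors = FALSE)
    }))
  })
  attr(dat, "ground_truth") <- list(slope = line$slope,
                                    intercept = line$intercept,
                                    noise_sigma = noise_sigma, spec = spec)
  dat
}
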