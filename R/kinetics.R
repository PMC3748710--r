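# Kinetic analyses: initial rates, first-order progress curves,
# single-exponential sliding fits, Michaelis-Menten ATPase fits with basal
# correction, and relative rates with propagated uncertainty.

#' Construct a kinetic time course
#'
#' @param times Times in minutes, nonnegative and strictly increasing.
#' @param values Observable values (percent supercoiling, spacing index, or
#'   fraction of nucleosomes moved), finite.
#' @param observable Label of the observable.
#' @param protein_nM Optional motor-protein concentration, nM.
#' @return An object of class `time_course`.
#' @export
time_course <- function(times, values, observable = "signal",
                        protein_nM = NA_real_) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) stop("times and values must match")
  if (any(times < 0)) stop("times must be nonnegative")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(values))) stop("values must be finite")
  structure(list(times = times, values = values, observable = observable,
                 protein_nM = protein_nM),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("<time_course> %s: %d points over %g-%g min\n",
              x$observable, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Initial rate from the early linear phase
#'
#' Ordinary least-squares slope of the first `n_points` observations,
#' normalized by protein concentration: units are observable units per
#' minute per nM. For a first-order process sampled at `k * t << 1` this
#' estimates `A * k / [protein]`.
#'
#' @param tc A [time_course()] with `protein_nM` set.
#' @param n_points Number of early points to regress over (>= 3).
#' @return List with `rate`, `se` (per minute per nM), `slope`, `slope_se`,
#'   `n_points`, `protein_nM`.
#' @export
initial_rate <- function(tc, n_points = 4L) {
  stopifnot(inherits(tc, "time_course"))
  if (is.na(tc$protein_nM) || tc$protein_nM <= 0)
    stop("initial_rate requires a positive protein_nM on the time course")
  if (n_points < 3L) stop("need at least 3 points for a slope")
  if (n_points > length(tc$times))
    stop("n_points exceeds the number of observations")
  idx <- seq_len(n_points)
  fit <- stats::lm(y ~ t, data = data.frame(t = tc$times[idx], y = tc$values[idx]))
  co <- summary(fit)$coefficients
  list(rate = unname(co["t", "Estimate"]) / tc$protein_nM,
       se = unname(co["t", "Std. Error"]) / tc$protein_nM,
       slope = unname(co["t", "Estimate"]),
       slope_se = unname(co["t", "Std. Error"]),
       n_points = n_points, protein_nM = tc$protein_nM)
}

# Shared exponential-saturation fitter: y = y0 + A * (1 - exp(-k t)).
# Multi-start nonlinear least squares; k seeded from a log-linear
# regression of the residual amplitude, plus 0.5x and 2x perturbations.
fit_exponential_rise <- function(tc, model_label, fit_offset = TRUE) {
  stopifnot(inherits(tc, "time_course"))
  t <- tc$times; y <- tc$values
  if (length(t) < 4L) stop("need at least 4 points for a first-order fit")
  A0 <- max(y) - min(y)
  y00 <- y[which.min(t)]
  if (A0 <= 0 || !any(y > y00 + 1e-12))
    stop("fit failure: no amplitude in the data (flat or decreasing signal)")
  # log-linear seed: log(Ainf - y) ~ -k t using a plateau guess
  plateau <- max(y) + 0.05 * A0
  resid_amp <- plateau - y
  ok <- resid_amp > 0 & t >= min(t)
  k0 <- tryCatch({
    sl <- stats::coef(stats::lm(log(resid_amp[ok]) ~ t[ok]))[2]
    max(as.numeric(-sl), 1e-6)
  }, error = function(e) 0.1)
  starts <- lapply(c(1, 0.5, 2), function(m)
    if (fit_offset) list(y0 = y00, A = A0, k = k0 * m)
    else list(A = A0, k = k0 * m))
  form <- if (fit_offset) y ~ y0 + A * (1 - exp(-k * t)) else y ~ A * (1 - exp(-k * t))
  dat <- data.frame(t = t, y = y)
  fit <- NULL; errs <- character(0)
  for (st in starts) {
    fit <- tryCatch(stats::nls(form, data = dat, start = st,
                               control = stats::nls.control(maxiter = 200,
                                                            warnOnly = FALSE),
                               algorithm = "port",
                               lower = if (fit_offset) c(-Inf, 0, 1e-9) else c(0, 1e-9)),
                    error = function(e) { errs <<- c(errs, conditionMessage(e)); NULL })
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("fit failure after multi-start (", length(starts), " starts): ",
         paste(unique(errs), collapse = "; "))
  co <- summary(fit)$coefficients
  k <- co["k", "Estimate"]
  pred <- stats::predict(fit)
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(model = model_label,
                 k = k, k_se = co["k", "Std. Error"],
                 amplitude = co["A", "Estimate"],
                 amplitude_se = co["A", "Std. Error"],
                 y0 = if (fit_offset) co["y0", "Estimate"] else 0,
                 half_time = log(2) / k,
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 observable = tc$observable, fitted = pred),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> %s: k = %.4g +/- %.2g /min, A = %.4g +/- %.2g, t1/2 = %.4g min, r^2 = %.4f\n",
              x$model, x$k, x$k_se, x$amplitude, x$amplitude_se,
              x$half_time, x$r_squared))
  invisible(x)
}

#' Fit first-order progress-curve kinetics
#'
#' Nonlinear least squares of `y = y0 + A * (1 - exp(-k t))` with a fitted
#' baseline offset `y0` (gel-derived observables carry lane-dependent
#' baselines; set `fit_offset = FALSE` to pin `y0 = 0`). Returns the rate
#' constant with standard error, amplitude, half-time `ln(2)/k`, and
#' r-squared against the fitted curve.
#'
#' @param tc A [time_course()] (>= 4 points).
#' @param fit_offset Fit the baseline offset? Default `TRUE`.
#' @return A `kinetic_fit` (model `"first_order"`).
#' @export
fit_first_order <- function(tc, fit_offset = TRUE)
  fit_exponential_rise(tc, "first_order", fit_offset)

#' Fit a single-exponential nucleosome sliding time course
#'
#' Identical functional form to [fit_first_order()]; kept as a separate
#' entry point because the observable (fraction of nucleosomes moved in a
#' sliding assay) and the reported quantity (sliding rate constant) differ.
#'
#' @inheritParams fit_first_order
#' @return A `kinetic_fit` (model `"single_exponential"`).
#' @export
fit_single_exponential <- function(tc, fit_offset = TRUE)
  fit_exponential_rise(tc, "single_exponential", fit_offset)

#' Fit Michaelis-Menten substrate-saturation ATPase kinetics
#'
#' Observed ATPase rate constants are first basal-corrected (`kobs -
#' basal`; the rate in the absence of substrate is subtracted from the
#' stimulated rates) and then fitted by nonlinear least squares to
#' `kobs = kcat * S / (Km + S)`.
#'
#' @param S Substrate concentrations, nM (>= 4 values recommended,
#'   bracketing Km).
#' @param kobs Observed rate constants at each `S`, per minute (uncorrected).
#' @param basal Basal rate constant in the absence of substrate, per minute
#'   (typically 10-30 /min for Chd1 preparations).
#' @param substrate Label: `"DNA"` or `"nucleosomes"`.
#' @return An object of class `mm_fit` with `kcat`, `Km` (each +/- SE),
#'   `basal_rate`, and `r_squared`.
#' @export
fit_michaelis_menten <- function(S, kobs, basal = 0,
                                 substrate = c("nucleosomes", "DNA")) {
  substrate <- match.arg(substrate)
  S <- as.numeric(S); kobs <- as.numeric(kobs)
  if (length(S) != length(kobs)) stop("S and kobs must match")
  if (length(S) < 4L) stop("need at least 4 substrate concentrations")
  if (basal < 0) stop("basal rate must be nonnegative")
  if (any(S > 500))
    warning("substrate concentrations above 500 nM exceed the assay's usual range")
  v <- kobs - basal
  if (all(v <= 0))
    stop("fit failure: all basal-corrected rates are <= 0")
  kcat0 <- max(v) * 1.1
  half <- kcat0 / 2
  Km0 <- S[which.min(abs(v - half))]
  if (Km0 <= 0) Km0 <- stats::median(S[S > 0])
  dat <- data.frame(S = S, v = v)
  fit <- NULL; errs <- character(0)
  for (m in list(c(1, 1), c(1, 0.5), c(1, 2), c(1.5, 1))) {
    fit <- tryCatch(stats::nls(v ~ kcat * S / (Km + S), data = dat,
                               start = list(kcat = kcat0 * m[1], Km = Km0 * m[2]),
                               algorithm = "port", lower = c(1e-9, 1e-9),
                               control = stats::nls.control(maxiter = 200)),
                    error = function(e) { errs <<- c(errs, conditionMessage(e)); NULL })
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("Michaelis-Menten fit failure after multi-start: ",
         paste(unique(errs), collapse = "; "))
  co <- summary(fit)$coefficients
  pred <- stats::predict(fit)
  ss_res <- sum((v - pred)^2); ss_tot <- sum((v - mean(v))^2)
  structure(list(kcat = co["kcat", "Estimate"], kcat_se = co["kcat", "Std. Error"],
                 Km = co["Km", "Estimate"], Km_se = co["Km", "Std. Error"],
                 basal_rate = basal, substrate = substrate,
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> %s-stimulated: kcat = %.4g +/- %.2g /min, Km = %.4g +/- %.2g nM (basal %.3g /min subtracted)\n",
              x$substrate, x$kcat, x$kcat_se, x$Km, x$Km_se, x$basal_rate))
  invisible(x)
}

# Round half away from zero at `digits` decimals (printed-table convention;
# base round() rounds half to even).
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Relative rate of a mutant vs the wild-type enzyme
#'
#' `percent = 100 * mutant / wild_type`, with the standard error propagated
#' in quadrature on relative errors:
#' `SE% = percent * sqrt((SEm/m)^2 + (SEw/w)^2)`.
#'
#' @param mutant,wild_type Rate constants (e.g. kcat, per minute).
#' @param mutant_se,wild_type_se Their standard errors (0 if unknown).
#' @param digits Decimal places for the rounded display value
#'   (half-away-from-zero, matching printed tables).
#' @return An object of class `relative_rate` with `percent`, `percent_se`,
#'   and rounded display values.
#' @examples
#' relative_rate(0.045, 2.2, 0.009, 0.2, digits = 1)  # 2.0 +/- 0.4 %
#' @export
relative_rate <- function(mutant, wild_type, mutant_se = 0, wild_type_se = 0,
                          digits = 0) {
  if (!is.numeric(wild_type) || wild_type <= 0)
    stop("wild-type rate must be positive")
  pct <- 100 * mutant / wild_type
  rel_m <- if (mutant != 0) mutant_se / mutant else 0
  rel_w <- wild_type_se / wild_type
  se <- abs(pct) * sqrt(rel_m^2 + rel_w^2)
  structure(list(numerator = mutant, numerator_se = mutant_se,
                 denominator = wild_type, denominator_se = wild_type_se,
                 percent = pct, percent_se = se,
                 percent_rounded = round_half_away(pct, digits),
                 percent_se_rounded = round_half_away(se, digits)),
            class = "relative_rate")
}

#' @export
print.relative_rate <- function(x, ...) {
  cat(sprintf("<relative_rate> %g +/- %g %% (unrounded %.4g +/- %.4g)\n",
              x$percent_rounded, x$percent_se_rounded, x$percent, x$percent_se))
  invisible(x)
}
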