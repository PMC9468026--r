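#' Fit the Langmuir binding isotherm calibration curve
#'
#' Nonlinear least squares fit of `signal = bmax * c / (kd + c)` over
#' per-FOV signals at known concentrations, the standard saturation-binding
#' calibration of a sandwich immunoassay. `kd` is the equilibrium
#' dissociation constant (pM) and `bmax` the maximum signal. Fitting starts
#' at `kd = median(concentrations)`, `bmax = max(signals)`, with both
#' parameters bounded positive; parameter standard errors and the covariance
#' come from the Jacobian-based covariance of the fit.
#'
#' @param concentrations Concentration per FOV, pM; at least 3 distinct
#'   non-zero values.
#' @param signals Per-FOV signal (same length), finite.
#' @param signal_kind Label carried along: `"absolute"`,
#'   `"normalized_coloc"` or `"normalized_single"`.
#' @return A `langmuir_fit`: list with `kd`, `bmax`, `sigma_kd`,
#'   `sigma_bmax`, `covariance` (2x2, order kd, bmax), `signal_kind`, and
#'   the `nls` object as `fit`.
#' @export
fit_langmuir <- function(concentrations, signals,
                         signal_kind = c("absolute", "normalized_coloc",
                                         "normalized_single")) {
  signal_kind <- match.arg(signal_kind)
  if (length(concentrations) != length(signals))
    stop("concentrations and signals must have the same length")
  if (!all(is.finite(signals))) stop("signals must be finite")
  if (length(unique(concentrations[concentrations > 0])) < 3L)
    stop("need at least 3 distinct non-zero concentrations")
  if (max(signals) <= 0)
    stop("signals contain no positive value; the isotherm is unidentifiable")
  dat <- data.frame(c = concentrations, y = signals)
  fit <- minpack.lm::nlsLM(
    y ~ bmax * c / (kd + c), data = dat,
    start = list(kd = median(concentrations[concentrations > 0]),
                 bmax = max(signals)),
    lower = c(kd = 1e-12, bmax = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)
  cv <- tryCatch(vcov(fit), error = function(e)
    stop("Langmuir fit did not yield a covariance: ", conditionMessage(e)))
  structure(list(kd = unname(est["kd"]), bmax = unname(est["bmax"]),
                 sigma_kd = sqrt(cv["kd", "kd"]),
                 sigma_bmax = sqrt(cv["bmax", "bmax"]),
                 covariance = cv[c("kd", "bmax"), c("kd", "bmax")],
                 signal_kind = signal_kind, fit = fit),
            class = "langmuir_fit")
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat(sprintf("Langmuir calibration (%s): Kd = %.4g +/- %.2g pM, Bmax = %.4g +/- %.2g\n",
              x$signal_kind, x$kd, x$sigma_kd, x$bmax, x$sigma_bmax))
  invisible(x)
}

#' Predict signal from concentration on a Langmuir calibration
#' @param fit A `langmuir_fit`.
#' @param concentration Concentration(s), pM.
#' @return Predicted signal(s) `bmax * c / (kd + c)`.
#' @export
predict_langmuir <- function(fit, concentration) {
  stopifnot(inherits(fit, "langmuir_fit"))
  fit$bmax * concentration / (fit$kd + concentration)
}

#' Invert a Langmuir calibration: signal to concentration
#'
#' Algebraic inverse of the isotherm, `c = kd * y / (bmax - y)`. Signals at
#' or above `bmax` map to `Inf` with a warning (the calibration cannot
#' resolve them); negative signals are clamped to concentration 0 with a
#' warning.
#'
#' @param fit A `langmuir_fit`.
#' @param signal Signal value(s).
#' @return Concentration(s), pM.
#' @export
invert_langmuir <- function(fit, signal) {
  stopifnot(inherits(fit, "langmuir_fit"))
  out <- numeric(length(signal))
  neg <- signal < 0
  sat <- signal >= fit$bmax
  if (any(neg)) warning("negative signal clamped to concentration 0")
  if (any(sat)) warning("signal at or above Bmax maps to infinite concentration")
  ok <- !neg & !sat
  out[neg] <- 0
  out[sat] <- Inf
  out[ok] <- fit$kd * signal[ok] / (fit$bmax - signal[ok])
  out
}

#' Limit of detection with propagated uncertainty
#'
#' The LOD signal is the blank mean plus three blank standard deviations,
#' `lod_signal = mean(blanks) + 3 * sd(blanks)`; its concentration is the
#' Langmuir inverse of that signal. The LOD uncertainty propagates the
#' calibration parameter errors and the blank error through the inverse
#' `f(y) = kd * y / (bmax - y)` in quadrature (covariance cross-terms
#' dropped):
#' `sigma_lod^2 = (kd*y/(bmax-y)^2 * sigma_bmax)^2 +
#'  (y/(bmax-y) * sigma_kd)^2 + (kd*bmax/(bmax-y)^2 * sigma_y)^2`.
#'
#' @param fit A `langmuir_fit`.
#' @param blank_signals Per-FOV signals measured without analyte (>= 2).
#' @return A `lod_result`: list with `lod_signal`, `lod_concentration` (pM),
#'   `sigma_lod` (pM), `blank_mean`, `blank_sd`. If the LOD signal reaches
#'   `bmax` the concentration is `Inf` with a warning.
#' @export
compute_lod <- function(fit, blank_signals) {
  stopifnot(inherits(fit, "langmuir_fit"))
  if (length(blank_signals) < 2L) stop("need at least 2 blank measurements")
  ybar <- mean(blank_signals)
  sy <- sd(blank_signals)
  y <- ybar + 3 * sy
  if (y >= fit$bmax) {
    warning("LOD signal reaches Bmax: limit of detection is unresolved (infinite)")
    conc <- Inf; slod <- Inf
  } else {
    conc <- fit$kd * y / (fit$bmax - y)
    slod <- sqrt((fit$kd * y / (fit$bmax - y)^2 * fit$sigma_bmax)^2 +
                 (y / (fit$bmax - y) * fit$sigma_kd)^2 +
                 (fit$kd * fit$bmax / (fit$bmax - y)^2 * sy)^2)
  }
  structure(list(lod_signal = y, lod_concentration = conc, sigma_lod = slod,
                 blank_mean = ybar, blank_sd = sy),
            class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf("LOD: signal %.4g -> %.4g +/- %.2g pM\n",
              x$lod_signal, x$lod_concentration, x$sigma_lod))
  invisible(x)
}

#' Mean absolute percentage log error (MAPLE)
#'
#' `MAPLE = (100 / n) * sum(|log(true) - log(pred)| / |log(true)|)`, the
#' relative error on the logarithmic concentration scale; the log-ratio form
#' makes it invariant to the logarithm base but not to the concentration
#' unit, which is fixed to pM here so that `log(true) > 0` over the assay's
#' working range.
#'
#' @param true_conc,pred_conc Positive concentration vectors, pM.
#' @return MAPLE in percent.
#' @export
maple <- function(true_conc, pred_conc) {
  stopifnot(length(true_conc) == length(pred_conc))
  if (any(true_conc <= 0)) stop("true concentrations must be positive (log scale)")
  pred <- pmax(pred_conc, .Machine$double.xmin)   # log(0) guarded
  100 * mean(abs(log(true_conc) - log(pred)) / abs(log(true_conc)))
}

#' Out-of-bag bootstrap quantification error
#'
#' Per bootstrap iteration the fields of view are resampled with
#' replacement; the resampled set is fit to the Langmuir isotherm, and the
#' fields of view never drawn (the out-of-bag set) are quantified by
#' inverting the fitted curve. MAPLE between true and predicted
#' concentrations summarizes the iteration; zero-concentration fields of
#' view are excluded from the error (their log is undefined) though they
#' participate in resampling and fitting. Iterations whose out-of-bag set is
#' empty or whose training set lacks 3 distinct non-zero concentrations are
#' redrawn (and counted).
#'
#' @param concentrations,signals Per-FOV calibration data (pM, signal).
#' @param signal_kind Passed to [fit_langmuir()].
#' @param n_boot Number of bootstrap iterations, default 1000.
#' @param rng_seed Optional integer seed.
#' @return List with `maple_mean`, `maple_sd` (percent, over iterations),
#'   `maple` (per-iteration vector) and `n_redrawn`.
#' @export
bootstrap_maple <- function(concentrations, signals,
                            signal_kind = "normalized_coloc",
                            n_boot = 1000L, rng_seed = NULL) {
  n <- length(concentrations)
  stopifnot(length(signals) == n)
  if (length(unique(concentrations[concentrations > 0])) < 2L)
    stop("need at least 2 distinct non-zero concentrations")
  if (n_boot < 1L) stop("n_boot must be >= 1")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  vals <- numeric(n_boot)
  redrawn <- 0L
  for (b in seq_len(n_boot)) {
    fit <- NULL
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), idx)
      oob <- oob[concentrations[oob] > 0]
      ok <- length(oob) > 0L && max(signals[idx]) > 0 &&
        length(unique(concentrations[idx][concentrations[idx] > 0])) >= 3L
      if (ok)
        fit <- tryCatch(fit_langmuir(concentrations[idx], signals[idx],
                                     signal_kind),
                        error = function(e) NULL)
      if (!is.null(fit)) break
      redrawn <- redrawn + 1L
      if (redrawn > 100L * n_boot)
        stop("bootstrap resamples repeatedly failed to support a Langmuir fit")
    }
    pred <- suppressWarnings(invert_langmuir(fit, signals[oob]))
    pred[!is.finite(pred)] <- max(concentrations)   # saturated signals
    vals[b] <- maple(concentrations[oob], pred)
  }
  list(maple_mean = mean(vals), maple_sd = sd(vals), maple = vals,
       n_redrawn = redrawn)
}
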