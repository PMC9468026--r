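#' Unregularized logistic regression on a single count statistic
#'
#' Maximum-likelihood logistic fit `P(y = 1 | x) = 1 / (1 + exp(-(w x + c)))`
#' with no penalty, by iteratively reweighted least squares. The problem is
#' convex, so the fit is deterministic given the data. With perfectly
#' separated classes the likelihood has no finite maximizer; the fit then
#' converges toward the boundary with a warning, and the scores remain
#' usable for ranking (the ROC is unaffected by the divergence).
#'
#' @param x Per-FOV statistic (single feature).
#' @param y Labels, 0 (target-free control) or 1 (target present); both
#'   classes must be present.
#' @return List with `w` (weight), `c` (intercept) and `separated` (logical,
#'   quasi-separation detected).
#' @export
fit_logistic <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (!all(y %in% c(0, 1))) stop("labels must be 0 or 1")
  if (length(unique(y)) < 2L) stop("both classes must be present for training")
  fit <- withCallingHandlers(
    glm(y ~ x, family = binomial()),
    warning = function(cond) invokeRestart("muffleWarning"))
  sep <- !fit$converged || any(abs(fit$fitted.values - 0.5) > 0.5 - 1e-8)
  if (sep)
    warning("classes are (quasi-)separated; coefficients at the boundary, scores still rank")
  list(w = unname(coef(fit)["x"]), c = unname(coef(fit)["(Intercept)"]),
       separated = sep)
}

#' ROC curve and AUC for a fitted single-feature classifier
#'
#' Scores `w x + c` are thresholded at every unique value (ties grouped);
#' true- and false-positive rates trace the ROC and the area is computed by
#' the trapezoid rule. For a monotone single-feature model this equals the
#' rank statistic (Mann-Whitney) of the raw feature.
#'
#' @param x,y Test statistic and labels (both classes present).
#' @param model Fit from [fit_logistic()].
#' @return A `roc_result`: list with `fpr`, `tpr` (curve points, monotone
#'   non-decreasing) and `auc` in `[0, 1]`.
#' @export
roc_auc <- function(x, y, model) {
  stopifnot(length(x) == length(y))
  if (length(unique(y)) < 2L) stop("AUC undefined: test set has a single class")
  scores <- model$w * x + model$c
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; lab <- y[ord]
  # group tied scores: cumulative counts at each distinct threshold
  last_of_tie <- c(diff(s) != 0, TRUE)
  tp <- cumsum(lab)[last_of_tie]
  fp <- cumsum(1 - lab)[last_of_tie]
  npos <- sum(y == 1); nneg <- sum(y == 0)
  tpr <- c(0, tp / npos)
  fpr <- c(0, fp / nneg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC with %d points, AUC = %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' Bootstrapped binary classification with ROC/AUC uncertainty
#'
#' Per iteration each class is resampled with replacement (class-stratified,
#' so every training set contains both classes); the fields of view never
#' drawn from either class form the out-of-bag test set. An unregularized
#' logistic classifier is fit on the training resample and scored on the
#' test set; the AUC sample distribution over iterations quantifies
#' classification confidence. Iterations with an out-of-bag set missing a
#' class are redrawn (and counted).
#'
#' @param positive,negative Per-FOV statistics for the target-present and
#'   target-free condition (each length >= 5).
#' @param n_boot Bootstrap iterations, default 1000.
#' @param rng_seed Optional integer seed; fixed seeds give identical AUC
#'   samples.
#' @return List with `auc_samples` (length `n_boot`), `auc_median`,
#'   `auc_quartiles` (25/75%), and `n_redrawn`.
#' @export
bootstrap_classification <- function(positive, negative, n_boot = 1000L,
                                     rng_seed = NULL) {
  if (length(positive) < 5L || length(negative) < 5L)
    stop("each class needs at least 5 fields of view")
  if (n_boot < 1L) stop("n_boot must be >= 1")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  npos <- length(positive); nneg <- length(negative)
  aucs <- numeric(n_boot)
  redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      ip <- sample.int(npos, npos, replace = TRUE)
      ineg <- sample.int(nneg, nneg, replace = TRUE)
      oob_p <- setdiff(seq_len(npos), ip)
      oob_n <- setdiff(seq_len(nneg), ineg)
      if (length(oob_p) > 0L && length(oob_n) > 0L) break
      redrawn <- redrawn + 1L
    }
    xtr <- c(positive[ip], negative[ineg])
    ytr <- c(rep(1, npos), rep(0, nneg))
    model <- suppressWarnings(fit_logistic(xtr, ytr))
    xte <- c(positive[oob_p], negative[oob_n])
    yte <- c(rep(1, length(oob_p)), rep(0, length(oob_n)))
    aucs[b] <- roc_auc(xte, yte, model)$auc
  }
  list(auc_samples = aucs, auc_median = median(aucs),
       auc_quartiles = quantile(aucs, c(0.25, 0.75), names = FALSE),
       n_redrawn = redrawn)
}
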