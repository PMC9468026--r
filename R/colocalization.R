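#' Count colocalized capture/detection antibody pairs in one field of view
#'
#' Detection-channel spot coordinates are mapped into the capture frame with
#' the registration transform; a capture spot and a transformed detection
#' spot within `radius_px` (Euclidean, default 1.5 px) form a candidate
#' pair. Candidates are sorted by distance (ties broken by capture then
#' detection index) and accepted greedily when both members are still
#' unassigned, so the matching is one-to-one and the colocalized count can
#' never exceed the smaller channel count -- one sandwich per capture
#' antibody.
#'
#' @param cab,dab `spot_set`s from the capture and detection channel of the
#'   same field of view.
#' @param transform `affine2d` mapping detection coordinates to the capture
#'   frame.
#' @param radius_px Colocalization criterion in px (> 0), default 1.5.
#' @return List with `counts` (a one-row data frame: `fov_id`, `cab_count`,
#'   `dab_count`, `coloc_count`) and `pairs`, a data frame of accepted pairs
#'   (`cab_idx`, `dab_idx`, `distance_px`).
#' @export
colocalize <- function(cab, dab, transform = affine_identity(), radius_px = 1.5) {
  stopifnot(inherits(cab, "spot_set"), inherits(dab, "spot_set"))
  if (radius_px <= 0) stop("radius_px must be positive")
  C <- as.matrix(cab$spots[, c("x", "y")])
  D <- as.matrix(dab$spots[, c("x", "y")])
  Dp <- apply_transform(transform, D)

  pairs <- data.frame(cab_idx = integer(0), dab_idx = integer(0),
                      distance_px = numeric(0))
  if (nrow(C) > 0L && nrow(Dp) > 0L) {
    d <- sqrt(outer(C[, 1], Dp[, 1], "-")^2 + outer(C[, 2], Dp[, 2], "-")^2)
    cand <- which(d <= radius_px, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      ord <- order(d[cand], cand[, 1], cand[, 2])
      cand <- cand[ord, , drop = FALSE]
      used_c <- logical(nrow(C)); used_d <- logical(nrow(Dp))
      keep <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_c[i] && !used_d[j]) {
          used_c[i] <- TRUE; used_d[j] <- TRUE; keep[k] <- TRUE
        }
      }
      cand <- cand[keep, , drop = FALSE]
      pairs <- data.frame(cab_idx = cand[, 1], dab_idx = cand[, 2],
                          distance_px = d[cand])
    }
  }
  counts <- data.frame(fov_id = cab$fov_id, cab_count = nrow(C),
                       dab_count = nrow(D), coloc_count = nrow(pairs),
                       stringsAsFactors = FALSE)
  list(counts = counts, pairs = pairs)
}

#' Normalize per-FOV counts to the capture-antibody count
#'
#' Adds the two normalized statistics: colocalized pairs per capture spot
#' (`normalized_coloc = coloc_count / cab_count`, the assay's primary
#' signal, 0 to 1 by construction) and detection spots per capture spot
#' (`normalized_single = dab_count / cab_count`). Fields of view with zero
#' capture spots get `NA` ratios and `valid = FALSE`; they are excluded from
#' aggregation rather than raising an error.
#'
#' @param counts Data frame with columns `cab_count`, `dab_count`,
#'   `coloc_count` (one row per field of view).
#' @return The data frame with `normalized_coloc`, `normalized_single` and
#'   logical `valid` columns added.
#' @export
normalize_counts <- function(counts) {
  stopifnot(all(c("cab_count", "dab_count", "coloc_count") %in% names(counts)))
  valid <- counts$cab_count > 0
  counts$normalized_coloc <- ifelse(valid, counts$coloc_count / counts$cab_count, NA_real_)
  counts$normalized_single <- ifelse(valid, counts$dab_count / counts$cab_count, NA_real_)
  counts$valid <- valid
  counts
}

#' Aggregate per-FOV counts into per-condition summaries
#'
#' Mean, sample standard deviation (n - 1 denominator) and coefficient of
#' variation (CV = sd / mean) of each count statistic, grouped by the given
#' label columns (for example concentration, coverslip). Invalid fields of
#' view (zero capture spots) are dropped first.
#'
#' @param counts Data frame from [normalize_counts()], optionally with label
#'   columns.
#' @param by Character vector of grouping columns present in `counts`, or
#'   `NULL` for a single group.
#' @return Long-format data frame: grouping columns, `statistic`, `n`,
#'   `mean`, `sd`, `cv`.
#' @export
aggregate_counts <- function(counts, by = NULL) {
  if (!is.null(counts$valid)) counts <- counts[counts$valid, , drop = FALSE]
  if (nrow(counts) < 2L) stop("need at least 2 valid fields of view to aggregate")
  stats_cols <- intersect(c("cab_count", "dab_count", "coloc_count",
                            "normalized_coloc", "normalized_single"),
                          names(counts))
  stats_cols <- stats_cols[vapply(stats_cols, function(sc)
    any(!is.na(counts[[sc]])), logical(1))]
  groups <- if (is.null(by)) list(rep.int(1L, nrow(counts)))
            else counts[by]
  split_idx <- split(seq_len(nrow(counts)), groups, drop = TRUE)
  out <- do.call(rbind, lapply(names(split_idx), function(g) {
    idx <- split_idx[[g]]
    do.call(rbind, lapply(stats_cols, function(sc) {
      v <- counts[[sc]][idx]
      v <- v[!is.na(v)]
      m <- mean(v); s <- sd(v)
      row <- data.frame(group = g, statistic = sc, n = length(v),
                        mean = m, sd = s,
                        cv = if (!is.finite(m) || m == 0) NA_real_ else s / m,
                        stringsAsFactors = FALSE)
      if (!is.null(by))
        row <- cbind(counts[idx[1], by, drop = FALSE], row[-1], row.names = NULL)
      row
    }))
  }))
  rownames(out) <- NULL
  out
}
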