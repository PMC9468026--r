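#' Gaussian denoising
#'
#' Smooths an intensity grid with an isotropic Gaussian kernel
#' (default sigma 0.8 px), the first stage of the detection pipeline. The
#' input is never modified.
#'
#' @param pixels Numeric matrix of non-negative intensities (or an
#'   `image_frame`).
#' @param sigma Kernel standard deviation in px, default 0.8.
#' @return Smoothed numeric matrix of the same size.
#' @export
denoise <- function(pixels, sigma = 0.8) {
  m <- .as_pixels(pixels)
  if (length(m) == 0L) stop("empty frame")
  .gaussian_blur_cpp(m, sigma)
}

#' Background subtraction by morphological reconstruction
#'
#' Estimates slowly varying, uneven illumination as a grayscale
#' morphological reconstruction by dilation under the smoothed image and
#' subtracts it, leaving a non-negative image that is (near) zero over
#' smooth background while diffraction-limited peaks keep their full
#' prominence.
#'
#' The default `"border"` method seeds the reconstruction with the image
#' minimum everywhere except at the border, where it equals the image: the
#' reconstruction then rises to any level reachable from the border without
#' descending, which removes illumination gradients exactly while isolated
#' peaks -- unreachable from the border without a dip -- survive at full
#' height. The image is reflection-padded (`pad` px) first so spots touching
#' the physical border are not flooded. The `"hdome"` method instead seeds
#' with `smoothed - h`; it returns the classical h-dome image, which caps
#' every peak's height at `h` and is provided for comparison.
#'
#' @param smoothed Numeric matrix from [denoise()].
#' @param method `"border"` (default) or `"hdome"`.
#' @param h Dome height for `method = "hdome"`; default one standard
#'   deviation of `smoothed`.
#' @param pad Reflection padding in px for `method = "border"`, default 8
#'   (at least the spot radius).
#' @return List with `subtracted` (non-negative matrix) and `background`
#'   (the reconstruction).
#' @export
subtract_background <- function(smoothed, method = c("border", "hdome"),
                                h = NULL, pad = 8L) {
  m <- .as_pixels(smoothed)
  method <- match.arg(method)
  if (method == "hdome") {
    if (is.null(h)) h <- sd(m)
    if (h < 0) stop("h must be >= 0")
    bg <- .reconstruct_dilation_cpp(m - h, m)
    return(list(subtracted = m - bg, background = bg))
  }
  p <- as.integer(pad)
  mp <- .pad_reflect(m, p)
  seed <- matrix(min(mp), nrow(mp), ncol(mp))
  seed[1, ] <- mp[1, ]; seed[nrow(mp), ] <- mp[nrow(mp), ]
  seed[, 1] <- mp[, 1]; seed[, ncol(mp)] <- mp[, ncol(mp)]
  bgp <- .reconstruct_dilation_cpp(seed, mp)
  idx_r <- p + seq_len(nrow(m)); idx_c <- p + seq_len(ncol(m))
  list(subtracted = (mp - bgp)[idx_r, idx_c],
       background = bgp[idx_r, idx_c])
}

# reflection padding (whole-sample) by p pixels on every side
.pad_reflect <- function(m, p) {
  if (p < 1L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(p < nr, p < nc)
  m[c(p:1, 1:nr, nr:(nr - p + 1)), c(p:1, 1:nc, nc:(nc - p + 1))]
}

#' Inverse hyperbolic sine intensity transform
#'
#' Maps background-subtracted intensities to a compressed dynamic range by
#' `asinh(v / s)`. The transform is strictly monotone, so it changes which
#' maxima pass the median + 1.2 sd threshold but never their ordering. The
#' scale `s` defaults to four standard deviations of the input (floored at
#' 1 count), so the mapping is close to linear through the bulk of the
#' intensity distribution and compresses only the extreme bright tail; the
#' default adapts to exposure.
#'
#' @param subtracted Non-negative numeric matrix.
#' @param scale Positive scale `s`; `NULL` (default) uses `max(4 * sd(v), 1)`.
#' @return Transformed matrix.
#' @export
transform_intensity <- function(subtracted, scale = NULL) {
  m <- .as_pixels(subtracted)
  if (is.null(scale)) scale <- max(4 * sd(m), 1)
  if (scale <= 0) stop("scale must be positive")
  asinh(m / scale)
}

# Select plateau-aware local maxima at or above median + multiplier * sd,
# with the statistics computed over the local-maxima intensity population
# (the quantities being selected), which keeps the cut calibrated across
# spot densities. With fewer than 2 maxima the statistics are undefined and
# all maxima are kept.
.select_maxima <- function(transformed, threshold_multiplier = 1.2) {
  mx <- .local_maxima_cpp(transformed)
  if (length(mx$value) >= 2L) {
    thr <- median(mx$value) + threshold_multiplier * sd(mx$value)
    keep <- mx$value >= thr
  } else keep <- rep(TRUE, length(mx$value))
  data.frame(x = mx$x[keep], y = mx$y[keep], intensity = mx$value[keep])
}

.as_pixels <- function(x) {
  m <- if (inherits(x, "image_frame")) x$pixels else x
  storage.mode(m) <- "double"
  m
}

.split_channel <- function(pixels, channel = c("capture", "detection")) {
  channel <- match.arg(channel)
  wh <- ncol(pixels) %/% 2L
  if (channel == "capture") pixels[, seq_len(wh), drop = FALSE]
  else pixels[, wh + seq_len(wh), drop = FALSE]
}

#' Detect single-molecule spots in one channel of a stitched frame
#'
#' Runs the full detection pipeline on the requested half-image: Gaussian
#' denoising (sigma 0.8), background subtraction by morphological
#' reconstruction, inverse hyperbolic sine intensity mapping, then
#' 8-connected local maxima kept when their transformed intensity is at
#' least the median plus 1.2 standard deviations of the maxima-intensity
#' population of the transformed half-image. Connected equal-valued
#' plateaus count once, at their centroid; maxima in the outermost pixel
#' ring are eligible like any other. Coordinates are 0-based in the
#' half-image frame. Each channel is processed independently, so the
#' threshold statistics are per half-image, per field of view.
#'
#' @param frame An `image_frame` (or bare pixel matrix) with even width;
#'   left half is the capture channel, right half the detection channel.
#' @param channel `"capture"` or `"detection"`.
#' @param sigma Denoising kernel sd (px), default 0.8.
#' @param threshold_multiplier Multiplier on the standard deviation in the
#'   maxima threshold, default 1.2.
#' @param method,h,pad Background estimation options passed to
#'   [subtract_background()].
#' @param scale asinh scale passed to [transform_intensity()].
#' @return A `spot_set`: list with `fov_id`, `channel`, and `spots`, a data
#'   frame of `x`, `y` (px, half-image frame) and `intensity` (transformed).
#'   A constant frame yields zero spots.
#' @export
detect_spots <- function(frame, channel = c("capture", "detection"),
                         sigma = 0.8, threshold_multiplier = 1.2,
                         method = c("border", "hdome"), h = NULL, pad = 8L,
                         scale = NULL) {
  channel <- match.arg(channel)
  pixels <- .as_pixels(frame)
  if (ncol(pixels) %% 2L != 0L) stop("stitched frame must have even width")
  half <- .split_channel(pixels, channel)
  sm <- denoise(half, sigma)
  sub <- subtract_background(sm, method = method, h = h, pad = pad)$subtracted
  tr <- transform_intensity(sub, scale)
  spots <- if (sd(tr) == 0) data.frame(x = numeric(0), y = numeric(0),
                                       intensity = numeric(0))
           else .select_maxima(tr, threshold_multiplier)
  structure(list(fov_id = if (inherits(frame, "image_frame")) frame$fov_id else NA_character_,
                 channel = channel, spots = spots),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("spot_set: %d %s-channel spots (fov %s)\n",
              nrow(x$spots), x$channel, x$fov_id))
  invisible(x)
}

#' Build a spot set from bare coordinates
#'
#' Used when coordinates come from a table or from simulation ground truth
#' rather than from image detection.
#'
#' @param xy Two-column matrix/data frame of `(x, y)` half-image coordinates.
#' @param channel `"capture"` or `"detection"`.
#' @param fov_id Identifier.
#' @param intensity Optional intensities (default `NA`).
#' @return A `spot_set`.
#' @export
spot_set <- function(xy, channel = c("capture", "detection"),
                     fov_id = NA_character_, intensity = NULL) {
  channel <- match.arg(channel)
  xy <- as.matrix(xy)
  if (nrow(xy) == 0L) {
    spots <- data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0))
  } else {
    stopifnot(ncol(xy) == 2L)
    spots <- data.frame(x = as.numeric(xy[, 1]), y = as.numeric(xy[, 2]),
                        intensity = if (is.null(intensity)) NA_real_ else intensity)
  }
  structure(list(fov_id = fov_id, channel = channel, spots = spots),
            class = "spot_set")
}

#' Field-of-view quality filter
#'
#' A field of view is kept only when the mean `y` coordinate of its
#' capture-channel spots lies within 75 px of the vertical middle of the
#' image; frames with spots crowded toward one edge (bubbles, dust) fail.
#' An empty spot set is discarded.
#'
#' @param spots A capture-channel `spot_set`.
#' @param image_height_px Height of the frame in px.
#' @param max_offset_px Allowed offset of the mean from the middle, default
#'   75 px.
#' @return List with logical `keep` and `mean_y`.
#' @export
qc_filter <- function(spots, image_height_px, max_offset_px = 75) {
  stopifnot(inherits(spots, "spot_set"))
  if (nrow(spots$spots) == 0L)
    return(list(keep = FALSE, mean_y = NA_real_))
  my <- mean(spots$spots$y)
  list(keep = abs(my - image_height_px / 2) <= max_offset_px, mean_y = my)
}
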