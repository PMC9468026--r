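#' 2-D affine transform in homogeneous coordinates
#'
#' Wraps a 3x3 homogeneous matrix whose last row is `c(0, 0, 1)`. The
#' transform maps column vectors `(x, y, 1)`; in this package the registration
#' transform maps detection-channel coordinates into the capture-channel
#' frame.
#'
#' @param matrix Numeric 3x3 matrix with last row `c(0, 0, 1)` (up to 1e-9)
#'   and non-zero determinant.
#' @return An object of class `affine2d`.
#' @examples
#' T <- affine2d(rbind(c(1, 0, 5), c(0, 1, -3), c(0, 0, 1)))
#' apply_transform(T, cbind(x = 0, y = 0))
#' @export
affine2d <- function(matrix) {
  m <- as.matrix(matrix)
  if (!all(dim(m) == c(3L, 3L))) stop("affine2d requires a 3x3 matrix")
  if (!all(abs(m[3, ] - c(0, 0, 1)) < 1e-9))
    stop("last row of an affine matrix must be (0, 0, 1)")
  m[3, ] <- c(0, 0, 1)
  if (abs(det(m)) < 1e-12) stop("affine matrix is singular")
  structure(list(matrix = m), class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat("2-D affine transform (homogeneous 3x3):\n")
  print(x$matrix)
  invisible(x)
}

#' Identity affine transform
#' @return An `affine2d` identity transform.
#' @export
affine_identity <- function() affine2d(diag(3))

#' Translation transform
#' @param tx,ty Translation in pixels along x (column) and y (row).
#' @return An `affine2d` translation.
#' @export
affine_translation <- function(tx, ty) {
  m <- diag(3); m[1, 3] <- tx; m[2, 3] <- ty
  affine2d(m)
}

#' Invert an affine transform
#' @param transform An `affine2d`.
#' @return The inverse `affine2d`.
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "affine2d"))
  affine2d(solve(transform$matrix))
}

#' Apply an affine transform to point coordinates
#'
#' @param transform An `affine2d`.
#' @param points Two-column matrix or data frame of `(x, y)` coordinates.
#' @return Matrix of transformed coordinates, same row order, columns
#'   `x`, `y`.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "affine2d"))
  p <- as.matrix(points)
  if (nrow(p) == 0L) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  stopifnot(ncol(p) == 2L)
  h <- cbind(p[, 1], p[, 2], 1) %*% t(transform$matrix)
  out <- h[, 1:2, drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

#' Pair bead detections across channels by mutual nearest neighbors
#'
#' Fiducial beads are visible in both channels; each capture-channel
#' detection is paired with its nearest detection-channel neighbor when the
#' relationship is mutual and the distance is below a gate, giving one-to-one
#' correspondences for the affine fit. Exact (all-pairs) nearest neighbors
#' are used; a spatial index would only accelerate, never change, the result.
#'
#' @param capture_xy,detection_xy Two-column matrices of spot coordinates
#'   (px) in their respective half-image frames.
#' @param max_distance_px Pairing gate in pixels (default 5): candidate pairs
#'   farther apart than this are discarded.
#' @return List with matrices `C` (capture) and `D` (detection) of paired
#'   coordinates, rows aligned.
#' @export
match_beads <- function(capture_xy, detection_xy, max_distance_px = 5) {
  C <- as.matrix(capture_xy); D <- as.matrix(detection_xy)
  if (nrow(C) == 0L || nrow(D) == 0L) stop("both coordinate sets must be non-empty")
  d2 <- outer(C[, 1], D[, 1], "-")^2 + outer(C[, 2], D[, 2], "-")^2
  nn_c <- apply(d2, 1, which.min)          # nearest D for each C
  nn_d <- apply(d2, 2, which.min)          # nearest C for each D
  keep <- which(nn_d[nn_c] == seq_len(nrow(C)) &
                d2[cbind(seq_len(nrow(C)), nn_c)] <= max_distance_px^2)
  if (length(keep) < 3L)
    stop("degenerate geometry: fewer than 3 mutual bead pairs within the distance gate")
  list(C = C[keep, , drop = FALSE], D = D[nn_c[keep], , drop = FALSE])
}

#' Estimate the affine map between two paired point sets
#'
#' Least-squares affine `T` minimizing `sum |T src_i - dst_i|^2` over the six
#' free parameters; with exactly three non-collinear pairs the fit is exact
#' (the pseudo-inverse solution reduces to a matrix inverse).
#'
#' @param src,dst Paired two-column coordinate matrices (same number of
#'   rows, at least 3, not all collinear). The returned transform maps
#'   `src` onto `dst`.
#' @return An `affine2d`.
#' @export
estimate_affine <- function(src, dst) {
  S <- as.matrix(src); E <- as.matrix(dst)
  stopifnot(ncol(S) == 2L, ncol(E) == 2L)
  if (nrow(S) != nrow(E)) stop("src and dst must have the same number of rows")
  if (nrow(S) < 3L) stop("degenerate geometry: at least 3 point pairs required")
  X <- cbind(S[, 1], S[, 2], 1)
  if (qr(X)$rank < 3L)
    stop("degenerate geometry: source points are collinear")
  B <- qr.solve(X, E)                      # 3x2, columns are rows of T
  affine2d(rbind(t(B), c(0, 0, 1)))
}

#' Average per-frame affine transforms
#'
#' Element-wise mean of the homogeneous matrices, the convention used when a
#' transform is estimated independently from each bead frame and the
#' per-frame estimates are pooled into one registration.
#'
#' @param transforms Non-empty list of `affine2d` objects.
#' @return The averaged `affine2d`.
#' @export
average_transforms <- function(transforms) {
  if (length(transforms) == 0L) stop("no transforms to average")
  stopifnot(all(vapply(transforms, inherits, logical(1), "affine2d")))
  m <- Reduce(`+`, lapply(transforms, `[[`, "matrix")) / length(transforms)
  affine2d(m)
}

#' Estimate the detection-to-capture registration from bead frames
#'
#' Convenience wrapper: per frame, match beads mutually and fit an affine;
#' the per-frame transforms are then averaged.
#'
#' @param bead_coords List of per-frame lists with elements `capture_xy` and
#'   `detection_xy` (bead coordinates in the half-image frames).
#' @param max_distance_px Pairing gate for [match_beads()].
#' @return An `affine2d` mapping detection coordinates into the capture
#'   frame.
#' @export
register_channels <- function(bead_coords, max_distance_px = 5) {
  ts <- lapply(bead_coords, function(fr) {
    p <- match_beads(fr$capture_xy, fr$detection_xy, max_distance_px)
    estimate_affine(p$D, p$C)
  })
  average_transforms(ts)
}
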