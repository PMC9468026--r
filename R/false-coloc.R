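#' Analytic false-colocalization rate
#'
#' For capture antibodies laid down as a uniform Poisson process of density
#' `rho` (per square micron), the probability that a random non-specific
#' detection event lands within `r` of at least one capture antibody is the
#' Poisson void probability complement, `1 - exp(-rho * pi * r^2)`. Reported
#' per 100 non-specific events. At low coverage the rate is approximately
#' `100 * rho * pi * r^2`, hence quadratic in the cutoff -- halving the
#' criterion quarters the false count.
#'
#' @param density Capture-antibody surface density, per square micron
#'   (>= 0).
#' @param cutoff_nm Colocalization cutoff distance in nm.
#' @return Expected falsely colocalized events per 100 non-specific events.
#' @export
analytic_false_rate <- function(density, cutoff_nm) {
  if (any(density < 0)) stop("density must be >= 0")
  if (any(cutoff_nm <= 0)) stop("cutoff must be positive")
  r_um <- cutoff_nm / 1000
  100 * (1 - exp(-density * pi * r_um^2))
}

#' Capture density giving a target false-colocalization rate
#'
#' Inverse of [analytic_false_rate()]:
#' `rho = -log(1 - rate/100) / (pi * r^2)`. Used to anchor the simulation to
#' an observed operating point (for example 4.5 false events per 100 at a
#' 200 nm criterion) when the physical surface density is not known.
#'
#' @param target_rate_per_100 Desired rate, strictly between 0 and 100.
#' @param cutoff_nm Cutoff distance in nm at which the rate is specified.
#' @return Density per square micron.
#' @export
calibrate_density <- function(target_rate_per_100, cutoff_nm) {
  if (target_rate_per_100 <= 0 || target_rate_per_100 >= 100)
    stop("target rate must be strictly between 0 and 100 per 100 events")
  if (cutoff_nm <= 0) stop("cutoff must be positive")
  r_um <- cutoff_nm / 1000
  -log(1 - target_rate_per_100 / 100) / (pi * r_um^2)
}

#' Monte-Carlo false-colocalization rate
#'
#' Places capture antibodies as a uniform Poisson process at the requested
#' density on a toroidal (wrap-around) square plane, draws uniformly
#' positioned non-specific detection events, and counts the fraction falling
#' within the cutoff of at least one capture antibody. The toroidal geometry
#' removes edge bias, so the estimate converges to
#' [analytic_false_rate()].
#'
#' @param density Capture density per square micron (or supply `cab_count`
#'   with `area_um2`).
#' @param cutoff_nm Colocalization cutoff in nm.
#' @param n_nonspecific Number of random detection events (>= 1), default
#'   1e6.
#' @param area_um2 Torus area in square microns, default 2500 (50 x 50 um).
#' @param rng_seed Optional integer seed.
#' @return List with `rate_per_100`, `se_per_100` (binomial standard error),
#'   `hits`, `n`, `n_cab`, `density`, `cutoff_nm`.
#' @export
simulate_false_rate <- function(density, cutoff_nm, n_nonspecific = 1e6,
                                area_um2 = 2500, rng_seed = NULL) {
  if (density < 0) stop("density must be >= 0")
  if (cutoff_nm <= 0) stop("cutoff must be positive")
  if (n_nonspecific < 1) stop("n_nonspecific must be >= 1")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  L <- sqrt(area_um2)
  n_cab <- rpois(1, density * area_um2)
  rx <- runif(n_cab, 0, L); ry <- runif(n_cab, 0, L)
  n <- as.integer(n_nonspecific)
  hits <- 0L
  chunk <- 250000L                       # bound memory for large draws
  done <- 0L
  while (done < n) {
    m <- min(chunk, n - done)
    hits <- hits + .count_within_torus_cpp(runif(m, 0, L), runif(m, 0, L),
                                           rx, ry, L, cutoff_nm / 1000)
    done <- done + m
  }
  p <- hits / n
  list(rate_per_100 = 100 * p, se_per_100 = 100 * sqrt(p * (1 - p) / n),
       hits = hits, n = n, n_cab = n_cab, density = density,
       cutoff_nm = cutoff_nm)
}

#' Sweep false-colocalization rates over cutoff distances
#'
#' Convenience wrapper producing the cutoff sweep table, with the density
#' either given or calibrated from an anchor rate at an anchor cutoff.
#'
#' @param cutoffs_nm Cutoff distances to evaluate, nm.
#' @param density Capture density per square micron, or `NULL` to calibrate.
#' @param anchor_rate_per_100,anchor_cutoff_nm Anchor operating point used
#'   when `density` is `NULL` (defaults 4.5 per 100 at 200 nm).
#' @param n_nonspecific Monte-Carlo draws per cutoff, default 1e6.
#' @param rng_seed Optional integer seed.
#' @return Data frame: `cutoff_nm`, `density_per_um2`, `simulated_rate`,
#'   `analytic_rate`, `se`, `n`.
#' @export
false_coloc_sweep <- function(cutoffs_nm, density = NULL,
                              anchor_rate_per_100 = 4.5,
                              anchor_cutoff_nm = 200,
                              n_nonspecific = 1e6, rng_seed = NULL) {
  if (is.null(density))
    density <- calibrate_density(anchor_rate_per_100, anchor_cutoff_nm)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  rows <- lapply(cutoffs_nm, function(r) {
    sim <- simulate_false_rate(density, r, n_nonspecific)
    data.frame(cutoff_nm = r, density_per_um2 = density,
               simulated_rate = sim$rate_per_100,
               analytic_rate = analytic_false_rate(density, r),
               se = sim$se_per_100, n = sim$n)
  })
  do.call(rbind, rows)
}
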