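# Run `code` under a given RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  code
}

#' Configuration for synthetic field trials
#'
#' Defines the linear score-to-yield model the generator draws from:
#' `yield(site, treatment, year) = intercept_t + slope_t * score_site + e`,
#' with `e ~ Normal(0, noise_sd_t^2)` independent across sites and years.
#' The default slopes and intercepts are the fitted relationships of the
#' packaged trials (CT and NK respond to the score; the P-fertilized
#' treatments are flat at their overall means), and the default noise SDs
#' are typical interannual yield SDs from those trials.
#'
#' @param n_sites number of sites (>= 3).
#' @param scores per-site inundation scores; default: the packaged site
#'   scores when `n_sites = 7`, else equally spaced on `[0, 1.1]`.
#' @param slopes,intercepts,noise_sd named numeric vectors over the four
#'   treatments CT, NK, NK+PR, NK+TSP (Mg/ha per score unit; Mg/ha; Mg/ha).
#' @param n_years years per site (default 3).
#' @param seed integer RNG seed.
#' @return List of class `trial_sim_config`.
#' @export
trial_sim_config <- function(n_sites = 7,
                             scores = NULL,
                             slopes = c(CT = 1.73, NK = 1.71,
                                        "NK+PR" = 0, "NK+TSP" = 0),
                             intercepts = c(CT = 0.56, NK = 1.26,
                                            "NK+PR" = 3.52, "NK+TSP" = 4.15),
                             noise_sd = c(CT = 0.4, NK = 0.9,
                                          "NK+PR" = 1.1, "NK+TSP" = 1.7),
                             n_years = 3, seed = 1) {
  trts <- c("CT", "NK", "NK+PR", "NK+TSP")
  if (n_sites < 3) stop("`n_sites` must be >= 3", call. = FALSE)
  for (v in list(slopes, intercepts, noise_sd))
    if (!all(trts %in% names(v)))
      stop("slopes, intercepts and noise_sd must name all four treatments",
           call. = FALSE)
  if (any(noise_sd < 0)) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (n_years < 1) stop("`n_years` must be >= 1", call. = FALSE)
  if (is.null(scores)) {
    scores <- if (n_sites == 7) load_site_terrain()$inundation_score
              else seq(0, 1.1, length.out = n_sites)
  }
  if (length(scores) != n_sites)
    stop("`scores` must have length `n_sites`", call. = FALSE)
  structure(list(n_sites = n_sites, scores = scores,
                 slopes = slopes[trts], intercepts = intercepts[trts],
                 noise_sd = noise_sd[trts], n_years = as.integer(n_years),
                 seed = as.integer(seed)),
            class = "trial_sim_config")
}

#' Simulate a field trial
#'
#' Draws per-site, per-treatment, per-year grain yields from the linear
#' score model of [trial_sim_config]. Deterministic given the config's
#' seed; negative draws are kept (they signal an unrealistic noise choice
#' rather than being silently truncated).
#'
#' @param config a [trial_sim_config].
#' @return List with `sites` (data frame: `site`, `score`) and `trials`
#'   (long data frame: `site`, `score`, `treatment`, `year`, `yield`).
#' @export
simulate_trial <- function(config = trial_sim_config()) {
  stopifnot(inherits(config, "trial_sim_config"))
  trts <- names(config$slopes)
  sites <- data.frame(site = sprintf("S%02d", seq_len(config$n_sites)),
                      score = config$scores)
  grid <- expand.grid(site_i = seq_len(config$n_sites),
                      treatment = trts,
                      year = seq_len(config$n_years),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- config$intercepts[grid$treatment] +
    config$slopes[grid$treatment] * sites$score[grid$site_i]
  eps <- with_seed(config$seed,
                   stats::rnorm(nrow(grid),
                                sd = config$noise_sd[grid$treatment]))
  trials <- data.frame(site = sites$site[grid$site_i],
                       score = sites$score[grid$site_i],
                       treatment = grid$treatment,
                       year = grid$year,
                       yield = as.numeric(mu + eps))
  list(sites = sites, trials = trials)
}

#' Configuration for synthetic DEMs
#'
#' Describes a tilted plane cut by a north-south parabolic channel, with
#' optional Gaussian bumps and white elevation noise. The defaults emulate
#' a gentle Central-Plateau lowland at 5 m resolution: a 0.5% southward
#' slope and a 200 m wide, 2 m deep valley on a 90 x 91 grid (455 m
#' across). The valley is deliberately wider than the 25-cell smoothing
#' window of the scoring pipeline -- a boxcar filter spanning the whole
#' channel averages its cross-curvature to zero, so narrower channels are
#' erased by design, exactly as microtopographic gullies are in the real
#' pipeline.
#'
#' @param rows,cols grid shape, each >= 30 (so a 25 x 25 filter is
#'   meaningful); an odd `cols` puts the channel axis on a grid column.
#' @param cell_size cell edge (m), default 5.
#' @param base_slope southward slope (m/m) at the southern (downstream)
#'   edge, default 0.005.
#' @param profile_curvature concave down-valley profile curvature (1/m,
#'   default 2e-5): the southward slope increases linearly upstream at this
#'   rate, so the longitudinal profile is concave (slope flattening toward
#'   the outlet) and the longitudinal convexity is -profile_curvature
#'   everywhere. Set 0 for an exactly planar tilt.
#' @param channel_depth channel depth (m) at the axis, default 2.
#' @param channel_width channel full width in cells (default 41, i.e.
#'   200 m at the default cell size).
#' @param bump_amplitude amplitude of the Gaussian bumps (m), default 0.
#' @param n_bumps number of bumps (default 5, ignored if amplitude 0).
#' @param noise_sd white-noise elevation SD (m), default 0.3 -- roughly
#'   the relative vertical noise of a 30 m-class photogrammetric surface
#'   model oversampled to 5 m. Noise matters structurally: it makes
#'   hillslope D8 drainage dendritic, which is what starves interfluves of
#'   accumulation relative to the valley. Set 0 for exact geometry tests.
#' @param seed integer RNG seed.
#' @return List of class `dem_sim_config`.
#' @export
dem_sim_config <- function(rows = 90, cols = 91, cell_size = 5,
                           base_slope = 0.005, profile_curvature = 2e-5,
                           channel_depth = 2,
                           channel_width = 41, bump_amplitude = 0,
                           n_bumps = 5, noise_sd = 0.3, seed = 1) {
  if (rows < 30 || cols < 30)
    stop("`rows` and `cols` must be >= 30", call. = FALSE)
  for (v in c(cell_size, profile_curvature, channel_depth, channel_width,
              bump_amplitude, noise_sd))
    if (v < 0) stop("magnitudes must be non-negative", call. = FALSE)
  if (cell_size <= 0) stop("`cell_size` must be positive", call. = FALSE)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 cell_size = cell_size, base_slope = base_slope,
                 profile_curvature = profile_curvature,
                 channel_depth = channel_depth,
                 channel_width = channel_width,
                 bump_amplitude = bump_amplitude, n_bumps = as.integer(n_bumps),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "dem_sim_config")
}

#' Simulate a DEM
#'
#' Elevation = southward tilt (with optional concave profile curvature)
#' - parabolic channel along the central column + seeded Gaussian bumps +
#' seeded white noise. The channel cross-section
#' at distance `d` (cells) from the axis is
#' `-depth * (1 - (2 d / width)^2)` for `|d| <= width / 2`, giving an
#' axis curvature of `8 * depth / width^2` per cell squared.
#'
#' @param config a [dem_sim_config].
#' @return A [raster_grid]; deterministic given `config$seed`.
#' @export
simulate_dem <- function(config = dem_sim_config()) {
  stopifnot(inherits(config, "dem_sim_config"))
  nr <- config$rows; nc <- config$cols; L <- config$cell_size
  row_i <- matrix(seq_len(nr), nr, nc)
  col_j <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  up <- (nr - row_i) * L   # distance upstream of the southern edge (m)
  z <- config$base_slope * up + 0.5 * config$profile_curvature * up^2
  axis <- (nc + 1) / 2
  if (config$channel_depth > 0 && config$channel_width > 0) {
    u <- 2 * (col_j - axis) / config$channel_width
    cut <- config$channel_depth * pmax(0, 1 - u^2)
    z <- z - cut
  }
  z <- z + with_seed(config$seed, {
    extra <- matrix(0, nr, nc)
    if (config$bump_amplitude > 0 && config$n_bumps > 0) {
      for (b in seq_len(config$n_bumps)) {
        cr <- stats::runif(1, 1, nr); cjc <- stats::runif(1, 1, nc)
        sd_c <- stats::runif(1, 2, max(4, min(nr, nc) / 8))
        extra <- extra + config$bump_amplitude *
          exp(-((row_i - cr)^2 + (col_j - cjc)^2) / (2 * sd_c^2))
      }
    }
    if (config$noise_sd > 0)
      extra <- extra + matrix(stats::rnorm(nr * nc, sd = config$noise_sd),
                              nr, nc)
    extra
  })
  raster_grid(z, cell_size = L)
}
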