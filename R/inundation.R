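#' Configuration of the inundation-score pipeline
#'
#' Bundles the tunable stages of [score_dem]: the 5x5 pre-filter that turns
#' integer elevations into smooth floats, the 25x25 post-filter applied
#' twice to the log-accumulation surface to suppress microtopography, the
#' DEM stage from which curvature is taken, how convexity enters the
#' composite, and the reporting scale.
#'
#' @param pre_filter_window odd window (cells) smoothing the raw DEM before
#'   flow routing; default 5.
#' @param post_filter_window odd window (cells) smoothing the
#'   log-accumulation surface; default 25.
#' @param post_filter_passes number of post-filter passes; default 2.
#' @param convexity_source which DEM the curvature is computed on:
#'   `"smoothed25"` (pre-filtered DEM plus one post-filter pass, default),
#'   `"smoothed5"` (pre-filtered only) or `"raw"`.
#' @param convexity_mode `"longitudinal_only"` (default; composite uses the
#'   longitudinal convexity only) or `"product_of_both"` (multiplies in the
#'   absolute cross-sectional convexity as well). The default follows the
#'   component arithmetic of the packaged site table, which is consistent
#'   with water accumulation x |longitudinal| only.
#' @param scale_factor multiplier applied to the composite; default 100
#'   (puts scores on the 0-1ish range convexities of order 1e-2 imply).
#' @param log_base base of the accumulation log transform; 10 or `exp(1)`.
#' @return A list of class `score_pipeline_config`.
#' @export
score_pipeline_config <- function(pre_filter_window = 5,
                                  post_filter_window = 25,
                                  post_filter_passes = 2,
                                  convexity_source = c("smoothed25",
                                                       "smoothed5", "raw"),
                                  convexity_mode = c("longitudinal_only",
                                                     "product_of_both"),
                                  scale_factor = 100,
                                  log_base = 10) {
  for (w in c(pre_filter_window, post_filter_window))
    if (w < 1 || w != floor(w) || w %% 2 == 0)
      stop("filter windows must be odd integers >= 1", call. = FALSE)
  if (post_filter_passes < 0 || post_filter_passes != floor(post_filter_passes))
    stop("`post_filter_passes` must be a non-negative integer", call. = FALSE)
  if (scale_factor <= 0) stop("`scale_factor` must be positive", call. = FALSE)
  structure(list(
    pre_filter_window = as.integer(pre_filter_window),
    post_filter_window = as.integer(post_filter_window),
    post_filter_passes = as.integer(post_filter_passes),
    convexity_source = match.arg(convexity_source),
    convexity_mode = match.arg(convexity_mode),
    scale_factor = scale_factor,
    log_base = log_base
  ), class = "score_pipeline_config")
}

#' Compose the inundation score from its terrain components
#'
#' The inundation score multiplies the normalized water accumulation score
#' by the absolute value of the (negative) convexity, scaled by
#' `scale_factor`. When the longitudinal convexity is zero or positive the
#' terrain sheds water, stagnation is assumed impossible, and the score is
#' clipped to zero. All arguments are vectorized.
#'
#' @param water_accumulation numeric in `[0, 1]`.
#' @param longitudinal_convexity numeric (1/m); negative = concave.
#' @param cross_sectional_convexity numeric (1/m); only used when
#'   `config$convexity_mode == "product_of_both"`.
#' @param config a [score_pipeline_config].
#' @return Non-negative numeric scores.
#' @export
compose_score <- function(water_accumulation, longitudinal_convexity,
                          cross_sectional_convexity = NULL,
                          config = score_pipeline_config()) {
  bad <- !is.na(water_accumulation) &
    (water_accumulation < 0 | water_accumulation > 1)
  if (any(bad))
    stop("`water_accumulation` must lie in [0, 1]", call. = FALSE)
  s <- water_accumulation * abs(longitudinal_convexity) * config$scale_factor
  if (config$convexity_mode == "product_of_both") {
    if (is.null(cross_sectional_convexity))
      stop("`cross_sectional_convexity` required for product_of_both mode",
           call. = FALSE)
    s <- s * abs(cross_sectional_convexity)
  }
  ifelse(longitudinal_convexity >= 0, 0, s)
}

#' Run the full DEM-to-inundation-score pipeline
#'
#' Executes, in order: focal mean (`pre_filter_window`) on the raw DEM;
#' depression filling; D8 flow directions; flow accumulation; log
#' transform; `post_filter_passes` focal means (`post_filter_window`);
#' min-max normalization to a water-accumulation score in `[0, 1]`;
#' convexity on the configured source DEM; and the per-cell zero-clipped
#' composite of [compose_score].
#'
#' @param dem a projected [raster_grid] of elevations in meters.
#' @param config a [score_pipeline_config].
#' @return An object of class `score_surfaces`: list with [raster_grid]
#'   elements `score`, `water_accumulation`, `longitudinal_convexity`,
#'   `cross_sectional_convexity`, `accumulation` (raw upstream-cell
#'   counts), plus the `config` used. The score raster is non-negative and
#'   nodata on the one-cell border (no curvature there).
#' @export
score_dem <- function(dem, config = score_pipeline_config()) {
  check_grid(dem)
  smoothed <- focal_mean(dem, config$pre_filter_window)
  filled <- fill_depressions(smoothed)
  dirs <- d8_directions(filled)
  acc <- flow_accumulation(dirs)
  wa <- log_transform(acc, base = config$log_base)
  for (i in seq_len(config$post_filter_passes))
    wa <- focal_mean(wa, config$post_filter_window)
  wa <- normalize_01(wa)
  conv_src <- switch(config$convexity_source,
    raw = dem,
    smoothed5 = smoothed,
    smoothed25 = focal_mean(smoothed, config$post_filter_window))
  conv <- convexity(conv_src)
  score_vals <- compose_score(
    as.vector(wa$values),
    as.vector(conv$longitudinal$values),
    as.vector(conv$cross_sectional$values),
    config = config)
  score <- raster_grid(matrix(score_vals, nrow(dem$values)),
                       cell_size = dem$cell_size, origin = dem$origin)
  structure(list(score = score,
                 water_accumulation = wa,
                 longitudinal_convexity = conv$longitudinal,
                 cross_sectional_convexity = conv$cross_sectional,
                 accumulation = acc,
                 config = config),
            class = "score_surfaces")
}

#' @export
print.score_surfaces <- function(x, ...) {
  cat("<score_surfaces> inundation-score pipeline output\n")
  print(x$score)
  invisible(x)
}

#' Extract per-site terrain records from scored surfaces
#'
#' Looks up the water-accumulation score, both convexities and the
#' inundation score at given cells. Duplicate points give duplicate
#' records; order is preserved.
#'
#' @param surfaces a `score_surfaces` object from [score_dem].
#' @param points data frame with columns `site`, `row`, `col` (1-based cell
#'   indices).
#' @return Data frame with one row per point: `site`, `row`, `col`,
#'   `water_accumulation`, `longitudinal_convexity`,
#'   `cross_sectional_convexity`, `inundation_score`.
#' @export
extract_sites <- function(surfaces, points) {
  stopifnot(inherits(surfaces, "score_surfaces"))
  if (nrow(points) == 0)
    return(data.frame(site = character(), row = integer(), col = integer(),
                      water_accumulation = numeric(),
                      longitudinal_convexity = numeric(),
                      cross_sectional_convexity = numeric(),
                      inundation_score = numeric()))
  dims <- dim(surfaces$score$values)
  for (i in seq_len(nrow(points))) {
    r <- points$row[i]; cc <- points$col[i]
    if (r < 1 || r > dims[1] || cc < 1 || cc > dims[2])
      stop(sprintf("site '%s': point (row %d, col %d) is outside the grid",
                   points$site[i], r, cc), call. = FALSE)
    if (is.na(surfaces$score$values[r, cc]))
      stop(sprintf("site '%s': cell (row %d, col %d) is nodata",
                   points$site[i], r, cc), call. = FALSE)
  }
  idx <- cbind(points$row, points$col)
  data.frame(
    site = points$site, row = points$row, col = points$col,
    water_accumulation = surfaces$water_accumulation$values[idx],
    longitudinal_convexity = surfaces$longitudinal_convexity$values[idx],
    cross_sectional_convexity = surfaces$cross_sectional_convexity$values[idx],
    inundation_score = surfaces$score$values[idx]
  )
}

#' Mean inundation score by soil group
#'
#' @param records data frame with columns `soil_group` and
#'   `inundation_score` (e.g. from [load_site_terrain] or [extract_sites]).
#' @param groups named list mapping a group label to the soil-group values
#'   it pools; default pools Lixisols with Luvisols and keeps Cambisols.
#' @param digits decimals for half-up rounding of the reported means
#'   (`NULL` to skip rounding).
#' @return Named numeric vector of group means.
#' @export
group_mean_scores <- function(records,
                              groups = list(
                                "Lixisols and Luvisols" = c("Lixisols",
                                                            "Luvisols"),
                                "Cambisols" = "Cambisols"),
                              digits = 2) {
  out <- vapply(groups, function(members) {
    sel <- records$soil_group %in% members
    if (!any(sel))
      stop("empty soil group in `groups`", call. = FALSE)
    mean(records$inundation_score[sel])
  }, numeric(1))
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}
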