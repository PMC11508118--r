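extdata_csv <- function(name) {
  path <- system.file("extdata", name, package = "inundr", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Packaged site terrain table
#'
#' The seven observation points of the Central Plateau survey: soil group,
#' normalized water accumulation score, longitudinal and cross-sectional
#' convexity (1/m), and the published inundation score. The
#' `*_printed` columns keep the exponent-notation strings exactly as
#' published, for provenance; the numeric columns are their parsed values.
#'
#' @return Data frame with 7 rows.
#' @export
load_site_terrain <- function() extdata_csv("site_terrain.csv")

#' Soil-group summary rows of the site terrain table
#'
#' @return Data frame with 2 rows (Lixisols and Luvisols pooled; Cambisols).
#' @export
load_site_terrain_groups <- function() extdata_csv("site_terrain_groups.csv")

#' Packaged field-trial table
#'
#' Per-site three-year means and standard deviations from the 2013-2015
#' phosphorus trials: submergence duration (days), cumulative water depth
#' (cm), grain yield (Mg/ha) under the CT, NK, NK+PR and NK+TSP treatments,
#' and the published yield increases over CT.
#'
#' @return Data frame with 7 rows.
#' @export
load_field_trials <- function() extdata_csv("field_trials.csv")

#' Soil-group and overall summary rows of the field-trial table
#'
#' @return Data frame with 3 rows (Lixisols and Luvisols; Cambisols; All
#'   sites). Note the pooled means were computed over unpublished
#'   plot/year-level replicates, so they are not the means of the printed
#'   site means.
#' @export
load_field_trials_groups <- function() extdata_csv("field_trials_groups.csv")

#' Packaged soil-horizon table
#'
#' The 38 horizons described in the seven soil profiles: depths (cm),
#' texture fractions (%), total C and N (g/kg), pH, electrical conductivity
#' (S/m), Bray1/Bray2 phosphorus (mg P/kg), exchangeable cations and CEC
#' (cmolc/kg), and the base-saturation indices (%). 34 horizons have
#' complete chemistry; 3 more have texture only; one deep horizon carries
#' no measurements. `depth_bottom` is `NA` for open-ended horizons (the
#' published depth string is kept in `depth_printed`).
#'
#' @param complete_only if `TRUE`, keep only horizons with complete
#'   chemistry (the subset correlation analyses use).
#' @return Data frame with 38 rows (34 if `complete_only`).
#' @export
load_soil_horizons <- function(complete_only = FALSE) {
  d <- extdata_csv("soil_horizons.csv")
  if (complete_only) {
    chem <- c("sand", "silt", "clay", "total_c", "total_n", "ph_h2o",
              "ph_kcl", "ec", "bray1_p", "bray2_p", "exch_al", "exch_na",
              "exch_k", "exch_ca", "exch_mg", "cec", "bs", "ebs")
    d <- d[stats::complete.cases(d[, chem]), ]
    rownames(d) <- NULL
  }
  d
}

#' Depth-weighted topsoil texture per site
#'
#' Averages sand, silt and clay over the horizons intersecting the 0 to
#' `depth` cm layer, weighted by the thickness of the intersection (the
#' convention used for relating topsoil texture to terrain).
#'
#' @param horizons data frame from [load_soil_horizons].
#' @param depth lower bound of the topsoil layer in cm (default 20).
#' @return Data frame with columns `site`, `sand`, `silt`, `clay`.
#' @export
topsoil_texture <- function(horizons, depth = 20) {
  sites <- unique(horizons$site)
  out <- lapply(sites, function(s) {
    h <- horizons[horizons$site == s & !is.na(horizons$sand), ]
    bot <- ifelse(is.na(h$depth_bottom), Inf, h$depth_bottom)
    w <- pmax(0, pmin(bot, depth) - pmax(h$depth_top, 0))
    if (sum(w) == 0)
      stop(sprintf("site '%s' has no texture data above %g cm", s, depth),
           call. = FALSE)
    data.frame(site = s,
               sand = sum(h$sand * w) / sum(w),
               silt = sum(h$silt * w) / sum(w),
               clay = sum(h$clay * w) / sum(w))
  })
  do.call(rbind, out)
}
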