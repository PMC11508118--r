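#' Simple linear regression with adjusted R-squared
#'
#' Ordinary least squares of `y` on `x` via [stats::lm], reported the way
#' single-regression panels in field-trial figures are: slope, intercept,
#' R-squared, adjusted R-squared `1 - (1 - R2)(n - 1)/(n - 2)`, and the
#' two-sided p-value of the slope.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`, `x` not constant.
#' @return List of class `ols_fit`: `slope`, `intercept`, `r2`, `r2_adj`,
#'   `p_value`, `n`.
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length",
                                   call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations", call. = FALSE)
  if (max(x) == min(x))
    stop("degenerate design: `x` is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = sm$r.squared,
    r2_adj = sm$adj.r.squared,
    p_value = unname(sm$coefficients[2, 4]),
    n = n
  ), class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("y = %.4f x + %.4f  (R2 = %.3f, R2adj = %.3f, p = %.4g, n = %d)\n",
              x$slope, x$intercept, x$r2, x$r2_adj, x$p_value, x$n))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked data (ties receive average ranks).
#'
#' @param x,y equal-length numeric vectors, `n >= 3`, neither constant.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length",
                                   call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete observations",
                          call. = FALSE)
  if (max(x) == min(x) || max(y) == min(y))
    stop("correlation undefined for a constant vector", call. = FALSE)
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

#' Correlation matrix of soil texture against soil properties
#'
#' Pairwise correlations of the sand/silt/clay fractions with each other
#' and with the chemical properties, over horizons with complete chemistry.
#' The packaged survey's printed matrix is reproduced by the
#' product-moment (Pearson) method; rank (Spearman) correlations are also
#' available.
#'
#' @param horizons data frame from [load_soil_horizons].
#' @param method `"pearson"` or `"spearman"`.
#' @param complete_only keep only horizons with complete chemistry
#'   (default TRUE; drops texture-only rows).
#' @return Numeric matrix: rows = all properties, columns = sand/silt/clay.
#' @export
texture_correlations <- function(horizons,
                                 method = c("pearson", "spearman"),
                                 complete_only = TRUE) {
  method <- match.arg(method)
  props <- c("sand", "silt", "clay", "total_c", "total_n", "ph_h2o",
             "ph_kcl", "ec", "bray1_p", "bray2_p", "exch_al", "exch_na",
             "exch_k", "exch_ca", "exch_mg", "cec", "bs", "ebs")
  d <- horizons[, props]
  if (complete_only) d <- d[stats::complete.cases(d), ]
  out <- matrix(NA_real_, length(props), 3,
                dimnames = list(props, c("sand", "silt", "clay")))
  for (p in props) for (tx in c("sand", "silt", "clay")) {
    if (p == tx) next
    out[p, tx] <- if (method == "spearman")
      spearman_rho(d[[p]], d[[tx]]) else stats::cor(d[[p]], d[[tx]])
  }
  attr(out, "n") <- nrow(d)
  out
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value, via [stats::t.test].
#'
#' @param a,b numeric vectors, each with at least 2 values.
#' @return List with `t`, `df`, `p_value`.
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations", call. = FALSE)
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Fits a one-way ANOVA ([stats::aov]), runs all-pairs Tukey honestly
#' significant difference comparisons ([stats::TukeyHSD]; Tukey-Kramer for
#' unbalanced groups), and summarizes them as letters: groups sharing a
#' letter are not significantly different at `alpha`. Letters are assigned
#' from the maximal cliques of the not-significantly-different graph, with
#' groups ordered by decreasing mean.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each `n >= 2`).
#' @param alpha family-wise significance level (default 0.05).
#' @return List with `f`, `p_value`, `tukey` (data frame of pairwise
#'   comparisons) and `letters` (named character vector).
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  ns <- vapply(groups, function(g) sum(!is.na(g)), integer(1))
  if (any(ns < 2))
    stop(sprintf("group '%s' has fewer than 2 observations",
                 names(groups)[which(ns < 2)[1]]), call. = FALSE)
  d <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)),
                   levels = names(groups)))
  fit <- stats::aov(value ~ group, data = d)
  an <- summary(fit)[[1]]
  hsd <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  tukey <- data.frame(comparison = rownames(hsd), hsd, row.names = NULL)
  names(tukey) <- c("comparison", "diff", "lwr", "upr", "p_adj")
  k <- length(groups)
  ns_mat <- matrix(TRUE, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(nrow(tukey))) {
    pair <- strsplit(tukey$comparison[i], "-", fixed = TRUE)[[1]]
    sig <- tukey$p_adj[i] < alpha
    ns_mat[pair[1], pair[2]] <- ns_mat[pair[2], pair[1]] <- !sig
  }
  letters_out <- cld_letters(ns_mat,
                             order_by = -vapply(groups, mean, numeric(1),
                                                na.rm = TRUE))
  list(f = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
       tukey = tukey, letters = letters_out)
}

# Compact letter display from a symmetric "not significantly different"
# adjacency matrix: every maximal clique gets one letter; a group's string
# concatenates the letters of the cliques it belongs to. Exact subset
# enumeration -- fine for the handful of treatment groups used here.
cld_letters <- function(ns_mat, order_by = NULL) {
  k <- nrow(ns_mat)
  labs <- rownames(ns_mat)
  ord <- if (is.null(order_by)) seq_len(k) else order(order_by)
  subsets <- list()
  for (code in seq_len(2^k - 1)) {
    members <- which(bitwAnd(code, 2^(seq_len(k) - 1)) > 0)
    if (all(ns_mat[members, members])) subsets[[length(subsets) + 1]] <- members
  }
  is_maximal <- vapply(subsets, function(s) {
    !any(vapply(subsets, function(t) length(t) > length(s) && all(s %in% t),
                logical(1)))
  }, logical(1))
  cliques <- subsets[is_maximal]
  # order cliques by the best-ranked group they contain, so letter 'a' goes
  # to the clique holding the first group in display order
  rank_of <- integer(k); rank_of[ord] <- seq_len(k)
  cliques <- cliques[order(vapply(cliques, function(s) min(rank_of[s]),
                                  integer(1)))]
  out <- stats::setNames(character(k), labs)
  for (i in seq_along(cliques))
    out[cliques[[i]]] <- paste0(out[cliques[[i]]], letters[i])
  out
}

#' Principal component analysis of standardized variables
#'
#' Z-scores every column and extracts components from the correlation
#' structure via [stats::prcomp].
#'
#' @param data numeric matrix or data frame, observations x variables, at
#'   least 2 variables and 2 observations, no missing values.
#' @return List of class `pca_fit`: `loadings` (variables x components,
#'   orthonormal columns), `sdev`, `proportion`, `cumulative`.
#' @export
pca_standardized <- function(data) {
  m <- as.matrix(data)
  if (ncol(m) < 2) stop("need at least 2 variables", call. = FALSE)
  if (nrow(m) < 2) stop("need at least 2 observations", call. = FALSE)
  if (anyNA(m)) stop("missing values are not allowed", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop(sprintf("cannot standardize zero-variance column '%s'",
                 colnames(m)[which(sds == 0)[1]]), call. = FALSE)
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  prop <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = pc$rotation, sdev = pc$sdev,
                 proportion = prop, cumulative = cumsum(prop)),
            class = "pca_fit")
}

#' @export
print.pca_fit <- function(x, ...) {
  cat("<pca_fit>\n")
  print(round(rbind(`Standard deviation` = x$sdev,
                    `Proportion of variance` = x$proportion,
                    `Cumulative proportion` = x$cumulative), 3))
  invisible(x)
}

#' Base saturation
#'
#' Percentage ratio of exchangeable basic cations (Ca + Mg + K + Na) to the
#' cation exchange capacity. May exceed 100 when the bases extracted add up
#' to more than the measured CEC.
#'
#' @param horizons data frame with columns `exch_ca`, `exch_mg`, `exch_k`,
#'   `exch_na`, `cec` (cmolc/kg).
#' @return Numeric vector of BS (%).
#' @export
base_saturation <- function(horizons) {
  if (any(!is.na(horizons$cec) & horizons$cec <= 0))
    stop("CEC must be positive", call. = FALSE)
  bases <- horizons$exch_ca + horizons$exch_mg + horizons$exch_k +
    horizons$exch_na
  100 * bases / horizons$cec
}

#' Effective base saturation
#'
#' Percentage of exchangeable bases over the effective CEC
#' (bases + exchangeable Al). Always `<= 100`.
#'
#' @param horizons data frame with columns `exch_ca`, `exch_mg`, `exch_k`,
#'   `exch_na`, `exch_al` (cmolc/kg).
#' @return Numeric vector of EBS (%).
#' @export
effective_base_saturation <- function(horizons) {
  bases <- horizons$exch_ca + horizons$exch_mg + horizons$exch_k +
    horizons$exch_na
  denom <- bases + horizons$exch_al
  if (any(!is.na(denom) & denom <= 0))
    stop("bases + exchangeable Al must be positive", call. = FALSE)
  100 * bases / denom
}

#' Yield increase over the unfertilized control
#'
#' @param trials data frame from [load_field_trials] (columns `yield_ct`,
#'   `yield_nk`, `yield_nkpr`, `yield_nktsp`).
#' @param treatment one of `"NK"`, `"NK+PR"`, `"NK+TSP"`.
#' @return Numeric vector, mean treatment yield minus mean control yield
#'   (Mg/ha) per site.
#' @export
yield_increase <- function(trials, treatment) {
  col <- switch(treatment,
                "NK" = "yield_nk", "NK+PR" = "yield_nkpr",
                "NK+TSP" = "yield_nktsp",
                stop(sprintf("unknown treatment '%s' (CT has no increase)",
                             treatment), call. = FALSE))
  trials[[col]] - trials$yield_ct
}

#' Relative yield of phosphate rock over triple superphosphate
#'
#' @param trials data frame from [load_field_trials].
#' @return Numeric vector `yield_nkpr / yield_nktsp` per site.
#' @export
relative_yield <- function(trials) {
  if (any(!is.na(trials$yield_nktsp) & trials$yield_nktsp <= 0))
    stop("NK+TSP yield must be positive", call. = FALSE)
  trials$yield_nkpr / trials$yield_nktsp
}
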