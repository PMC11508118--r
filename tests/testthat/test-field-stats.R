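test_that("OLS recovers exact lines and matches the closed form", {
  x <- c(0.1, 0.4, 0.9, 1.3, 2.0)
  f <- suppressWarnings(ols_fit(x, 2 * x + 1))  # exact fit warns in summary.lm
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)

  set.seed(21)
  for (rep in 1:5) {
    xr <- rnorm(15); yr <- 1.5 * xr + rnorm(15)
    f <- ols_fit(xr, yr)
    sxx <- sum((xr - mean(xr))^2)
    sxy <- sum((xr - mean(xr)) * (yr - mean(yr)))
    expect_equal(f$slope, sxy / sxx, tolerance = 1e-10)
    expect_equal(f$r2_adj, 1 - (1 - f$r2) * (15 - 1) / (15 - 2),
                 tolerance = 1e-10)
    res <- yr - f$intercept - f$slope * xr
    expect_lt(abs(sum(res)), 1e-9 * 15 * sd(yr))
  }
  expect_error(ols_fit(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(ols_fit(1:2, 1:2), "at least 3")
})

test_that("Spearman rho matches the rank-enumeration oracle and is monotone-invariant", {
  expect_equal(spearman_rho(1:8, (1:8)^3), 1)
  x <- c(1, 2, 2, 3); y <- c(1, 3, 2, 4)
  expect_equal(spearman_rho(x, y), spearman_oracle(x, y), tolerance = 1e-12)
  set.seed(33)
  for (rep in 1:5) {
    a <- sample(1:6, 12, replace = TRUE); b <- rnorm(12)
    expect_equal(spearman_rho(a, b), spearman_oracle(a, b), tolerance = 1e-12)
    expect_equal(spearman_rho(exp(a), b), spearman_rho(a, b))
    expect_equal(spearman_rho(a, qlogis(pnorm(b))), spearman_rho(a, b),
                 tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("Welch t-test matches the longhand formula", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  got <- welch_t(a, b)
  want <- welch_oracle(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$df, want$df, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  set.seed(8)
  big <- welch_t(rnorm(1000), rnorm(1000, mean = 1))
  expect_lt(big$p_value, 0.001)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("Tukey letters separate exactly the significant pairs", {
  same <- anova_tukey(list(a1 = c(1, 2, 3), a2 = c(1, 2, 3), a3 = c(1, 2, 3)))
  expect_true(all(same$letters == same$letters[1]))

  set.seed(14)
  far <- anova_tukey(list(lo = rnorm(5, 0, 0.1), mid = rnorm(5, 10, 0.1),
                          hi = rnorm(5, 20, 0.1)))
  expect_equal(length(unique(far$letters)), 3)
  expect_equal(nchar(far$letters), c(lo = 1L, mid = 1L, hi = 1L),
               ignore_attr = TRUE)

  # with two groups, Tukey p equals the pooled-variance t-test p
  g1 <- c(3.2, 4.1, 5.0, 4.4); g2 <- c(5.1, 6.0, 5.4)
  two <- anova_tukey(list(A = g1, B = g2))
  expect_equal(two$tukey$p_adj,
               t.test(g1, g2, var.equal = TRUE)$p.value, tolerance = 1e-9)

  # letters never separate a pair whose Tukey p >= alpha
  set.seed(99)
  for (rep in 1:10) {
    gr <- list(a = rnorm(4, 0), b = rnorm(4, rnorm(1, 0, 2)),
               c = rnorm(4, rnorm(1, 0, 2)), d = rnorm(4, rnorm(1, 0, 2)))
    res <- anova_tukey(gr)
    for (i in seq_len(nrow(res$tukey))) {
      pair <- strsplit(res$tukey$comparison[i], "-", fixed = TRUE)[[1]]
      share <- any(strsplit(res$letters[pair[1]], "")[[1]] %in%
                     strsplit(res$letters[pair[2]], "")[[1]])
      if (res$tukey$p_adj[i] >= 0.05) expect_true(share)
      else expect_false(share)
    }
  }
  expect_error(anova_tukey(list(a = 1, b = c(1, 2))), "fewer than 2")
})

test_that("standardized PCA has orthonormal loadings and oracle eigenvalues", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.0)
  perfect <- pca_standardized(cbind(a = x, b = 2 * x + 3))
  expect_equal(perfect$proportion[1], 1, tolerance = 1e-12)

  set.seed(55)
  m <- matrix(rnorm(40), 10, 4)
  fit <- pca_standardized(m)
  expect_equal(crossprod(fit$loadings), diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sum(fit$proportion), 1, tolerance = 1e-10)
  expect_true(all(diff(fit$cumulative) >= -1e-12))
  # reconstructed correlation matrix: V diag(sdev^2) V'
  rec <- fit$loadings %*% diag(fit$sdev^2) %*% t(fit$loadings)
  expect_equal(rec, cor(m), tolerance = 1e-8, ignore_attr = TRUE)

  fixed <- matrix(c(1, 2, 3, 4, 5,
                    2, 1, 4, 3, 6,
                    5, 4, 3, 2, 1), 5, 3)
  got <- pca_standardized(fixed)$sdev^2
  want <- sort(eigen(cor(fixed), symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(got, want, tolerance = 1e-10)

  bad <- cbind(u = 1:5, v = rep(2, 5))
  expect_error(pca_standardized(bad), "'v'")
})

test_that("base saturation indices reproduce the published worked examples", {
  h <- load_soil_horizons()
  nand <- h[h$site == "Nandiala" & h$horizon == "Bwg1", ]
  expect_lt(abs(base_saturation(nand) - 67.4), 0.2)
  nass <- h[h$site == "Nassoulou" & h$horizon == "Apg", ]
  expect_lt(abs(effective_base_saturation(nass) - 83.7), 0.1)

  toy <- data.frame(exch_ca = 2, exch_mg = 1, exch_k = 0.5, exch_na = 0.5,
                    exch_al = 0, cec = 4)
  expect_equal(base_saturation(toy), 100)
  expect_equal(effective_base_saturation(toy), 100)  # Al = 0
  toy0 <- data.frame(exch_ca = 0, exch_mg = 0, exch_k = 0, exch_na = 0,
                     exch_al = 1, cec = 5)
  expect_equal(base_saturation(toy0), 0)
  expect_error(base_saturation(data.frame(exch_ca = 1, exch_mg = 0,
                                          exch_k = 0, exch_na = 0, cec = 0)),
               "positive")
})

test_that("yield increases and relative yields come straight off the trial means", {
  tr <- load_field_trials()
  nass <- tr$site == "Nassoulou"
  expect_equal(yield_increase(tr, "NK")[nass], 0.58)
  expect_equal(yield_increase(tr, "NK+PR")[nass], 3.68)
  expect_error(yield_increase(tr, "CT"), "unknown")

  rel <- relative_yield(tr)
  expect_equal(rel[tr$site == "Ramongo"], 3.78 / 3.52, tolerance = 1e-12)
  expect_equal(round(rel[tr$site == "Siguinvouse"], 4), 0.4766)
  eq <- data.frame(yield_nkpr = 2.5, yield_nktsp = 2.5)
  expect_equal(relative_yield(eq), 1)
})

test_that("texture correlation matrix uses the complete-chemistry subset", {
  h <- load_soil_horizons()
  mat <- texture_correlations(h, method = "pearson")
  expect_equal(attr(mat, "n"), 34)
  expect_true(is.na(mat["sand", "sand"]))
  expect_equal(mat["clay", "sand"], mat["sand", "clay"])
  rank_mat <- texture_correlations(h, method = "spearman")
  expect_equal(rank_mat["clay", "sand"],
               spearman_oracle(h$clay[!is.na(h$cec)], h$sand[!is.na(h$cec)]),
               tolerance = 1e-12)
})
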