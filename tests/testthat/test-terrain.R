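south_plane <- function(nr = 6, nc = 5, slope = 1, cell = 5)
  rg(matrix(rev(seq_len(nr)) * slope, nr, nc), cell)

test_that("depression filling leaves draining terrain alone and levels pits", {
  p <- south_plane()
  expect_equal(fill_depressions(p)$values, p$values)

  rim <- matrix(5, 3, 3); rim[2, 2] <- 1
  expect_equal(fill_depressions(rg(rim))$values[2, 2], 5)

  # output >= input, and no interior cell below all its neighbors
  set.seed(31)
  z <- matrix(rnorm(15 * 15, sd = 2), 15, 15)
  f <- fill_depressions(rg(z))$values
  expect_true(all(f >= z))
  for (i in 2:14) for (j in 2:14)
    expect_gte(f[i, j], min(f[(i - 1):(i + 1), (j - 1):(j + 1)][-5]))
})

test_that("depression filling matches an independent priority-flood oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    g <- rg(matrix(rnorm(15 * 15, sd = 3), 15, 15))
    expect_equal(fill_depressions(g)$values, priority_flood_oracle(g),
                 tolerance = 1e-12)
  }
})

test_that("D8 directions follow steepest descent with the fixed tie order", {
  p <- south_plane(6, 6)
  codes <- d8_directions(p)$codes
  expect_true(all(codes[1:5, 2:5] == 5L))  # S everywhere in the interior
  expect_true(all(codes[6, ] == 0L))       # southern edge drains out

  bowl <- matrix(2, 3, 3); bowl[2, 2] <- 0
  cb <- d8_directions(rg(bowl))$codes
  # every ring cell points at the center
  expect_equal(cb[1, 2], 5L); expect_equal(cb[3, 2], 1L)
  expect_equal(cb[2, 1], 3L); expect_equal(cb[2, 3], 7L)
  expect_equal(cb[1, 1], 4L); expect_equal(cb[3, 3], 8L)

  # equal drop to S and E: E wins (first maximum in N,NE,E,SE,S,SW,W,NW)
  tie <- matrix(2, 3, 3); tie[2, 2] <- 1; tie[3, 2] <- 0; tie[2, 3] <- 0
  expect_equal(d8_directions(rg(tie))$codes[2, 2], 3L)

  # determinism
  set.seed(9)
  g <- fill_depressions(rg(matrix(rnorm(100), 10, 10)))
  expect_identical(d8_directions(g)$codes, d8_directions(g)$codes)
})

test_that("pits are terminal sinks by default and refusable on request", {
  pit <- matrix(5, 5, 5); pit[3, 3] <- 1
  codes <- d8_directions(rg(pit))$codes
  expect_equal(codes[3, 3], 0L)
  expect_error(d8_directions(rg(pit), on_pit = "error"), "fill_depressions")
})

test_that("flow accumulation counts upstream cells", {
  p <- south_plane(6, 5)
  acc <- flow_accumulation(d8_directions(p))$values
  for (r in 1:6) expect_true(all(acc[r, 2:4] == r - 1))

  bowl <- matrix(2, 3, 3); bowl[2, 2] <- 0
  ab <- flow_accumulation(d8_directions(rg(bowl)))$values
  expect_equal(ab[2, 2], 8)
  expect_equal(sum(ab == 0), 8)

  expect_equal(flow_accumulation(d8_directions(p), include_self = TRUE)$values,
               acc + 1)
})

test_that("flow accumulation matches the path-walking oracle on rough terrain", {
  for (seed in 1:3) {
    set.seed(seed)
    dem <- fill_depressions(rg(matrix(rnorm(12 * 12, sd = 2), 12, 12)))
    dirs <- d8_directions(dem)
    acc <- flow_accumulation(dirs)$values
    expect_equal(acc, path_walk_oracle(dirs))
    # conservation: total count equals the total of all path lengths,
    # which is what the oracle accumulates one step at a time
    expect_equal(sum(acc), sum(path_walk_oracle(dirs)))
    # every flow step is non-increasing in filled elevation
    z <- dem$values
    dr <- c(-1, -1, 0, 1, 1, 1, 0, -1); dc <- c(0, 1, 1, 1, 0, -1, -1, -1)
    for (i in 1:12) for (j in 1:12) {
      k <- dirs$codes[i, j]
      if (k > 0) expect_lte(z[i + dr[k], j + dc[k]], z[i, j])
    }
  }
})

test_that("convexity is zero on a plane and analytic on exact quadratics", {
  x <- (1:9 - 5) * 5; y <- rev(1:9) * 5
  plane <- rg(outer(y, x, function(yy, xx) 0.01 * yy))
  cv <- convexity(plane)
  expect_equal(max(abs(cv$longitudinal$values[2:8, 2:8])), 0, tolerance = 1e-14)
  expect_equal(max(abs(cv$cross_sectional$values[2:8, 2:8])), 0,
               tolerance = 1e-14)

  # parabolic channel z = b*y + a*x^2: on the axis column the gradient is
  # along y, so the cross-section picks up the full 2a, concave => negative
  ch <- channel_dem(b = 0.05, a = 0.001)
  cvc <- convexity(ch)
  expect_equal(cvc$cross_sectional$values[2:8, 5], rep(-0.002, 7),
               tolerance = 1e-10)
  expect_equal(cvc$longitudinal$values[2:8, 5], rep(0, 7), tolerance = 1e-10)

  # dome z = -a(x^2 + y^2): both convexities +2a at every interior cell
  yd <- (1:9 - 5) * 5
  dome <- rg(outer(yd, x, function(yy, xx) -0.001 * (xx^2 + yy^2)))
  cvd <- convexity(dome)
  expect_equal(cvd$longitudinal$values[2:8, 2:8],
               matrix(0.002, 7, 7), tolerance = 1e-10)
  expect_equal(cvd$cross_sectional$values[2:8, 2:8],
               matrix(0.002, 7, 7), tolerance = 1e-10)
})

test_that("convexity ignores datum shifts and scales with vertical exaggeration", {
  set.seed(13)
  z <- matrix(rnorm(64), 8, 8)
  a <- convexity(rg(z)); b <- convexity(rg(z + 100)); c3 <- convexity(rg(3 * z))
  expect_equal(a$longitudinal$values, b$longitudinal$values, tolerance = 1e-9)
  expect_equal(c3$cross_sectional$values, 3 * a$cross_sectional$values,
               tolerance = 1e-9)
  expect_error(convexity(rg(matrix(1, 2, 5))), "3 x 3")
})
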