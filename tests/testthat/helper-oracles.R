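# Independent brute-force oracles used to pin the vectorized implementations.
# These deliberately share no code with the package internals.

rg <- function(m, cell = 5) raster_grid(m, cell_size = cell)

# per-cell loop focal mean: average of valid in-bounds cells in the window
focal_mean_oracle <- function(grid, window) {
  z <- grid$values
  h <- (window - 1) / 2
  out <- z
  for (i in seq_len(nrow(z))) for (j in seq_len(ncol(z))) {
    if (is.na(z[i, j])) next
    ri <- max(1, i - h):min(nrow(z), i + h)
    cj <- max(1, j - h):min(ncol(z), j + h)
    out[i, j] <- mean(z[ri, cj], na.rm = TRUE)
  }
  out
}

ngb8 <- function(i, j, nr, nc) {
  dr <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  dc <- c(0, 1, 1, 1, 0, -1, -1, -1)
  keep <- i + dr >= 1 & i + dr <= nr & j + dc >= 1 & j + dc <= nc
  cbind(i + dr[keep], j + dc[keep])
}

# classical priority-flood: repeatedly pop the lowest frontier cell and
# raise its unvisited neighbors to at least that level
priority_flood_oracle <- function(grid) {
  z <- grid$values
  nr <- nrow(z); nc <- ncol(z)
  filled <- z
  visited <- matrix(FALSE, nr, nc)
  frontier <- matrix(FALSE, nr, nc)
  edge <- matrix(FALSE, nr, nc)
  edge[1, ] <- edge[nr, ] <- edge[, 1] <- edge[, nc] <- TRUE
  frontier[edge & !is.na(z)] <- TRUE
  while (any(frontier)) {
    idx <- which(frontier)
    c0 <- idx[which.min(filled[idx])]
    frontier[c0] <- FALSE
    visited[c0] <- TRUE
    i <- (c0 - 1) %% nr + 1; j <- (c0 - 1) %/% nr + 1
    nb <- ngb8(i, j, nr, nc)
    for (k in seq_len(nrow(nb))) {
      n0 <- (nb[k, 2] - 1) * nr + nb[k, 1]
      if (!visited[n0] && !frontier[n0] && !is.na(z[n0])) {
        filled[n0] <- max(z[n0], filled[c0])
        frontier[n0] <- TRUE
      }
    }
  }
  filled
}

# walk every cell's flow path and increment every downstream cell
path_walk_oracle <- function(dirs) {
  codes <- dirs$codes
  nr <- nrow(codes); nc <- ncol(codes)
  dr <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  dc <- c(0, 1, 1, 1, 0, -1, -1, -1)
  acc <- matrix(0, nr, nc)
  acc[is.na(codes)] <- NA
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(codes[i, j])) next
    ci <- i; cj <- j; steps <- 0
    while (codes[ci, cj] > 0) {
      k <- codes[ci, cj]
      ci <- ci + dr[k]; cj <- cj + dc[k]
      acc[ci, cj] <- acc[ci, cj] + 1
      steps <- steps + 1
      if (steps > nr * nc) stop("oracle: cycle")
    }
  }
  acc
}

# Welch statistic written out longhand
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# average ranks by explicit counting, then the Pearson formula longhand
spearman_oracle <- function(x, y) {
  avg_rank <- function(v)
    sapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2)
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# a small valley DEM used by several scoring tests
channel_dem <- function(b = 0.05, a = 0.001, n = 9, cell = 5) {
  x <- (seq_len(n) - (n + 1) / 2) * cell
  y <- rev(seq_len(n)) * cell
  rg(outer(y, x, function(yy, xx) b * yy + a * xx^2), cell)
}
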