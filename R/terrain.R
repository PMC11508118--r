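# D8 neighbor scan order is fixed: N, NE, E, SE, S, SW, W, NW.
# Codes: 0 = outlet (drains off-grid), 1..8 = index into this order, NA = nodata.
D8_DR <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
D8_DC <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
D8_NAMES <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")

shift_mat <- function(m, dr, dc, fill = NA) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r_dst <- max(1L, 1L - dr):min(nr, nr - dr)
  c_dst <- max(1L, 1L - dc):min(nc, nc - dc)
  out[r_dst, c_dst] <- m[r_dst + dr, c_dst + dc]
  out
}

# Valid cells on the grid edge or touching a nodata cell: water can exit there.
boundary_mask <- function(nodata) {
  nr <- nrow(nodata); nc <- ncol(nodata)
  b <- matrix(FALSE, nr, nc)
  b[1, ] <- TRUE; b[nr, ] <- TRUE; b[, 1] <- TRUE; b[, nc] <- TRUE
  for (k in 1:8)
    b <- b | shift_mat(nodata, D8_DR[k], D8_DC[k], fill = FALSE)
  b & !nodata
}

#' Fill depressions in a DEM
#'
#' Raises interior pits to their spill elevation so that every cell has a
#' non-ascending path to the grid edge (or to a nodata hole, treated as an
#' exit). Uses the iterative inundation relaxation: the water surface starts
#' at infinity except on boundary cells and is lowered to
#' `max(ground, min(neighbors) + epsilon)` until it stops changing, whose
#' fixed point is the classical filled surface. With `epsilon = 0` filled
#' depressions become level flats (resolved later during flow routing);
#' a small positive `epsilon` imposes a drainage gradient instead.
#'
#' @param dem a [raster_grid] of elevations (m).
#' @param epsilon non-negative elevation increment per cell step (m).
#' @return A [raster_grid] with `output >= input` everywhere and no interior
#'   cell strictly lower than all of its valid neighbors.
#' @export
fill_depressions <- function(dem, epsilon = 0) {
  check_grid(dem)
  if (epsilon < 0) stop("`epsilon` must be non-negative", call. = FALSE)
  z <- dem$values
  nodata <- dem$nodata
  bnd <- boundary_mask(nodata)
  w <- matrix(Inf, nrow(z), ncol(z))
  w[bnd] <- z[bnd]
  w[nodata] <- NA_real_
  max_iter <- length(z) + 2L
  for (it in seq_len(max_iter)) {
    nmin <- matrix(Inf, nrow(z), ncol(z))
    for (k in 1:8) {
      s <- shift_mat(w, D8_DR[k], D8_DC[k], fill = Inf)
      s[is.na(s)] <- Inf   # nodata neighbors impose no ceiling
      nmin <- pmin(nmin, s)
    }
    cand <- pmax(z, nmin + epsilon)
    new_w <- pmin(w, cand)
    new_w[bnd] <- z[bnd]
    new_w[nodata] <- NA_real_
    if (identical(new_w, w)) break
    w <- new_w
    if (it == max_iter)
      stop("depression filling failed to converge", call. = FALSE)
  }
  if (any(is.infinite(w[!nodata])))
    stop("isolated cells with no drainage path; check the nodata mask",
         call. = FALSE)
  with_values(dem, w)
}

#' D8 steepest-descent flow directions
#'
#' Assigns each valid cell the single neighbor with the maximum positive
#' drop per unit distance (diagonal distance = `cell_size * sqrt(2)`). Ties
#' go to the first maximum in the fixed scan order N, NE, E, SE, S, SW, W,
#' NW. Boundary cells with no lower neighbor drain off-grid (code 0). Level
#' flats left by [fill_depressions] are routed toward their spill point by
#' breadth-first growth from the cells that already drain.
#'
#' Interior cells with no lower or equal neighbor are pits: under
#' `on_pit = "sink"` (default) they become terminal cells that trap the
#' flow routed into them, matching the usual GIS behavior on unfilled
#' terrain; `on_pit = "error"` refuses them and points at
#' [fill_depressions].
#'
#' @param dem a (preferably depression-filled) [raster_grid].
#' @param on_pit `"sink"` or `"error"`; see above.
#' @return An object of class `flow_directions`: list with `codes` (integer
#'   matrix; 0 = outlet/sink, 1..8 = N,NE,E,SE,S,SW,W,NW, NA = nodata) and
#'   `cell_size`.
#' @export
d8_directions <- function(dem, on_pit = c("sink", "error")) {
  on_pit <- match.arg(on_pit)
  check_grid(dem)
  z <- dem$values
  nodata <- dem$nodata
  dist <- dem$cell_size * ifelse(D8_DR != 0 & D8_DC != 0, sqrt(2), 1)
  best_drop <- matrix(-Inf, nrow(z), ncol(z))
  codes <- matrix(0L, nrow(z), ncol(z))
  for (k in 1:8) {
    zn <- shift_mat(z, D8_DR[k], D8_DC[k], fill = NA)
    drop <- (z - zn) / dist[k]
    drop[is.na(drop)] <- -Inf
    upd <- drop > best_drop     # strict: first maximum in scan order wins
    best_drop[upd] <- drop[upd]
    codes[upd] <- k
  }
  unresolved <- !nodata & !(best_drop > 0)
  codes[unresolved] <- 0L
  bnd <- boundary_mask(nodata)
  # boundary cells with no positive drop exit the grid
  unresolved <- unresolved & !bnd
  # breadth-first flat routing: grow from already-draining cells through
  # equal-elevation neighbors, pointing each flat cell at its BFS parent
  resolved <- !nodata & !unresolved
  while (any(unresolved)) {
    assigned <- matrix(FALSE, nrow(z), ncol(z))
    for (k in 1:8) {
      rn <- shift_mat(resolved, D8_DR[k], D8_DC[k], fill = FALSE)
      zn <- shift_mat(z, D8_DR[k], D8_DC[k], fill = NA)
      hit <- unresolved & !assigned & rn & !is.na(zn) & zn == z
      codes[hit] <- k
      assigned <- assigned | hit
    }
    if (!any(assigned)) {
      if (on_pit == "error") {
        p <- which(unresolved, arr.ind = TRUE)[1, ]
        stop(sprintf("unfilled pit at (row %d, col %d); run fill_depressions() first",
                     p[1], p[2]), call. = FALSE)
      }
      break   # remaining cells are pits (or closed flats): terminal sinks
    }
    resolved <- resolved | assigned
    unresolved <- unresolved & !assigned
  }
  codes[nodata] <- NA_integer_
  structure(list(codes = codes, cell_size = dem$cell_size),
            class = "flow_directions")
}

#' @export
print.flow_directions <- function(x, ...) {
  cat(sprintf("<flow_directions> %d x %d, %d outlets\n",
              nrow(x$codes), ncol(x$codes), sum(x$codes == 0L, na.rm = TRUE)))
  invisible(x)
}

#' Direction codes as a raster
#'
#' @param dirs a `flow_directions` object.
#' @return A [raster_grid] of integer codes (0 = outlet, 1 = N, 2 = NE,
#'   3 = E, 4 = SE, 5 = S, 6 = SW, 7 = W, 8 = NW).
#' @export
direction_raster <- function(dirs) {
  stopifnot(inherits(dirs, "flow_directions"))
  raster_grid(matrix(as.numeric(dirs$codes), nrow(dirs$codes)),
              cell_size = dirs$cell_size)
}

#' D8 flow accumulation
#'
#' Counts, for every cell, the number of distinct upstream cells whose flow
#' path passes through it (the cell itself excluded by default). Computed by
#' topological (Kahn) traversal of the direction graph.
#'
#' @param dirs a `flow_directions` object from [d8_directions].
#' @param include_self logical; add 1 to every valid cell's count.
#' @return A [raster_grid] of non-negative counts.
#' @export
flow_accumulation <- function(dirs, include_self = FALSE) {
  stopifnot(inherits(dirs, "flow_directions"))
  codes <- dirs$codes
  nr <- nrow(codes); nc <- ncol(codes)
  n <- nr * nc
  code_v <- as.integer(codes)
  valid <- which(!is.na(code_v))
  # receiver cell index (column-major) for each cell; NA for outlets/nodata
  recv <- rep(NA_integer_, n)
  flow <- valid[code_v[valid] > 0L]
  if (length(flow)) {
    k <- code_v[flow]
    r <- ((flow - 1L) %% nr) + 1L
    cc <- ((flow - 1L) %/% nr) + 1L
    recv[flow] <- (cc + D8_DC[k] - 1L) * nr + (r + D8_DR[k])
  }
  indeg <- tabulate(recv[!is.na(recv)], nbins = n)
  acc <- rep(0, n)
  queue <- integer(length(valid))
  seeds <- valid[indeg[valid] == 0L]
  queue[seq_along(seeds)] <- seeds
  tail <- length(seeds)
  head <- 1L
  while (head <= tail) {
    c0 <- queue[head]; head <- head + 1L
    r0 <- recv[c0]
    if (!is.na(r0)) {
      acc[r0] <- acc[r0] + acc[c0] + 1
      indeg[r0] <- indeg[r0] - 1L
      if (indeg[r0] == 0L) {
        tail <- tail + 1L
        queue[tail] <- r0
      }
    }
  }
  if (tail < length(valid)) {
    left <- setdiff(valid, queue[seq_len(tail)])
    r <- ((left[1] - 1L) %% nr) + 1L
    cc <- ((left[1] - 1L) %/% nr) + 1L
    stop(sprintf("cyclic flow detected at (row %d, col %d)", r, cc),
         call. = FALSE)
  }
  if (include_self) acc[valid] <- acc[valid] + 1
  m <- matrix(NA_real_, nr, nc)
  m[valid] <- acc[valid]
  raster_grid(m, cell_size = dirs$cell_size)
}

#' Longitudinal and cross-sectional convexity
#'
#' Fits the 3x3 finite-difference quadratic (Zevenbergen-Thorne stencil) at
#' every interior cell and returns the negated second directional derivative
#' of elevation along the gradient (longitudinal, i.e. profile direction)
#' and perpendicular to it (cross-sectional). The sign convention is the
#' geomorphological one: negative = concave topography that stagnates
#' water, positive = convex shedding topography. Units are 1/m.
#'
#' Cells with (numerically) zero gradient take the negated raw second
#' derivatives instead: `-d2z/dy2` as longitudinal and `-d2z/dx2` as
#' cross-sectional, so symmetric valley floors and dome tops still score.
#' Border and nodata-adjacent cells are nodata.
#'
#' @param dem a [raster_grid] with at least 3 rows and 3 columns.
#' @param grad_tol gradient-squared threshold below which a cell is treated
#'   as flat.
#' @return List of class `convexity_grids` with elements `longitudinal` and
#'   `cross_sectional`, both [raster_grid]s.
#' @export
convexity <- function(dem, grad_tol = 1e-12) {
  check_grid(dem)
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3)
    stop("convexity needs a grid of at least 3 x 3 cells", call. = FALSE)
  L <- dem$cell_size
  # 8 shifted neighbors; any NA in the 3x3 window voids the cell
  zN <- shift_mat(z, -1L, 0L); zS <- shift_mat(z, 1L, 0L)
  zE <- shift_mat(z, 0L, 1L); zW <- shift_mat(z, 0L, -1L)
  zNE <- shift_mat(z, -1L, 1L); zNW <- shift_mat(z, -1L, -1L)
  zSE <- shift_mat(z, 1L, 1L); zSW <- shift_mat(z, 1L, -1L)
  zx <- (zE - zW) / (2 * L)             # x: east, +col
  zy <- (zN - zS) / (2 * L)             # y: north, -row
  zxx <- (zE - 2 * z + zW) / L^2
  zyy <- (zN - 2 * z + zS) / L^2
  zxy <- (zNE - zNW - zSE + zSW) / (4 * L^2)
  g2 <- zx^2 + zy^2
  flat <- !is.na(g2) & g2 < grad_tol
  g2safe <- ifelse(flat | is.na(g2), 1, g2)
  d2_along <- (zxx * zx^2 + 2 * zxy * zx * zy + zyy * zy^2) / g2safe
  d2_across <- (zxx * zy^2 - 2 * zxy * zx * zy + zyy * zx^2) / g2safe
  d2_along[flat] <- zyy[flat]
  d2_across[flat] <- zxx[flat]
  long <- -d2_along
  cross <- -d2_across
  structure(list(
    longitudinal = raster_grid(long, cell_size = L, origin = dem$origin),
    cross_sectional = raster_grid(cross, cell_size = L, origin = dem$origin)
  ), class = "convexity_grids")
}
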