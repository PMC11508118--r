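#' Gridded raster container
#'
#' A minimal single-band raster: a numeric matrix of cell values, a square
#' cell size in meters, and a nodata mask. Row 1 is the northern edge and
#' column 1 the western edge; cell centers are the reference points. Grids
#' are assumed to be in a projected, meter-unit coordinate system (the
#' scoring pipeline is meaningless on geographic-degree grids).
#'
#' Cells flagged nodata carry `NA` in `values` and are excluded from every
#' statistic and filter window.
#'
#' @param values numeric matrix of cell values; `NA` entries are treated as
#'   nodata in addition to anything flagged in `nodata_mask`.
#' @param cell_size positive cell edge length in meters.
#' @param nodata_mask optional logical matrix of the same shape; `TRUE`
#'   marks nodata cells.
#' @param origin numeric length-2 `(x, y)` of the lower-left corner in
#'   projected coordinates (informational only).
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size = 5, nodata_mask = NULL,
                        origin = c(0, 0)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("grid must have at least one row and one column", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || is.na(cell_size) ||
      cell_size <= 0)
    stop("`cell_size` must be a single positive number", call. = FALSE)
  if (is.null(nodata_mask)) {
    nodata_mask <- is.na(values)
  } else {
    if (!is.logical(nodata_mask) || !identical(dim(nodata_mask), dim(values)))
      stop("`nodata_mask` must be a logical matrix with the shape of `values`",
           call. = FALSE)
    nodata_mask <- nodata_mask | is.na(values)
  }
  values[nodata_mask] <- NA_real_
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         nodata = nodata_mask, origin = as.numeric(origin)),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  nv <- sum(!x$nodata)
  cat(sprintf("<raster_grid> %d x %d cells, cell size %g m, %d valid\n",
              nrow(x$values), ncol(x$values), x$cell_size, nv))
  if (nv > 0)
    cat(sprintf("  range: [%g, %g]\n",
                min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

is_raster_grid <- function(x) inherits(x, "raster_grid")

check_grid <- function(grid, need_valid = TRUE) {
  if (!is_raster_grid(grid))
    stop("expected a `raster_grid` object", call. = FALSE)
  if (need_valid && all(grid$nodata))
    stop("grid has no valid (non-nodata) cells", call. = FALSE)
  invisible(grid)
}

with_values <- function(grid, values) {
  grid$values <- values
  grid$nodata <- grid$nodata | is.na(values)
  grid$values[grid$nodata] <- NA_real_
  grid
}

#' Half-up decimal rounding
#'
#' `round()` in R rounds half to even; printed agronomic tables round half
#' away from zero, so table-reproduction paths use this instead.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero at `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Focal (moving-window) mean filter
#'
#' Low-pass filters a grid by replacing each valid cell with the arithmetic
#' mean of the valid cells in the centered `window` x `window` neighborhood.
#' At edges the window shrinks to its intersection with the grid; nodata
#' neighbors are omitted from the mean and nodata cells stay nodata.
#'
#' @param grid a [raster_grid].
#' @param window odd positive integer window edge length, in cells.
#' @return A [raster_grid] of the same shape.
#' @export
focal_mean <- function(grid, window) {
  check_grid(grid)
  if (!is.numeric(window) || length(window) != 1L || is.na(window) ||
      window < 1 || window != floor(window) || window %% 2 == 0)
    stop("`window` must be an odd positive integer", call. = FALSE)
  if (window == 1) return(grid)
  z <- grid$values
  nr <- nrow(z); nc <- ncol(z)
  h <- (window - 1L) / 2L
  vals <- ifelse(is.na(z), 0, z)
  ok <- !is.na(z)
  sums <- matrix(0, nr, nc)
  cnts <- matrix(0, nr, nc)
  for (dr in -h:h) {
    r_dst <- max(1L, 1L - dr):min(nr, nr - dr)
    r_src <- r_dst + dr
    for (dc in -h:h) {
      c_dst <- max(1L, 1L - dc):min(nc, nc - dc)
      c_src <- c_dst + dc
      sums[r_dst, c_dst] <- sums[r_dst, c_dst] + vals[r_src, c_src]
      cnts[r_dst, c_dst] <- cnts[r_dst, c_dst] + ok[r_src, c_src]
    }
  }
  out <- sums / cnts
  out[grid$nodata] <- NA_real_
  with_values(grid, out)
}

#' Logarithmic transform of a non-negative grid
#'
#' Maps every valid cell `x` to `log(x + offset, base)`; with the defaults
#' (base 10, offset 1), zero maps to zero and the transform is monotone, as
#' required when compressing heavy-tailed flow-accumulation counts.
#'
#' @param grid a [raster_grid] with all valid cells `>= 0`.
#' @param base logarithm base, 10 or `exp(1)`.
#' @param offset constant added before taking the log (default 1).
#' @return A [raster_grid].
#' @export
log_transform <- function(grid, base = 10, offset = 1) {
  check_grid(grid)
  neg <- which(!grid$nodata & grid$values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative value at cell (row %d, col %d); log transform needs non-negative cells",
                 neg[1, 1], neg[1, 2]), call. = FALSE)
  with_values(grid, log(grid$values + offset, base = base))
}

#' Min-max normalization to [0, 1]
#'
#' Affinely rescales the valid cells so the minimum maps to 0 and the
#' maximum to 1. Rank order is preserved. Note the result depends on the
#' analysis extent: the same cell gets a different normalized value if the
#' grid is cropped, so scores from different extents are not comparable.
#'
#' @param grid a [raster_grid] with at least two distinct valid values.
#' @return A [raster_grid] with valid cells in `[0, 1]`.
#' @export
normalize_01 <- function(grid) {
  check_grid(grid)
  lo <- min(grid$values, na.rm = TRUE)
  hi <- max(grid$values, na.rm = TRUE)
  if (hi <= lo)
    stop("degenerate range: all valid cells are equal; cannot normalize",
         call. = FALSE)
  with_values(grid, (grid$values - lo) / (hi - lo))
}

#' Read an ESRI ASCII grid
#'
#' Parses the plain-text ArcInfo ASCII raster interchange format
#' (`ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header followed
#' by rows of values, north row first).
#'
#' @param path file path.
#' @return A [raster_grid].
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && !is.na(suppressWarnings(as.numeric(parts[2]))) &&
        grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      i <- i + 1L
    } else break
  }
  for (k in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[k]])) stop(sprintf("missing '%s' in ASCII grid header", k),
                                call. = FALSE)
  vals <- scan(text = paste(lines[-seq_len(i)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("ASCII grid body does not match nrows x ncols", call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  raster_grid(m, cell_size = hdr$cellsize,
              origin = c(hdr$xllcorner %||% 0, hdr$yllcorner %||% 0))
}

#' Write an ESRI ASCII grid
#'
#' @param grid a [raster_grid].
#' @param path output file path.
#' @param nodata_value numeric written for nodata cells (default -9999).
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(grid, path, nodata_value = -9999) {
  check_grid(grid, need_valid = FALSE)
  z <- grid$values
  z[is.na(z)] <- nodata_value
  hdr <- c(
    sprintf("ncols %d", ncol(z)),
    sprintf("nrows %d", nrow(z)),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2]),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", nodata_value)
  )
  body <- apply(z, 1, function(r) paste(format(r, trim = TRUE, digits = 15),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
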