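## Gridded multi-variable paleoclimate time series with land/ice masks.
## Arrays are dimensioned [lon, lat, time]; sea cells are NA in every variable.

CLIMATE_VARS <- c("BIO5", "BIO6", "BIO12", "NPP", "rugosity")

#' Construct a climate cube
#'
#' A climate cube holds per-slice rasters for the five environmental
#' variables used throughout the package (BIO5 maximum temperature of the
#' warmest month, deg C; BIO6 minimum temperature of the coldest month,
#' deg C; BIO12 annual precipitation, mm/yr; NPP net primary productivity;
#' rugosity, unitless), together with per-slice land and ice masks, on a
#' regular lon/lat grid.
#'
#' @param grid List with `xmin`, `ymin` (western/southern edge of the grid,
#'   degrees), `res` (cell size, degrees), `n_lon`, `n_lat`.
#' @param times Slice ages in years BP, strictly increasing.
#' @param vars Named list of numeric arrays `[n_lon, n_lat, n_time]`, one per
#'   variable in [CLIMATE_VARS].
#' @param land,ice Logical arrays of the same shape.
#' @return An object of class `climate_cube`.
#' @export
climate_cube <- function(grid, times, vars, land, ice) {
  x <- structure(list(grid = grid, times = as.numeric(times),
                      vars = vars, land = land, ice = ice),
                 class = "climate_cube")
  validate_climate_cube(x)
}

#' @rdname climate_cube
#' @param x A `climate_cube`.
#' @export
validate_climate_cube <- function(x) {
  g <- x$grid
  for (f in c("xmin", "ymin", "res", "n_lon", "n_lat"))
    if (is.null(g[[f]])) stop2("grid field '", f, "' missing")
  if (g$res <= 0) stop2("grid resolution must be > 0")
  if (g$n_lon < 2 || g$n_lat < 2)
    stop2("degenerate grid: need at least 2 cells per axis")
  if (is.unsorted(x$times, strictly = TRUE))
    stop2("time axis must be strictly increasing")
  nt <- length(x$times)
  dims <- c(g$n_lon, g$n_lat, nt)
  missing_vars <- setdiff(CLIMATE_VARS, names(x$vars))
  if (length(missing_vars))
    stop2("variable ", missing_vars[1], " absent")
  for (v in CLIMATE_VARS)
    if (!identical(dim(x$vars[[v]]), as.integer(dims)))
      stop2("variable ", v, " has wrong dimensions")
  for (m in c("land", "ice")) {
    if (is.null(x[[m]])) stop2("mask ", m, " absent")
    if (!identical(dim(x[[m]]), as.integer(dims)))
      stop2("mask ", m, " has wrong dimensions")
  }
  ## spacing rule: 1000 y at/below 22 kya, 2000 y above (warn only: real
  ## reconstructions may deviate)
  if (nt > 1) {
    d <- diff(x$times)
    expect <- ifelse(x$times[-1] <= 22000, 1000, 2000)
    if (any(d != expect))
      warn2("time axis deviates from the 1000/2000-year spacing rule")
  }
  ## sea cells must be missing-valued everywhere
  for (v in CLIMATE_VARS) {
    bad <- !x$land & !is.na(x$vars[[v]])
    if (any(bad)) {
      x$vars[[v]][!x$land] <- NA_real_
    }
    if (any(x$land & !is.finite(x$vars[[v]])))
      stop2("variable ", v, " has non-finite values on land")
  }
  x
}

#' @export
print.climate_cube <- function(x, ...) {
  g <- x$grid
  cat("Climate cube:", g$n_lon, "x", g$n_lat, "cells at", g$res,
      "deg,", length(x$times), "time slices\n")
  cat("  extent: lon [", g$xmin, ",", g$xmin + g$n_lon * g$res,
      ") lat [", g$ymin, ",", g$ymin + g$n_lat * g$res, ")\n")
  cat("  slices:", min(x$times), "-", max(x$times), "yr BP\n")
  cat("  variables:", paste(names(x$vars), collapse = ", "), "\n")
  invisible(x)
}

cell_centers_lon <- function(grid) grid$xmin + (seq_len(grid$n_lon) - 0.5) * grid$res
cell_centers_lat <- function(grid) grid$ymin + (seq_len(grid$n_lat) - 0.5) * grid$res

## half-open cell membership [west, east) x [south, north); NA outside grid
cell_index <- function(grid, lon, lat) {
  ix <- floor((lon - grid$xmin) / grid$res) + 1
  iy <- floor((lat - grid$ymin) / grid$res) + 1
  ix[ix < 1 | ix > grid$n_lon] <- NA_integer_
  iy[iy < 1 | iy > grid$n_lat] <- NA_integer_
  list(ix = as.integer(ix), iy = as.integer(iy))
}

#' Assign ages to the nearest time slice
#'
#' Each age is mapped to the slice minimizing `|age - slice|`; exact ties are
#' broken toward the older slice. Ages more than half the local slice spacing
#' beyond either end of the axis are an error.
#'
#' @param age_calBP Numeric vector of ages, years BP.
#' @param times Sorted slice ages (years BP), e.g. `cube$times`.
#' @return Numeric vector of slice ages.
#' @examples
#' nearest_slice(c(15400, 23100, 23000), paleo_time_axis())
#' @export
nearest_slice <- function(age_calBP, times) {
  if (length(times) < 1) stop2("empty time axis")
  gaps <- slice_gaps(times)
  lo <- times[1] - gaps$lo[1] / 2
  hi <- times[length(times)] + gaps$hi[length(times)] / 2
  bad <- which(age_calBP < lo | age_calBP > hi)
  if (length(bad))
    stop2("ages outside the tolerated range [", lo, ", ", hi, "]: rows ",
          paste(utils::head(bad, 5), collapse = ", "))
  vapply(age_calBP, function(a) {
    d <- abs(a - times)
    cand <- which(d == min(d))
    times[max(cand)]  # tie -> older
  }, numeric(1))
}

#' Extract environmental values at dated points
#'
#' Looks up, for each (lon, lat, age) point, the five variable values of the
#' containing grid cell at the nearest time slice. Points falling on sea or
#' ice cells are flagged (`flagged = TRUE`, environment NA), never silently
#' dropped. Input row order is preserved.
#'
#' @param cube A [climate_cube].
#' @param points Data frame with columns `longitude`/`lon`, `latitude`/`lat`
#'   and `age_calBP`/`age`.
#' @return Data frame with lon, lat, age_calBP, the assigned slice age
#'   (`time`), one column per variable, and a logical `flagged` column.
#' @export
extract_env <- function(cube, points) {
  lon <- points$longitude %||% points$lon
  lat <- points$latitude %||% points$lat
  age <- points$age_calBP %||% points$age
  if (is.null(lon) || is.null(lat) || is.null(age))
    stop2("points need longitude, latitude and age_calBP columns")
  idx <- cell_index(cube$grid, lon, lat)
  out_grid <- which(is.na(idx$ix) | is.na(idx$iy))
  if (length(out_grid))
    stop2("points outside the grid: rows ",
          paste(utils::head(out_grid, 5), collapse = ", "))
  slice <- nearest_slice(age, cube$times)
  it <- match(slice, cube$times)
  lin <- cbind(idx$ix, idx$iy, it)
  env <- sapply(CLIMATE_VARS, function(v) cube$vars[[v]][lin])
  env <- matrix(env, nrow = length(lon),
                dimnames = list(NULL, CLIMATE_VARS))
  on_land <- cube$land[lin]
  on_ice <- cube$ice[lin]
  flagged <- !on_land | on_ice
  env[flagged, ] <- NA_real_
  out <- data.frame(lon = lon, lat = lat, age_calBP = age, time = slice,
                    env, flagged = flagged)
  rownames(out) <- NULL
  out
}

## environment table of every land, ice-free cell at one slice
slice_env_table <- function(cube, slice) {
  it <- match(slice, cube$times)
  if (is.na(it)) stop2("slice ", slice, " not in the cube")
  ok <- which(cube$land[, , it] & !cube$ice[, , it], arr.ind = TRUE)
  if (!is.matrix(ok)) ok <- matrix(ok, ncol = 2)
  lons <- cell_centers_lon(cube$grid)
  lats <- cell_centers_lat(cube$grid)
  env <- sapply(CLIMATE_VARS, function(v)
    cube$vars[[v]][cbind(ok[, 1], ok[, 2], it)])
  env <- matrix(env, nrow = nrow(ok), dimnames = list(NULL, CLIMATE_VARS))
  data.frame(lon = lons[ok[, 1]], lat = lats[ok[, 2]], time = slice,
             ix = ok[, 1], iy = ok[, 2], env)
}

#' Environmental availability densities through time
#'
#' Histograms one variable's values over land, ice-free cells, slice by
#' slice, on common bin edges spanning the global min/max, each column
#' normalized to sum to one.
#'
#' @param cube A [climate_cube].
#' @param variable One of the five variable names.
#' @param n_bins Number of bins (>= 2, default 50).
#' @return An object of class `density_matrix`: bin edges/midpoints, the
#'   slice ages and a `n_bins x n_slices` density matrix.
#' @export
availability_density <- function(cube, variable, n_bins = 50) {
  if (!variable %in% names(cube$vars)) stop2("variable ", variable, " absent")
  if (n_bins < 2) stop2("n_bins must be >= 2")
  nt <- length(cube$times)
  vals <- lapply(seq_len(nt), function(it) {
    ok <- cube$land[, , it] & !cube$ice[, , it]
    cube$vars[[variable]][, , it][ok]
  })
  all_vals <- unlist(vals)
  if (!length(all_vals)) stop2("no land, ice-free cells in any slice")
  rng <- range(all_vals)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  dens <- matrix(0, n_bins, nt, dimnames = list(NULL, cube$times))
  for (it in seq_len(nt)) {
    v <- vals[[it]]
    if (!length(v)) {
      warn2("slice ", cube$times[it], " has no land, ice-free cells")
      next
    }
    h <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
    dens[, it] <- tabulate(h, n_bins) / length(v)
  }
  structure(list(variable = variable, edges = edges,
                 mid = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                 times = cube$times, density = dens),
            class = "density_matrix")
}

#' Write / read a climate cube as a plain-text bundle
#'
#' The on-disk format is a directory with `meta.json` (grid, time axis,
#' variable names) and `data.csv` (one row per cell per slice: time, lon,
#' lat, land, ice and the five variables; sea cells carry NA). Slice order
#' on disk is immaterial: the time axis is sorted ascending on load.
#'
#' @param cube A [climate_cube].
#' @param path Directory to create/read.
#' @return `write_climate_cube` returns `path` invisibly;
#'   `read_climate_cube` returns a validated [climate_cube].
#' @export
write_climate_cube <- function(cube, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(grid = cube$grid, times = cube$times,
               variables = names(cube$vars))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  g <- cube$grid
  nt <- length(cube$times)
  lons <- rep(cell_centers_lon(g), times = g$n_lat * nt)
  lats <- rep(rep(cell_centers_lat(g), each = g$n_lon), times = nt)
  tt <- rep(cube$times, each = g$n_lon * g$n_lat)
  df <- data.frame(time = tt, lon = lons, lat = lats,
                   land = as.integer(cube$land),
                   ice = as.integer(cube$ice))
  for (v in names(cube$vars)) df[[v]] <- as.vector(cube$vars[[v]])
  utils::write.csv(df, file.path(path, "data.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_climate_cube
#' @export
read_climate_cube <- function(path) {
  mf <- file.path(path, "meta.json")
  df <- file.path(path, "data.csv")
  if (!file.exists(mf) || !file.exists(df))
    stop2("not a climate cube bundle: ", path)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  g <- as.list(meta$grid)
  for (v in CLIMATE_VARS)
    if (!v %in% meta$variables) stop2("variable ", v, " absent")
  dat <- utils::read.csv(df)
  for (m in c("land", "ice"))
    if (!m %in% names(dat)) stop2("mask ", m, " absent")
  times <- sort(unique(dat$time))
  nt <- length(times)
  dims <- c(g$n_lon, g$n_lat, nt)
  ## order rows canonically: time, then lat, then lon
  idx <- cell_index(g, dat$lon, dat$lat)
  ord <- order(match(dat$time, times), idx$iy, idx$ix)
  dat <- dat[ord, ]
  vars <- lapply(CLIMATE_VARS, function(v) array(dat[[v]], dims))
  names(vars) <- CLIMATE_VARS
  climate_cube(g, times, vars,
               land = array(dat$land == 1, dims),
               ice = array(dat$ice == 1, dims))
}

#' @export
print.density_matrix <- function(x, ...) {
  cat("Availability density for", x$variable, ":", nrow(x$density), "bins x",
      ncol(x$density), "slices\n")
  invisible(x)
}

#' Export an availability density matrix as CSV (bins x slices)
#' @param x A `density_matrix`.
#' @param path Output CSV path.
#' @export
write_density_matrix <- function(x, path) {
  df <- data.frame(bin_mid = x$mid, x$density, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
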