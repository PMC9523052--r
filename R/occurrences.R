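## Occurrence handling: window filtering, one-record-per-cell-per-slice
## collapse, and joining presence/background rows to the environment.

#' Read and window-filter an occurrence table
#'
#' Reads a CSV (or takes a data frame) of dated, georeferenced occurrences
#' and applies the study time window. The window is a closed interval:
#' records dated exactly at either bound are retained. Longitudes are
#' normalized to [-180, 180). Rows with invalid coordinates or negative
#' ages are dropped with a warning naming their row numbers; rows outside
#' the window are dropped with a logged count. The exclusion report is
#' attached as `attr(x, "exclusions")`.
#'
#' @param path CSV path or a data frame with columns species, longitude,
#'   latitude, age_calBP and optionally age_error.
#' @param window `c(young, old)` in calibrated years BP (default
#'   `c(7500, 47000)`).
#' @return Occurrence data frame with an `exclusions` attribute.
#' @export
read_occurrences <- function(path, window = c(7500, 47000)) {
  x <- if (is.data.frame(path)) path else utils::read.csv(path)
  req <- c("species", "longitude", "latitude", "age_calBP")
  for (col in req)
    if (!col %in% names(x)) stop2("required column '", col, "' missing")
  if (!"age_error" %in% names(x)) x$age_error <- NA_real_
  if (window[1] >= window[2]) stop2("window: young must be < old")
  x$longitude <- normalize_lon(x$longitude)
  invalid <- which(!is.finite(x$longitude) | !is.finite(x$latitude) |
                     abs(x$latitude) > 90 | !is.finite(x$age_calBP) |
                     x$age_calBP < 0)
  if (length(invalid)) {
    warn2("dropping ", length(invalid), " rows with invalid coordinates",
          " or ages: rows ", paste(utils::head(invalid, 10), collapse = ", "))
    x <- x[-invalid, ]
  }
  outside <- x$age_calBP < window[1] | x$age_calBP > window[2]
  n_out <- sum(outside)
  x <- x[!outside, , drop = FALSE]
  rownames(x) <- NULL
  attr(x, "exclusions") <- list(invalid = length(invalid),
                                invalid_rows = invalid,
                                outside_window = n_out,
                                window = window)
  x
}

#' Collapse occurrences to one record per cell per slice
#'
#' Assigns every record to its grid cell (half-open cells) and nearest time
#' slice, then keeps exactly one record per (species, cell, slice): the one
#' with the smallest age_error (missing age_error sorts last), remaining
#' ties broken by record content (age, then coordinates) so the result is
#' invariant to row order. Output is sorted by species, slice, cell, and
#' carries the assigned slice age in a `slice` column. Collapse is
#' idempotent.
#'
#' @param x Occurrence data frame (see [read_occurrences]).
#' @param grid Grid spec (e.g. `cube$grid`).
#' @param times Slice ages (e.g. `cube$times`).
#' @return Collapsed occurrence data frame with a `slice` column.
#' @export
collapse_occurrences <- function(x, grid, times) {
  if (nrow(x) == 0) {
    x$slice <- numeric(0)
    return(x)
  }
  idx <- cell_index(grid, x$longitude, x$latitude)
  bad <- which(is.na(idx$ix) | is.na(idx$iy))
  if (length(bad))
    stop2("records outside the grid: rows ",
          paste(utils::head(bad, 5), collapse = ", "))
  slice <- nearest_slice(x$age_calBP, times)
  cell <- (idx$iy - 1L) * grid$n_lon + idx$ix
  key <- paste(x$species, slice, cell, sep = "\r")
  err <- ifelse(is.na(x$age_error), Inf, x$age_error)
  ord <- order(key, err, x$age_calBP, x$longitude, x$latitude,
               seq_len(nrow(x)))
  keep <- ord[!duplicated(key[ord])]
  out <- x[keep, , drop = FALSE]
  out$slice <- slice[keep]
  cell_k <- cell[keep]
  final <- order(out$species, out$slice, cell_k)
  out <- out[final, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- NULL
  out
}

#' Join presences and backgrounds to the environment
#'
#' Builds, for each background repetition, the GAM design table: presence
#' rows (response 1) are identical across repetitions, background rows
#' (response 0) differ; every row carries the five variable values of its
#' cell at its slice. Presence rows that fall on sea or ice cells are
#' removed with a logged count (attribute `exclusions`); background rows
#' are drawn from eligible cells by construction.
#'
#' @param presences Collapsed occurrence table (see [collapse_occurrences]).
#' @param backgrounds A `repetition_set` from
#'   [sample_background_repetitions].
#' @param cube A [climate_cube].
#' @return A list of class `model_tables`: one data frame per repetition
#'   with columns response, time, lon, lat, the five variables and `rep`.
#' @export
build_model_table <- function(presences, backgrounds, cube) {
  stopifnot(inherits(backgrounds, "repetition_set"))
  pres_env <- extract_env(cube, presences)
  n_flagged <- sum(pres_env$flagged)
  if (n_flagged)
    message(n_flagged, " presence rows on sea or ice cells removed")
  pres_env <- pres_env[!pres_env$flagged, , drop = FALSE]
  pres_rows <- data.frame(response = 1L, time = pres_env$time,
                          lon = pres_env$lon, lat = pres_env$lat,
                          pres_env[CLIMATE_VARS])
  tables <- lapply(seq_along(backgrounds$reps), function(r) {
    bg <- backgrounds$reps[[r]]
    if (nrow(bg) == 0) stop2("repetition ", r, " has zero background points")
    bg_env <- extract_env(cube, data.frame(longitude = bg$lon,
                                           latitude = bg$lat,
                                           age_calBP = bg$slice))
    bg_rows <- data.frame(response = 0L, time = bg_env$time,
                          lon = bg_env$lon, lat = bg_env$lat,
                          bg_env[CLIMATE_VARS])
    tab <- rbind(pres_rows, bg_rows)
    tab$rep <- r
    rownames(tab) <- NULL
    tab
  })
  structure(tables, class = "model_tables",
            exclusions = list(presence_flagged = n_flagged))
}

#' Write an exclusion report as JSON
#' @param x An object carrying an `exclusions` attribute.
#' @param path Output path.
#' @export
write_exclusion_report <- function(x, path) {
  ex <- attr(x, "exclusions") %||% list()
  jsonlite::write_json(ex, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
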