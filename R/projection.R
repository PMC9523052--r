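## Geographic projection: per-slice suitability maps, minimum-predicted-
## area binarization, and averages over the four climatic periods.

#' The four climatic periods
#'
#' pre-LGM 47-27 kya, LGM 27-18 kya, Late Glacial 18-11.7 kya, Holocene
#' 11.7-7.5 kya. A slice on a shared boundary belongs to the older period
#' (intervals are `[young, old)`, the oldest closed above).
#'
#' @return Data frame with name, old, young (years BP).
#' @export
climatic_periods <- function() {
  data.frame(name = c("pre-LGM", "LGM", "Late Glacial", "Holocene"),
             old = c(47000, 27000, 18000, 11700),
             young = c(27000, 18000, 11700, 7500))
}

assign_period <- function(slice, periods = climatic_periods()) {
  out <- rep(NA_character_, length(slice))
  for (i in seq_len(nrow(periods))) {
    sel <- slice >= periods$young[i] & slice < periods$old[i]
    if (i == 1) sel <- sel | slice == periods$old[1]
    out[sel] <- periods$name[i]
  }
  out
}

#' Project an ensemble onto one time slice
#'
#' Evaluates the ensemble on the environment of every land, ice-free cell
#' at the slice; sea and ice cells are missing.
#'
#' @param ensemble A `paleo_ensemble` (or a single `paleo_gam`).
#' @param cube A [climate_cube].
#' @param slice Slice age (years BP), must be in the cube.
#' @param method Aggregation method for ensembles.
#' @return Object of class `suitability_map`: slice, grid, `n_lon x n_lat`
#'   probability matrix (NA off land or on ice).
#' @export
project_slice <- function(ensemble, cube, slice, method = NULL) {
  it <- match(slice, cube$times)
  if (is.na(it)) stop2("slice ", slice, " not in the cube")
  cells <- slice_env_table(cube, slice)
  p <- if (inherits(ensemble, "paleo_ensemble"))
    predict(ensemble, cells, method = method %||% ensemble$best)
  else predict(ensemble, cells)
  vals <- matrix(NA_real_, cube$grid$n_lon, cube$grid$n_lat)
  vals[cbind(cells$ix, cells$iy)] <- p
  structure(list(slice = slice, grid = cube$grid, values = vals),
            class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  cat("Suitability map at", x$slice, "yr BP;",
      sum(!is.na(x$values)), "cells, mean",
      sprintf("%.3f", mean(x$values, na.rm = TRUE)), "\n")
  invisible(x)
}

#' @param x A `suitability_map`.
#' @param ... Passed to [graphics::image].
#' @rdname project_slice
#' @export
plot.suitability_map <- function(x, ...) {
  g <- x$grid
  graphics::image(cell_centers_lon(g), cell_centers_lat(g), x$values,
                  xlab = "longitude", ylab = "latitude",
                  col = grDevices::hcl.colors(32, "viridis"),
                  main = paste(x$slice, "yr BP"), ...)
  invisible(x)
}

#' Minimum-predicted-area threshold
#'
#' The largest suitability threshold t such that at least `coverage` of
#' the presence predictions are >= t (default coverage 0.99), so the
#' binary map recovers 99% of the observations by construction.
#'
#' @param pred_presence Predicted probabilities at presences.
#' @param coverage Required presence coverage in (0, 1].
#' @return The threshold (a value from `pred_presence`).
#' @export
mpa_threshold <- function(pred_presence, coverage = 0.99) {
  if (!length(pred_presence)) stop2("empty prediction vector")
  if (coverage <= 0 || coverage > 1) stop2("coverage must be in (0, 1]")
  m <- ceiling(coverage * length(pred_presence))
  sort(pred_presence, decreasing = TRUE)[m]
}

#' Binarize suitability maps at a fixed threshold
#'
#' Cell = 1 iff probability >= threshold; NA cells stay NA. One threshold
#' serves all slices of a species.
#'
#' @param maps A `suitability_map` or list of them.
#' @param threshold Threshold from [mpa_threshold].
#' @return `binary_map` object(s) mirroring the input shape.
#' @export
binarize_maps <- function(maps, threshold) {
  bin1 <- function(m) {
    structure(list(slice = m$slice, grid = m$grid,
                   values = (m$values >= threshold) * 1,
                   threshold = threshold),
              class = "binary_map")
  }
  if (inherits(maps, "suitability_map")) return(bin1(maps))
  lapply(maps, bin1)
}

#' Average binary maps over climatic periods
#'
#' Groups binary maps by the period of their slice (boundary slices to the
#' older period), and per period averages the member maps over cells that
#' are land in ALL member slices; the union of member ice masks is carried
#' for display. Empty periods are skipped with a warning.
#'
#' @param binary_maps List of `binary_map`s (one per slice).
#' @param cube The [climate_cube] (for land/ice masks).
#' @param periods Period definitions (default [climatic_periods]).
#' @return Object of class `period_summary`: per period the mean map,
#'   member slices, the all-member land mask and union ice mask.
#' @export
period_average <- function(binary_maps, cube, periods = climatic_periods()) {
  slices <- vapply(binary_maps, `[[`, numeric(1), "slice")
  labels <- assign_period(slices, periods)
  out <- list()
  for (pn in periods$name) {
    members <- which(labels == pn)
    if (!length(members)) {
      warn2("period ", pn, " has no member slices; skipped")
      next
    }
    its <- match(slices[members], cube$times)
    land_all <- apply(cube$land[, , its, drop = FALSE], c(1, 2), all)
    ice_any <- apply(cube$ice[, , its, drop = FALSE], c(1, 2), any)
    stack <- simplify2array(lapply(binary_maps[members], `[[`, "values"))
    if (length(dim(stack)) == 2) dim(stack) <- c(dim(stack), 1)
    mean_map <- apply(stack, c(1, 2), function(v)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
    mean_map[!land_all] <- NA_real_
    out[[pn]] <- list(name = pn, mean = mean_map, slices = slices[members],
                      n_members = length(members), land_all = land_all,
                      ice_union = ice_any)
  }
  structure(list(periods = out, grid = cube$grid,
                 threshold = binary_maps[[1]]$threshold),
            class = "period_summary")
}

#' @export
print.period_summary <- function(x, ...) {
  cat("Period summary at threshold", sprintf("%.4f", x$threshold), "\n")
  for (p in x$periods)
    cat(sprintf("  %-12s %d slices, mean occupancy %.3f\n", p$name,
                p$n_members, mean(p$mean, na.rm = TRUE)))
  invisible(x)
}

#' Assemble the interaction-plot data bundle
#'
#' Per variable: the ensemble-mean effect surface, the presence points in
#' (time, variable value) space, and the availability density matrix, with
#' a shared color scale (global maximum absolute effect over included
#' nodes) so surfaces are comparable across variables.
#'
#' @param surfaces Named list of `interaction_surface`s (one per variable).
#' @param presence_env Presence environment table from [extract_env].
#' @param densities Named list of `density_matrix` objects.
#' @return List of class `interaction_bundle`.
#' @export
interaction_bundle <- function(surfaces, presence_env, densities) {
  vars <- names(surfaces)
  scale_max <- max(vapply(surfaces, function(s) {
    e <- abs(s$effect)
    e[!s$mask] <- NA
    max(e, na.rm = TRUE)
  }, numeric(1)))
  items <- lapply(vars, function(v) {
    list(surface = surfaces[[v]],
         presence_points = data.frame(time_kya = presence_env$time / 1000,
                                      value = presence_env[[v]]),
         density = densities[[v]])
  })
  names(items) <- vars
  structure(list(variables = items, effect_scale = scale_max),
            class = "interaction_bundle")
}
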