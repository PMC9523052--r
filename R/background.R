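## Time-matched random background sampling, repeated across independent
## sets. Background points represent available environment, not absences:
## presence cells remain eligible, and cells can be drawn more than once.

#' Sample repeated sets of time-matched background points
#'
#' For every presence, draws `ratio` background cells uniformly with
#' replacement from the land, ice-free cells of that presence's time slice
#' (within `region` if given), placing points at cell centers. The whole
#' procedure is repeated `n_rep` times with distinct per-repetition seeds
#' derived from the master seed, so the per-slice background count is
#' always `ratio` times the presence count and only locations vary across
#' seeds.
#'
#' @param presences Collapsed occurrence table with a `slice` column (see
#'   [collapse_occurrences]); if `slice` is absent it is assigned by
#'   [nearest_slice].
#' @param cube A [climate_cube].
#' @param n_rep Number of repetitions (default 25).
#' @param ratio Background:presence ratio (default 50).
#' @param region Optional bounding box `c(xmin, xmax, ymin, ymax)` on cell
#'   centers; defaults to the cube's full extent.
#' @param seed Master seed.
#' @return Object of class `repetition_set`: per-repetition data frames of
#'   (lon, lat, slice), the per-repetition seeds, `ratio` and per-slice
#'   presence counts.
#' @export
sample_background_repetitions <- function(presences, cube, n_rep = 25,
                                          ratio = 50, region = NULL,
                                          seed = 1) {
  if (nrow(presences) == 0) stop2("no presences to match")
  if (is.null(presences$slice))
    presences$slice <- nearest_slice(presences$age_calBP, cube$times)
  counts <- table(presences$slice)
  slices <- as.numeric(names(counts))
  ## eligible cells per slice, restricted to the region
  eligible <- lapply(slices, function(t) {
    cells <- slice_env_table(cube, t)
    if (!is.null(region))
      cells <- cells[cells$lon >= region[1] & cells$lon <= region[2] &
                       cells$lat >= region[3] & cells$lat <= region[4], ,
                     drop = FALSE]
    if (nrow(cells) == 0)
      stop2("slice ", t, ": no eligible background cells")
    cells
  })
  names(eligible) <- names(counts)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_rep)
  reps <- lapply(seq_len(n_rep), function(r) {
    set.seed(seeds[r])
    per_slice <- lapply(seq_along(slices), function(i) {
      cells <- eligible[[i]]
      n_bg <- ratio * as.integer(counts[i])
      pick <- sample.int(nrow(cells), n_bg, replace = TRUE)
      data.frame(lon = cells$lon[pick], lat = cells$lat[pick],
                 slice = slices[i])
    })
    out <- do.call(rbind, per_slice)
    rownames(out) <- NULL
    out
  })
  structure(list(reps = reps, seeds = seeds, ratio = ratio, n_rep = n_rep,
                 presence_counts = counts),
            class = "repetition_set")
}

#' @export
print.repetition_set <- function(x, ...) {
  cat("Background repetition set:", x$n_rep, "repetitions at ratio",
      x$ratio, ":1\n")
  cat("  rows per repetition:", nrow(x$reps[[1]]), "over",
      length(x$presence_counts), "slices\n")
  invisible(x)
}

#' Write a repetition set to disk
#'
#' One CSV per repetition plus a JSON manifest (seeds, ratio, counts).
#'
#' @param x A `repetition_set`.
#' @param dir Output directory.
#' @export
write_repetition_set <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in seq_along(x$reps))
    utils::write.csv(x$reps[[r]],
                     file.path(dir, sprintf("background_rep%02d.csv", r)),
                     row.names = FALSE)
  jsonlite::write_json(list(n_rep = x$n_rep, ratio = x$ratio,
                            seeds = x$seeds,
                            presence_counts = as.list(x$presence_counts)),
                       file.path(dir, "background_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
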