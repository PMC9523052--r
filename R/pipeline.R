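## End-to-end fitting: collapse -> background -> paired GAMs per
## repetition -> AIC comparison -> Boyce gating -> ensembles, wrapped in a
## single fitting function returning a classed object, plus a config-driven
## pipeline runner with a reproducibility manifest.

#' Fit the time-aggregated niche-change model
#'
#' The central estimator of the package. Takes dated occurrences and a
#' paleoclimate cube and (1) window-filters and collapses occurrences to
#' one record per cell per slice, (2) draws `n_rep` independent sets of
#' time-matched background points at `ratio` background points per
#' presence, (3) fits the constant-niche and changing-niche binomial GAMs
#' to every repetition, (4) compares them by AIC per repetition, (5)
#' scores every changing-niche fit with the continuous Boyce index against
#' the available environment (all land, ice-free cells of all slices), and
#' (6) ensembles the accepted fits by mean and median, keeping the
#' higher-BCI ensemble. Optionally computes deviance-partition variable
#' importance and per-repetition diagnostics.
#'
#' @param occurrences Occurrence CSV path or data frame (species,
#'   longitude, latitude, age_calBP, age_error).
#' @param cube A [climate_cube].
#' @param window Closed time window in years BP (default `c(7500, 47000)`).
#' @param region Optional bounding box for background sampling.
#' @param n_rep Background repetitions (default 25).
#' @param ratio Background:presence ratio (default 50).
#' @param vars Environmental variables (default all five).
#' @param k,k_time,gamma,optimizer Passed to [fit_gam].
#' @param bci_threshold Boyce acceptance threshold (default 0.8).
#' @param n_windows,window_fraction Passed to [boyce_index].
#' @param seed Master seed (controls background sampling).
#' @param importance Compute [variable_importance] over accepted
#'   repetitions (default FALSE; costly).
#' @param diagnostics Run [diagnose_fit] per changing-niche repetition
#'   (default FALSE).
#' @param verbose Print progress.
#' @return Object of class `paleo_sdm` with components `occurrences`
#'   (collapsed), `backgrounds`, `tables`, `fits_constant`,
#'   `fits_changing`, `comparison`, `bci` (per-repetition
#'   `boyce_result`s), `ensemble`, `screen`, and optionally `importance`
#'   and `diagnostics`.
#' @export
paleo_sdm <- function(occurrences, cube, window = c(7500, 47000),
                      region = NULL, n_rep = 25, ratio = 50,
                      vars = CLIMATE_VARS, k = NULL, k_time = 5,
                      gamma = 1.4, optimizer = "efs", bci_threshold = 0.8,
                      n_windows = 101, window_fraction = 0.1, seed = 1,
                      importance = FALSE, diagnostics = FALSE,
                      verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  occ <- read_occurrences(occurrences, window = window)
  collapsed <- collapse_occurrences(occ, cube$grid, cube$times)
  say("collapsed ", nrow(occ), " -> ", nrow(collapsed), " occurrences")
  bg <- sample_background_repetitions(collapsed, cube, n_rep = n_rep,
                                      ratio = ratio, region = region,
                                      seed = seed)
  tables <- build_model_table(collapsed, bg, cube)
  screen <- correlation_screen(tables[[1]], vars = vars)
  if (!screen$pass)
    warn2("correlation screen failed: max |r| = ",
          sprintf("%.2f", screen$max_abs))
  say("fitting ", n_rep, " repetition pairs (n = ", nrow(tables[[1]]),
      " rows each)")
  fits_constant <- vector("list", n_rep)
  fits_changing <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    fits_constant[[r]] <- fit_gam(tables[[r]], kind = "constant",
                                  vars = vars, k = k, gamma = gamma,
                                  optimizer = optimizer)
    fits_changing[[r]] <- fit_gam(tables[[r]], kind = "changing",
                                  vars = vars, k = k, k_time = k_time,
                                  gamma = gamma, optimizer = optimizer)
    say("  rep ", r, ": dAIC = ",
        sprintf("%.1f", fits_constant[[r]]$scores$aic -
                  fits_changing[[r]]$scores$aic))
  }
  comparison <- select_model(fits_constant, fits_changing)
  ## evaluation sets: presences vs all land, ice-free cells of all slices
  eval_presence <- tables[[1]][tables[[1]]$response == 1, ]
  eval_available <- do.call(rbind, lapply(cube$times, function(t)
    slice_env_table(cube, t)))
  bci <- lapply(fits_changing, function(f)
    boyce_index(predict(f, eval_presence), predict(f, eval_available),
                n_windows = n_windows, window_fraction = window_fraction,
                threshold = bci_threshold))
  bci_values <- vapply(bci, `[[`, numeric(1), "bci")
  say("per-repetition BCI: ",
      paste(sprintf("%.2f", bci_values), collapse = " "))
  ensemble <- build_ensemble(fits_changing, bci_values, eval_presence,
                             eval_available, threshold = bci_threshold,
                             n_windows = n_windows,
                             window_fraction = window_fraction)
  out <- structure(list(
    occurrences = collapsed, backgrounds = bg, tables = tables,
    screen = screen, fits_constant = fits_constant,
    fits_changing = fits_changing, comparison = comparison,
    bci = bci, bci_values = bci_values, ensemble = ensemble,
    eval_presence = eval_presence, eval_available = eval_available,
    vars = vars, window = window,
    config = list(n_rep = n_rep, ratio = ratio, k = default_k(vars, k),
                  k_time = k_time, gamma = gamma,
                  bci_threshold = bci_threshold, seed = seed)),
    class = "paleo_sdm")
  if (importance) {
    acc <- ensemble$member_reps
    out$importance <- variable_importance(tables[acc], vars = vars,
                                          kind = "changing",
                                          full_fits = fits_changing[acc],
                                          k = k, k_time = k_time,
                                          gamma = gamma,
                                          optimizer = optimizer)
  }
  if (diagnostics)
    out$diagnostics <- lapply(seq_len(n_rep), function(r)
      diagnose_fit(fits_changing[[r]], tables[[r]], seed = seed + r))
  out
}

#' @export
print.paleo_sdm <- function(x, ...) {
  cat("Time-aggregated niche-change SDM\n")
  cat("  presences:", nrow(x$occurrences), "collapsed records over",
      length(unique(x$occurrences$slice)), "slices\n")
  cat("  repetitions:", x$config$n_rep, "at ratio", x$config$ratio, ":1\n")
  print(x$comparison)
  cat(sprintf("  accepted fits (BCI > %.2f): %d of %d\n",
              x$config$bci_threshold, length(x$ensemble$members),
              x$config$n_rep))
  cat(sprintf("  best ensemble: %s (BCI %.3f)\n", x$ensemble$best,
              x$ensemble$bci[[x$ensemble$best]]$bci))
  invisible(x)
}

#' @export
summary.paleo_sdm <- function(object, ...) {
  structure(list(comparison = object$comparison$table,
                 fraction_changing = object$comparison$fraction_changing,
                 bci = object$bci_values,
                 ensemble_best = object$ensemble$best,
                 ensemble_bci = object$ensemble$bci[[object$ensemble$best]]$bci,
                 screen = object$screen,
                 importance = object$importance,
                 n_presences = nrow(object$occurrences)),
            class = "summary.paleo_sdm")
}

#' @export
print.summary.paleo_sdm <- function(x, ...) {
  cat("Per-repetition model comparison:\n")
  print(x$comparison[c("rep", "aic_constant", "aic_changing", "delta_aic",
                       "winner")], digits = 6)
  cat(sprintf("\nChanging niche favored in %.0f%% of repetitions\n",
              100 * x$fraction_changing))
  cat("Per-repetition BCI:", paste(sprintf("%.3f", x$bci), collapse = " "),
      "\n")
  cat(sprintf("Best ensemble: %s (BCI %.3f)\n", x$ensemble_best,
              x$ensemble_bci))
  if (!is.null(x$importance)) {
    cat("\nVariable importance (deviance explained):\n")
    print(x$importance, digits = 3)
  }
  invisible(x)
}

#' @export
predict.paleo_sdm <- function(object, newdata, ...) {
  predict(object$ensemble, newdata, ...)
}

#' @param x A `paleo_sdm` object.
#' @param type "surface" (environment-by-time effect heatmap) or "map"
#'   (suitability map at one slice).
#' @param variable Variable for `type = "surface"`.
#' @param cube,slice For `type = "map"`.
#' @param ... Passed on to the underlying plot method.
#' @rdname paleo_sdm
#' @export
plot.paleo_sdm <- function(x, type = c("surface", "map"),
                           variable = x$vars[1], cube = NULL, slice = NULL,
                           ...) {
  type <- match.arg(type)
  if (type == "surface") {
    plot(smooth_surface(x$ensemble$members, variable), ...)
  } else {
    if (is.null(cube) || is.null(slice))
      stop2("type = 'map' needs cube and slice")
    plot(project_slice(x$ensemble, cube, slice), ...)
  }
  invisible(x)
}

#' Project a fitted model to binary range maps per climatic period
#'
#' Projects the best ensemble onto every slice of the cube, derives the
#' minimum-predicted-area threshold from the training presences (one
#' threshold per species, pooled across slices), binarizes, and averages
#' the binary maps within the four climatic periods.
#'
#' @param object A `paleo_sdm`.
#' @param cube The [climate_cube].
#' @param coverage MPA presence coverage (default 0.99).
#' @return List: `maps` (per-slice suitability), `threshold`, `binary`,
#'   `periods` (a `period_summary`).
#' @export
project_ensemble <- function(object, cube, coverage = 0.99) {
  maps <- lapply(cube$times, function(t)
    project_slice(object$ensemble, cube, t))
  pred_pres <- predict(object$ensemble, object$eval_presence)
  thr <- mpa_threshold(pred_pres, coverage)
  binary <- binarize_maps(maps, thr)
  list(maps = maps, threshold = thr, binary = binary,
       periods = period_average(binary, cube))
}

## ---- config-driven pipeline ------------------------------------------

validate_run_config <- function(config) {
  errs <- character(0)
  need <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  need(!is.null(config$output_dir), "output_dir is required")
  need(!is.null(config$seed) && is.numeric(config$seed),
       "a numeric seed is mandatory")
  has_scenario <- !is.null(config$scenario)
  has_paths <- !is.null(config$climate_cube) && !is.null(config$occurrences)
  need(has_scenario || has_paths,
       "either a scenario or climate_cube + occurrences paths are required")
  chk01 <- function(name, lo = 0, hi = 1) {
    v <- config[[name]]
    if (!is.null(v) && (!is.numeric(v) || v <= lo || v > hi))
      errs <<- c(errs, paste0(name, " must be in (", lo, ", ", hi, "]"))
  }
  chk01("bci_threshold"); chk01("mpa_coverage")
  chk01("correlation_threshold"); chk01("concurvity_threshold")
  if (!is.null(config$n_rep) && config$n_rep < 1)
    errs <- c(errs, "n_rep must be >= 1")
  if (!is.null(config$ratio) && config$ratio < 1)
    errs <- c(errs, "ratio must be >= 1")
  if (length(errs))
    stop2("invalid run config:\n  - ", paste(errs, collapse = "\n  - "))
  invisible(TRUE)
}

#' Run the full pipeline from a configuration
#'
#' Orchestrates simulate/load -> collapse -> background -> fit -> evaluate
#' -> ensemble -> project from a single config (a list or a YAML file) and
#' writes every stage output plus a JSON manifest (package version, seeds,
#' per-stage timings, MD5 hashes of all written files) under
#' `output_dir`. Reruns with the same config and seed produce identical
#' hashes.
#'
#' Config fields: `output_dir`, `seed` (mandatory); either `scenario`
#' ("default", "shift", or a [scenario_config] list) or paths
#' `climate_cube` + `occurrences`; optional `window`, `region`, `n_rep`,
#' `ratio`, `k_time`, `gamma`, `bci_threshold`, `mpa_coverage`,
#' `importance`, `diagnostics`, `verbose`.
#'
#' @param config List or path to a YAML file.
#' @return The manifest (invisibly also written as JSON).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out_files <- character(0)
  timings <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- tryCatch(expr, error = function(e)
      stop2("stage '", stage, "' failed: ", conditionMessage(e)))
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    v
  }
  seed <- as.integer(config$seed)

  ## stage: data
  dat <- tick("data", {
    if (!is.null(config$scenario)) {
      sc <- config$scenario
      cfg <- if (identical(sc, "default")) scenario_config(seed = seed)
      else if (identical(sc, "shift")) scenario_config_shift(seed = seed)
      else do.call(scenario_config, sc)
      simulate_scenario(cfg, file.path(config$output_dir, "data"),
                        occ_seed = seed + 1)
    } else {
      list(cube = read_climate_cube(config$climate_cube),
           occurrences = utils::read.csv(config$occurrences))
    }
  })
  if (!is.null(config$scenario))
    out_files <- c(out_files,
                   file.path(config$output_dir, "data",
                             c("occurrences.csv", "truth.json")),
                   file.path(config$output_dir, "data", "climate_cube",
                             c("meta.json", "data.csv")))

  ## stage: fit + evaluate
  model <- tick("fit", paleo_sdm(
    dat$occurrences, dat$cube,
    window = config$window %||% c(7500, 47000),
    region = config$region, n_rep = config$n_rep %||% 25,
    ratio = config$ratio %||% 50, k_time = config$k_time %||% 5,
    gamma = config$gamma %||% 1.4,
    bci_threshold = config$bci_threshold %||% 0.8, seed = seed,
    importance = isTRUE(config$importance),
    diagnostics = isTRUE(config$diagnostics),
    verbose = isTRUE(config$verbose)))

  wr <- function(x, name) {
    p <- file.path(config$output_dir, name)
    utils::write.csv(x, p, row.names = FALSE)
    out_files <<- c(out_files, p)
    p
  }
  tick("write_tables", {
    wr(model$occurrences, "collapsed.csv")
    wr(model$comparison$table, "model_comparison.csv")
    wr(data.frame(rep = seq_along(model$bci_values),
                  bci = model$bci_values,
                  accepted = model$bci_values >
                    model$config$bci_threshold), "bci.csv")
    if (!is.null(model$importance)) wr(model$importance, "importance.csv")
    bg_dir <- file.path(config$output_dir, "background")
    write_repetition_set(model$backgrounds, bg_dir)
    out_files <<- c(out_files, list.files(bg_dir, full.names = TRUE))
  })

  ## stage: project
  proj <- tick("project", project_ensemble(model, dat$cube,
                                           config$mpa_coverage %||% 0.99))
  tick("write_maps", {
    g <- dat$cube$grid
    per <- do.call(rbind, lapply(proj$periods$periods, function(p) {
      idx <- which(!is.na(p$mean), arr.ind = TRUE)
      data.frame(period = p$name,
                 lon = cell_centers_lon(g)[idx[, 1]],
                 lat = cell_centers_lat(g)[idx[, 2]],
                 mean_occupancy = p$mean[idx],
                 ice = p$ice_union[idx])
    }))
    wr(per, "period_maps.csv")
    surf <- do.call(rbind, lapply(model$vars, function(v) {
      s <- smooth_surface(model$ensemble$members, v)
      data.frame(variable = v,
                 value = rep(s$value, times = length(s$time_kya)),
                 time_kya = rep(s$time_kya, each = length(s$value)),
                 effect = as.vector(s$effect),
                 near_data = as.vector(s$mask))
    }))
    wr(surf, "interaction_surfaces.csv")
  })

  manifest <- list(
    package = "paleoniche",
    version = as.character(utils::packageVersion("paleoniche")),
    seed = seed,
    background_seeds = model$backgrounds$seeds,
    config = config[setdiff(names(config), "output_dir")],
    n_occurrences = nrow(model$occurrences),
    n_repetitions = model$config$n_rep,
    aic = model$comparison$table[c("rep", "aic_constant", "aic_changing",
                                   "delta_aic", "winner")],
    fraction_changing = model$comparison$fraction_changing,
    bci = model$bci_values,
    ensemble = list(best = model$ensemble$best,
                    bci = model$ensemble$bci[[model$ensemble$best]]$bci,
                    members = model$ensemble$member_reps),
    mpa_threshold = proj$threshold,
    timings = timings,
    hashes = as.list(tools::md5sum(sort(unique(out_files)))))
  names(manifest$hashes) <- basename(sort(unique(out_files)))
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
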