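## Synthetic paleoclimate scenarios: gridded variables with spatial
## gradients, smooth random fields and a glacial temporal signal; a known
## (optionally time-varying) niche; and biased presence sampling from it.

#' Scenario configuration for the synthetic generator
#'
#' Bundles every knob of the synthetic world: grid extent and resolution,
#' the time window (slices follow [paleo_time_axis]), per-variable spatial
#' gradients, smooth-noise amplitude and glacial trend amplitude, the
#' ice-sheet schedule, the sea fraction, the true niche and the sampling
#' design. Defaults describe a European-scale domain at coarse resolution
#' with a Last Glacial Maximum cooling peak at 21 kya, a niche driven by
#' BIO5, BIO6 and BIO12 (NPP and rugosity are inert), and mildly east-biased
#' sampling; pairwise variable correlations stay below the 0.7 screen by
#' construction.
#'
#' @param extent Numeric `c(xmin, xmax, ymin, ymax)` in degrees.
#' @param res Cell size in degrees (> 0).
#' @param window `c(young, old)` years BP; slices are taken from
#'   [paleo_time_axis] within it.
#' @param variables Named list; each element has `baseline`, `grad_lat`,
#'   `grad_lon` (per-degree gradients), `noise_sd` (sd of a smooth random
#'   spatial field) and `trend` (amplitude added times the glacial signal;
#'   negative = glacial cooling/drying).
#' @param glacial `list(peak, width)` of the Gaussian-in-time glacial signal
#'   \eqn{g(t) = \exp(-((t-peak)/width)^2)}, years BP.
#' @param ice `list(lat_max, advance)`: cells with center latitude above
#'   `lat_max - advance * g(t)` are ice-covered.
#' @param sea_frac Fraction of cells made sea (time-constant coastline).
#' @param niche Niche specification passed to [define_niche]; a list with
#'   `curves` and optionally `change_time` + `post_curves`.
#' @param sampling `list(n_per_slice, bias_strength, age_error, species)`.
#' @param seed Integer seed controlling the cube's random fields.
#' @param collinear If TRUE, BIO5 and NPP share the same spatial field and
#'   gradients, producing a correlation above 0.7 (to exercise the screen's
#'   failure path).
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(extent = c(-12.5, 47.5, 35, 65),
                            res = 2.5,
                            window = c(7500, 47000),
                            variables = NULL,
                            glacial = list(peak = 21000, width = 9000),
                            ice = list(lat_max = 64, advance = 10),
                            sea_frac = 0.1,
                            niche = NULL,
                            sampling = list(n_per_slice = 12,
                                            bias_strength = 1,
                                            age_error = 150,
                                            species = "synthetic_species"),
                            seed = 7,
                            collinear = FALSE) {
  if (res <= 0) stop2("resolution must be > 0")
  if (window[1] >= window[2]) stop2("window: young must be < old")
  if ((sampling$n_per_slice %||% 0) < 0) stop2("n_per_slice must be >= 0")
  if (is.null(variables))
    variables <- list(
      BIO5  = list(baseline = 24,  grad_lat = -0.45, grad_lon = 0,
                   noise_sd = 1.5, trend = -6),
      BIO6  = list(baseline = 2,   grad_lat = -0.20, grad_lon = -0.08,
                   noise_sd = 3.5, trend = -10),
      BIO12 = list(baseline = 900, grad_lat = 0,     grad_lon = -6,
                   noise_sd = 150, trend = -150),
      NPP   = list(baseline = 0.9, grad_lat = -0.004, grad_lon = 0.003,
                   noise_sd = 0.2, trend = -0.25),
      rugosity = list(baseline = 0.5, grad_lat = 0, grad_lon = 0,
                      noise_sd = 0.35, trend = 0))
  if (is.null(niche))
    niche <- list(curves = list(BIO5 = list(opt = 18, width = 8),
                                BIO6 = list(opt = -5, width = 8),
                                BIO12 = list(opt = 700, width = 400)))
  structure(list(extent = extent, res = res, window = window,
                 variables = variables, glacial = glacial, ice = ice,
                 sea_frac = sea_frac, niche = niche, sampling = sampling,
                 seed = seed, collinear = collinear),
            class = "scenario_config")
}

#' Default change-point scenario
#'
#' Same world as [scenario_config] but the BIO6 optimum shifts from -20 deg C
#' (before/at `change_time`, i.e. older slices) to -5 deg C afterwards --
#' a strong, detectable niche change.
#'
#' @param change_time Years BP of the niche change (default 16000).
#' @param ... Passed to [scenario_config].
#' @export
scenario_config_shift <- function(change_time = 16000, ...) {
  cfg <- scenario_config(...)
  cfg$niche <- list(
    curves = list(BIO5 = list(opt = 14, width = 10),
                  BIO6 = list(opt = -20, width = 8),
                  BIO12 = list(opt = 700, width = 400)),
    change_time = change_time,
    post_curves = list(BIO5 = list(opt = 18, width = 10),
                       BIO6 = list(opt = -5, width = 8),
                       BIO12 = list(opt = 700, width = 400)))
  cfg
}

## smooth 2D random field on the unit square via a low-order cosine basis,
## standardized to mean 0 / sd 1 over the grid
cosine_field <- function(n_lon, n_lat, order = 3) {
  u <- (seq_len(n_lon) - 0.5) / n_lon
  v <- (seq_len(n_lat) - 0.5) / n_lat
  f <- matrix(0, n_lon, n_lat)
  for (p in 0:order) for (q in 0:order) {
    if (p == 0 && q == 0) next
    amp <- stats::rnorm(1) / (1 + p + q)
    ph1 <- stats::runif(1, 0, 2 * pi)
    ph2 <- stats::runif(1, 0, 2 * pi)
    f <- f + amp * outer(cos(p * pi * u + ph1), cos(q * pi * v + ph2))
  }
  (f - mean(f)) / stats::sd(f)
}

#' Generate a synthetic climate cube
#'
#' Builds the five-variable cube described by a [scenario_config]: each
#' variable is baseline + latitudinal/longitudinal gradient + a smooth
#' random spatial field + a glacial temporal trend; ice follows the
#' configured schedule (largest extent at the glacial peak) and the
#' coastline is a time-constant random smooth field thresholded at the sea
#' fraction. Fully deterministic given `config$seed`.
#'
#' @param config A [scenario_config].
#' @return A [climate_cube].
#' @export
generate_climate_cube <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  g <- list(xmin = config$extent[1], ymin = config$extent[3],
            res = config$res,
            n_lon = as.integer(round((config$extent[2] - config$extent[1]) /
                                       config$res)),
            n_lat = as.integer(round((config$extent[4] - config$extent[3]) /
                                       config$res)))
  if (g$n_lon < 2 || g$n_lat < 2)
    stop2("degenerate grid: need at least 2 cells per axis")
  times <- paleo_time_axis(config$window[1], config$window[2])
  nt <- length(times)
  lons <- cell_centers_lon(g)
  lats <- cell_centers_lat(g)
  lon_m <- matrix(lons, g$n_lon, g$n_lat)
  lat_m <- matrix(lats, g$n_lon, g$n_lat, byrow = TRUE)

  set.seed(config$seed)
  coast <- cosine_field(g$n_lon, g$n_lat)
  fields <- lapply(names(config$variables), function(v)
    cosine_field(g$n_lon, g$n_lat))
  names(fields) <- names(config$variables)
  if (isTRUE(config$collinear)) fields$NPP <- fields$BIO5

  sea <- coast < stats::quantile(coast, config$sea_frac)
  gsig <- exp(-((times - config$glacial$peak) / config$glacial$width)^2)

  dims <- c(g$n_lon, g$n_lat, nt)
  land <- array(rep(!sea, nt), dims)
  ice <- array(FALSE, dims)
  for (it in seq_len(nt)) {
    lim <- config$ice$lat_max - config$ice$advance * gsig[it]
    ice[, , it] <- land[, , it] & (lat_m > lim)
  }

  vars <- list()
  for (v in names(config$variables)) {
    p <- config$variables[[v]]
    spatial <- p$baseline + p$grad_lat * (lat_m - mean(lats)) +
      p$grad_lon * (lon_m - mean(lons)) + p$noise_sd * fields[[v]]
    if (isTRUE(config$collinear) && v == "NPP") {
      pb <- config$variables$BIO5
      spatial <- p$baseline + 0.02 * (pb$grad_lat * (lat_m - mean(lats)) +
                                        pb$noise_sd * fields$BIO5)
    }
    arr <- array(NA_real_, dims)
    for (it in seq_len(nt)) {
      sl <- spatial + p$trend * gsig[it]
      sl[sea] <- NA_real_
      arr[, , it] <- sl
    }
    vars[[v]] <- arr
  }
  climate_cube(g, times, vars, land, ice)
}

#' Define a (possibly time-varying) niche function
#'
#' The niche is a product of per-variable unimodal Gaussian response curves
#' \eqn{\exp(-((x - opt)/width)^2)}, each peaking at 1, so suitability is
#' always in [0, 1]. A change-point niche uses `curves` for slices at or
#' older than `change_time` (time counted in years BP: larger = older) and
#' `post_curves` for younger slices. Curves may also be given as functions
#' of the variable; these are validated to stay within [0, 1] over
#' `ranges` (or a default probe grid).
#'
#' @param curves Named list: per variable either `list(opt, width)` or a
#'   function of the variable value.
#' @param change_time Optional change point, years BP.
#' @param post_curves Curves used for ages younger than `change_time`.
#' @param ranges Optional named list of `c(min, max)` used to validate
#'   function-valued curves.
#' @return A function `f(env, age)` of class `niche_function`, where `env`
#'   is a data frame with the curve variables and `age` is years BP.
#' @export
define_niche <- function(curves, change_time = NULL, post_curves = NULL,
                         ranges = NULL) {
  if (!is.null(change_time) && is.null(post_curves))
    stop2("change_time given without post_curves")
  check_curve <- function(cv, v) {
    if (is.function(cv)) {
      r <- ranges[[v]] %||% c(-1e3, 1e3)
      probe <- cv(seq(r[1], r[2], length.out = 201))
      if (any(!is.finite(probe)) || any(probe < 0) || any(probe > 1))
        stop2("curve for ", v, " yields values outside [0, 1]")
    } else if (is.null(cv$opt) || is.null(cv$width) || cv$width <= 0)
      stop2("curve for ", v, " needs opt and width > 0")
    invisible(NULL)
  }
  for (v in names(curves)) check_curve(curves[[v]], v)
  if (!is.null(post_curves))
    for (v in names(post_curves)) check_curve(post_curves[[v]], v)

  eval_curves <- function(cvs, env) {
    s <- rep(1, nrow(env))
    for (v in names(cvs)) {
      if (!v %in% names(env)) stop2("niche variable ", v, " missing from env")
      cv <- cvs[[v]]
      s <- s * if (is.function(cv)) cv(env[[v]])
      else exp(-((env[[v]] - cv$opt) / cv$width)^2)
    }
    s
  }
  f <- function(env, age) {
    if (!is.data.frame(env)) env <- as.data.frame(env)
    if (length(age) == 1) age <- rep(age, nrow(env))
    if (is.null(change_time)) return(eval_curves(curves, env))
    s <- numeric(nrow(env))
    pre <- age >= change_time
    if (any(pre)) s[pre] <- eval_curves(curves, env[pre, , drop = FALSE])
    if (any(!pre)) s[!pre] <- eval_curves(post_curves, env[!pre, , drop = FALSE])
    s
  }
  structure(f, class = c("niche_function", "function"),
            curves = curves, change_time = change_time,
            post_curves = post_curves)
}

niche_from_spec <- function(spec, ranges = NULL) {
  if (inherits(spec, "niche_function")) return(spec)
  define_niche(spec$curves, spec$change_time, spec$post_curves, ranges)
}

#' Sample presence records from a known niche
#'
#' For each time slice, draws the configured number of presences from the
#' slice's land, ice-free cells with probability proportional to
#' suitability times a geographic sampling-bias intensity (an east-west
#' logistic ramp, mimicking uneven archaeological sampling effort). Records
#' take the cell-center coordinates and an age jittered uniformly within
#' the slice's half-spacing, so nearest-slice assignment round-trips to the
#' generating slice.
#'
#' @param cube A [climate_cube].
#' @param niche A [define_niche] function (or a niche spec list).
#' @param sampling `list(n_per_slice, bias_strength, age_error, species)`;
#'   `n_per_slice` may be a single count or one per slice.
#' @param seed Integer seed.
#' @return Data frame with columns species, longitude, latitude, age_calBP,
#'   age_error (an occurrence table).
#' @export
sample_occurrences <- function(cube, niche, sampling = list(), seed = 1) {
  niche <- niche_from_spec(niche)
  n_per <- sampling$n_per_slice %||% 12
  bias_strength <- sampling$bias_strength %||% 0
  age_error <- sampling$age_error %||% 150
  species <- sampling$species %||% "synthetic_species"
  nt <- length(cube$times)
  n_per <- rep(n_per, length.out = nt)
  if (any(n_per < 0)) stop2("n_per_slice must be >= 0")
  gaps <- slice_gaps(cube$times)
  lon_rng <- range(cell_centers_lon(cube$grid))
  set.seed(seed)
  out <- vector("list", nt)
  for (it in seq_len(nt)) {
    t <- cube$times[it]
    cells <- slice_env_table(cube, t)
    if (nrow(cells) == 0)
      stop2("slice ", t, " has no ice-free land")
    if (n_per[it] == 0) next
    suit <- niche(cells[CLIMATE_VARS[CLIMATE_VARS %in% names(cells)]], t)
    bias <- 1 / (1 + exp(-bias_strength *
                           (cells$lon - mean(lon_rng)) / (diff(lon_rng) / 4)))
    w <- suit * bias
    if (sum(w) <= 0)
      stop2("slice ", t, ": no cell with positive sampling weight")
    pick <- sample.int(nrow(cells), n_per[it], replace = TRUE, prob = w)
    jit <- stats::runif(n_per[it], -gaps$lo[it] / 2, gaps$hi[it] / 2)
    out[[it]] <- data.frame(species = species,
                            longitude = cells$lon[pick],
                            latitude = cells$lat[pick],
                            age_calBP = t + jit,
                            age_error = age_error)
  }
  slices <- rep(cube$times, vapply(out, function(x)
    if (is.null(x)) 0L else nrow(x), integer(1)))
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(species = character(), longitude = numeric(),
                      latitude = numeric(), age_calBP = numeric(),
                      age_error = numeric())
  rownames(out) <- NULL
  attr(out, "slice") <- slices  # generating slice, for round-trip checks
  out
}

#' Write a scenario's outputs to disk
#'
#' Convenience wrapper: generates the cube and occurrences from a
#' [scenario_config] and writes the cube bundle, the occurrence CSV and the
#' truth record (the scenario config as JSON) under `dir`.
#'
#' @param config A [scenario_config].
#' @param dir Output directory.
#' @param occ_seed Seed for occurrence sampling (cube uses `config$seed`).
#' @return Invisibly, a list with the cube and occurrence table.
#' @export
simulate_scenario <- function(config, dir, occ_seed = config$seed + 1) {
  cube <- generate_climate_cube(config)
  occ <- sample_occurrences(cube, config$niche, config$sampling,
                            seed = occ_seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_climate_cube(cube, file.path(dir, "climate_cube"))
  utils::write.csv(occ, file.path(dir, "occurrences.csv"), row.names = FALSE)
  truth <- unclass(config)
  truth$niche$curves <- lapply(truth$niche$curves, unclass)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(cube = cube, occurrences = occ))
}
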