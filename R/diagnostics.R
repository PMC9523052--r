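## Pre-fit and post-fit checks: Pearson correlation screen, concurvity,
## simulation-based quantile-residual tests, and Moran's I on residuals.

#' Pairwise correlation screen
#'
#' Pearson correlations between all pairs of environmental variables; the
#' screen fails if any |r| meets or exceeds the threshold (0.7 by
#' convention in SDM work). Zero-variance variables give NA pairs with a
#' warning.
#'
#' @param env Data frame containing the variables.
#' @param threshold Failure threshold on |r| (default 0.7).
#' @param vars Variables to screen (default: the five climate variables
#'   present in `env`).
#' @return List: correlation `matrix`, `max_abs`, logical `pass`.
#' @export
correlation_screen <- function(env, threshold = 0.7,
                               vars = intersect(CLIMATE_VARS, names(env))) {
  if (nrow(env) < 3) stop2("need at least 3 rows")
  x <- env[vars]
  zero_var <- vapply(x, function(v) stats::sd(v, na.rm = TRUE) == 0,
                     logical(1))
  if (any(zero_var))
    warn2("zero-variance variables: ", paste(vars[zero_var], collapse = ", "))
  suppressWarnings(m <- stats::cor(x, use = "pairwise.complete.obs"))
  off <- abs(m[upper.tri(m)])
  max_abs <- if (all(is.na(off))) NA_real_ else max(off, na.rm = TRUE)
  list(matrix = m, max_abs = max_abs,
       pass = is.na(max_abs) || max_abs < threshold, threshold = threshold)
}

#' Per-term concurvity
#'
#' For each smooth term, the proportion of its fitted component's variance
#' explained by least-squares projection onto the column space of all
#' other terms (including the intercept): the smooth-model analogue of
#' collinearity, in [0, 1].
#'
#' @param x A `paleo_gam` with at least two smooth terms.
#' @return Named numeric vector (one value per smooth term); empty for
#'   single-term models.
#' @export
concurvity_check <- function(x) {
  fit <- x$fit
  if (length(fit$smooth) < 2) return(stats::setNames(numeric(0), character(0)))
  X <- mgcv::predict.gam(fit, type = "lpmatrix")
  beta <- stats::coef(fit)
  w <- fit$prior.weights %||% rep(1, nrow(X))
  out <- vapply(seq_along(fit$smooth), function(i) {
    cols <- fit$smooth[[i]]$first.para:fit$smooth[[i]]$last.para
    g <- as.numeric(X[, cols, drop = FALSE] %*% beta[cols])
    Xo <- X[, -cols, drop = FALSE]
    proj <- stats::lm.wfit(Xo, g, w)$fitted.values
    ss_g <- sum(w * g^2)
    if (ss_g == 0) return(0)
    min(1, max(0, sum(w * proj^2) / ss_g))
  }, numeric(1))
  names(out) <- vapply(fit$smooth, `[[`, character(1), "label")
  out
}

#' Simulation-based residual checks
#'
#' Simulates `n_sim` response vectors from the fitted Bernoulli
#' probabilities and computes, per observation, the randomized quantile of
#' the observed response among the simulations. Reports a
#' Kolmogorov-Smirnov uniformity test on those quantiles, a dispersion
#' test (observed Pearson statistic against its simulated distribution;
#' note that for independent binary data this statistic has essentially no
#' power against marginal misspecification -- it is reported for
#' completeness, as is conventional) and an outlier test (observations
#' outside the simulated range, tested against its exact Bernoulli null
#' probability).
#'
#' @param x A `paleo_gam`.
#' @param data The model table the fit was trained on (one Bernoulli trial
#'   per row); if NULL, the fit's internal (weight-aggregated) rows are
#'   expanded back to trials.
#' @param n_sim Number of simulations (>= 100; default 250).
#' @param seed Optional seed.
#' @return List with `uniformity` (ks statistic + p), `dispersion` (ratio
#'   + p), `outliers` (count + p) and the quantile residuals.
#' @export
residual_checks <- function(x, data = NULL, n_sim = 250, seed = NULL) {
  if (n_sim < 100) stop2("n_sim must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  fit <- x$fit
  if (is.null(data)) {
    w <- round(fit$prior.weights %||% rep(1, length(fit$y)))
    p <- rep(stats::fitted(fit), w)
    y <- rep(fit$y, w)
  } else {
    p <- as.numeric(predict(x, data))
    y <- data$response
  }
  n <- length(y)
  sims <- matrix(stats::rbinom(n * n_sim, 1, rep(p, n_sim)), n, n_sim)
  n_less <- rowSums(sims < y)
  n_eq <- rowSums(sims == y)
  u <- (n_less + stats::runif(n) * (n_eq + 1)) / (n_sim + 1)
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  ## dispersion: Pearson chi-square of observed vs simulations
  w <- 1 / pmax(p * (1 - p), 1e-12)
  s_obs <- sum((y - p)^2 * w)
  s_sim <- colSums((sims - p)^2 * w)
  ratio <- s_obs / mean(s_sim)
  p_disp <- 2 * min((1 + sum(s_sim >= s_obs)) / (n_sim + 1),
                    (1 + sum(s_sim <= s_obs)) / (n_sim + 1))
  ## outliers: observations outside the simulated range; under a correct
  ## model this happens iff all n_sim draws miss the observed value
  out_ct <- sum(y < apply(sims, 1, min) | y > apply(sims, 1, max))
  p_null <- mean(p * (1 - p)^n_sim + (1 - p) * p^n_sim)
  p_out <- stats::binom.test(out_ct, n, p_null)$p.value
  list(uniformity = list(statistic = unname(ks$statistic),
                         p = unname(ks$p.value)),
       dispersion = list(ratio = ratio, p = min(1, p_disp)),
       outliers = list(count = out_ct, p = p_out),
       quantile_residuals = u, n_sim = n_sim)
}

#' Moran's I on model residuals
#'
#' Spatial autocorrelation statistic with inverse great-circle-distance
#' weights restricted to point pairs in the same time slice (zero weight
#' across slices), row-standardized. Significance comes from a one-sided
#' (greater) permutation test shuffling the residual labels. Pairs closer
#' than `min_dist_km` (e.g. duplicated cell centers) are clamped to that
#' distance; pairs beyond `max_dist_km` get zero weight.
#'
#' @param residuals Numeric residual vector.
#' @param lon,lat Coordinates in degrees.
#' @param slice Slice age per point (NULL = one slice).
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional seed.
#' @param min_dist_km,max_dist_km Distance clamps in km.
#' @return List: `I`, `expected` (-1/(n-1)), `p`, permutation mean/sd.
#' @export
morans_i <- function(residuals, lon, lat, slice = NULL, n_perm = 999,
                     seed = NULL, min_dist_km = 1, max_dist_km = Inf) {
  n <- length(residuals)
  if (n < 10) stop2("need at least 10 points")
  if (any(!is.finite(residuals))) stop2("residuals must be finite")
  if (is.null(slice)) slice <- rep(1, n)
  if (!is.null(seed)) set.seed(seed)
  blocks <- split(seq_len(n), slice)
  W <- vector("list", length(blocks))
  rs <- numeric(n)  # row sums before standardization
  any_spread <- FALSE
  for (b in seq_along(blocks)) {
    ii <- blocks[[b]]
    if (length(ii) < 2) { W[b] <- list(NULL); next }
    d <- geosphere::distm(cbind(lon[ii], lat[ii]),
                          fun = geosphere::distHaversine) / 1000
    if (any(d > 0)) any_spread <- TRUE
    w <- 1 / pmax(d, min_dist_km)
    w[d > max_dist_km] <- 0
    diag(w) <- 0
    W[[b]] <- w
    rs[ii] <- rowSums(w)
  }
  if (!any_spread) stop2("all points at identical locations")
  if (all(rs == 0)) stop2("no point pairs within a slice")
  ## row-standardize
  for (b in seq_along(blocks)) {
    ii <- blocks[[b]]
    if (is.null(W[[b]])) next
    nz <- rs[ii] > 0
    W[[b]][nz, ] <- W[[b]][nz, , drop = FALSE] / rs[ii][nz]
  }
  s0 <- sum(vapply(W, function(w) if (is.null(w)) 0 else sum(w), numeric(1)))
  stat <- function(x) {
    xc <- x - mean(x)
    num <- 0
    for (b in seq_along(blocks)) {
      if (is.null(W[[b]])) next
      ii <- blocks[[b]]
      num <- num + sum(xc[ii] * (W[[b]] %*% xc[ii]))
    }
    (n / s0) * num / sum(xc^2)
  }
  I_obs <- stat(residuals)
  I_perm <- vapply(seq_len(n_perm), function(i) stat(sample(residuals)),
                   numeric(1))
  list(I = I_obs, expected = -1 / (n - 1),
       p = (1 + sum(I_perm >= I_obs)) / (n_perm + 1),
       perm_mean = mean(I_perm), perm_sd = stats::sd(I_perm),
       n_perm = n_perm, n = n)
}

#' Full diagnostics report for one repetition fit
#'
#' Runs the correlation screen, concurvity, residual checks and (on a
#' seeded subsample capped at `moran_points` rows) Moran's I, and applies
#' the configured pass rules: correlations < `cor_threshold`, concurvity
#' < `concurvity_threshold`, residual tests non-significant, Moran's I
#' pass if p >= 0.05 or |I| < 0.1.
#'
#' @param x A `paleo_gam`.
#' @param data The repetition's model table (for coordinates and slices).
#' @param cor_threshold,concurvity_threshold Thresholds (defaults 0.7, 0.8).
#' @param n_sim Residual-check simulations.
#' @param moran_points Subsample cap for Moran's I (default 500).
#' @param n_perm Moran permutations (default 199).
#' @param seed Seed for the stochastic checks.
#' @return List of class `diagnostics_report`.
#' @export
diagnose_fit <- function(x, data, cor_threshold = 0.7,
                         concurvity_threshold = 0.8, n_sim = 250,
                         moran_points = 500, n_perm = 199, seed = 1) {
  cors <- correlation_screen(data, threshold = cor_threshold, vars = x$vars)
  conc <- concurvity_check(x)
  res <- residual_checks(x, data, n_sim = n_sim, seed = seed)
  ## Pearson residuals on the expanded table (the fit itself is
  ## weight-aggregated, so per-row residuals come from predictions)
  p <- as.numeric(predict(x, data))
  r <- (data$response - p) / sqrt(pmax(p * (1 - p), 1e-12))
  idx <- seq_along(r)
  if (length(idx) > moran_points) {
    set.seed(seed)
    idx <- sort(sample(idx, moran_points))
  }
  mi <- morans_i(r[idx], data$lon[idx], data$lat[idx], data$time[idx],
                 n_perm = n_perm, seed = seed)
  structure(list(
    correlation = cors,
    concurvity = list(values = conc, threshold = concurvity_threshold,
                      pass = all(conc < concurvity_threshold)),
    residual_tests = res,
    morans_i = c(mi, list(pass = mi$p >= 0.05 || abs(mi$I) < 0.1))),
    class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("Diagnostics report\n")
  cat(sprintf("  max |r| = %.3f (%s)\n", x$correlation$max_abs,
              if (x$correlation$pass) "pass" else "FAIL"))
  if (length(x$concurvity$values))
    cat(sprintf("  max concurvity = %.3f (%s)\n", max(x$concurvity$values),
                if (x$concurvity$pass) "pass" else "FAIL"))
  cat(sprintf("  residual uniformity p = %.3f, dispersion p = %.3f, outliers p = %.3f\n",
              x$residual_tests$uniformity$p, x$residual_tests$dispersion$p,
              x$residual_tests$outliers$p))
  cat(sprintf("  Moran's I = %.4f (p = %.3f, %s)\n", x$morans_i$I,
              x$morans_i$p, if (x$morans_i$pass) "pass" else "FAIL"))
  invisible(x)
}
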