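# Independent oracles and shared fixtures. Oracles are deliberately naive
# (brute force / textbook formulas) and never call the code paths they
# check.

# session-level cache so expensive fixtures are built once per run
.fixture_env <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# small world: 10 x 8 cells, 11 slices (10-20 kya)
tiny_config <- function(...) {
  scenario_config(extent = c(0, 25, 40, 60), res = 2.5,
                  window = c(10000, 20000),
                  sampling = list(n_per_slice = 8, bias_strength = 1,
                                  age_error = 100, species = "sp"),
                  seed = 11, ...)
}
tiny_cube <- function() cached("tiny_cube", generate_climate_cube(tiny_config()))

tiny_occ <- function() cached("tiny_occ", {
  cfg <- tiny_config()
  sample_occurrences(tiny_cube(), cfg$niche, cfg$sampling, seed = 21)
})

# textbook IRLS for logistic regression (design includes intercept)
irls_logistic <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  as.vector(beta)
}

# naive continuous Boyce index: explicit double loop over windows,
# drop empty-availability windows, collapse consecutive duplicate F,
# Spearman against midpoints
boyce_naive <- function(pp, pa, n_windows = 101, wf = 0.1) {
  rng <- range(pa)
  W <- wf * diff(rng)
  lows <- seq(rng[1], rng[2] - W, length.out = n_windows)
  F_out <- mids <- c()
  for (lo in lows) {
    hi <- lo + W
    P <- 0
    for (v in pp) if (v >= lo && v <= hi) P <- P + 1
    E <- 0
    for (v in pa) if (v >= lo && v <= hi) E <- E + 1
    if (E > 0) {
      F_out <- c(F_out, (P / length(pp)) / (E / length(pa)))
      mids <- c(mids, lo + W / 2)
    }
  }
  keep <- c(TRUE, diff(F_out) != 0)
  cor(F_out[keep], mids[keep], method = "spearman")
}

# direct-formula Moran's I with row-standardized inverse-distance
# weights within slice (haversine distance, explicit loops)
moran_naive <- function(x, lon, lat, slice, min_dist_km = 1) {
  n <- length(x)
  hav <- function(i, j) {
    r <- pi / 180
    a <- sin((lat[j] - lat[i]) * r / 2)^2 +
      cos(lat[i] * r) * cos(lat[j] * r) * sin((lon[j] - lon[i]) * r / 2)^2
    2 * 6378137 * asin(sqrt(a)) / 1000
  }
  w <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && slice[i] == slice[j])
      w[i, j] <- 1 / max(hav(i, j), min_dist_km)
  rs <- rowSums(w)
  for (i in seq_len(n)) if (rs[i] > 0) w[i, ] <- w[i, ] / rs[i]
  xc <- x - mean(x)
  (n / sum(w)) * sum(w * outer(xc, xc)) / sum(xc^2)
}

# simulated single-variable presence/background table (no cube involved)
sim_table <- function(n, truth = function(x) 2 - 8 * (x - 0.5)^2,
                      n_slices = 10, seed = 1) {
  set.seed(seed)
  x <- runif(n)
  tt <- sample(seq(8000, 8000 + (n_slices - 1) * 1000, by = 1000), n,
               replace = TRUE)
  eta <- truth(x) - 3
  data.frame(response = rbinom(n, 1, plogis(eta)), BIO5 = x, time = tt,
             lon = runif(n, 0, 10), lat = runif(n, 40, 50),
             true_logit = eta)
}
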