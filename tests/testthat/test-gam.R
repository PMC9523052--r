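test_that("a linear fit reproduces the hand-rolled IRLS logistic solution", {
  set.seed(41)
  n <- 800
  d <- data.frame(BIO5 = rnorm(n), BIO6 = rnorm(n), time = 10000)
  eta <- -2 + 0.8 * d$BIO5 - 0.5 * d$BIO6
  d$response <- rbinom(n, 1, plogis(eta))
  fit <- fit_gam(d, kind = "linear", vars = c("BIO5", "BIO6"))
  beta_hat <- coef(fit)
  beta_oracle <- irls_logistic(cbind(1, d$BIO5, d$BIO6), d$response)
  expect_equal(unname(beta_hat), beta_oracle, tolerance = 1e-6)
  # scores against hand formulas
  p <- plogis(as.vector(cbind(1, d$BIO5, d$BIO6) %*% beta_oracle))
  dev <- -2 * sum(d$response * log(p) + (1 - d$response) * log(1 - p))
  p0 <- mean(d$response)
  dev0 <- -2 * sum(d$response * log(p0) + (1 - d$response) * log(1 - p0))
  s <- fit$scores
  expect_equal(s$deviance, dev, tolerance = 1e-8)
  expect_equal(s$null_deviance, dev0, tolerance = 1e-8)
  expect_equal(s$aic, dev + 2 * 3, tolerance = 1e-6)
  expect_equal(s$dev_expl, 1 - dev / dev0, tolerance = 1e-8)
  expect_equal(s$nagelkerke,
               (1 - exp((dev - dev0) / n)) / (1 - exp(-dev0 / n)),
               tolerance = 1e-8)
})

test_that("intercept-only structure yields prevalence predictions and zero scores", {
  set.seed(42)
  n <- 2040  # prevalence 1/51 as with 50:1 background
  d <- data.frame(response = rep(c(1L, 0L), c(40, 2000)),
                  BIO5 = rnorm(n), time = 10000)
  fit <- fit_gam(d, kind = "constant", vars = "BIO5", k = 6)
  # with no real effect, mean fitted equals prevalence (score equation)
  expect_equal(mean(predict(fit, d)), 40 / 2040, tolerance = 1e-6)
  expect_lt(fit$scores$dev_expl, 0.02)
  expect_lt(fit$scores$nagelkerke, 0.05)
})

test_that("near-separable data drives Nagelkerke R2 toward 1", {
  d <- data.frame(response = rep(c(1L, 0L), each = 100),
                  BIO5 = c(rnorm(100, 5), rnorm(100, -5)), time = 10000)
  fit <- suppressWarnings(fit_gam(d, kind = "linear", vars = "BIO5"))
  expect_gte(fit$scores$nagelkerke, 0.99)
})

test_that("smooth fits recover a quadratic logit and respond monotonically", {
  tab <- sim_table(3000, seed = 43)
  fit <- fit_gam(tab, kind = "constant", vars = "BIO5")
  pred_link <- as.numeric(mgcv::predict.gam(fit$fit,
                                            newdata = tab, type = "link",
                                            newdata.guaranteed = TRUE))
  expect_gt(cor(pred_link, tab$true_logit), 0.98)
  # monotone section of the truth -> monotone predictions
  grid <- data.frame(BIO5 = seq(0.55, 0.95, length.out = 30), time = 10000)
  p <- predict(fit, grid)
  expect_true(all(diff(p) < 0))
})

test_that("deviance is nested and the unpenalized limit matches the linear model", {
  cube <- tiny_cube()
  occ <- collapse_occurrences(tiny_occ(), cube$grid, cube$times)
  bg <- sample_background_repetitions(occ, cube, n_rep = 1, ratio = 10,
                                      seed = 3)
  tab <- build_model_table(occ, bg, cube)[[1]]
  vars <- c("BIO5", "BIO6")
  ## identical fixed smoothing on shared penalty structure:
  ## changing-niche residual deviance <= constant-niche (nested bases)
  f_const <- fit_gam(tab, kind = "constant", vars = vars, k = 5,
                     sp = rep(0, 2))
  f_chang <- fit_gam(tab, kind = "changing", vars = vars, k = 5, k_time = 4,
                     sp = rep(0, 4))
  expect_lte(f_chang$scores$deviance, f_const$scores$deviance + 1e-6)

  ## lambda -> infinity collapses each smooth onto its linear null space
  f_inf <- fit_gam(tab, kind = "constant", vars = vars, k = 5,
                   sp = rep(1e12, 2))
  f_lin <- fit_gam(tab, kind = "linear", vars = vars)
  eta_inf <- as.numeric(mgcv::predict.gam(f_inf$fit, newdata = tab,
                                          type = "link",
                                          newdata.guaranteed = TRUE))
  eta_lin <- as.numeric(mgcv::predict.gam(f_lin$fit, newdata = tab,
                                          type = "link",
                                          newdata.guaranteed = TRUE))
  expect_equal(eta_inf, eta_lin, tolerance = 1e-4)
})

test_that("row order never changes scores", {
  tab <- sim_table(1500, seed = 44)
  f1 <- fit_gam(tab, kind = "changing", vars = "BIO5", k = 8, k_time = 4)
  set.seed(9)
  f2 <- fit_gam(tab[sample(nrow(tab)), ], kind = "changing", vars = "BIO5",
                k = 8, k_time = 4)
  expect_equal(f1$scores$aic, f2$scores$aic, tolerance = 1e-8)
  expect_equal(f1$scores$deviance, f2$scores$deviance, tolerance = 1e-8)
})

test_that("prediction flags extrapolation and errors on missing variables", {
  tab <- sim_table(500, seed = 45)
  fit <- fit_gam(tab, kind = "constant", vars = "BIO5", k = 6)
  p <- predict(fit, data.frame(BIO5 = c(0.5, 5), time = 10000))
  expect_true(all(p > 0 & p < 1))
  expect_identical(attr(p, "extrapolated"), c(FALSE, TRUE))
  expect_error(predict(fit, data.frame(BIO6 = 1)), "missing variable")
})

test_that("basis dimension checking flags saturated smooths and suggests larger k", {
  set.seed(46)
  n <- 2000
  x <- runif(n)
  d <- data.frame(response = rbinom(n, 1, plogis(2 * sin(12 * pi * x))),
                  BIO5 = x, time = 10000)
  low_k <- fit_gam(d, kind = "constant", vars = "BIO5", k = 4)
  rep_low <- check_basis_dimension(low_k)
  expect_true(rep_low$flagged)
  expect_identical(rep_low$k_suggested, pmin(2L * rep_low$k, 10L))
  smooth_truth <- sim_table(2000, seed = 47)
  ok <- fit_gam(smooth_truth, kind = "constant", vars = "BIO5", k = 10)
  expect_false(check_basis_dimension(ok)$flagged)
})

test_that("constant-niche surfaces are flat in time; single-fit mean is the fit itself", {
  tab <- sim_table(1200, seed = 48)
  fit <- fit_gam(tab, kind = "constant", vars = "BIO5", k = 8)
  s <- smooth_surface(fit, "BIO5", n_time = 7, n_value = 15)
  for (j in 2:7) expect_equal(s$effect[, j], s$effect[, 1])
  s2 <- smooth_surface(list(fit), "BIO5", n_time = 7, n_value = 15)
  expect_equal(s2$effect, s$effect)
  expect_error(smooth_surface(fit, "BIO6"), "not in formula")
})

test_that("tensor fits on time-constant truth predict consistently across time", {
  tab <- sim_table(4000, seed = 49)
  fit <- fit_gam(tab, kind = "changing", vars = "BIO5", k = 8, k_time = 4)
  grid_old <- data.frame(BIO5 = seq(0.05, 0.95, length.out = 40),
                         time = 16000)
  grid_new <- transform(grid_old, time = 9000)
  p_old <- predict(fit, grid_old)
  p_new <- predict(fit, grid_new)
  expect_gt(cor(p_old, p_new), 0.7)
})

test_that("basis blocks have the documented dimensions and penalty null spaces", {
  set.seed(50)
  x <- runif(80)
  b <- build_basis(x, k = 6)
  expect_identical(ncol(b$X_unconstrained), 6L)
  expect_identical(ncol(b$X), 5L)
  # constrained block is orthogonal to the intercept
  expect_lt(max(abs(colSums(b$X))), 1e-8)
  # penalty annihilates the coefficient representation of linear functions
  cl <- qr.coef(qr(b$X_unconstrained), 1 + 2 * x)
  expect_lt(abs(t(cl) %*% b$S_unconstrained[[1]] %*% cl), 1e-16)
  # re-evaluation at the training points reproduces the design
  expect_equal(eval_basis(b, x), b$X, ignore_attr = TRUE)
  expect_error(build_basis(rep(1, 20), k = 4), "constant")
  expect_warning(build_basis(rep(1:3, 10), k = 5), "reduced")
})

test_that("tensor blocks have product dimensions and margin-wise penalties", {
  set.seed(51)
  x1 <- runif(60)
  x2 <- runif(60)
  bt <- build_tensor(build_basis(x1, k = 5), build_basis(x2, k = 4))
  expect_identical(ncol(bt$X_unconstrained), 20L)
  expect_identical(ncol(bt$X), 19L)
  expect_length(bt$S, 2)
  # penalties are symmetric PSD
  for (S in bt$S_unconstrained) {
    expect_equal(S, t(S))
    expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
  # a field constant along margin 2 incurs no margin-2 penalty
  b2 <- build_basis(x2, k = 4)
  c2 <- qr.coef(qr(b2$X_unconstrained), rep(1, 60))
  beta <- as.vector(t(outer(rnorm(5), c2)))
  expect_lt(abs(t(beta) %*% bt$S_unconstrained[[2]] %*% beta), 1e-20)
  expect_error(build_tensor(build_basis(runif(10), k = 4),
                            build_basis(runif(12), k = 4)),
               "different row sets")
})
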