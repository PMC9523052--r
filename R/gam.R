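## Binomial presence/background GAMs. The constant-niche model has one
## thin-plate regression spline per environmental variable; the
## changing-niche model replaces each with a tensor-product smooth of the
## variable and time, letting its effect change through time. Fitting is
## penalized likelihood with REML smoothing-parameter selection and an
## extra complexity penalty gamma, via mgcv.

default_k <- function(vars, k = NULL) {
  out <- ifelse(vars == "BIO6", 16L, 10L)
  names(out) <- vars
  if (!is.null(k)) {
    if (is.null(names(k))) out[] <- k else out[names(k)] <- k
  }
  out
}

niche_formula <- function(kind, vars, k, k_time) {
  terms <- switch(kind,
    linear = vars,
    constant = sprintf("s(%s, k = %d, bs = 'tp')", vars, k[vars]),
    changing = sprintf("te(%s, time_kya, k = c(%d, %d), bs = 'tp')",
                       vars, k[vars], k_time),
    stop2("unknown model kind: ", kind))
  stats::as.formula(paste("response ~", paste(terms, collapse = " + ")))
}

#' Fit a presence/background niche GAM
#'
#' Fits the binomial (logit) GAM of one model kind to one repetition's
#' model table. `kind = "constant"` uses one univariate smooth per
#' environmental variable; `kind = "changing"` uses one variable-by-time
#' tensor-product smooth per variable (main effects absorbed in the
#' tensor; no standalone time smooth, since time-matched background keeps
#' per-slice prevalence constant and a pure time effect would be
#' unidentifiable); `kind = "linear"` is a plain logistic regression on
#' the variables (used for oracle checks). Smoothing parameters are
#' selected by REML with complexity multiplier `gamma`, using mgcv's
#' extended Fellner-Schall optimizer by default (the same REML criterion
#' as the default Newton optimizer, several-fold faster on tensor-heavy
#' formulas; switch with `optimizer = "newton"`). Rows with identical
#' response and covariates (frequent, because background cells are drawn
#' with replacement from a finite grid) are aggregated into prior weights
#' before fitting -- the replicated-Bernoulli likelihood, so every score
#' is identical to the row-expanded fit, just cheaper.
#'
#' @param data Model table: columns `response` (0/1), `time` (years BP)
#'   and the environmental variables.
#' @param kind One of "constant", "changing", "linear".
#' @param vars Environmental variables to include (default all five).
#' @param k Basis dimensions; default 16 for BIO6, 10 otherwise. A named
#'   vector overrides per variable, a single number overrides all.
#' @param k_time Basis dimension of the time margin of tensor smooths
#'   (default 5).
#' @param gamma Complexity multiplier on the effective degrees of freedom
#'   in the smoothing criterion (default 1.4).
#' @param method Smoothing selection criterion (default "REML"; "GCV.Cp"
#'   and "ML" are accepted and passed through).
#' @param optimizer Smoothing-parameter optimizer: "efs" (default) or
#'   "newton".
#' @param sp Optional fixed smoothing parameters (passed to mgcv).
#' @return Object of class `paleo_gam`: the mgcv fit plus the model kind,
#'   basis specification, scores (see [model_scores]) and per-variable
#'   training ranges.
#' @export
fit_gam <- function(data, kind = c("changing", "constant", "linear"),
                    vars = CLIMATE_VARS, k = NULL, k_time = 5, gamma = 1.4,
                    method = "REML", optimizer = c("efs", "newton"),
                    sp = NULL) {
  kind <- match.arg(kind)
  optimizer <- match.arg(optimizer)
  missing_vars <- setdiff(c("response", vars), names(data))
  if (length(missing_vars))
    stop2("missing columns: ", paste(missing_vars, collapse = ", "))
  if (length(unique(data$response)) < 2)
    stop2("data must contain both presences and background")
  if (anyNA(data[vars])) stop2("missing environment values in model table")
  if (kind == "changing") {
    if (!"time" %in% names(data)) stop2("missing columns: time")
    data$time_kya <- data$time / 1000
  }
  kk <- default_k(vars, k)
  form <- niche_formula(kind, vars, kk, k_time)
  n_expanded <- nrow(data)
  key_cols <- c("response", vars, if (kind == "changing") "time_kya")
  key <- do.call(paste, c(data[key_cols], sep = "\r"))
  first <- !duplicated(key)
  w <- as.vector(table(key)[key[first]])
  data <- data[first, , drop = FALSE]
  data$.w <- w
  fit <- if (is.null(sp))
    mgcv::gam(form, family = stats::binomial(), data = data,
              weights = .w, method = method, gamma = gamma,
              optimizer = if (optimizer == "efs") "efs"
                          else c("outer", "newton"))
  else
    mgcv::gam(form, family = stats::binomial(), data = data,
              weights = .w, gamma = gamma, sp = sp)
  if (!isTRUE(fit$converged))
    warn2("smoothing-parameter optimization did not converge")
  tr_vars <- c(vars, if (kind == "changing") "time_kya")
  train_range <- lapply(data[tr_vars], range)
  out <- structure(list(fit = fit, kind = kind, vars = vars, k = kk,
                        k_time = k_time, gamma = gamma,
                        optimizer = optimizer,
                        method = method, n = n_expanded,
                        train_range = train_range),
                   class = "paleo_gam")
  out$scores <- model_scores(out)
  out
}

#' Model scores of a fitted niche GAM
#'
#' Returns the log-likelihood (Bernoulli, saturated log-likelihood 0),
#' total effective degrees of freedom (trace of the influence matrix),
#' AIC = -2 loglik + 2 edf, deviance explained
#' = 1 - D_res / D_null, and Nagelkerke R^2
#' = (1 - exp((D_res - D_null)/n)) / (1 - exp(-D_null/n)).
#'
#' @param x A `paleo_gam` (or a fitted mgcv model).
#' @return Named list of scores.
#' @export
model_scores <- function(x) {
  fit <- if (inherits(x, "paleo_gam")) x$fit else x
  d_res <- stats::deviance(fit)
  d_null <- fit$null.deviance
  n <- sum(fit$prior.weights)  # total Bernoulli trials, not grouped rows
  edf <- sum(fit$edf)
  loglik <- -d_res / 2
  dev_expl <- 1 - d_res / d_null
  nagelkerke <- (1 - exp((d_res - d_null) / n)) / (1 - exp(-d_null / n))
  list(loglik = loglik, edf = edf, aic = -2 * loglik + 2 * edf,
       null_deviance = d_null, deviance = d_res,
       dev_expl = dev_expl, nagelkerke = nagelkerke, n = n)
}

#' @export
print.paleo_gam <- function(x, ...) {
  s <- x$scores
  cat("Niche GAM (", x$kind, " niche), n = ", x$n, "\n", sep = "")
  cat(sprintf("  AIC %.2f | deviance explained %.3f | Nagelkerke R2 %.3f | edf %.1f\n",
              s$aic, s$dev_expl, s$nagelkerke, s$edf))
  invisible(x)
}

#' @export
AIC.paleo_gam <- function(object, ..., k = 2) object$scores$aic

#' @export
logLik.paleo_gam <- function(object, ...) {
  structure(object$scores$loglik, df = object$scores$edf, class = "logLik")
}

#' @export
coef.paleo_gam <- function(object, ...) stats::coef(object$fit)

#' Predict occurrence probabilities
#'
#' Deterministic response-scale predictions. Rows where any variable lies
#' more than 5% of its training range beyond the training minimum/maximum
#' are flagged as extrapolated in the `extrapolated` attribute (prediction
#' still returned).
#'
#' @param object A `paleo_gam`.
#' @param newdata Data frame with the model variables (and `time` for
#'   changing-niche fits).
#' @param type Passed to mgcv (default "response").
#' @param ... Unused.
#' @return Numeric vector of probabilities with attribute `extrapolated`.
#' @export
predict.paleo_gam <- function(object, newdata, type = "response", ...) {
  if (missing(newdata))
    return(stats::fitted(object$fit))
  if (object$kind == "changing" && !"time_kya" %in% names(newdata)) {
    if (!"time" %in% names(newdata)) stop2("missing variable: time")
    newdata$time_kya <- newdata$time / 1000
  }
  miss <- setdiff(object$vars, names(newdata))
  if (length(miss)) stop2("missing variable: ", paste(miss, collapse = ", "))
  extrap <- rep(FALSE, nrow(newdata))
  for (v in names(object$train_range)) {
    r <- object$train_range[[v]]
    tol <- 0.05 * diff(r)
    extrap <- extrap | newdata[[v]] < r[1] - tol | newdata[[v]] > r[2] + tol
  }
  p <- as.numeric(mgcv::predict.gam(object$fit, newdata = newdata,
                                    type = type, newdata.guaranteed = TRUE))
  attr(p, "extrapolated") <- extrap
  p
}

#' @export
residuals.paleo_gam <- function(object, type = c("deviance", "pearson",
                                                 "quantile"), ...) {
  type <- match.arg(type)
  if (type != "quantile") return(stats::residuals(object$fit, type = type))
  p <- stats::fitted(object$fit)
  y <- object$fit$y
  ## randomized quantile residuals for Bernoulli: U(F(y-), F(y))
  u <- stats::runif(length(y), stats::pbinom(y - 1, 1, p),
                    stats::pbinom(y, 1, p))
  stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
}

#' @export
simulate.paleo_gam <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- stats::fitted(object$fit)
  out <- as.data.frame(matrix(stats::rbinom(length(p) * nsim, 1, p),
                              ncol = nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Check basis dimensions against estimated degrees of freedom
#'
#' Flags smooth terms whose effective degrees of freedom approach their
#' basis size (edf > k' - margin, where k' is the number of coefficients of
#' the term), suggesting a doubled basis dimension capped at the configured
#' maxima (16 for BIO6, 10 otherwise, per margin).
#'
#' @param x A `paleo_gam`.
#' @param margin Slack below k' (default 0.5).
#' @param k_cap Named caps for suggested k (default `c(BIO6 = 16)` with 10
#'   otherwise).
#' @return Data frame: term, k (basis size), k' (coefficients), edf, flag,
#'   suggested k.
#' @export
check_basis_dimension <- function(x, margin = 0.5, k_cap = NULL) {
  fit <- x$fit
  caps <- default_k(x$vars, k_cap)
  rows <- lapply(seq_along(fit$smooth), function(i) {
    sm <- fit$smooth[[i]]
    cols <- sm$first.para:sm$last.para
    edf <- sum(fit$edf[cols])
    kprime <- length(cols)
    v <- sm$term[1]
    cap <- if (v %in% names(caps)) caps[[v]] else 10L
    kdim <- if (!is.null(sm$margin)) sm$margin[[1]]$bs.dim else sm$bs.dim
    flagged <- edf > kprime - margin
    data.frame(term = sm$label, k = kdim, k_coef = kprime, edf = edf,
               flagged = flagged,
               k_suggested = if (flagged) min(2L * kdim, cap) else kdim)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract the environment-by-time effect surface of a smooth
#'
#' Evaluates the centered partial effect (link scale) of one variable's
#' smooth term on a regular (time x value) grid, averaged pointwise across
#' a list of fitted repetitions. Constant-niche fits yield surfaces that
#' are constant along the time axis. Grid nodes farther than `mask_frac`
#' of each axis range from every training datum are masked.
#'
#' Because the changing-niche tensors absorb their variable's main effect
#' and each tensor also carries an arbitrary share of the (by design
#' unidentifiable) pure time effect, `center = "global"` (one overall
#' mean, the conventional partial-effect display) can shift whole time
#' columns up or down. `center = "by_time"` subtracts each time column's
#' mean over unmasked nodes, isolating the value-by-time interaction --
#' the right scale for asking when a preference changed sign.
#'
#' @param fits A `paleo_gam` or list of them sharing the same formula.
#' @param variable Variable whose surface to extract.
#' @param n_time,n_value Grid resolution (default 50 x 50).
#' @param mask_frac Masking distance as a fraction of each axis range
#'   (default 0.1); `Inf` disables masking.
#' @param center "global" (default) or "by_time" (see Details).
#' @return Object of class `interaction_surface`: value grid, time grid
#'   (kya), `n_value x n_time` effect matrix, logical mask (TRUE = near
#'   data), number of member fits.
#' @export
smooth_surface <- function(fits, variable, n_time = 50, n_value = 50,
                           mask_frac = 0.1,
                           center = c("global", "by_time")) {
  center <- match.arg(center)
  if (inherits(fits, "paleo_gam")) fits <- list(fits)
  f1 <- fits[[1]]
  if (!variable %in% f1$vars) stop2("variable ", variable, " not in formula")
  if (!all(vapply(fits, function(f) identical(f$kind, f1$kind), logical(1))))
    stop2("all fits must share the same model kind")
  v_rng <- range(unlist(lapply(fits, function(f) f$train_range[[variable]])))
  t_rng <- if (f1$kind == "changing")
    range(unlist(lapply(fits, function(f) f$train_range$time_kya)))
  else c(7.5, 47)
  v_grid <- seq(v_rng[1], v_rng[2], length.out = n_value)
  t_grid <- seq(t_rng[1], t_rng[2], length.out = n_time)
  nd <- expand.grid(value = v_grid, time_kya = t_grid)
  names(nd)[1] <- variable
  ## other covariates at training means (irrelevant for term prediction)
  for (v in setdiff(f1$vars, variable)) nd[[v]] <- 0
  surf <- matrix(0, n_value, n_time)
  for (f in fits) {
    label <- if (f$kind == "changing")
      sprintf("te(%s,time_kya)", variable) else sprintf("s(%s)", variable)
    tm <- mgcv::predict.gam(f$fit, newdata = nd, type = "terms",
                            terms = label, newdata.guaranteed = TRUE)
    eff <- matrix(as.numeric(tm), n_value, n_time)
    surf <- surf + (eff - mean(eff)) / length(fits)
  }
  ## mask nodes far from any training (value, time) datum
  mask <- matrix(TRUE, n_value, n_time)
  if (is.finite(mask_frac)) {
    tr <- do.call(rbind, lapply(fits, function(f) {
      m <- f$fit$model
      data.frame(v = m[[variable]],
                 t = if (f1$kind == "changing") m$time_kya else NA_real_)
    }))
    v_tol <- mask_frac * diff(v_rng)
    if (f1$kind == "changing") {
      t_tol <- mask_frac * diff(t_rng)
      for (j in seq_len(n_time)) {
        near_t <- tr$v[abs(tr$t - t_grid[j]) <= t_tol]
        mask[, j] <- vapply(v_grid, function(vv)
          any(abs(near_t - vv) <= v_tol), logical(1))
      }
    } else {
      near <- vapply(v_grid, function(vv) any(abs(tr$v - vv) <= v_tol),
                     logical(1))
      mask[] <- near
    }
  }
  if (center == "by_time") {
    tmp <- surf
    tmp[!mask] <- NA
    surf <- sweep(surf, 2, colMeans(tmp, na.rm = TRUE))
  }
  structure(list(variable = variable, value = v_grid, time_kya = t_grid,
                 effect = surf, mask = mask, center = center,
                 n_members = length(fits)),
            class = "interaction_surface")
}

#' @export
print.interaction_surface <- function(x, ...) {
  cat("Interaction surface for", x$variable, "(mean of", x$n_members,
      "fits):", length(x$value), "x", length(x$time_kya), "grid\n")
  invisible(x)
}

#' @param x An `interaction_surface`.
#' @param ... Passed to [graphics::image].
#' @rdname smooth_surface
#' @export
plot.interaction_surface <- function(x, ...) {
  eff <- x$effect
  eff[!x$mask] <- NA
  lim <- max(abs(eff), na.rm = TRUE)
  pal <- grDevices::colorRampPalette(c("#2166ac", "white", "#b2182b"))(64)
  graphics::image(x$time_kya, x$value, t(eff), zlim = c(-lim, lim),
                  col = pal, xlab = "time (kya BP)", ylab = x$variable,
                  xlim = rev(range(x$time_kya)), ...)
  graphics::contour(x$time_kya, x$value, t(eff), add = TRUE, lwd = 0.5)
  invisible(x)
}
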