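## Model selection across repetitions, the continuous Boyce index,
## deviance-partition variable importance, and ensemble construction.

#' Compare constant- and changing-niche fits across repetitions
#'
#' Per repetition: AIC of each model, delta AIC = AIC(constant) -
#' AIC(changing) (positive favors the changing-niche model), the winner
#' (argmin AIC; delta of exactly zero is a tie), and a "supported" column
#' that declares the winner better supported only when |delta AIC| > 2.
#' Nagelkerke R^2 and deviance explained are reported side by side.
#'
#' @param fits_constant,fits_changing Paired lists of `paleo_gam` fits
#'   (same length, same repetition order).
#' @return Object of class `model_comparison`: per-repetition data frame
#'   plus the fraction of repetitions favoring the changing-niche model
#'   (`fraction_changing`, argmin AIC) and the fraction supporting it
#'   beyond the 2-unit margin (`fraction_supported`).
#' @export
select_model <- function(fits_constant, fits_changing) {
  if (length(fits_constant) != length(fits_changing))
    stop2("unpaired repetitions: ", length(fits_constant), " constant vs ",
          length(fits_changing), " changing fits")
  rows <- lapply(seq_along(fits_constant), function(r) {
    sc <- fits_constant[[r]]$scores
    sh <- fits_changing[[r]]$scores
    delta <- sc$aic - sh$aic
    data.frame(rep = r, aic_constant = sc$aic, aic_changing = sh$aic,
               delta_aic = delta,
               winner = if (delta > 0) "changing"
                        else if (delta < 0) "constant" else "tie",
               supported = abs(delta) > 2,
               dev_expl_constant = sc$dev_expl, dev_expl_changing = sh$dev_expl,
               nagelkerke_constant = sc$nagelkerke,
               nagelkerke_changing = sh$nagelkerke)
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab,
                 fraction_changing = mean(tab$winner == "changing"),
                 fraction_supported = mean(tab$delta_aic > 2)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison over", nrow(x$table), "repetitions:",
      sprintf("changing niche favored in %.0f%%", 100 * x$fraction_changing),
      "\n")
  cat(sprintf("  mean delta AIC (constant - changing) = %.1f\n",
              mean(x$table$delta_aic)))
  invisible(x)
}

#' Continuous Boyce index
#'
#' Presence-only evaluation: `n_windows` overlapping windows of width
#' `window_fraction` of the available-prediction range slide over that
#' range; per window, F = (share of presence predictions inside) / (share
#' of available predictions inside), windows with zero available share are
#' dropped, runs of consecutive identical F values are collapsed to one,
#' and the index is the Spearman rank correlation between F and the window
#' midpoints. 1 means suitability ranks presences perfectly; 0 is random.
#'
#' @param pred_presence Predicted probabilities at presences.
#' @param pred_available Predicted probabilities over the evaluation
#'   (available) cells.
#' @param n_windows Number of windows (default 101).
#' @param window_fraction Window width as a fraction of the available
#'   range (default 0.1).
#' @param rm_duplicate Collapse consecutive duplicate F values (default
#'   TRUE, the standard continuous formulation).
#' @param threshold Acceptance threshold recorded in the result (default
#'   0.8).
#' @return Object of class `boyce_result`: midpoints, P, E, F, `bci`,
#'   logical `pass`.
#' @export
boyce_index <- function(pred_presence, pred_available, n_windows = 101,
                        window_fraction = 0.1, rm_duplicate = TRUE,
                        threshold = 0.8) {
  if (!length(pred_presence) || !length(pred_available))
    stop2("empty prediction vector")
  if (any(pred_presence < 0 | pred_presence > 1) ||
      any(pred_available < 0 | pred_available > 1))
    stop2("predictions must be in [0, 1]")
  rng <- range(pred_available)
  if (diff(rng) == 0)
    stop2("all available predictions identical: Boyce index undefined")
  width <- window_fraction * diff(rng)
  lows <- seq(rng[1], rng[2] - width, length.out = n_windows)
  mids <- lows + width / 2
  P <- E <- numeric(n_windows)
  for (i in seq_len(n_windows)) {
    hi <- lows[i] + width
    P[i] <- mean(pred_presence >= lows[i] & pred_presence <= hi)
    E[i] <- mean(pred_available >= lows[i] & pred_available <= hi)
  }
  keep <- E > 0
  F_ratio <- P[keep] / E[keep]
  mids_k <- mids[keep]
  if (rm_duplicate && length(F_ratio) > 1) {
    dup <- c(FALSE, diff(F_ratio) == 0)
    F_ratio <- F_ratio[!dup]
    mids_k <- mids_k[!dup]
  }
  bci <- if (length(F_ratio) < 2 || stats::sd(F_ratio) == 0) 0
  else suppressWarnings(stats::cor(F_ratio, mids_k, method = "spearman"))
  structure(list(midpoints = mids_k, F = F_ratio,
                 P = P[keep], E = E[keep], bci = bci,
                 threshold = threshold, pass = bci > threshold),
            class = "boyce_result")
}

#' @export
print.boyce_result <- function(x, ...) {
  cat(sprintf("Continuous Boyce index: %.3f (%s at threshold %.2f)\n",
              x$bci, if (x$pass) "accepted" else "rejected", x$threshold))
  invisible(x)
}

#' Deviance-partition variable importance
#'
#' Two complementary measures per variable, averaged across the supplied
#' (BCI-accepted) repetitions: *total* deviance explained is the deviance
#' explained of a model containing only that variable (keeping its time
#' tensor under the changing-niche kind, so constant/changing comparisons
#' stay aligned); *unique* deviance explained is the full model's deviance
#' explained minus that of the model dropping the variable. Their
#' difference is the share the variable has in common with the others.
#'
#' @param tables List of model tables (accepted repetitions only), or one
#'   table.
#' @param vars Variables (default the five climate variables).
#' @param kind Model kind (default "changing").
#' @param full_fits Optional precomputed full fits (one per table) to
#'   avoid refitting.
#' @param ... Passed to [fit_gam] (k, gamma, optimizer, ...).
#' @return Data frame of class `importance_table`: variable, total,
#'   unique, shared.
#' @export
variable_importance <- function(tables, vars = CLIMATE_VARS,
                                kind = "changing", full_fits = NULL, ...) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (!length(tables)) stop2("no accepted repetitions supplied")
  acc <- matrix(0, length(vars), 2,
                dimnames = list(vars, c("total", "unique")))
  for (i in seq_along(tables)) {
    tab <- tables[[i]]
    full <- if (!is.null(full_fits)) full_fits[[i]]
    else fit_gam(tab, kind = kind, vars = vars, ...)
    de_full <- full$scores$dev_expl
    for (v in vars) {
      single <- fit_gam(tab, kind = kind, vars = v, ...)
      drop1 <- fit_gam(tab, kind = kind, vars = setdiff(vars, v), ...)
      acc[v, "total"] <- acc[v, "total"] + single$scores$dev_expl
      acc[v, "unique"] <- acc[v, "unique"] + (de_full - drop1$scores$dev_expl)
    }
  }
  acc <- acc / length(tables)
  out <- data.frame(variable = vars, total = acc[, "total"],
                    unique = acc[, "unique"],
                    shared = acc[, "total"] - acc[, "unique"])
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Build mean/median ensembles of accepted fits
#'
#' Keeps the fits whose Boyce index exceeds the threshold, aggregates
#' their predicted probabilities pointwise by mean and by median, scores
#' both ensembles with the Boyce index on the evaluation data, and flags
#' the higher-scoring one as best (ties go to the mean).
#'
#' @param fits List of `paleo_gam` fits (one per repetition).
#' @param bci Numeric vector of per-fit Boyce indices (same length).
#' @param eval_presence,eval_available Environment tables (with `time`)
#'   for presences and available cells, used to score the ensembles.
#' @param threshold Acceptance threshold (default 0.8).
#' @param n_windows,window_fraction Passed to [boyce_index].
#' @return Object of class `paleo_ensemble`.
#' @export
build_ensemble <- function(fits, bci, eval_presence, eval_available,
                           threshold = 0.8, n_windows = 101,
                           window_fraction = 0.1) {
  if (length(fits) != length(bci)) stop2("one BCI per fit required")
  keep <- which(bci > threshold)
  if (!length(keep))
    stop2("no fits above the BCI threshold ", threshold, "; per-repetition",
          " BCI: ", paste(sprintf("%.2f", bci), collapse = ", "))
  members <- fits[keep]
  pp <- vapply(members, function(f) predict(f, eval_presence),
               numeric(nrow(eval_presence)))
  pa <- vapply(members, function(f) predict(f, eval_available),
               numeric(nrow(eval_available)))
  score <- function(fun) {
    boyce_index(apply(pp, 1, fun), apply(pa, 1, fun),
                n_windows = n_windows, window_fraction = window_fraction,
                threshold = threshold)
  }
  b_mean <- score(mean)
  b_median <- score(stats::median)
  best <- if (b_median$bci > b_mean$bci) "median" else "mean"
  structure(list(members = members, member_reps = keep, member_bci = bci[keep],
                 bci = list(mean = b_mean, median = b_median),
                 best = best, threshold = threshold),
            class = "paleo_ensemble")
}

#' @export
print.paleo_ensemble <- function(x, ...) {
  cat("Ensemble of", length(x$members), "accepted fits (BCI >",
      x$threshold, ")\n")
  cat(sprintf("  mean-ensemble BCI %.3f | median-ensemble BCI %.3f | best: %s\n",
              x$bci$mean$bci, x$bci$median$bci, x$best))
  invisible(x)
}

#' Predict from an ensemble
#'
#' Pointwise aggregation (by the ensemble's best method unless overridden)
#' of the member fits' predicted probabilities.
#'
#' @param object A `paleo_ensemble`.
#' @param newdata Environment table with `time`.
#' @param method "mean" or "median" (default: the ensemble's best).
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.paleo_ensemble <- function(object, newdata,
                                   method = object$best, ...) {
  fun <- if (method == "median") stats::median else mean
  pm <- vapply(object$members, function(f) predict(f, newdata),
               numeric(nrow(newdata)))
  if (nrow(newdata) == 1) pm <- matrix(pm, nrow = 1)
  apply(pm, 1, fun)
}
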