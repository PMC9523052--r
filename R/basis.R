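## Spline basis building blocks. These expose the ingredients the niche
## GAMs are made of -- penalized low-rank smooths and their tensor
## products -- for inspection and testing; model fitting itself goes
## through fit_gam().

#' Build a univariate penalized spline basis
#'
#' Thin-plate regression spline basis (the default family used by the
#' niche models) for one covariate: `k` columns before identifiability
#' constraints, `k - 1` after absorbing the sum-to-zero constraint. The
#' penalty is positive semi-definite with constant and linear functions in
#' its null space.
#'
#' @param x Numeric covariate vector (>= k distinct values; fewer reduces
#'   k with a warning; a constant is an error).
#' @param k Basis dimension (>= 3).
#' @param bs Basis family passed to mgcv (default "tp").
#' @return Object of class `basis_block`: `X` (constrained design, k-1
#'   columns), `X_unconstrained` (k columns), penalty list `S` (on the
#'   constrained parameterization), `S_unconstrained`, `k`, and the mgcv
#'   smooth object for re-evaluation.
#' @export
build_basis <- function(x, k = 10, bs = "tp") {
  if (k < 3) stop2("k must be >= 3")
  n_distinct <- length(unique(x))
  if (n_distinct < 2) stop2("constant covariate: no basis can be built")
  if (n_distinct < k) {
    warn2("only ", n_distinct, " distinct values; k reduced from ", k)
    k <- n_distinct
  }
  dat <- data.frame(x = x)
  sm_u <- mgcv::smoothCon(mgcv::s(x, k = k, bs = bs), data = dat,
                          absorb.cons = FALSE)[[1]]
  sm_c <- mgcv::smoothCon(mgcv::s(x, k = k, bs = bs), data = dat,
                          absorb.cons = TRUE)[[1]]
  structure(list(X = sm_c$X, X_unconstrained = sm_u$X,
                 S = sm_c$S, S_unconstrained = sm_u$S,
                 k = k, smooth = sm_c, smooth_unconstrained = sm_u),
            class = "basis_block")
}

#' Evaluate a basis at new covariate values
#'
#' Re-evaluating at the training values reproduces the training design
#' rows exactly.
#'
#' @param block A `basis_block`.
#' @param x New covariate values.
#' @param constrained Use the constrained parameterization (default TRUE).
#' @return Design matrix rows for `x`.
#' @export
eval_basis <- function(block, x, constrained = TRUE) {
  sm <- if (constrained) block$smooth else block$smooth_unconstrained
  mgcv::PredictMat(sm, data.frame(x = x))
}

#' Build a tensor-product interaction basis from two margins
#'
#' Row-wise Kronecker product of the margins' unconstrained designs
#' (`k1 * k2` columns), with one penalty per margin (each margin's
#' wiggliness penalized separately: `S1 x I` and `I x S2`), then a
#' sum-to-zero constraint against the intercept. Coefficient fields that
#' are constant along one margin incur zero penalty from that margin.
#'
#' @param block1,block2 `basis_block`s built on the same rows.
#' @return Object of class `tensor_block`: constrained design `X`, penalty
#'   list `S` (two matrices), unconstrained design and penalties, margin
#'   sizes.
#' @export
build_tensor <- function(block1, block2) {
  X1 <- block1$X_unconstrained
  X2 <- block2$X_unconstrained
  if (nrow(X1) != nrow(X2)) stop2("margins built on different row sets")
  k1 <- ncol(X1); k2 <- ncol(X2)
  ## row-wise Kronecker: column order (j2 fastest), matching S1 x I, I x S2
  X <- X1[, rep(seq_len(k1), each = k2), drop = FALSE] *
    X2[, rep(seq_len(k2), times = k1), drop = FALSE]
  S1 <- block1$S_unconstrained[[1]] %x% diag(k2)
  S2 <- diag(k1) %x% block2$S_unconstrained[[1]]
  ## absorb sum-to-zero constraint 1'Xb = 0 via Householder (QR of the
  ## column-mean vector), as mgcv does for tensor identifiability
  cmeans <- colMeans(X)
  qrc <- qr(matrix(cmeans, ncol = 1))
  Xc <- t(qr.qty(qrc, t(X)))[, -1, drop = FALSE]
  constrain <- function(S) {
    tmp <- qr.qty(qrc, t(qr.qty(qrc, t(S))))
    tmp[-1, -1, drop = FALSE]
  }
  structure(list(X = Xc, S = list(constrain(S1), constrain(S2)),
                 X_unconstrained = X, S_unconstrained = list(S1, S2),
                 k = c(k1, k2)),
            class = "tensor_block")
}
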