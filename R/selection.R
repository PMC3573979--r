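#' Residual sum of squares
#'
#' @param y observed response.
#' @param yhat predicted response of equal length.
#' @return `sum((y - yhat)^2)`.
#' @export
rss <- function(y, yhat) {
  if (length(y) != length(yhat))
    stop("y and yhat differ in length (", length(y), " vs ", length(yhat), ")")
  sum((y - yhat)^2)
}

#' Mallows Cp model-selection statistic
#'
#' `Cp = RSS_p / S^2 - M'' + 2p`. Two variants of the residual scale `S` are
#' provided. `form = "printed"` uses `S = RSS_pmax / pmax`, the mean full-model
#' residual sum of squares per coefficient; `form = "classical"` uses the
#' usual residual variance estimate `S^2 = RSS_pmax / (M'' - pmax)`. The
#' printed literature form is unusual (its `S` is squared again in the
#' denominator) and is kept as this function's default for checking published
#' worked values, but [extilar_control()] defaults the fitting pipeline to the
#' classical form; see the methods vignette for the rationale.
#'
#' @param rss_p residual sum of squares of the candidate model.
#' @param p number of nonzero coefficients of the candidate model.
#' @param rss_pmax residual sum of squares of the full model (all `pmax`
#'   columns); must be positive.
#' @param pmax total number of candidate coefficients.
#' @param m number of observations (rows), `M''`.
#' @param form `"printed"` (default) or `"classical"`.
#' @return the Cp value.
#' @examples
#' mallows_cp(2, 2, 1, 4, 10)  # S = 0.25, Cp = 2/0.0625 - 10 + 4 = 26
#' @export
mallows_cp <- function(rss_p, p, rss_pmax, pmax, m,
                       form = c("printed", "classical")) {
  form <- match.arg(form)
  if (pmax <= 0) stop("pmax must be positive")
  if (rss_pmax <= 0)
    stop("Cp is undefined for a zero full-model RSS")
  s2 <- switch(form,
               printed = (rss_pmax / pmax)^2,
               classical = {
                 if (m <= pmax) stop("classical Cp needs m > pmax")
                 rss_pmax / (m - pmax)
               })
  rss_p / s2 - m + 2 * p
}

#' Proposal measure Pm
#'
#' `Pm = alpha * RSS_p / RSS_max + p / pmax`: the weighted, scaled residual
#' sum of squares plus the scaled model size. The model minimizing Pm is
#' preferred; larger `alpha` tolerates more coefficients. `RSS_max` and `pmax`
#' set the common scale of the comparison: within one [extilar_fit()] they are
#' the empty-model residual sum of squares and the column count, and across
#' forward-selection iterations in [extilar()] they are the largest RSS and
#' the largest column budget among the compared proposals.
#'
#' @param rss_p residual sum of squares of the candidate model.
#' @param rss_max reference (empty-model) residual sum of squares, > 0.
#' @param p number of nonzero coefficients.
#' @param pmax total number of candidate coefficients, > 0.
#' @param alpha weight of the fit term, `alpha >= 1`.
#' @return the Pm value.
#' @examples
#' pm_measure(1, 1, 4, 4, alpha = 1)  # both ratios 1 -> 2
#' @export
pm_measure <- function(rss_p, rss_max, p, pmax, alpha = 1) {
  stopifnot(rss_max > 0, pmax > 0, alpha >= 1)
  alpha * rss_p / rss_max + p / pmax
}

#' Select a path model by minimal Cp
#'
#' Scores every knot of a [adaptive_lars()] path with [mallows_cp()] and
#' returns the knot with minimal Cp; ties are broken toward the smaller model.
#' The full-model reference `RSS_pmax` is the unpenalized least-squares fit on
#' all usable columns and `pmax` the total column count. In the degenerate
#' case of a (numerically) perfect full fit, where Cp is undefined, the
#' sparsest knot whose RSS is indistinguishable from zero is returned.
#'
#' @param path a `"lars_path"`.
#' @param m number of observations `M''`; defaults to `length(path$y)`.
#' @param form Cp variant, see [mallows_cp()].
#' @return list with `index` (selected knot), `step` (the knot), `cp`
#'   (vector of Cp values, `NA` for the degenerate case), `rss_pmax`, `pmax`.
#' @export
select_by_cp <- function(path, m = length(path$y),
                         form = c("printed", "classical")) {
  form <- match.arg(form)
  stopifnot(inherits(path, "lars_path"), length(path$steps) >= 1L)
  pmax <- path$n_columns
  usable <- setdiff(seq_len(pmax), path$excluded)
  beta_full <- ols_refit_matrix(path$X, path$y, usable)
  rss_pmax <- rss(path$y, drop(path$X %*% beta_full))
  rss0 <- sum(path$y^2)
  p_k <- vapply(path$steps, `[[`, 0L, "p")
  rss_k <- vapply(path$steps, `[[`, 0, "rss")
  if (rss_pmax <= 1e-12 * max(rss0, 1)) {
    # perfect full fit: pick the sparsest knot that also fits perfectly
    ok <- which(rss_k <= max(1e-10 * max(rss0, 1), rss_pmax))
    idx <- ok[order(p_k[ok])][1L]
    return(list(index = idx, step = path$steps[[idx]], cp = rep(NA_real_, length(p_k)),
                rss_pmax = rss_pmax, pmax = pmax))
  }
  cp <- vapply(seq_along(path$steps), function(k)
    mallows_cp(rss_k[k], p_k[k], rss_pmax, pmax, m, form = form), 0)
  idx <- order(cp, p_k)[1L]
  list(index = idx, step = path$steps[[idx]], cp = cp,
       rss_pmax = rss_pmax, pmax = pmax)
}

#' Unpenalized least-squares refit on an active column set
#'
#' After variable selection along the path, coefficients are re-estimated by
#' ordinary least squares restricted to the active columns; all other
#' coefficients are zero. A rank-deficient active set yields the minimum-norm
#' solution with a warning.
#'
#' @param rp a `regression_problem` (or a design matrix with `y` supplied).
#' @param active integer or character vector of active columns.
#' @param y response when `rp` is a matrix.
#' @return full-length coefficient vector.
#' @export
ols_refit <- function(rp, active, y = NULL) {
  if (inherits(rp, "regression_problem")) {
    X <- rp$X; y <- rp$y
  } else X <- as.matrix(rp)
  if (is.character(active)) active <- match(active, colnames(X))
  ols_refit_matrix(X, y, active)
}

ols_refit_matrix <- function(X, y, active) {
  beta <- numeric(ncol(X))
  names(beta) <- colnames(X)
  active <- as.integer(active)
  if (!length(active)) return(beta)
  Xa <- X[, active, drop = FALSE]
  qx <- qr(Xa)
  if (qx$rank < length(active)) {
    warning("rank-deficient active set (rank ", qx$rank, " < ",
            length(active), "); returning the minimum-norm solution")
    sv <- svd(Xa)
    pos <- sv$d > max(dim(Xa)) * .Machine$double.eps * sv$d[1L]
    coefs <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    beta[active] <- drop(coefs)
  } else {
    beta[active] <- qr.coef(qx, y)
  }
  beta
}
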