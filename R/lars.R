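#' Adaptive LARS/LASSO solution path
#'
#' Computes the full LASSO solution path under the weighted L1 constraint
#' `sum(delta_j * |beta_j|) <= s` by least-angle regression with the LASSO
#' drop modification. The adaptive weighting is realized by the standard
#' reparameterization: column `j` is scaled by `1/delta_j`, the plain LASSO
#' path is computed in `gamma = delta * beta`, and coefficients are rescaled
#' back. Every path knot satisfies the KKT conditions of the weighted LASSO
#' at its penalty level. No intercept and no column standardization: the
#' model has no constant term and responses/predictors share the scaled
#' log2-FC scale.
#'
#' Columns with all-zero entries carry no information and are excluded from
#' the candidate set with a warning (their coefficients remain zero). When
#' two columns reach the maximal absolute correlation simultaneously (to a
#' relative tolerance of 1e-12) the lower column index enters first, so the
#' path is reproducible. The path stops early if the active Gram matrix
#' becomes numerically singular (rank limit).
#'
#' @param x a [build_design()] `regression_problem`, or a numeric design
#'   matrix.
#' @param y response vector (ignored when `x` is a `regression_problem`).
#' @param delta per-column penalty weights in (0, 1]; defaults to the
#'   problem's penalty weights or to 1.
#' @param max_steps safety cap on the number of path steps.
#' @return Object of class `"lars_path"`: list with `steps` (each a list
#'   `active`, `beta`, `s`, `rss`, `p`, `lambda`, `event`), `delta`, `X`, `y`,
#'   `n_columns`. Step 1 is the empty model.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40), 10, 4)
#' y <- X %*% c(2, 0, -1, 0) + rnorm(10, sd = 0.1)
#' path <- adaptive_lars(X, y)
#' vapply(path$steps, `[[`, 0, "rss")  # non-increasing
#' @export
adaptive_lars <- function(x, y = NULL, delta = NULL, max_steps = NULL) {
  if (inherits(x, "regression_problem")) {
    X <- x$X
    if (is.null(delta)) delta <- x$penalty
    y <- x$y
  } else X <- as.matrix(x)
  if (is.null(delta)) delta <- rep(1, ncol(X))
  stopifnot(length(y) == nrow(X), length(delta) == ncol(X),
            all(delta > 0), all(delta <= 1))
  Xs <- sweep(X, 2L, delta, "/")
  raw <- lars_lasso_path(Xs, y, max_steps = max_steps)
  steps <- lapply(raw$steps, function(st) {
    beta <- st$gamma / delta
    list(active = st$active, beta = beta,
         s = sum(delta * abs(beta)),
         rss = st$rss, p = st$p, lambda = st$lambda, event = st$event)
  })
  structure(list(steps = steps, delta = delta, X = X, y = y,
                 n_columns = ncol(X), excluded = raw$excluded),
            class = "lars_path")
}

#' @export
print.lars_path <- function(x, ...) {
  cat(sprintf("LARS/LASSO path: %d knots over %d columns (final p = %d)\n",
              length(x$steps), x$n_columns,
              x$steps[[length(x$steps)]]$p))
  invisible(x)
}

# Plain LARS with the LASSO modification (Efron et al. style), no intercept,
# no standardization. Exactly one active-set change per recorded knot.
lars_lasso_path <- function(X, y, max_steps = NULL, tol = 1e-12) {
  n <- nrow(X); p <- ncol(X)
  if (p < 1L) stop("design matrix has no columns")
  norms2 <- colSums(X^2)
  usable <- norms2 > 0
  excluded <- which(!usable)
  if (length(excluded))
    warning("excluding all-zero column(s): ",
            paste(colnames(X)[excluded] %||% excluded, collapse = ", "))
  if (is.null(max_steps)) max_steps <- 8L * p + 2L

  gamma_hat <- numeric(p)
  active <- integer(0)
  cvec <- drop(crossprod(X, y))
  scale0 <- max(abs(cvec[usable]), 1)
  steps <- list(list(active = integer(0), gamma = gamma_hat,
                     rss = sum(y^2), p = 0L,
                     lambda = max(abs(cvec[usable]), 0), event = "init"))
  just_dropped <- FALSE

  for (step in seq_len(max_steps)) {
    resid <- y - X %*% gamma_hat
    cvec <- drop(crossprod(X, resid))
    inactive <- setdiff(which(usable), active)
    Cmax <- max(abs(cvec[c(active, inactive)]))
    if (Cmax <= tol * scale0) break

    event <- NULL
    if (!just_dropped) {
      if (!length(inactive)) break
      cin <- abs(cvec[inactive])
      cands <- inactive[cin >= max(cin) - tol * scale0]
      # only add if the entrant actually matches the overall max correlation
      if (max(cin) < Cmax - tol * scale0) break  # numerically stuck
      j_new <- min(cands)  # tie-break: lowest column index
      active <- c(active, j_new)
      event <- paste0("add:", j_new)
    }

    sA <- sign(cvec[active])
    sA[sA == 0] <- 1
    G <- crossprod(X[, active, drop = FALSE])
    GA1 <- tryCatch(solve(G, sA), error = function(e) NULL)
    if (is.null(GA1) || sum(GA1 * sA) <= 0) {
      if (!is.null(event)) {
        # the entrant is collinear with the active set: retire it and go on
        j_bad <- active[length(active)]
        active <- active[-length(active)]
        usable[j_bad] <- FALSE
        next
      }
      break  # rank limit reached within the active set
    }
    AA <- 1 / sqrt(sum(GA1 * sA))
    w <- AA * GA1
    u <- X[, active, drop = FALSE] %*% w
    a <- drop(crossprod(X, u))
    Cact <- max(abs(cvec[active]))

    gamma_full <- Cact / AA  # step to the active-set least-squares fit
    gamma_add <- gamma_full
    if (length(setdiff(which(usable), active))) {
      rest <- setdiff(which(usable), active)
      g1 <- (Cact - cvec[rest]) / (AA - a[rest])
      g2 <- (Cact + cvec[rest]) / (AA + a[rest])
      gg <- c(g1, g2)
      gg <- gg[is.finite(gg) & gg > tol * scale0]
      if (length(gg)) gamma_add <- min(gg)
    }
    # LASSO modification: coefficient zero crossings force a drop
    gd <- -gamma_hat[active] / w
    gd[!is.finite(gd) | gd <= tol] <- Inf
    gamma_drop <- min(gd)

    gamma <- min(gamma_add, gamma_drop, gamma_full)
    gamma_hat[active] <- gamma_hat[active] + gamma * w

    if (gamma_drop <= gamma_add && gamma_drop <= gamma_full &&
        is.finite(gamma_drop)) {
      j_out <- active[which.min(gd)]
      gamma_hat[j_out] <- 0
      active <- setdiff(active, j_out)
      just_dropped <- TRUE
      event <- paste0(if (is.null(event)) "" else paste0(event, "+"),
                      "drop:", j_out)
    } else just_dropped <- FALSE

    rss <- sum((y - X %*% gamma_hat)^2)
    lambda <- max(abs(crossprod(X, y - X %*% gamma_hat)))
    steps[[length(steps) + 1L]] <-
      list(active = active, gamma = gamma_hat, rss = rss,
           p = sum(gamma_hat != 0), lambda = lambda, event = event)
    if (!length(active) && just_dropped == FALSE && is.null(event)) break
  }
  list(steps = steps, excluded = excluded)
}
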