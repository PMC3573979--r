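#' @export
print.extilar <- function(x, ...) {
  cat("Dynamic TF-network model (adaptive LARS + Cp/Pm selection)\n")
  if (!is.null(x$call)) cat("Call: ", deparse(x$call), "\n", sep = "")
  d <- x$diagnostics
  cat(sprintf("  %d genes, %d TFs; %d gene-to-TF, %d autoreg, %d input edges\n",
              length(x$genes), length(x$tfs), nrow(x$w_edges),
              sum(x$autoreg != 0), nrow(x$input_edges)))
  cat(sprintf("  RSS = %.5g (null %.5g), p = %d of %d columns, Pm = %.4g\n",
              d$rss, d$rss_null, d$p, d$n_cols, d$pm))
  if (!is.null(x$trace))
    cat(sprintf("  forward selection: %d iteration(s), final model from iteration %d\n",
                nrow(x$trace) - 1L, x$final_iteration))
  invisible(x)
}

#' @export
summary.extilar <- function(object, ...) {
  out <- list(diagnostics = object$diagnostics,
              w_edges = object$w_edges,
              autoreg = object$autoreg[object$autoreg != 0],
              input_edges = object$input_edges,
              trace = object$trace,
              metrics = evaluate_network(object))
  class(out) <- "summary.extilar"
  out
}

#' @export
print.summary.extilar <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("Fit: RSS %.5g | Cp %.4g | Pm %.4g | p = %d/%d\n",
              d$rss, d$cp, d$pm, d$p, d$n_cols))
  m <- x$metrics
  cat(sprintf("Edges: %d gene-to-TF (%d prior-supported), %d autoreg, %d input; precision %.4f\n",
              m$n_gene_to_tf, m$n_prior_supported, m$n_autoreg, m$n_input,
              m$precision))
  if (nrow(x$w_edges)) {
    cat("\nGene-to-TF edges:\n")
    print(x$w_edges, row.names = FALSE, digits = 4)
  }
  if (length(x$autoreg)) {
    cat("\nAuto-regulation:\n"); print(round(x$autoreg, 4))
  }
  if (nrow(x$input_edges)) {
    cat("\nInput edges:\n")
    print(x$input_edges, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
coef.extilar <- function(object, all = FALSE, ...) {
  rp <- object$problem
  beta <- stats::setNames(numeric(ncol(rp$X)), colnames(rp$X))
  cm <- rp$col_meta
  if (nrow(object$w_edges))
    beta[paste0("w:", object$w_edges$source, ">", object$w_edges$tf)] <-
      object$w_edges$weight
  nz <- object$autoreg != 0
  beta[paste0("a:", names(object$autoreg)[nz])] <- object$autoreg[nz]
  if (nrow(object$input_edges))
    beta[paste0("d:", object$input_edges$input, ">", object$input_edges$gene)] <-
      object$input_edges$weight
  if (all) beta else beta[beta != 0]
}

#' @export
fitted.extilar <- function(object, ...) {
  one_step_predict(object$problem, coef(object, all = TRUE))
}

#' One-step predictions of a fitted network
#'
#' Returns the model's predicted difference quotients `X %*% beta` for the
#' training rows (default) or for a new dataset prepared like the training
#' data (same binding structure, inputs and weights).
#'
#' @param object a fitted `"extilar"` model.
#' @param newdata optional [expression_dataset()] on the same gene universe.
#' @param ... unused.
#' @return numeric vector of predicted responses, with the corresponding
#'   `row_meta` attached as attribute `"row_meta"`.
#' @export
predict.extilar <- function(object, newdata = NULL, ...) {
  rp <- object$problem
  if (!is.null(newdata)) {
    rp <- build_design(newdata, object$binding,
                       pk = NULL, inputs = object$inputs,
                       weights = object$control$weights,
                       measured_only = object$control$measured_only)
  }
  beta <- coef(object, all = TRUE)[colnames(rp$X)]
  yhat <- one_step_predict(rp, unname(beta))
  attr(yhat, "row_meta") <- rp$row_meta
  yhat
}

#' @export
residuals.extilar <- function(object, ...) {
  object$problem$y - fitted(object)
}

#' Plot measured data against the simulated model fit
#'
#' Simulates the fitted network from the mean replicate values at the first
#' time point and overlays the trajectories (lines) on the measured replicate
#' means (points, with replicate range bars).
#'
#' @param x a fitted `"extilar"` model.
#' @param genes subset of genes to show (default: up to 12).
#' @param ... passed to [graphics::plot()].
#' @export
plot.extilar <- function(x, genes = NULL, ...) {
  ds <- x$data
  if (is.null(genes)) genes <- utils::head(ds$genes, 12L)
  x0 <- apply(ds$values[, 1L, , drop = FALSE], 1L, mean)
  tr <- simulate(x, x0 = x0,
                 times = seq(min(ds$times), max(ds$times), length.out = 101L))
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(genes)),
                       mar = c(3, 3, 2, 0.5), mgp = c(1.8, 0.6, 0))
  on.exit(graphics::par(old))
  for (g in genes) {
    mm <- apply(ds$values[g, , , drop = FALSE], 2L, mean)
    lo <- apply(ds$values[g, , , drop = FALSE], 2L, min)
    hi <- apply(ds$values[g, , , drop = FALSE], 2L, max)
    graphics::plot(ds$times, mm, ylim = range(lo, hi, tr$states[, g]),
                   xlab = "time (h)", ylab = "scaled log2-FC", main = g,
                   pch = 16, ...)
    graphics::arrows(ds$times, lo, ds$times, hi, angle = 90, code = 3,
                     length = 0.02, col = "grey50")
    graphics::lines(tr$times, tr$states[, g], col = "steelblue", lwd = 2)
  }
  invisible(x)
}
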