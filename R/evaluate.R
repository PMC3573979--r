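#' Edge counts, precision and validation overlap of a network
#'
#' Precision is the ratio of prior-supported edges to the total number of
#' inferred relations excluding the input-to-gene relations, i.e.
#' `prior-supported / (gene-to-TF + auto-regulation edges)` by default.
#' Auto-regulation edges count in the denominator but can never be
#' prior-supported (only gene-to-TF prior pairs can); set
#' `include_autoreg = FALSE` to restrict the denominator to gene-to-TF edges.
#' Validation overlap counts the implied length-2 gene -> TF -> gene paths
#' that appear in the (inference-independent) validation relation set.
#'
#' @param nm an `extilar_network` (typically a fitted `"extilar"` model).
#' @param pk [prior_knowledge()]; if `NULL`, prior support recorded on the
#'   fitted edges (if any) is used and validation overlap is 0.
#' @param include_autoreg include auto-regulation edges in the precision
#'   denominator (default `TRUE`).
#' @return list with `n_gene_to_tf`, `n_autoreg`, `n_input`,
#'   `n_prior_supported`, `precision`, `n_validation_hits`,
#'   `validation_hits` (data frame).
#' @examples
#' # printed worked example: 25 prior-supported of 49 non-input edges
#' 25 / 49  # 0.5102
#' @export
evaluate_network <- function(nm, pk = NULL, include_autoreg = TRUE) {
  we <- nm$w_edges
  n_g2t <- nrow(we)
  n_aut <- sum(nm$autoreg != 0)
  n_inp <- nrow(nm$input_edges)
  if (!is.null(pk) && nrow(pk$gene_to_tf)) {
    supported <- n_g2t > 0 &
      paste(we$source, we$tf) %in% paste(pk$gene_to_tf$gene, pk$gene_to_tf$tf)
    n_prior <- sum(supported)
  } else if (!is.null(we$prior_supported)) {
    n_prior <- sum(we$prior_supported)
  } else n_prior <- 0L
  denom <- n_g2t + if (include_autoreg) n_aut else 0L
  precision <- if (n_prior == 0L) 0 else n_prior / denom

  hits <- data.frame(src_gene = character(), dst_gene = character())
  if (!is.null(pk) && nrow(pk$validation) && n_g2t) {
    imp <- implied_gene_relations(nm)
    key <- unique(paste(imp$src_gene, imp$dst_gene))
    vkey <- paste(pk$validation$src_gene, pk$validation$dst_gene)
    hits <- pk$validation[vkey %in% key, , drop = FALSE]
  }
  list(n_gene_to_tf = n_g2t, n_autoreg = n_aut, n_input = n_inp,
       n_prior_supported = n_prior, precision = precision,
       n_validation_hits = nrow(hits), validation_hits = hits)
}

#' Precision from printed edge counts
#'
#' The bare arithmetic of the precision measure, for checking published
#' count/precision pairs: `prior_supported / total_non_input_edges`.
#'
#' @param n_prior number of prior-supported edges.
#' @param n_edges total number of inferred non-input edges.
#' @return precision in `[0, 1]` (0 when `n_prior` is 0).
#' @export
precision_from_counts <- function(n_prior, n_edges) {
  stopifnot(n_prior >= 0, n_edges >= n_prior)
  if (n_prior == 0) return(0)
  n_prior / n_edges
}

#' Sweep the prior-integration weight delta
#'
#' Runs one full forward-selection inference per delta value and tabulates,
#' per run, the number of non-input edges, the prior-supported count, the
#' precision and the fit RSS. Decreasing delta soft-integrates the prior
#' knowledge more strongly, so the prior-supported count trends upward.
#'
#' @param ds,candidates,pk,inputs,control as in [extilar()].
#' @param deltas numeric vector of delta values in (0, 1].
#' @param ... passed to [extilar()] (e.g. `scale = FALSE`).
#' @return data frame with columns `delta`, `edges`, `prior_edges`,
#'   `precision`, `rss`; the fitted models are attached as attribute
#'   `"fits"`.
#' @export
delta_sweep <- function(ds, candidates = NULL, pk = NULL, inputs = list(),
                        deltas = c(1, 0.75, 0.5, 0.25, 0.1, 0.05, 0.01),
                        control = extilar_control(), ...) {
  stopifnot(all(deltas > 0), all(deltas <= 1))
  fits <- lapply(deltas, function(d) {
    ctl <- control
    ctl$weights$delta_prior <- d
    extilar(ds, candidates, pk = pk, inputs = inputs, control = ctl, ...)
  })
  rows <- lapply(seq_along(deltas), function(i) {
    m <- evaluate_network(fits[[i]], pk)
    data.frame(delta = deltas[i],
               edges = m$n_gene_to_tf + m$n_autoreg,
               prior_edges = m$n_prior_supported,
               precision = m$precision,
               rss = fits[[i]]$diagnostics$rss)
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  out
}

#' Grid study over input and auto-regulation penalty weights
#'
#' Evaluates one full inference per (input weight, auto-regulation weight)
#' combination, producing the precision / RSS / edge-count surface used to
#' choose operating weights.
#'
#' @param ds,candidates,pk,inputs,control as in [extilar()].
#' @param input_weights,autoreg_weights numeric vectors in (0, 1].
#' @param ... passed to [extilar()].
#' @return data frame with one row per grid cell: `input_weight`,
#'   `autoreg_weight`, `edges`, `prior_edges`, `precision`, `rss`.
#' @export
weight_grid_study <- function(ds, candidates = NULL, pk = NULL,
                              inputs = list(),
                              input_weights = c(0.25, 0.5, 0.75, 0.9, 1),
                              autoreg_weights = c(0.25, 0.5, 0.75, 0.9, 1),
                              control = extilar_control(), ...) {
  grid <- expand.grid(input_weight = input_weights,
                      autoreg_weight = autoreg_weights)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    ctl <- control
    ctl$weights$input_weight <- grid$input_weight[i]
    ctl$weights$autoreg_weight <- grid$autoreg_weight[i]
    fit <- extilar(ds, candidates, pk = pk, inputs = inputs, control = ctl, ...)
    m <- evaluate_network(fit, pk)
    data.frame(input_weight = grid$input_weight[i],
               autoreg_weight = grid$autoreg_weight[i],
               edges = m$n_gene_to_tf + m$n_autoreg,
               prior_edges = m$n_prior_supported,
               precision = m$precision, rss = fit$diagnostics$rss)
  })
  do.call(rbind, rows)
}
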