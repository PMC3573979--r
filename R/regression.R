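#' Penalty weight scheme for the adaptive LASSO
#'
#' Per-column penalty weights delta in (0, 1]; a smaller weight shrinks the
#' corresponding coefficient less and therefore encourages inclusion of the
#' edge ("soft integration"). `delta_prior` applies to gene-to-TF columns
#' supported by prior knowledge, `delta_default` to unsupported ones,
#' `input_weight` to input-to-gene columns and `autoreg_weight` to
#' auto-regulation columns. Defaults are the operating point found by the
#' weight-grid parameter study (input 0.5, auto-regulation 0.75) with a
#' moderate prior integration of delta = 0.5.
#'
#' A hard force-include (delta = 0) is undefined under the weighted L1
#' constraint; values below 1e-6 are raised to 1e-6 with a warning.
#'
#' @param delta_prior,delta_default,input_weight,autoreg_weight numeric in
#'   (0, 1].
#' @return list of class `"weight_scheme"`.
#' @export
weight_scheme <- function(delta_prior = 0.5, delta_default = 1,
                          input_weight = 0.5, autoreg_weight = 0.75) {
  w <- list(delta_prior = delta_prior, delta_default = delta_default,
            input_weight = input_weight, autoreg_weight = autoreg_weight)
  for (nm in names(w)) {
    if (w[[nm]] <= 0) {
      warning(nm, " <= 0 is undefined; raised to 1e-6 (near-forced inclusion)")
      w[[nm]] <- 1e-6
    }
    if (w[[nm]] > 1) stop(nm, " must lie in (0, 1]")
    if (w[[nm]] < 1e-6) {
      warning(nm, " < 1e-6 raised to 1e-6")
      w[[nm]] <- 1e-6
    }
  }
  structure(w, class = "weight_scheme")
}

#' Forward-difference response vector
#'
#' For each target gene, replicate and consecutive grid transition, computes
#' the difference quotient `(x_i[t_m, r] - x_i[t_m-1, r]) / dt`. Row order is
#' deterministic: gene-major, then replicate, then time.
#'
#' @param ds an equidistant [expression_dataset()]; with
#'   `measured_only = TRUE` the grid may be non-equidistant, since each
#'   transition carries its own time interval.
#' @param targets character vector of target genes (those with at least one
#'   binding TF or input relation).
#' @param measured_only if `TRUE`, drop interpolated grid points and build
#'   one row per transition between consecutive *measured* points, each with
#'   its own `dt`; interpolated points then contribute no rows.
#' @return list with `y` (numeric) and `row_meta` (data frame with columns
#'   `gene`, `rep`, `m` giving the transition `m-1 -> m`, plus `t_prev` and
#'   `dt`).
#' @export
build_response <- function(ds, targets = ds$genes, measured_only = FALSE) {
  if (measured_only && any(ds$interpolated)) {
    keep <- !ds$interpolated
    ds <- expression_dataset(ds$values[, keep, , drop = FALSE],
                             genes = ds$genes, times = ds$times[keep])
  }
  if (!measured_only && !is_equidistant(ds))
    stop("dataset grid is not equidistant; run interpolate_to_grid() first")
  stopifnot(all(targets %in% ds$genes))
  M <- length(ds$times); R <- n_replicates(ds)
  if (M < 2L) stop("need at least two time points")
  grid <- expand.grid(m = 2:M, rep = seq_len(R), gene = targets,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("gene", "rep", "m")]
  gi <- match(grid$gene, ds$genes)
  idx_now  <- cbind(gi, grid$m, grid$rep)
  idx_prev <- cbind(gi, grid$m - 1L, grid$rep)
  grid$dt <- ds$times[grid$m] - ds$times[grid$m - 1L]
  y <- (ds$values[idx_now] - ds$values[idx_prev]) / grid$dt
  grid$t_prev <- ds$times[grid$m - 1L]
  list(y = as.numeric(y), row_meta = grid, dt = unique(grid$dt),
       dataset = ds)
}

#' Build the joint block-structured regression problem
#'
#' Assembles the response `y = dx/dt` and the design matrix whose columns are,
#' in order: gene-to-TF columns (one shared coefficient `w_kj` per (TF k,
#' source gene j) pair with `b_kj = 0`, carrying `x_j[t_m-1, r]` in the rows
#' of every gene `i` with `b_ki = 1`), input columns (`u_c(t_m-1)` in the rows
#' of the target gene only) and auto-regulation columns (`x_h[t_m-1, r]` in
#' the rows of gene `h`). Row count is `(M-1) * N'_r * R` and column count
#' `(F*N - B) + U + A`, where `N'_r` is the number of genes with at least one
#' binding site or input relation, `B` the number of binding relations, `U`
#' the number of input-to-gene relations and `A = N'_r`.
#'
#' If `inputs` are supplied but `pk` lists no input-to-gene candidates, every
#' gene is treated as a candidate target of every input.
#'
#' @param ds equidistant [expression_dataset()] (scaled).
#' @param bm [binding_matrix()], already augmented (no orphan target genes
#'   among the modelled genes is required only in so far as orphans without
#'   input relations simply contribute no rows).
#' @param pk [prior_knowledge()] or `NULL`.
#' @param inputs list of [input_signal()]s (possibly empty).
#' @param weights a [weight_scheme()].
#' @param measured_only passed to [build_response()].
#' @return Object of class `"regression_problem"`: list with `y`, `X`,
#'   `row_meta`, `col_meta` (columns `type`, `tf`, `source`, `input`, `gene`),
#'   `penalty`, `dims`, `dt`.
#' @export
build_design <- function(ds, bm, pk = NULL, inputs = list(),
                         weights = weight_scheme(), measured_only = FALSE) {
  if (is.null(pk)) pk <- prior_knowledge()
  stopifnot(inherits(bm, "binding_matrix"), inherits(weights, "weight_scheme"))
  if (!setequal(colnames(bm), ds$genes) || ncol(bm) != length(ds$genes))
    stop("binding matrix gene set does not match the dataset")
  b <- unclass(bm)[, ds$genes, drop = FALSE]
  genes <- ds$genes; tfs <- rownames(b)
  N <- length(genes); F_ <- length(tfs)

  bad <- setdiff(unique(as.character(pk$gene_to_tf$gene)), genes)
  if (length(bad)) stop("prior edge references unknown gene(s): ",
                        paste(bad, collapse = ", "))

  # input-to-gene candidates
  input_ids <- vapply(inputs, function(u) u$id, "")
  ig <- pk$input_to_gene
  if (length(inputs) && nrow(ig) == 0L)
    ig <- expand.grid(input = input_ids, gene = genes,
                      stringsAsFactors = FALSE)
  ig <- ig[ig$input %in% input_ids & ig$gene %in% genes, , drop = FALSE]
  ig <- ig[order(ig$input, ig$gene), , drop = FALSE]

  bound <- colSums(b) > 0
  has_input <- genes %in% ig$gene
  targets <- genes[bound | has_input]
  if (!length(targets)) stop("no gene has a binding site or input relation")

  resp <- build_response(ds, targets, measured_only = measured_only)
  y <- resp$y; rm_ <- resp$row_meta
  ds <- resp$dataset  # interpolated points are gone under measured_only
  n_rows <- length(y)

  # column metadata ---------------------------------------------------------
  g2t <- NULL
  if (F_ > 0L) {
    free <- which(b == 0, arr.ind = TRUE)  # (k, j) with b_kj = 0
    g2t <- data.frame(tf = tfs[free[, 1L]], source = genes[free[, 2L]],
                      stringsAsFactors = FALSE)
    g2t <- g2t[order(g2t$tf, g2t$source), , drop = FALSE]
  }
  n_g2t <- if (is.null(g2t)) 0L else nrow(g2t)
  n_inp <- nrow(ig)
  n_aut <- length(targets)

  col_meta <- data.frame(
    type = c(rep("gene_to_tf", n_g2t), rep("input", n_inp), rep("autoreg", n_aut)),
    tf = c(if (n_g2t) g2t$tf else character(), rep(NA, n_inp + n_aut)),
    source = c(if (n_g2t) g2t$source else character(), rep(NA, n_inp + n_aut)),
    input = c(rep(NA, n_g2t), if (n_inp) ig$input else character(), rep(NA, n_aut)),
    gene = c(rep(NA, n_g2t), if (n_inp) ig$gene else character(), targets),
    stringsAsFactors = FALSE)

  # design matrix -----------------------------------------------------------
  # P[row, j]: expression of source gene j at the row's previous time point
  gi_prev <- cbind(rep(seq_len(N), each = n_rows),
                   rep(rm_$m - 1L, N), rep(rm_$rep, N))
  P <- matrix(ds$values[gi_prev], n_rows, N)
  colnames(P) <- genes
  row_gene_idx <- match(rm_$gene, genes)

  X <- matrix(0, n_rows, nrow(col_meta))
  if (n_g2t) {
    for (cc in seq_len(n_g2t)) {
      k <- g2t$tf[cc]; j <- g2t$source[cc]
      X[, cc] <- P[, j] * b[k, row_gene_idx]
    }
  }
  if (n_inp) {
    for (cc in seq_len(n_inp)) {
      u <- inputs[[match(ig$input[cc], input_ids)]]
      X[, n_g2t + cc] <- eval_input(u, rm_$t_prev) * (rm_$gene == ig$gene[cc])
    }
  }
  for (cc in seq_len(n_aut))
    X[, n_g2t + n_inp + cc] <- P[, targets[cc]] * (rm_$gene == targets[cc])

  colnames(X) <- column_labels(col_meta)

  # penalty weights ----------------------------------------------------------
  prior_key <- paste(pk$gene_to_tf$gene, pk$gene_to_tf$tf, sep = "\r")
  penalty <- numeric(nrow(col_meta))
  is_g2t <- col_meta$type == "gene_to_tf"
  penalty[is_g2t] <- ifelse(
    paste(col_meta$source[is_g2t], col_meta$tf[is_g2t], sep = "\r") %in% prior_key,
    weights$delta_prior, weights$delta_default)
  penalty[col_meta$type == "input"] <- weights$input_weight
  penalty[col_meta$type == "autoreg"] <- weights$autoreg_weight

  dims <- list(N = N, F = F_, C = length(inputs),
               M = length(ds$times), R = n_replicates(ds),
               N_r = sum(bound), N_r_prime = length(targets),
               B = sum(b), N_prime = F_ * N - sum(b),
               U = n_inp, A = n_aut,
               M_pp = n_rows, N_pp = nrow(col_meta))

  structure(list(y = y, X = X, row_meta = rm_, col_meta = col_meta,
                 penalty = penalty, dims = dims, dt = resp$dt,
                 targets = targets),
            class = "regression_problem")
}

column_labels <- function(cm) {
  ifelse(cm$type == "gene_to_tf", paste0("w:", cm$source, ">", cm$tf),
  ifelse(cm$type == "input", paste0("d:", cm$input, ">", cm$gene),
         paste0("a:", cm$gene)))
}

#' @export
print.regression_problem <- function(x, ...) {
  d <- x$dims
  cat(sprintf("Regression problem: %d rows x %d columns\n", d$M_pp, d$N_pp))
  cat(sprintf("  (M-1)=%d transitions x N'_r=%d genes x R=%d replicates\n",
              d$M - 1L, d$N_r_prime, d$R))
  cat(sprintf("  columns: %d gene-to-TF (F*N - B = %d*%d - %d), %d input, %d autoreg\n",
              d$N_prime, d$F, d$N, d$B, d$U, d$A))
  invisible(x)
}

#' One-step predictions of a coefficient vector
#'
#' Evaluates `X %*% beta`, the model's one-step difference-quotient
#' predictions, used for RSS computation and diagnostics.
#'
#' @param rp a `regression_problem`.
#' @param beta coefficient vector of length `ncol(rp$X)`.
#' @return numeric vector of predicted responses.
#' @export
one_step_predict <- function(rp, beta) {
  if (length(beta) != ncol(rp$X))
    stop("beta has length ", length(beta), ", expected ", ncol(rp$X))
  as.numeric(rp$X %*% beta)
}
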