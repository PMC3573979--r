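#' Control parameters for network inference
#'
#' @param delta penalty weight in (0, 1] for gene-to-TF columns supported by
#'   prior knowledge; smaller values integrate the prior more strongly.
#'   Default 0.5 (moderate integration).
#' @param delta_default weight for unsupported gene-to-TF columns (default 1).
#' @param input_weight penalty weight for input-to-gene columns (default 0.5).
#' @param autoreg_weight penalty weight for auto-regulation columns
#'   (default 0.75).
#' @param alpha fit weight of the proposal measure Pm, `>= 1` (default 1).
#' @param dt grid spacing in hours for interpolation and the difference
#'   quotients (default 1).
#' @param cp_form Mallows-Cp variant used for path-knot selection, see
#'   [mallows_cp()]. The default is the classical estimator-based form: the
#'   printed literature form scales the noise estimate by `1/pmax`, which on
#'   these regression problems grows the implied noise so large that the
#'   densest knot always wins, defeating the sparsity purpose of the
#'   criterion.
#' @param max_iter cap on forward-selection iterations (default `Inf`).
#' @param measured_only restrict regression rows to measured transitions.
#' @param rel_tol relative tolerance for "RSS not undercut" and RSS
#'   tie-breaking in forward selection.
#' @return list of class `"extilar_control"`.
#' @export
extilar_control <- function(delta = 0.5, delta_default = 1,
                            input_weight = 0.5, autoreg_weight = 0.75,
                            alpha = 1, dt = 1,
                            cp_form = c("classical", "printed"),
                            max_iter = Inf, measured_only = FALSE,
                            rel_tol = 1e-12) {
  structure(list(
    weights = weight_scheme(delta, delta_default, input_weight, autoreg_weight),
    alpha = alpha, dt = dt, cp_form = match.arg(cp_form),
    max_iter = max_iter, measured_only = measured_only, rel_tol = rel_tol),
    class = "extilar_control")
}

#' Infer coefficients for a fixed TF-to-gene structure
#'
#' Builds the joint regression problem for the given binding structure, runs
#' the adaptive LARS/LASSO path, selects the path model minimizing Mallows Cp
#' (sparse networks are favored), re-estimates the selected coefficients by an
#' unpenalized OLS fit and assembles the resulting network model. This is one
#' evaluation inside the forward-selection loop of [extilar()], and the whole
#' inference when the TF-to-gene structure is already known.
#'
#' @param ds a scaled, equidistant [expression_dataset()].
#' @param bm [binding_matrix()] defining the (fixed) TF-to-gene structure;
#'   augment orphan genes with [augment_artificial_tfs()] beforehand if
#'   needed.
#' @param pk [prior_knowledge()] or `NULL`.
#' @param inputs list of [input_signal()]s.
#' @param control an [extilar_control()].
#' @return Object of class `c("extilar", "extilar_network")` with the fitted
#'   coefficients, the regression problem (`$problem`), the LARS path
#'   (`$path`) and diagnostics `rss`, `cp`, `pm`, `rss_null`, `p`.
#' @export
extilar_fit <- function(ds, bm, pk = NULL, inputs = list(),
                        control = extilar_control()) {
  stopifnot(inherits(control, "extilar_control"))
  rp <- build_design(ds, bm, pk = pk, inputs = inputs,
                     weights = control$weights,
                     measured_only = control$measured_only)
  rss_null <- sum(rp$y^2)

  if (rss_null == 0) {
    beta <- stats::setNames(numeric(ncol(rp$X)), colnames(rp$X))
    sel <- list(index = 1L, cp = NA_real_)
    path <- NULL
  } else {
    path <- withCallingHandlers(
      adaptive_lars(rp),
      warning = function(w) {
        if (grepl("all-zero column", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    sel <- select_by_cp(path, m = rp$dims$M_pp, form = control$cp_form)
    beta <- ols_refit(rp, sel$step$active)
    beta[abs(beta) < 1e-10 * max(abs(beta), 1)] <- 0  # numerically-zero refits
  }

  fit_rss <- rss(rp$y, one_step_predict(rp, beta))
  p_used <- sum(beta != 0)
  pm <- if (rss_null > 0)
    pm_measure(fit_rss, rss_null, p_used, rp$dims$N_pp, control$alpha)
  else p_used / rp$dims$N_pp

  nm <- assemble_network(rp, beta, bm, pk, inputs,
                         diagnostics = list(
                           rss = fit_rss, rss_null = rss_null,
                           cp = if (all(is.na(sel$cp))) NA_real_ else min(sel$cp, na.rm = TRUE),
                           pm = pm, p = p_used,
                           n_rows = rp$dims$M_pp, n_cols = rp$dims$N_pp))
  fit <- nm
  fit$problem <- rp
  fit$path <- path
  fit$control <- control
  fit$data <- ds
  class(fit) <- c("extilar", "extilar_network")
  fit
}

assemble_network <- function(rp, beta, bm, pk, inputs, diagnostics) {
  cm <- rp$col_meta
  nz <- beta != 0
  w_edges <- NULL
  sel <- nz & cm$type == "gene_to_tf"
  if (any(sel)) {
    w_edges <- data.frame(tf = cm$tf[sel], source = cm$source[sel],
                          weight = unname(beta[sel]), stringsAsFactors = FALSE)
    if (!is.null(pk) && nrow(pk$gene_to_tf))
      w_edges$prior_supported <- paste(w_edges$source, w_edges$tf) %in%
        paste(pk$gene_to_tf$gene, pk$gene_to_tf$tf)
    else w_edges$prior_supported <- FALSE
  }
  sel <- nz & cm$type == "autoreg"
  autoreg <- if (any(sel)) stats::setNames(unname(beta[sel]), cm$gene[sel]) else NULL
  sel <- nz & cm$type == "input"
  input_edges <- if (any(sel))
    data.frame(input = cm$input[sel], gene = cm$gene[sel],
               weight = unname(beta[sel]), stringsAsFactors = FALSE)
  else NULL
  network_model(genes = colnames(bm), binding = bm, w_edges = w_edges,
                autoreg = autoreg, input_edges = input_edges,
                inputs = inputs, diagnostics = diagnostics)
}

#' Fit a dynamic transcription-factor network by forward selection
#'
#' The main fitting function. Starting from a base structure containing no
#' candidate TF-to-gene relation (only artificial TFs for genes that no
#' candidate covers, so every gene remains a possible regulation target), the
#' greedy loop evaluates, at each iteration, a full [extilar_fit()] for the
#' current structure plus each unused candidate relation and adds the
#' candidate yielding the minimal RSS. It stops when candidates are exhausted
#' or the previous iteration's RSS is not undercut. Among all iteration
#' snapshots the final model is the one minimizing the proposal measure Pm.
#'
#' @param ds an [expression_dataset()]; scaled to per-gene absolute maximum 1
#'   and interpolated to an equidistant `control$dt` grid unless `scale` /
#'   `interpolate` are `FALSE`.
#' @param candidates data frame of candidate TF-to-gene relations with columns
#'   `tf`, `gene` (the structure search space); may be empty.
#' @param pk [prior_knowledge()] or `NULL`.
#' @param inputs list of [input_signal()]s.
#' @param control an [extilar_control()].
#' @param scale,interpolate preprocessing switches.
#' @return Object of class `c("extilar", "extilar_network")`; in addition to
#'   the [extilar_fit()] fields it carries `$trace`, a per-iteration data
#'   frame (added relation, RSS, Pm), and `$candidates`.
#' @examples
#' \donttest{
#' scen <- synthetic_scenario(seed = 1)
#' fit <- extilar(scen$data, scen$candidates, inputs = scen$network$inputs,
#'                scale = FALSE)
#' print(fit)
#' }
#' @seealso [extilar_fit()], [evaluate_network()], [simulate.extilar_network()]
#' @export
extilar <- function(ds, candidates = NULL, pk = NULL, inputs = list(),
                    control = extilar_control(), scale = TRUE,
                    interpolate = TRUE) {
  cl <- match.call()
  if (scale) ds <- scale_profiles(ds)
  if (interpolate) ds <- interpolate_to_grid(ds, control$dt)
  if (is.null(candidates) || !nrow(as.data.frame(candidates)))
    candidates <- data.frame(tf = character(), gene = character())
  candidates <- as.data.frame(candidates, stringsAsFactors = FALSE)
  stopifnot(all(c("tf", "gene") %in% names(candidates)))
  candidates <- candidates[order(candidates$tf, candidates$gene), , drop = FALSE]

  # permanent artificial TFs: genes no candidate can ever cover
  base_bm <- binding_matrix(
    if (nrow(candidates))
      data.frame(tf = candidates$tf[0], gene = candidates$gene[0]) else NULL,
    genes = ds$genes)
  uncovered <- setdiff(ds$genes, unique(candidates$gene))
  art <- if (length(uncovered))
    data.frame(tf = paste0("AT_", uncovered), gene = uncovered,
               origin = "artificial", stringsAsFactors = FALSE)
  else NULL

  make_bm <- function(sel_idx) {
    rel <- if (length(sel_idx))
      data.frame(tf = candidates$tf[sel_idx], gene = candidates$gene[sel_idx],
                 origin = "selected", stringsAsFactors = FALSE)
    else NULL
    binding_matrix(rbind(rel, art), genes = ds$genes)
  }

  fit_structure <- function(sel_idx)
    extilar_fit(ds, make_bm(sel_idx), pk = pk, inputs = inputs,
                control = control)

  # Pm compares the iteration proposals on one common scale: RSS relative to
  # the largest RSS among the proposals (the no-relation base network) and p
  # relative to the largest coefficient budget N'' among the proposals
  snapshot_pm <- function(f, rss_max, pmax) {
    if (is.null(f)) return(Inf)
    d <- f$diagnostics
    if (!is.finite(rss_max) || rss_max <= 0) return(d$p / pmax)
    pm_measure(d$rss, rss_max, d$p, pmax, control$alpha)
  }

  selected <- integer(0)
  # the base structure can lack target genes entirely (no inputs, no binding);
  # it then scores as an infinitely bad fit and the first iteration must add
  current <- tryCatch(fit_structure(selected), error = function(e) {
    if (grepl("no gene has a binding site", conditionMessage(e))) NULL
    else stop(e)
  })
  if (is.null(current) && !nrow(candidates))
    stop("no inputs, no binding relations and no candidates: nothing to fit")
  snapshots <- list(current)
  trace <- data.frame(iteration = 0L, tf = NA_character_, gene = NA_character_,
                      rss = if (is.null(current)) Inf else current$diagnostics$rss,
                      stringsAsFactors = FALSE)
  iter <- 0L
  repeat {
    remaining <- setdiff(seq_len(nrow(candidates)), selected)
    if (!length(remaining) || iter >= control$max_iter) break
    iter <- iter + 1L
    fits <- lapply(remaining, function(i) fit_structure(c(selected, i)))
    rss_i <- vapply(fits, function(f) f$diagnostics$rss, 0)
    # candidates ordered lexicographically by (tf, gene); ties take the first
    best <- which(rss_i <= min(rss_i) * (1 + control$rel_tol))[1L]
    prev_rss <- trace$rss[nrow(trace)]
    if (rss_i[best] >= prev_rss * (1 - control$rel_tol) &&
        rss_i[best] >= prev_rss - control$rel_tol) break  # RSS not undercut
    selected <- c(selected, remaining[best])
    current <- fits[[best]]
    snapshots[[length(snapshots) + 1L]] <- current
    trace <- rbind(trace, data.frame(
      iteration = iter, tf = candidates$tf[remaining[best]],
      gene = candidates$gene[remaining[best]],
      rss = current$diagnostics$rss, stringsAsFactors = FALSE))
  }

  rss_max <- suppressWarnings(max(trace$rss[is.finite(trace$rss)]))
  pmax <- max(vapply(snapshots, function(f)
    if (is.null(f)) 0 else f$diagnostics$n_cols, 0))
  pm_all <- vapply(snapshots, snapshot_pm, 0, rss_max = rss_max, pmax = pmax)
  trace$pm <- pm_all
  if (all(!is.finite(pm_all))) stop("no fittable structure was found")
  final_i <- order(pm_all, seq_along(pm_all))[1L]
  fit <- snapshots[[final_i]]
  fit$trace <- trace
  fit$final_iteration <- final_i - 1L
  fit$candidates <- candidates
  fit$call <- cl
  fit
}
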