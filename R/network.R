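#' Construct a regulatory network model
#'
#' The simulatable object of the method: a set of TF-to-gene binding relations
#' `b_ki`, gene-to-TF regulatory edges with weights `w_kj` (activation > 0,
#' repression < 0), per-gene auto-regulation coefficients `a_i` (lumping
#' self-regulation and transcript degradation) and input-to-gene edges with
#' weights `d_ci` driven by external [input_signal()]s. Gene `i` is regulated
#' by gene `j` via TF `k` iff `b_ki = 1`, `b_kj = 0` and `w_kj != 0`; implied
#' gene-gene relations are the `j -> k -> i` paths.
#'
#' @param genes character vector of gene identifiers.
#' @param binding a [binding_matrix()] over `genes`.
#' @param w_edges data frame with columns `tf`, `source`, `weight`
#'   (gene-to-TF edges); may be empty/`NULL`.
#' @param autoreg named numeric vector of auto-regulation coefficients
#'   (missing genes default to 0 = no auto-regulation edge).
#' @param input_edges data frame with columns `input`, `gene`, `weight`; may
#'   be empty/`NULL`.
#' @param inputs list of [input_signal()]s.
#' @param diagnostics optional list of fit diagnostics.
#' @return Object of class `"extilar_network"`.
#' @export
network_model <- function(genes, binding, w_edges = NULL, autoreg = NULL,
                          input_edges = NULL, inputs = list(),
                          diagnostics = list()) {
  genes <- as.character(genes)
  stopifnot(inherits(binding, "binding_matrix"),
            setequal(colnames(binding), genes))
  if (is.null(w_edges) || !nrow(as.data.frame(w_edges)))
    w_edges <- data.frame(tf = character(), source = character(),
                          weight = numeric(), stringsAsFactors = FALSE)
  w_edges <- as.data.frame(w_edges, stringsAsFactors = FALSE)
  stopifnot(all(c("tf", "source", "weight") %in% names(w_edges)))
  if (is.null(input_edges) || !nrow(as.data.frame(input_edges)))
    input_edges <- data.frame(input = character(), gene = character(),
                              weight = numeric(), stringsAsFactors = FALSE)
  a <- stats::setNames(numeric(length(genes)), genes)
  if (!is.null(autoreg)) {
    stopifnot(!is.null(names(autoreg)), all(names(autoreg) %in% genes))
    a[names(autoreg)] <- autoreg
  }
  b <- unclass(binding)[, genes, drop = FALSE]
  # structural exclusion: no edge from a gene the TF itself binds
  if (nrow(w_edges)) {
    stopifnot(all(w_edges$tf %in% rownames(b)),
              all(w_edges$source %in% genes))
    viol <- b[cbind(w_edges$tf, w_edges$source)] == 1
    if (any(viol))
      stop("gene-to-TF edge from a gene bound by the same TF: ",
           paste(paste0(w_edges$source[viol], "->", w_edges$tf[viol]),
                 collapse = ", "))
  }
  structure(list(genes = genes, tfs = rownames(b), binding = binding,
                 w_edges = w_edges, autoreg = a, input_edges = input_edges,
                 inputs = inputs, diagnostics = diagnostics),
            class = "extilar_network")
}

#' @export
print.extilar_network <- function(x, ...) {
  cat(sprintf("Regulatory network: %d genes, %d TFs\n",
              length(x$genes), length(x$tfs)))
  cat(sprintf("  %d gene-to-TF edges, %d auto-regulation, %d input edges\n",
              nrow(x$w_edges), sum(x$autoreg != 0), nrow(x$input_edges)))
  if (length(x$diagnostics))
    cat("  diagnostics:",
        paste(names(x$diagnostics)[vapply(x$diagnostics, is.numeric, TRUE)],
              vapply(x$diagnostics[vapply(x$diagnostics, is.numeric, TRUE)],
                     function(v) format(v[1L], digits = 5), ""),
              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Effective gene-gene system matrix of a network
#'
#' Collapses the TF bridges into a gene-level linear system:
#' `A[i, j] = sum_k b_ki * (1 - b_kj) * w_kj + a_i * 1[i == j]`, so that the
#' dynamics read `dx/dt = A x + D u(t)`.
#'
#' @param nm an `extilar_network`.
#' @return list with `A` (genes x genes), `D` (genes x inputs, possibly
#'   0-column) and `inputs`.
#' @export
system_matrix <- function(nm) {
  n <- length(nm$genes)
  A <- matrix(0, n, n, dimnames = list(nm$genes, nm$genes))
  b <- unclass(nm$binding)
  if (nrow(nm$w_edges)) {
    for (e in seq_len(nrow(nm$w_edges))) {
      k <- nm$w_edges$tf[e]; j <- nm$w_edges$source[e]
      tgt <- nm$genes[b[k, nm$genes] == 1]
      A[tgt, j] <- A[tgt, j] + nm$w_edges$weight[e]
    }
  }
  diag(A) <- diag(A) + nm$autoreg[nm$genes]
  ids <- vapply(nm$inputs, function(u) u$id, "")
  D <- matrix(0, n, length(ids), dimnames = list(nm$genes, ids))
  if (nrow(nm$input_edges))
    for (e in seq_len(nrow(nm$input_edges)))
      D[nm$input_edges$gene[e], nm$input_edges$input[e]] <-
        nm$input_edges$weight[e]
  list(A = A, D = D, inputs = nm$inputs)
}

#' Implied gene-gene relations of a network
#'
#' Enumerates the length-2 regulatory paths `source gene -> TF -> target
#' gene` implied by the gene-to-TF edges and the binding relations. These are
#' the relations that can be checked against independent validation
#' knowledge.
#'
#' @param nm an `extilar_network`.
#' @return data frame with columns `src_gene`, `tf`, `dst_gene`, `weight`.
#' @export
implied_gene_relations <- function(nm) {
  out <- list()
  b <- unclass(nm$binding)
  if (nrow(nm$w_edges))
    for (e in seq_len(nrow(nm$w_edges))) {
      k <- nm$w_edges$tf[e]; j <- nm$w_edges$source[e]
      tgt <- setdiff(nm$genes[b[k, nm$genes] == 1], j)
      if (length(tgt))
        out[[length(out) + 1L]] <-
          data.frame(src_gene = j, tf = k, dst_gene = tgt,
                     weight = nm$w_edges$weight[e], stringsAsFactors = FALSE)
    }
  if (!length(out))
    return(data.frame(src_gene = character(), tf = character(),
                      dst_gene = character(), weight = numeric()))
  res <- do.call(rbind, out)
  res[order(res$src_gene, res$tf, res$dst_gene), , drop = FALSE]
}
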