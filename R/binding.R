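#' Transcription-factor binding matrix
#'
#' Binary indicator matrix `b[k, i] = 1` if gene `i` possesses a binding site
#' for transcription factor `k` (one row per TF, one column per gene). Each
#' entry carries an origin: `"candidate"` (extracted binding knowledge,
#' eligible for forward selection), `"selected"` (chosen by forward
#' selection), or `"artificial"` (an auxiliary TF introduced so that an
#' otherwise orphan gene can be a regulation target).
#'
#' TFs that bind no gene contribute nothing to the model (their columns in the
#' regression matrix would be identically zero, and the column-count formula
#' N' = F*N - B assumes every TF binds at least one gene); such rows are
#' dropped with a warning.
#'
#' @param edges data frame with columns `tf`, `gene` and optionally `origin`;
#'   or `NULL` for an empty matrix over `genes`.
#' @param genes character vector of all modelled gene identifiers.
#' @return Object of class `"binding_matrix"`: binary matrix TF x gene with an
#'   `"origin"` character matrix attribute.
#' @export
binding_matrix <- function(edges = NULL, genes) {
  genes <- as.character(genes)
  if (is.null(edges) || nrow(edges) == 0L) {
    b <- matrix(0, 0L, length(genes), dimnames = list(NULL, genes))
    org <- matrix(NA_character_, 0L, length(genes), dimnames = list(NULL, genes))
    return(structure(b, origin = org, class = c("binding_matrix", "matrix")))
  }
  stopifnot(all(c("tf", "gene") %in% names(edges)))
  if (!"origin" %in% names(edges)) edges$origin <- "candidate"
  unknown <- setdiff(unique(as.character(edges$gene)), genes)
  if (length(unknown))
    stop("binding edge references unknown gene(s): ", paste(unknown, collapse = ", "))
  tfs <- unique(as.character(edges$tf))
  b <- matrix(0, length(tfs), length(genes), dimnames = list(tfs, genes))
  org <- matrix(NA_character_, length(tfs), length(genes),
                dimnames = list(tfs, genes))
  for (e in seq_len(nrow(edges))) {
    b[as.character(edges$tf[e]), as.character(edges$gene[e])] <- 1
    org[as.character(edges$tf[e]), as.character(edges$gene[e])] <-
      as.character(edges$origin[e])
  }
  empty <- rowSums(b) == 0
  if (any(empty)) {
    warning("dropping TF(s) binding no gene: ",
            paste(tfs[empty], collapse = ", "))
    b <- b[!empty, , drop = FALSE]; org <- org[!empty, , drop = FALSE]
  }
  structure(b, origin = org, class = c("binding_matrix", "matrix"))
}

#' @export
print.binding_matrix <- function(x, ...) {
  org <- attr(x, "origin")
  n_art <- if (nrow(x)) sum(apply(org == "artificial", 1L,
                                  function(r) any(r, na.rm = TRUE))) else 0L
  cat(sprintf("Binding matrix: %d TFs (%d artificial) x %d genes, %d relations\n",
              nrow(x), n_art, ncol(x), sum(x)))
  invisible(x)
}

#' Convert a binding matrix back to an edge list
#' @param bm a `binding_matrix`.
#' @return data frame with columns `tf`, `gene`, `origin`.
#' @export
binding_edges <- function(bm) {
  idx <- which(unclass(bm) == 1, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(tf = character(), gene = character(),
                      origin = character(), stringsAsFactors = FALSE))
  org <- attr(bm, "origin")
  data.frame(tf = rownames(bm)[idx[, 1L]], gene = colnames(bm)[idx[, 2L]],
             origin = org[idx], stringsAsFactors = FALSE)[
               order(rownames(bm)[idx[, 1L]], colnames(bm)[idx[, 2L]]), ,
               drop = FALSE]
}

#' Add artificial TFs for orphan genes
#'
#' Every gene with no binding TF receives a fresh artificial TF
#' (`AT_<gene>`) that binds only that gene, so the gene is available as a
#' regulation target; existing entries are untouched. Without this step an
#' orphan gene could act as a regulator but never be regulated.
#'
#' @param bm a `binding_matrix`.
#' @param genes genes that must be covered (defaults to all columns of `bm`).
#' @return The augmented `binding_matrix`.
#' @export
augment_artificial_tfs <- function(bm, genes = colnames(bm)) {
  genes <- as.character(genes)
  stopifnot(all(genes %in% colnames(bm)))
  cov <- if (nrow(bm)) colSums(unclass(bm)[, genes, drop = FALSE]) > 0 else
    rep(FALSE, length(genes))
  orphans <- genes[!cov]
  if (!length(orphans)) return(bm)
  old <- binding_edges(bm)
  add <- data.frame(tf = paste0("AT_", orphans), gene = orphans,
                    origin = "artificial", stringsAsFactors = FALSE)
  binding_matrix(rbind(old, add), genes = colnames(bm))
}

#' Read / write binding relations as a TSV edge list
#'
#' Format: `tf<TAB>gene<TAB>origin`, one relation per line, with header.
#'
#' @param path file path.
#' @param genes gene universe for the resulting matrix.
#' @return [read_binding()] returns a `binding_matrix`.
#' @export
read_binding <- function(path, genes) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  binding_matrix(tab, genes = genes)
}

#' @rdname read_binding
#' @param bm a `binding_matrix`.
#' @export
write_binding <- function(bm, path) {
  utils::write.table(binding_edges(bm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Prior and validation knowledge
#'
#' Bundles the two knowledge sets the method keeps strictly separate:
#' gene-to-TF prior edges (soft-integrated into the penalty weights during
#' inference) and directed gene-gene validation relations (consulted only
#' post hoc, never by the solver). Input-to-gene candidates say which genes an
#' external perturbation may act on.
#'
#' @param gene_to_tf data frame with columns `gene`, `tf` (may be `NULL`).
#' @param input_to_gene data frame with columns `input`, `gene` (may be `NULL`).
#' @param validation data frame with columns `src_gene`, `dst_gene` (may be
#'   `NULL`).
#' @return Object of class `"prior_knowledge"`.
#' @export
prior_knowledge <- function(gene_to_tf = NULL, input_to_gene = NULL,
                            validation = NULL) {
  empty <- function(...) {
    df <- data.frame(matrix(character(), 0L, length(c(...))))
    names(df) <- c(...); df
  }
  if (is.null(gene_to_tf)) gene_to_tf <- empty("gene", "tf")
  if (is.null(input_to_gene)) input_to_gene <- empty("input", "gene")
  if (is.null(validation)) validation <- empty("src_gene", "dst_gene")
  stopifnot(all(c("gene", "tf") %in% names(gene_to_tf)),
            all(c("input", "gene") %in% names(input_to_gene)),
            all(c("src_gene", "dst_gene") %in% names(validation)))
  structure(list(gene_to_tf = gene_to_tf, input_to_gene = input_to_gene,
                 validation = validation),
            class = "prior_knowledge")
}

#' @export
print.prior_knowledge <- function(x, ...) {
  cat(sprintf(paste0("Prior knowledge: %d gene-to-TF prior edges, ",
                     "%d input-to-gene candidates, %d validation relations\n"),
              nrow(x$gene_to_tf), nrow(x$input_to_gene), nrow(x$validation)))
  invisible(x)
}

#' Read prior / validation knowledge edge lists
#'
#' `read_prior()` expects `gene<TAB>tf`, `read_validation()` expects
#' `src_gene<TAB>dst_gene`, both with header.
#'
#' @param path file path.
#' @return a data frame.
#' @export
read_prior <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)

#' @rdname read_prior
#' @export
read_validation <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)
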