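#' Export a network in SIF format
#'
#' One line per edge, `source<TAB>interaction<TAB>target`. Gene-to-TF edges
#' are written as `activates` (weight > 0) or `represses` (weight < 0),
#' TF-to-gene binding relations as `binds`, input edges as `input` and
#' auto-regulation edges as self-loops (`activates`/`represses`). Edges are
#' sorted so the export is byte-identical for identical models.
#'
#' @param nm an `extilar_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_sif <- function(nm, path) {
  rows <- list()
  if (nrow(nm$w_edges))
    rows[[1L]] <- data.frame(
      src = nm$w_edges$source,
      interaction = ifelse(nm$w_edges$weight > 0, "activates", "represses"),
      dst = nm$w_edges$tf, stringsAsFactors = FALSE)
  be <- binding_edges(nm$binding)
  if (nrow(be))
    rows[[length(rows) + 1L]] <- data.frame(
      src = be$tf, interaction = "binds", dst = be$gene,
      stringsAsFactors = FALSE)
  aut <- nm$autoreg[nm$autoreg != 0]
  if (length(aut))
    rows[[length(rows) + 1L]] <- data.frame(
      src = names(aut),
      interaction = ifelse(aut > 0, "activates", "represses"),
      dst = names(aut), stringsAsFactors = FALSE)
  if (nrow(nm$input_edges))
    rows[[length(rows) + 1L]] <- data.frame(
      src = nm$input_edges$input, interaction = "input",
      dst = nm$input_edges$gene, stringsAsFactors = FALSE)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(src = character(), interaction = character(), dst = character())
  out <- out[order(out$src, out$interaction, out$dst), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Nodes carry a `kind` attribute (`gene`, `tf`, `input`); edges carry
#' `kind`, `weight`, `prior_supported` and `origin` attributes. The output is
#' valid GraphML readable by Cytoscape or igraph.
#'
#' @param nm an `extilar_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(nm, path) {
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  key <- function(id, dom, name, type) {
    k <- xml2::xml_add_child(doc, "key")
    xml2::xml_set_attrs(k, c(id = id, `for` = dom,
                             attr.name = name, attr.type = type))
  }
  key("kind_n", "node", "kind", "string")
  key("kind_e", "edge", "kind", "string")
  key("weight", "edge", "weight", "double")
  key("prior", "edge", "prior_supported", "boolean")
  key("origin", "edge", "origin", "string")
  g <- xml2::xml_add_child(doc, "graph", id = "network", edgedefault = "directed")
  add_node <- function(id, kind) {
    n <- xml2::xml_add_child(g, "node", id = id)
    d <- xml2::xml_add_child(n, "data", key = "kind_n")
    xml2::xml_set_text(d, kind)
  }
  for (gene in nm$genes) add_node(gene, "gene")
  for (tf in nm$tfs) add_node(tf, "tf")
  for (u in nm$inputs) add_node(u$id, "input")
  add_edge <- function(src, dst, kind, weight = NA, prior = NA, origin = NA) {
    e <- xml2::xml_add_child(g, "edge", source = src, target = dst)
    dd <- xml2::xml_add_child(e, "data", key = "kind_e")
    xml2::xml_set_text(dd, kind)
    if (!is.na(weight)) {
      dd <- xml2::xml_add_child(e, "data", key = "weight")
      xml2::xml_set_text(dd, sprintf("%.12g", weight))
    }
    if (!is.na(prior)) {
      dd <- xml2::xml_add_child(e, "data", key = "prior")
      xml2::xml_set_text(dd, tolower(as.character(prior)))
    }
    if (!is.na(origin)) {
      dd <- xml2::xml_add_child(e, "data", key = "origin")
      xml2::xml_set_text(dd, origin)
    }
  }
  if (nrow(nm$w_edges))
    for (i in seq_len(nrow(nm$w_edges)))
      add_edge(nm$w_edges$source[i], nm$w_edges$tf[i], "gene_to_tf",
               weight = nm$w_edges$weight[i],
               prior = isTRUE(nm$w_edges$prior_supported[i]))
  be <- binding_edges(nm$binding)
  if (nrow(be))
    for (i in seq_len(nrow(be)))
      add_edge(be$tf[i], be$gene[i], "tf_to_gene", origin = be$origin[i])
  aut <- nm$autoreg[nm$autoreg != 0]
  for (g2 in names(aut)) add_edge(g2, g2, "autoreg", weight = aut[[g2]])
  if (nrow(nm$input_edges))
    for (i in seq_len(nrow(nm$input_edges)))
      add_edge(nm$input_edges$input[i], nm$input_edges$gene[i], "input",
               weight = nm$input_edges$weight[i])
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Export all coefficients and diagnostics as JSON
#'
#' Full machine-readable dump: genes, TFs, binding relations, gene-to-TF
#' edges, auto-regulation, input edges, input signal definitions and fit
#' diagnostics. Deterministic for identical models.
#'
#' @param nm an `extilar_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_network_json <- function(nm, path) {
  obj <- list(
    genes = nm$genes,
    tfs = nm$tfs,
    binding = binding_edges(nm$binding),
    gene_to_tf = nm$w_edges,
    autoreg = as.list(nm$autoreg[nm$autoreg != 0]),
    input_edges = nm$input_edges,
    inputs = lapply(nm$inputs, function(u)
      list(id = u$id, kind = u$kind, params = u$params)),
    diagnostics = nm$diagnostics[vapply(nm$diagnostics, is.numeric, TRUE)])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a network model from its JSON export
#' @param path path written by [export_network_json()].
#' @return an `extilar_network`.
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  inputs <- lapply(seq_len(NROW(obj$inputs)), function(i) {
    row <- if (is.data.frame(obj$inputs)) obj$inputs[i, ] else obj$inputs[[i]]
    params <- if (is.data.frame(row$params)) as.list(row$params) else row$params
    do.call(input_signal, c(list(kind = row$kind, id = row$id),
                            params %||% list()))
  })
  bm <- binding_matrix(obj$binding, genes = obj$genes)
  network_model(obj$genes, bm,
                w_edges = obj$gene_to_tf,
                autoreg = unlist(obj$autoreg),
                input_edges = obj$input_edges,
                inputs = inputs,
                diagnostics = as.list(obj$diagnostics))
}

#' Write a delta-sweep or weight-grid table as TSV
#' @param tab data frame from [delta_sweep()] or [weight_grid_study()].
#' @param path output file path.
#' @export
write_sweep_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
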