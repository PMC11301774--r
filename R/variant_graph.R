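# Variant graph: how sequence variations relative to the template are
# connected by peptide reads. One node per (template position, observed
# variant) where a read disagrees with the template; an edge whenever one
# read carries both variants, so co-occurring variants of one clone form
# connected components in polyclonal mixtures.

#' Build the variant graph for one template
#'
#' Walks every placed read's alignment and records each disagreement with
#' the template: mismatched single residues, and rotation/isobaric
#' residue-set steps (keyed at the step's start position, labelled with
#' the read's residue set). Node support counts reads carrying the
#' variant; an edge connects two variants co-occurring in the same read,
#' weighted by the number of such reads.
#'
#' @param placed_reads Placements from [match_to_templates()], all on one
#'   template.
#' @param template Template row or list with `sequence`.
#' @return An [igraph::igraph] with vertex attributes `position`
#'   (0-based), `variant`, `support`, and edge attribute `weight`.
#' @export
build_variant_graph <- function(placed_reads, template) {
  tpl <- strsplit(template$sequence, "")[[1]]
  node_support <- list()
  edge_count <- list()
  for (k in seq_len(nrow(placed_reads))) {
    aln <- placed_reads$alignment[[k]]
    rchars <- strsplit(placed_reads$sequence[k], "")[[1]]
    ti <- aln$template_start; ri <- aln$read_start
    st <- aln$steps
    variants <- character(0)
    for (s in seq_len(nrow(st))) {
      kind <- st$kind[s]
      lt <- st$len_template[s]; lr <- st$len_read[s]
      if (kind == "mismatch") {
        key <- paste0(ti, ":", rchars[ri + 1])
        variants <- c(variants, key)
      } else if (kind %in% c("rotation", "isobaric")) {
        key <- paste0(ti, ":",
                      set_label(paste(rchars[(ri + 1):(ri + lr)],
                                      collapse = "")))
        variants <- c(variants, key)
      } else if (kind == "match" && tpl[ti + 1] == "X") {
        # wildcard positions are not variants
      }
      ti <- ti + lt; ri <- ri + lr
    }
    variants <- unique(variants)
    for (v in variants) {
      node_support[[v]] <- (node_support[[v]] %||% 0L) + 1L
    }
    if (length(variants) >= 2L) {
      pairs <- utils::combn(sort(variants), 2L)
      for (c2 in seq_len(ncol(pairs))) {
        ek <- paste(pairs[1, c2], pairs[2, c2], sep = "|")
        edge_count[[ek]] <- (edge_count[[ek]] %||% 0L) + 1L
      }
    }
  }
  nodes <- sort(names(node_support))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  if (length(nodes)) {
    pos <- as.integer(sub(":.*$", "", nodes))
    var <- sub("^[0-9]+:", "", nodes)
    g <- igraph::set_vertex_attr(g, "name", value = nodes)
    g <- igraph::set_vertex_attr(g, "position", value = pos)
    g <- igraph::set_vertex_attr(g, "variant", value = var)
    g <- igraph::set_vertex_attr(g, "support",
                                 value = unlist(node_support[nodes]))
    if (length(edge_count)) {
      eks <- sort(names(edge_count))
      ends <- do.call(rbind, strsplit(eks, "|", fixed = TRUE))
      g <- igraph::add_edges(
        g, as.vector(t(cbind(match(ends[, 1], nodes),
                             match(ends[, 2], nodes)))))
      g <- igraph::set_edge_attr(g, "weight",
                                 value = unlist(edge_count[eks]))
    }
  }
  g
}

#' Export a variant graph as DOT
#'
#' @param graph Variant graph from [build_variant_graph()].
#' @param path Output file.
#' @export
write_variant_graph_dot <- function(graph, path) {
  igraph::write_graph(graph, path, format = "dot")
  invisible(path)
}

#' Export a variant graph as JSON node-link data
#'
#' @param graph Variant graph from [build_variant_graph()].
#' @param path Output file.
#' @export
write_variant_graph_json <- function(graph, path) {
  nodes <- data.frame(
    id = igraph::V(graph)$name %||% character(0),
    position = igraph::V(graph)$position %||% integer(0),
    variant = igraph::V(graph)$variant %||% character(0),
    support = igraph::V(graph)$support %||% integer(0),
    stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(graph)
  links <- data.frame(source = el[, 1], target = el[, 2],
                      weight = igraph::E(graph)$weight %||% integer(0),
                      stringsAsFactors = FALSE)
  jsonlite::write_json(list(nodes = nodes, links = links), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
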