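# The bipartite association network: molecule and microbe nodes, one edge
# per retained association.

#' Build the bipartite association network
#'
#' Nodes are exactly the features incident to at least one edge; molecule
#' nodes carry m/z (and annotation when supplied), microbe nodes carry
#' taxonomy when supplied.  Bipartiteness is asserted on every build.
#'
#' @param edges Edge table from [association_scan()] (columns
#'   `molecule_id`, `microbe_id`, `mz`, `test`, `statistic`, `p_value`,
#'   `sign`).
#' @param taxonomy Optional named character vector: taxonomy string per
#'   microbe id.
#' @param annotation Optional named character vector: annotation per
#'   molecule id.
#' @return An undirected `igraph` graph with vertex attributes `kind`
#'   (`"molecule"`/`"microbe"`), logical `type` (TRUE for molecules, the
#'   igraph bipartite convention), `mz`, `taxonomy`, and the edge
#'   attributes of `edges`.
#' @export
build_network <- function(edges, taxonomy = NULL, annotation = NULL) {
  mols <- unique(edges$molecule_id)
  mics <- unique(edges$microbe_id)
  clash <- intersect(mols, mics)
  if (length(clash))
    abort("ids on both sides break bipartiteness: ",
          paste(utils::head(clash, 3L), collapse = ", "))
  mz_by_mol <- tapply(edges$mz, edges$molecule_id, function(v) v[1L])
  vertices <- data.frame(
    name = c(mols, mics),
    kind = rep(c("molecule", "microbe"), c(length(mols), length(mics))),
    type = rep(c(TRUE, FALSE), c(length(mols), length(mics))),
    mz = c(unname(mz_by_mol[mols]), rep(NA_real_, length(mics))),
    taxonomy = c(rep(NA_character_, length(mols)),
                 if (is.null(taxonomy)) rep(NA_character_, length(mics))
                 else unname(taxonomy[mics])),
    annotation = c(if (is.null(annotation)) rep(NA_character_, length(mols))
                   else unname(annotation[mols]),
                   rep(NA_character_, length(mics))),
    stringsAsFactors = FALSE)
  eattr <- as.data.frame(edges[, c("molecule_id", "microbe_id", "test",
                                   "statistic", "p_value", "sign")])
  names(eattr)[1:2] <- c("from", "to")
  g <- igraph::graph_from_data_frame(eattr, directed = FALSE,
                                     vertices = vertices)
  if (igraph::ecount(g) > 0) {
    ends <- igraph::ends(g, igraph::E(g))
    kinds <- igraph::V(g)$kind
    names(kinds) <- igraph::V(g)$name
    if (any(kinds[ends[, 1]] == kinds[ends[, 2]]))
      abort("network is not bipartite")
  }
  g
}

#' Connected modules of the association network
#'
#' Connected components with at least `min_size` nodes, largest first (ties
#' broken by the smallest contained node id, for determinism).
#'
#' @param net Graph from [build_network()].
#' @param min_size Minimum component size (default 2, one edge).
#' @return List of character vectors of node names.
#' @export
connected_modules <- function(net, min_size = 2L) {
  comp <- igraph::components(net)
  mods <- split(igraph::V(net)$name, comp$membership)
  mods <- mods[lengths(mods) >= min_size]
  first <- vapply(mods, function(m) min(m), character(1))
  mods <- mods[order(-lengths(mods), first)]
  unname(mods)
}

#' Collapse network nodes by a grouping key
#'
#' Optional coarse view: merges nodes that share a key (for example a
#' taxonomy prefix at family level, or an annotation naming the same
#' molecule).  Edges between merged groups are contracted; parallel edges
#' keep the smallest P value.
#'
#' @param net Graph from [build_network()].
#' @param key Named character vector: group label per node name; nodes
#'   without a key keep their own name.
#' @return Collapsed `igraph` graph.
#' @export
collapse_nodes <- function(net, key) {
  nm <- igraph::V(net)$name
  lab <- ifelse(is.na(key[nm]) | !nm %in% names(key), nm, key[nm])
  g <- igraph::contract(net, factor(lab, levels = unique(lab)),
                        vertex.attr.comb = list(name = function(x) x[1L],
                                                kind = function(x) x[1L],
                                                type = function(x) x[1L],
                                                "first"))
  igraph::V(g)$name <- unique(lab)
  igraph::simplify(g, edge.attr.comb = list(p_value = "min",
                                            statistic = "first",
                                            test = "first", sign = "first"))
}

#' Export the association network
#'
#' @param net Graph from [build_network()].
#' @param path Output path.
#' @param format `"graphml"` (typed node/edge attributes) or `"edge_tsv"`
#'   (flat edge list with the scan columns plus a component id).
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "edge_tsv")) {
  if (is.character(format) && length(format) == 1L &&
      !format %in% c("graphml", "edge_tsv"))
    abort("unknown export format: ", format)
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    e <- igraph::as_data_frame(net, what = "edges")
    v <- igraph::as_data_frame(net, what = "vertices")
    kind <- stats::setNames(v$kind, v$name)
    mz <- stats::setNames(v$mz, v$name)
    swap <- kind[e$from] != "molecule"
    tmp <- e$from[swap]; e$from[swap] <- e$to[swap]; e$to[swap] <- tmp
    comp <- igraph::components(net)$membership
    out <- data.frame(molecule_id = e$from, microbe_id = e$to,
                      mz = unname(mz[e$from]),
                      test = e$test, statistic = e$statistic,
                      p_value = e$p_value, sign = e$sign,
                      component = unname(comp[e$from]),
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Import a network written by [export_network()]
#'
#' @param path File path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @return An `igraph` graph; for `"edge_tsv"` the network is rebuilt with
#'   [build_network()] and round-trips it exactly.
#' @export
import_network <- function(path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if ("id" %in% igraph::vertex_attr_names(g))
      g <- igraph::delete_vertex_attr(g, "id")
    g
  } else {
    e <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = c(molecule_id = "character",
                                          microbe_id = "character"))
    build_network(tibble::as_tibble(e))
  }
}
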