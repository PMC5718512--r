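#' Build a levelled knowledge graph from node and edge tables
#'
#' The levelled knowledge graph is the container every other function in the
#' package operates on. Nodes belong to exactly one of five levels --
#' compound, reaction, enzyme, module, pathway -- and edges link entities
#' across levels (a compound participating in a reaction, a reaction
#' catalysed by an enzyme, and so on). Two views of the same edge set are
#' kept: an undirected view used by heat diffusion, and a directed view in
#' which every edge points from the lower level towards the strictly higher
#' one (compound < reaction < enzyme < module < pathway), used by PageRank
#' and by reachability-based pathway membership.
#'
#' The edge schema accepts any cross-level edge but warns on pairs other
#' than compound-reaction, reaction-enzyme, enzyme-module, module-pathway
#' and the enzyme-pathway shortcut. Edges between two nodes of the same
#' level (including self-loops) are rejected: they cannot be oriented by
#' level and the knowledge-base schema has no use for them. Duplicate edges
#' are collapsed with a warning.
#'
#' @param nodes Data frame with columns `id` (unique identifier), `level`
#'   (one of `"compound"`, `"reaction"`, `"enzyme"`, `"module"`,
#'   `"pathway"`), and optionally `name` (display label).
#' @param edges Data frame whose first two columns are the edge endpoints
#'   (conventionally `source` and `target`); every endpoint must appear in
#'   `nodes$id`.
#' @param restrict_to_largest_cc Keep only the largest connected component
#'   (default `TRUE`). The scoring model assumes a single connected working
#'   graph; with `FALSE` a disconnected graph is returned with a warning.
#'
#' @return An object of class `levelled_graph`: a list with elements
#'   `graph` (undirected [igraph][igraph::graph] with a `level` vertex
#'   attribute), `directed` (the level-oriented view over the same edges),
#'   `nodes` (tibble `id`, `level`, `name`), and `level_counts` (named
#'   integer vector).
#'
#' @examples
#' nodes <- tibble::tibble(
#'   id = c("c1", "r1", "p1"),
#'   level = c("compound", "reaction", "pathway")
#' )
#' edges <- tibble::tibble(source = c("c1", "r1"), target = c("r1", "p1"))
#' lg <- levelled_graph(nodes, edges)
#' lg$level_counts
#' @export
levelled_graph <- function(nodes, edges, restrict_to_largest_cc = TRUE) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  if (!all(c("id", "level") %in% names(nodes))) {
    abort("`nodes` must have columns `id` and `level`.")
  }
  if (ncol(edges) < 2) {
    abort("`edges` must have at least two columns (source, target).")
  }
  nodes$id <- as.character(nodes$id)
  nodes$level <- as.character(nodes$level)
  if (!"name" %in% names(nodes)) nodes$name <- nodes$id
  nodes <- nodes[, c("id", "level", "name")]

  bad_level <- setdiff(unique(nodes$level), .levels)
  if (length(bad_level) > 0) {
    abort(paste0(
      "Unknown level label(s): ", paste(bad_level, collapse = ", "),
      ". Levels must be one of: ", paste(.levels, collapse = ", "), "."
    ))
  }
  if (anyDuplicated(nodes$id)) {
    abort(paste0(
      "Duplicated node id(s): ",
      paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", ")
    ))
  }

  src <- as.character(edges[[1]])
  tgt <- as.character(edges[[2]])
  missing_ep <- !(src %in% nodes$id) | !(tgt %in% nodes$id)
  if (any(missing_ep)) {
    i <- which(missing_ep)[1]
    bad <- setdiff(c(src[i], tgt[i]), nodes$id)
    abort(paste0(
      "Edge row ", which(missing_ep)[1], " (", src[i], ", ", tgt[i],
      ") references unknown node id(s): ", paste(bad, collapse = ", ")
    ))
  }

  lev <- setNames(nodes$level, nodes$id)
  same_level <- lev[src] == lev[tgt]
  if (any(same_level)) {
    i <- which(same_level)[1]
    abort(paste0(
      "Edge (", src[i], ", ", tgt[i], ") links two ", lev[src[i]],
      " nodes; edges must cross levels."
    ))
  }
  pair <- .pair_key(lev[src], lev[tgt])
  off_schema <- !(pair %in% .schema_pairs)
  if (any(off_schema)) {
    warn(paste0(
      sum(off_schema), " edge(s) link non-schema level pairs (",
      paste(unique(pair[off_schema]), collapse = ", "),
      "); kept, but the usual schema is ",
      paste(.schema_pairs, collapse = ", "), "."
    ))
  }

  # canonical (lower level first) form for dedup
  lo_first <- match(lev[src], .levels) <= match(lev[tgt], .levels)
  from <- ifelse(lo_first, src, tgt)
  to <- ifelse(lo_first, tgt, src)
  dup <- duplicated(paste(from, to, sep = "\r"))
  if (any(dup)) {
    warn(paste0(sum(dup), " duplicate edge(s) collapsed."))
    from <- from[!dup]
    to <- to[!dup]
  }

  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = as.data.frame(nodes)
  )

  if (restrict_to_largest_cc) {
    comp <- igraph::components(g)
    if (comp$no > 1) {
      keep <- which(comp$membership == which.max(comp$csize))
      g <- igraph::induced_subgraph(g, keep)
      nodes <- nodes[nodes$id %in% igraph::V(g)$name, ]
    }
  } else if (!igraph::is_connected(g)) {
    warn("Graph is not connected; diffusion scoring requires a connected graph.")
  }

  new_levelled_graph(g, nodes)
}

# internal constructor from a validated undirected igraph + node tibble
new_levelled_graph <- function(g, nodes) {
  nodes <- nodes[match(igraph::V(g)$name, nodes$id), ]
  directed <- orient_by_level(g)
  counts <- table(factor(nodes$level, levels = .levels))
  structure(
    list(
      graph = g,
      directed = directed,
      nodes = tibble::as_tibble(nodes),
      level_counts = setNames(as.integer(counts), names(counts))
    ),
    class = "levelled_graph"
  )
}

# orient every undirected edge from the lower level to the higher one
orient_by_level <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  lev <- setNames(igraph::V(g)$level, igraph::V(g)$name)
  lo_first <- match(lev[el[, 1]], .levels) <= match(lev[el[, 2]], .levels)
  from <- ifelse(lo_first, el[, 1], el[, 2])
  to <- ifelse(lo_first, el[, 2], el[, 1])
  vdf <- data.frame(
    name = igraph::V(g)$name,
    level = igraph::V(g)$level,
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = TRUE, vertices = vdf
  )
}

#' @export
print.levelled_graph <- function(x, ...) {
  cat("Levelled knowledge graph\n")
  cat("  nodes:", sum(x$level_counts), " edges:", igraph::ecount(x$graph), "\n")
  cat("  levels:",
      paste(sprintf("%s=%d", names(x$level_counts), x$level_counts),
            collapse = ", "), "\n")
  invisible(x)
}

#' Node table of a levelled graph
#'
#' @param graph A [levelled_graph].
#' @return Tibble with columns `id`, `level`, `name`, `degree`.
#' @export
node_table <- function(graph) {
  stopifnot(inherits(graph, "levelled_graph"))
  dplyr::mutate(graph$nodes, degree = igraph::degree(graph$graph))
}

#' Read a levelled graph from node and edge TSV files
#'
#' The node table must have a header `id  level  name` (name optional) and
#' the edge table a header `source  target`.
#'
#' @param node_file,edge_file Paths to tab-separated tables.
#' @inheritParams levelled_graph
#' @return A [levelled_graph].
#' @export
read_levelled_graph <- function(node_file, edge_file,
                                restrict_to_largest_cc = TRUE) {
  nodes <- readr::read_tsv(node_file, col_types = readr::cols(.default = "c"))
  edges <- readr::read_tsv(edge_file, col_types = readr::cols(.default = "c"))
  levelled_graph(nodes, edges, restrict_to_largest_cc = restrict_to_largest_cc)
}

#' Write a levelled graph as node and edge TSV tables
#'
#' @param graph A [levelled_graph].
#' @param node_file,edge_file Output paths.
#' @return `graph`, invisibly.
#' @export
write_graph_tables <- function(graph, node_file, edge_file) {
  stopifnot(inherits(graph, "levelled_graph"))
  readr::write_tsv(graph$nodes, node_file)
  el <- igraph::as_edgelist(graph$directed, names = TRUE)
  readr::write_tsv(
    tibble::tibble(source = el[, 1], target = el[, 2]), edge_file
  )
  invisible(graph)
}

#' Read or write a levelled graph in GraphML format
#'
#' The `level` node attribute is preserved; on read it is validated against
#' the five-level schema.
#'
#' @param file Path to a GraphML file.
#' @inheritParams levelled_graph
#' @return `read_levelled_graphml()` returns a [levelled_graph];
#'   `write_levelled_graphml()` returns `graph` invisibly.
#' @export
read_levelled_graphml <- function(file, restrict_to_largest_cc = TRUE) {
  g <- igraph::read_graph(file, format = "graphml")
  if (is.null(igraph::vertex_attr(g, "level"))) {
    abort("GraphML file has no `level` node attribute.")
  }
  nodes <- tibble::tibble(
    id = igraph::V(g)$name,
    level = igraph::V(g)$level,
    name = igraph::vertex_attr(g, "label") %||% igraph::V(g)$name
  )
  el <- igraph::as_edgelist(g, names = TRUE)
  levelled_graph(nodes, tibble::tibble(source = el[, 1], target = el[, 2]),
                 restrict_to_largest_cc = restrict_to_largest_cc)
}

#' @rdname read_levelled_graphml
#' @export
write_levelled_graphml <- function(graph, file) {
  stopifnot(inherits(graph, "levelled_graph"))
  g <- graph$graph
  igraph::V(g)$label <- graph$nodes$name
  igraph::write_graph(g, file, format = "graphml")
  invisible(graph)
}

#' Read a compound list from a plain-text file
#'
#' One identifier per line; blank lines and `#` comments are ignored.
#'
#' @param file Path to the list.
#' @return Character vector of identifiers.
#' @export
read_compound_list <- function(file) {
  x <- readr::read_lines(file)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Map a list of compound identifiers onto a graph
#'
#' Matches the user's identifiers against the graph's compound nodes.
#' Identifiers that are absent from the graph, or that match a node of a
#' different level, are dropped and reported with a message -- partial
#' overlap between an experimental compound list and the knowledge base is
#' the normal situation, not an error. Matching nothing at all is an error,
#' since there is nothing to diffuse from.
#'
#' @param graph A [levelled_graph].
#' @param ids Character vector of compound identifiers (duplicates allowed).
#' @return An object of class `input_set`: list with `compound_ids`
#'   (matched, deduplicated), `n_in` (their count) and `dropped`
#'   (identifiers not usable).
#' @export
map_input <- function(graph, ids) {
  stopifnot(inherits(graph, "levelled_graph"))
  ids <- as.character(ids)
  if (length(ids) == 0) abort("`ids` is empty.")
  ids <- unique(ids)
  compounds <- graph$nodes$id[graph$nodes$level == "compound"]
  matched <- ids[ids %in% compounds]
  dropped <- setdiff(ids, matched)
  if (length(matched) == 0) {
    abort("None of the identifiers match a compound node in the graph.")
  }
  if (length(dropped) > 0) {
    inform(paste0(
      length(dropped), " identifier(s) not mapped to graph compounds: ",
      paste(head(dropped, 10), collapse = ", "),
      if (length(dropped) > 10) ", ..." else ""
    ))
  }
  structure(
    list(compound_ids = matched, n_in = length(matched), dropped = dropped),
    class = "input_set"
  )
}

#' @export
print.input_set <- function(x, ...) {
  cat("Input set:", x$n_in, "mapped compound(s)")
  if (length(x$dropped)) cat(",", length(x$dropped), "dropped")
  cat("\n")
  invisible(x)
}
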