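#' Extract the reaction-compound graph
#'
#' The unweighted subgraph induced on the reaction and compound nodes,
#' restricted to its largest connected component. Resistance distances for
#' validating reported reactions are computed on this graph: it captures
#' the chemistry (which compounds interconvert through which reactions)
#' without the annotation levels above.
#'
#' @param graph A [levelled_graph] with at least one reaction and one
#'   compound.
#' @return Object of class `rc_graph`: list with `graph` (igraph), `ids`,
#'   `levels`, and a cache environment for the Laplacian pseudoinverse.
#' @export
reaction_compound_graph <- function(graph) {
  stopifnot(inherits(graph, "levelled_graph"))
  keep <- graph$nodes$level %in% c("reaction", "compound")
  if (sum(graph$nodes$level == "reaction") == 0) {
    abort("Graph has no reaction nodes.")
  }
  if (sum(graph$nodes$level == "compound") == 0) {
    abort("Graph has no compound nodes.")
  }
  sub <- igraph::induced_subgraph(graph$graph, which(keep))
  comp <- igraph::components(sub)
  if (comp$no > 1) {
    sub <- igraph::induced_subgraph(
      sub, which(comp$membership == which.max(comp$csize))
    )
  }
  if (igraph::vcount(sub) == 0) abort("Induced reaction-compound graph is empty.")
  structure(
    list(
      graph = sub,
      ids = igraph::V(sub)$name,
      levels = igraph::V(sub)$level,
      cache = new.env(parent = emptyenv())
    ),
    class = "rc_graph"
  )
}

#' @export
print.rc_graph <- function(x, ...) {
  cat("Reaction-compound graph:", length(x$ids), "nodes (",
      sum(x$levels == "reaction"), "reactions,",
      sum(x$levels == "compound"), "compounds ),",
      igraph::ecount(x$graph), "edges\n")
  invisible(x)
}

# Moore-Penrose pseudoinverse of the rc-graph Laplacian, cached
lap_pinv <- function(rc_graph) {
  if (is.null(rc_graph$cache$Lplus)) {
    L <- as.matrix(igraph::laplacian_matrix(rc_graph$graph, sparse = TRUE))
    rc_graph$cache$Lplus <- MASS::ginv(L)
    dimnames(rc_graph$cache$Lplus) <- list(rc_graph$ids, rc_graph$ids)
  }
  rc_graph$cache$Lplus
}

#' Effective resistance distance between two nodes
#'
#' Treats every edge as a unit resistor; the distance between `i` and `j`
#' is the effective resistance of the network between them,
#' `Omega(i, j) = L+_ii + L+_jj - 2 L+_ij` with `L+` the Moore-Penrose
#' pseudoinverse of the graph Laplacian. Unlike shortest paths it shrinks
#' when many parallel routes exist, making it robust to hub-dominated
#' paths. The `"grounded"` route solves the Kirchhoff system directly
#' (unit current injected at `j`, node `i` grounded) and exists as an
#' independent computation path; both agree to solver tolerance.
#'
#' @param rc_graph An [rc_graph][reaction_compound_graph].
#' @param i,j Node ids in the graph.
#' @param method `"pseudoinverse"` (cached, good for many queries) or
#'   `"grounded"` (sparse solve per query).
#' @return A nonnegative number; 0 iff `i == j`.
#' @export
resistance_distance <- function(rc_graph, i, j,
                                method = c("pseudoinverse", "grounded")) {
  stopifnot(inherits(rc_graph, "rc_graph"))
  method <- match.arg(method)
  missing <- setdiff(c(i, j), rc_graph$ids)
  if (length(missing) > 0) {
    abort(paste0("Node(s) not in the reaction-compound graph: ",
                 paste(missing, collapse = ", ")))
  }
  if (i == j) return(0)
  if (method == "pseudoinverse") {
    Lp <- lap_pinv(rc_graph)
    Lp[i, i] + Lp[j, j] - 2 * Lp[i, j]
  } else {
    L <- igraph::laplacian_matrix(rc_graph$graph, sparse = TRUE)
    gi <- match(i, rc_graph$ids)
    gj <- match(j, rc_graph$ids)
    M <- L[-gi, -gi, drop = FALSE]
    e <- numeric(nrow(M))
    jj <- if (gj > gi) gj - 1L else gj
    e[jj] <- 1
    x <- Matrix::solve(M, e)
    as.numeric(x[jj])
  }
}

#' Summarise resistance distances from a reaction set to target compounds
#'
#' For each target compound, the mean and standard deviation of the
#' resistance distances from every reaction in the set. Nodes absent from
#' the reaction-compound graph are dropped with a warning (the validation
#' is silently restricted to the connected chemistry, as the distances are
#' undefined elsewhere).
#'
#' @param rc_graph An [rc_graph][reaction_compound_graph].
#' @param reaction_set Character vector of reaction ids (e.g. the
#'   reactions in a reported solution).
#' @param target_compounds Character vector of compound ids (e.g. an
#'   independently measured metabolite set).
#' @return Tibble `target`, `n_reactions`, `mean`, `sd`.
#' @export
reaction_distance_summary <- function(rc_graph, reaction_set,
                                      target_compounds) {
  stopifnot(inherits(rc_graph, "rc_graph"))
  reaction_set <- unique(reaction_set)
  target_compounds <- unique(target_compounds)
  dropped <- setdiff(c(reaction_set, target_compounds), rc_graph$ids)
  if (length(dropped) > 0) {
    warn(paste0(length(dropped),
                " node(s) absent from the reaction-compound graph dropped: ",
                paste(head(dropped, 5), collapse = ", ")))
  }
  reaction_set <- intersect(reaction_set, rc_graph$ids)
  target_compounds <- intersect(target_compounds, rc_graph$ids)
  if (length(reaction_set) == 0) {
    abort("No reactions left after dropping absent nodes.")
  }
  if (length(target_compounds) == 0) {
    abort("No target compounds left after dropping absent nodes.")
  }
  D <- resistance_matrix(rc_graph, reaction_set, target_compounds)
  tibble::tibble(
    target = target_compounds,
    n_reactions = length(reaction_set),
    mean = unname(colMeans(D)),
    sd = unname(apply(D, 2, sd))
  )
}

# dense distance block rows x cols via the cached pseudoinverse
resistance_matrix <- function(rc_graph, rows, cols) {
  Lp <- lap_pinv(rc_graph)
  d <- diag(Lp)
  outer(d[rows], d[cols], "+") - 2 * Lp[rows, cols, drop = FALSE]
}

#' Compare reported reactions to the input's first-neighbour reactions
#'
#' The first-neighbour set contains every reaction adjacent to any input
#' compound -- the reactions one would flag without any diffusion model.
#' For each target compound, a one-sided Mann-Whitney rank-sum test asks
#' whether the reported reactions sit closer (smaller resistance
#' distance) to the target than the first neighbours do; p-values are
#' Benjamini-Hochberg adjusted across all (solution x target)
#' comparisons. Comparisons where either side has fewer than 2 distances
#' are skipped and flagged.
#'
#' @param rc_graph An [rc_graph][reaction_compound_graph].
#' @param reported_reactions Character vector of reaction ids, or a named
#'   list of such vectors (one per solution).
#' @param input_compounds Compound ids of the original input (defines the
#'   first-neighbour reactions).
#' @param target_compounds Independent compound set to measure distances
#'   to.
#' @return Tibble `solution`, `target`, `n_reported`, `n_neighbour`,
#'   `mean_reported`, `mean_neighbour`, `p`, `p_adj`, `skipped`.
#' @export
neighbour_comparison <- function(rc_graph, reported_reactions,
                                 input_compounds, target_compounds) {
  stopifnot(inherits(rc_graph, "rc_graph"))
  if (!is.list(reported_reactions)) {
    reported_reactions <- list(solution = reported_reactions)
  }
  if (is.null(names(reported_reactions))) {
    names(reported_reactions) <- paste0("solution",
                                        seq_along(reported_reactions))
  }
  input_compounds <- intersect(unique(input_compounds), rc_graph$ids)
  if (length(input_compounds) == 0) {
    abort("No input compounds present in the reaction-compound graph.")
  }
  nb <- igraph::adjacent_vertices(
    rc_graph$graph, match(input_compounds, rc_graph$ids)
  )
  neighbours <- unique(unlist(lapply(nb, function(v) v$name)))
  neighbours <- neighbours[
    rc_graph$levels[match(neighbours, rc_graph$ids)] == "reaction"
  ]
  target_compounds <- intersect(unique(target_compounds), rc_graph$ids)
  if (length(target_compounds) == 0) {
    abort("No target compounds present in the reaction-compound graph.")
  }
  D_nb <- resistance_matrix(rc_graph, neighbours, target_compounds)

  rows <- purrr::map_dfr(names(reported_reactions), function(sol) {
    rset <- intersect(unique(reported_reactions[[sol]]), rc_graph$ids)
    rset <- rset[rc_graph$levels[match(rset, rc_graph$ids)] == "reaction"]
    if (length(rset) == 0) {
      abort(paste0("Solution `", sol, "` has no reactions in the graph."))
    }
    D_rep <- resistance_matrix(rc_graph, rset, target_compounds)
    purrr::map_dfr(seq_along(target_compounds), function(ti) {
      x <- D_rep[, ti]
      y <- D_nb[, ti]
      skipped <- length(x) < 2 || length(y) < 2
      p <- if (skipped) NA_real_ else {
        suppressWarnings(
          wilcox.test(x, y, alternative = "less", exact = FALSE)$p.value
        )
      }
      tibble::tibble(
        solution = sol, target = target_compounds[ti],
        n_reported = length(x), n_neighbour = length(y),
        mean_reported = mean(x), mean_neighbour = mean(y),
        p = p, skipped = skipped
      )
    })
  })
  rows$p_adj <- NA_real_
  ok <- !rows$skipped
  rows$p_adj[ok] <- p.adjust(rows$p[ok], method = "BH")
  rows
}
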