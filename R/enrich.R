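#' Pathway membership by directed reachability
#'
#' A compound belongs to a pathway when the pathway can be reached from it
#' in the level-directed view (compound -> reaction -> enzyme -> module ->
#' pathway, plus enzyme -> pathway shortcuts). This reachability rule --
#' rather than direct annotation edges -- is what the over-representation
#' baseline and the proportional signal scheme use, and it lets a pathway
#' have enzyme-only membership paths.
#'
#' @param graph A [levelled_graph].
#' @return Named list mapping each pathway id to the character vector of
#'   member compound ids (possibly empty).
#' @export
pathway_compounds <- function(graph) {
  stopifnot(inherits(graph, "levelled_graph"))
  compounds <- graph$nodes$id[graph$nodes$level == "compound"]
  pathways <- graph$nodes$id[graph$nodes$level == "pathway"]
  if (length(pathways) == 0) return(setNames(list(), character(0)))
  d <- igraph::distances(graph$directed, v = compounds, to = pathways,
                         mode = "out")
  lapply(setNames(pathways, pathways), function(p) {
    compounds[is.finite(d[, p])]
  })
}

#' One-tailed hypergeometric over-representation test for a pathway
#'
#' The classical ORA baseline: with `N` compounds in the graph, `K` of
#' them members of the pathway (by directed reachability), and an input of
#' `n_in` compounds showing `hits` members, the p-value is
#' `P(X >= hits)` for `X ~ Hypergeometric(N, K, n_in)`. This is exactly
#' the null distribution of the pathway's diffusion temperature on a
#' bipartite single-membership graph, which is how ORA arises as a special
#' case of the diffusion-plus-null-model approach.
#'
#' @param graph A [levelled_graph].
#' @param input An `input_set` or character vector of compound ids.
#' @param pathway A pathway node id.
#' @param membership Optional cached result of [pathway_compounds()].
#' @return A single p-value.
#' @export
ora_pathway_test <- function(graph, input, pathway, membership = NULL) {
  stopifnot(inherits(graph, "levelled_graph"))
  lev <- graph$nodes$level[match(pathway, graph$nodes$id)]
  if (is.na(lev) || lev != "pathway") {
    abort(paste0("`", pathway, "` is not a pathway node."))
  }
  ids <- input_ids(input)
  compounds <- graph$nodes$id[graph$nodes$level == "compound"]
  check_input_ids(ids, compounds)
  members <- (membership %||% pathway_compounds(graph))[[pathway]]
  N <- length(compounds)
  K <- length(members)
  hits <- length(intersect(ids, members))
  phyper(hits - 1, K, N - K, length(ids), lower.tail = FALSE)
}

#' Select the k best nodes from normalised scores
#'
#' Ranking key: descending z for `norm` results, ascending p for `sim`
#' results; ties broken by descending raw score, then by node id --
#' deterministic, never random. Degenerate nodes (`z = NA`) are not
#' rankable; when fewer than `k` rankable nodes exist the selection is
#' truncated with a warning.
#'
#' @param scores Tibble from [zscore_normalise()] or
#'   [monte_carlo_pvalues()].
#' @param k Number of nodes to keep (>= 1).
#' @return Character vector of selected node ids.
#' @export
select_top_k <- function(scores, k) {
  if (k < 1) abort("`k` must be >= 1.")
  if ("z" %in% names(scores)) {
    ok <- !is.na(scores$z)
    key <- -scores$z
  } else if ("p" %in% names(scores)) {
    ok <- rep(TRUE, nrow(scores))
    key <- scores$p
  } else {
    abort("`scores` has neither a `z` nor a `p` column.")
  }
  rankable <- scores[ok, ]
  key <- key[ok]
  if (k > nrow(rankable)) {
    warn(paste0("Only ", nrow(rankable), " rankable node(s); k truncated."))
    k <- nrow(rankable)
  }
  ord <- order(key, -rankable$score, rankable$id)
  rankable$id[ord][seq_len(k)]
}

#' Connected-component summary of a subgraph
#'
#' Weak connected components: spurious isolated picks show up as many
#' small components, a coherent biological perturbation as one large one.
#'
#' @param subgraph An igraph object (typically the induced solution
#'   subgraph).
#' @return Tibble with `n_cc` and `largest_cc`.
#' @export
cc_summary <- function(subgraph) {
  if (igraph::vcount(subgraph) == 0) {
    return(tibble::tibble(n_cc = 0L, largest_cc = 0L))
  }
  comp <- igraph::components(subgraph, mode = "weak")
  tibble::tibble(n_cc = comp$no, largest_cc = as.integer(max(comp$csize)))
}

#' Overlap coefficient between two node sets
#'
#' `|A intersect B| / min(|A|, |B|)`: 1 when the smaller set is contained
#' in the larger, 0 when disjoint.
#'
#' @param set1,set2 Non-empty character vectors.
#' @return A number in \[0, 1\].
#' @export
overlap_coefficient <- function(set1, set2) {
  set1 <- unique(set1)
  set2 <- unique(set2)
  if (length(set1) == 0 || length(set2) == 0) {
    abort("Overlap coefficient is undefined for empty sets.")
  }
  length(intersect(set1, set2)) / min(length(set1), length(set2))
}

#' Run the full enrichment pipeline
#'
#' Scores every node from the input compounds, normalises against the
#' random-input null, selects the top `k` nodes and reports the induced
#' subgraph with its connected-component summary and a pathway table.
#'
#' With `approx = "norm"` the null is the closed-form one (z-scores); with
#' `approx = "sim"`, `n_vote` independent Monte-Carlo runs of `n_perm`
#' permutations each report their own top-k set and a strict-majority
#' consensus is kept, so the reported size may differ slightly from `k`.
#'
#' @param graph A connected [levelled_graph].
#' @param input An `input_set` from [map_input()] or a character vector of
#'   compound ids.
#' @param method `"hd"` (heat diffusion) or `"pr"` (PageRank).
#' @param approx `"norm"` (analytic z-scores) or `"sim"` (Monte-Carlo
#'   p-values with consensus).
#' @param k Desired solution size (default 250).
#' @param n_perm Permutations per Monte-Carlo run (default 10000).
#' @param n_vote Number of Monte-Carlo runs entering the consensus
#'   (default 9).
#' @param seed Master seed for the permutation streams.
#' @param damping PageRank damping factor (default 0.85).
#' @param response Optional precomputed [response_matrix].
#' @return Object of class `enrichment`: list with `scores` (per-node
#'   tibble), `selected` (node ids), `subgraph` (induced undirected
#'   igraph), `cc` (tibble from [cc_summary()]), `pathways` (per-pathway
#'   tibble with statistic and hit counts), and `params`.
#' @examples
#' lg <- generate_synthetic_graph(
#'   level_sizes = c(pathway = 3, module = 3, enzyme = 6,
#'                   reaction = 12, compound = 20),
#'   seed = 7
#' )
#' inp <- map_input(lg, lg$nodes$id[lg$nodes$level == "compound"][1:4])
#' res <- enrich(lg, inp, method = "hd", approx = "norm", k = 10)
#' glance(res)
#' @export
enrich <- function(graph, input, method = c("hd", "pr"),
                   approx = c("norm", "sim"), k = 250,
                   n_perm = 10000, n_vote = 9, seed = 1,
                   damping = 0.85, response = NULL) {
  stopifnot(inherits(graph, "levelled_graph"))
  method <- match.arg(method)
  approx <- match.arg(approx)
  if (k > nrow(graph$nodes)) abort("`k` exceeds the number of nodes.")
  input <- if (inherits(input, "input_set")) input else map_input(graph, input)

  response <- response %||% build_response(graph, method, damping)

  if (approx == "norm") {
    observed <- response_scores(response, input)
    moments <- null_input_moments(length(response$compound_ids), input$n_in)
    null <- analytic_null_moments(response, moments)
    scores <- zscore_normalise(observed, null)
    selected <- select_top_k(scores, k)
  } else {
    per_run <- vector("list", n_vote)
    scores_runs <- vector("list", n_vote)
    for (j in seq_len(n_vote)) {
      sc <- monte_carlo_pvalues(
        graph, input, method = method, n_perm = n_perm, seed = seed,
        damping = damping, response = response,
        perm_offset = (j - 1) * n_perm
      )
      per_run[[j]] <- select_top_k(sc, k)
      scores_runs[[j]] <- sc
    }
    selected <- consensus_vote(per_run, n_vote)
    # report the first run's scores with consensus vote counts
    scores <- scores_runs[[1]]
    votes <- table(unlist(per_run))
    scores$votes <- as.integer(votes[scores$id])
    scores$votes[is.na(scores$votes)] <- 0L
  }

  sub <- igraph::induced_subgraph(
    graph$graph, match(selected, graph$nodes$id)
  )
  membership <- pathway_compounds(graph)
  sel_paths <- selected[selected %in% names(membership)]
  n_compounds <- sum(graph$nodes$level == "compound")
  pathways <- purrr::map_dfr(sel_paths, function(p) {
    members <- membership[[p]]
    hits <- length(intersect(input$compound_ids, members))
    row <- scores[scores$id == p, ]
    tibble::tibble(
      pathway = p,
      statistic = if ("z" %in% names(row)) row$z else row$p,
      n_members = length(members),
      hits = hits,
      ora_p = phyper(hits - 1, length(members),
                     n_compounds - length(members),
                     input$n_in, lower.tail = FALSE)
    )
  })
  if (nrow(pathways) > 0) {
    pathways <- dplyr::arrange(
      pathways,
      if (approx == "norm") dplyr::desc(.data$statistic) else .data$statistic
    )
  }

  structure(
    list(
      scores = scores, selected = selected, subgraph = sub,
      cc = cc_summary(sub), pathways = pathways,
      params = list(method = method, approx = approx, k = k,
                    n_perm = n_perm, n_vote = n_vote, seed = seed,
                    damping = damping, n_in = input$n_in)
    ),
    class = "enrichment"
  )
}

#' @export
print.enrichment <- function(x, ...) {
  p <- x$params
  cat("Enrichment result (", toupper(p$method), " ", p$approx, ")\n",
      sep = "")
  cat("  input compounds:", p$n_in, "\n")
  cat("  selected nodes:", length(x$selected),
      sprintf("(k = %d)", p$k), "\n")
  cat("  subgraph: ", x$cc$n_cc, " CC(s), largest ", x$cc$largest_cc,
      " nodes\n", sep = "")
  if (nrow(x$pathways) > 0) {
    cat("  pathways in solution:", nrow(x$pathways), "\n")
  }
  invisible(x)
}

#' Tidy a fitted enrichment result
#'
#' @param x An `enrichment` object.
#' @param ... Unused.
#' @return Per-node tibble of scores with a `selected` flag.
#' @export
tidy.enrichment <- function(x, ...) {
  dplyr::mutate(x$scores, selected = .data$id %in% x$selected)
}

#' One-row summary of an enrichment result
#'
#' @param x An `enrichment` object.
#' @param ... Unused.
#' @return One-row tibble: method, approximation, k, nodes reported,
#'   connected components, largest component, pathways in solution.
#' @export
glance.enrichment <- function(x, ...) {
  tibble::tibble(
    method = x$params$method, approx = x$params$approx,
    k = x$params$k, n_selected = length(x$selected),
    n_cc = x$cc$n_cc, largest_cc = x$cc$largest_cc,
    n_pathways = nrow(x$pathways)
  )
}

#' Plot an enrichment result
#'
#' Shows the normalised statistic of the selected nodes against their
#' rank, coloured by level -- a quick view of which levels dominate the
#' solution.
#'
#' @param object An `enrichment` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$selected, ]
  stat_col <- if ("z" %in% names(df)) "z" else "p"
  df$statistic <- df[[stat_col]]
  df <- df[order(if (stat_col == "z") -df$statistic else df$statistic), ]
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$statistic,
                                   colour = .data$level)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "rank in solution",
      y = if (stat_col == "z") "z-score" else "empirical p-value",
      colour = "level"
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.enrichment <- function(x, ...) print(autoplot(x, ...))

#' Write the standard output files of an enrichment run
#'
#' Writes `<prefix>.scores.tsv` (per-node table),
#' `<prefix>.subgraph.graphml` (induced solution subgraph),
#' `<prefix>.pathways.tsv` and `<prefix>.summary.json`.
#'
#' @param result An `enrichment` object.
#' @param prefix Output path prefix.
#' @return `result`, invisibly.
#' @export
write_enrichment <- function(result, prefix) {
  stopifnot(inherits(result, "enrichment"))
  readr::write_tsv(tidy(result), paste0(prefix, ".scores.tsv"))
  readr::write_tsv(result$pathways, paste0(prefix, ".pathways.tsv"))
  igraph::write_graph(result$subgraph, paste0(prefix, ".subgraph.graphml"),
                      format = "graphml")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(
        method = result$params$method, approx = result$params$approx,
        k = result$params$k, n_selected = length(result$selected),
        n_cc = result$cc$n_cc, largest_cc = result$cc$largest_cc,
        selected = result$selected
      ),
      paste0(prefix, ".summary.json"), auto_unbox = TRUE
    )
  }
  invisible(result)
}
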