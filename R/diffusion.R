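#' Assemble the conductance system for heat diffusion
#'
#' Heat diffusion treats the undirected knowledge graph as a meshed object:
#' input compounds inject unit heat flow and pathway nodes are connected to
#' a cold boundary through which all flow eventually leaves. The stationary
#' temperatures solve the linear system `(L + B) T = G`, where `L` is the
#' unnormalised graph Laplacian of the undirected view and `B` is diagonal
#' with `B[i,i] = 1` exactly when node `i` is a pathway. The boundary term
#' makes the system positive definite whenever every connected component
#' contains at least one pathway node, so the temperatures are unique and
#' nonnegative.
#'
#' @param graph A [levelled_graph] in which every connected component has
#'   at least one pathway node.
#' @return An object of class `conductance_system`: list with `KI` (sparse
#'   symmetric matrix `L + B`), `ids` (node ordering), `levels`,
#'   `is_pathway` (logical), and `is_compound`.
#' @export
conductance_system <- function(graph) {
  stopifnot(inherits(graph, "levelled_graph"))
  lev <- graph$nodes$level
  if (!any(lev == "pathway")) {
    abort("Graph has no pathway node: the conductance system is singular.")
  }
  # L + B is positive definite iff every connected component contains a
  # boundary (pathway) node; otherwise that component's block is singular
  comp <- igraph::components(graph$graph)
  has_boundary <- tapply(lev == "pathway", comp$membership, any)
  if (!all(has_boundary)) {
    abort(paste0(sum(!has_boundary),
                 " connected component(s) contain no pathway node: ",
                 "the conductance system is singular."))
  }
  L <- igraph::laplacian_matrix(graph$graph, sparse = TRUE)
  B <- Matrix::Diagonal(x = as.numeric(lev == "pathway"))
  KI <- methods::as(Matrix::forceSymmetric(L + B), "CsparseMatrix")
  structure(
    list(
      KI = KI,
      ids = graph$nodes$id,
      levels = lev,
      is_pathway = lev == "pathway",
      is_compound = lev == "compound"
    ),
    class = "conductance_system"
  )
}

#' @export
print.conductance_system <- function(x, ...) {
  cat("Conductance system (L + B):", length(x$ids), "nodes,",
      sum(x$is_pathway), "boundary (pathway) node(s)\n")
  invisible(x)
}

#' Stationary heat-diffusion temperatures
#'
#' Solves `(L + B) T = G` for the generation vector `G` that is 1 on the
#' input compounds and 0 elsewhere. Flow conservation holds at the
#' solution: the total flow leaving through the pathway boundary,
#' `sum(B[i,i] * T[i])`, equals the injected flow `n_in`.
#'
#' @param system A [conductance_system].
#' @param input An `input_set` from [map_input()] mapped onto the same
#'   graph, or a character vector of compound ids.
#' @return Tibble with columns `id`, `level`, `score` (the temperatures),
#'   with attributes `method = "hd"` and `n_in`.
#' @examples
#' nodes <- tibble::tibble(id = c("c", "r", "p"),
#'                         level = c("compound", "reaction", "pathway"))
#' edges <- tibble::tibble(source = c("c", "r"), target = c("r", "p"))
#' lg <- levelled_graph(nodes, edges)
#' heat_diffusion_scores(conductance_system(lg), map_input(lg, "c"))
#' @export
heat_diffusion_scores <- function(system, input) {
  stopifnot(inherits(system, "conductance_system"))
  ids <- input_ids(input)
  check_input_ids(ids, system$ids[system$is_compound])
  G <- as.numeric(system$ids %in% ids)
  T_ <- as.numeric(Matrix::solve(system$KI, G))
  score_tibble(system$ids, system$levels, T_, method = "hd",
               n_in = length(ids))
}

#' Heat-diffusion response matrix
#'
#' Column `j` holds the temperatures produced by a unit input on compound
#' `j` alone. By linearity of the solve, the temperatures for any input set
#' are the sum of the corresponding columns; this is what makes the
#' closed-form null moments and fast permutation scoring possible.
#'
#' @param system A [conductance_system].
#' @param compound_ids Compound ids to use as columns; default all
#'   compounds in the graph.
#' @return Object of class `response_matrix`: list with `R` (dense numeric
#'   matrix, nodes x compounds), `ids`, `levels`, `compound_ids`,
#'   `method = "hd"`.
#' @export
heat_response_matrix <- function(system, compound_ids = NULL) {
  stopifnot(inherits(system, "conductance_system"))
  all_comp <- system$ids[system$is_compound]
  compound_ids <- compound_ids %||% all_comp
  check_input_ids(compound_ids, all_comp)
  n <- length(system$ids)
  cols <- match(compound_ids, system$ids)
  E <- Matrix::sparseMatrix(i = cols, j = seq_along(cols),
                            x = 1, dims = c(n, length(cols)))
  R <- as.matrix(Matrix::solve(system$KI, E))
  dimnames(R) <- list(system$ids, compound_ids)
  new_response_matrix(R, system$ids, system$levels, compound_ids, "hd")
}

new_response_matrix <- function(R, ids, levels, compound_ids, method) {
  structure(
    list(R = R, ids = ids, levels = levels,
         compound_ids = compound_ids, method = method),
    class = "response_matrix"
  )
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("Response matrix (", toupper(x$method), "): ",
      nrow(x$R), " nodes x ", ncol(x$R), " compounds\n", sep = "")
  invisible(x)
}

#' Scores for an input set through a response matrix
#'
#' For heat diffusion the result equals the direct linear solve; for
#' PageRank it is the linear (un-normalised) restart response divided by
#' `n_in`, the raw score used by the analytic null.
#'
#' @param response A [response_matrix][heat_response_matrix].
#' @param input An `input_set` or character vector of compound ids.
#' @return Tibble `id`, `level`, `score` with attributes `method`, `n_in`.
#' @export
response_scores <- function(response, input) {
  stopifnot(inherits(response, "response_matrix"))
  ids <- input_ids(input)
  check_input_ids(ids, response$compound_ids)
  cols <- match(ids, response$compound_ids)
  v <- if (length(cols) == 1) response$R[, cols] else rowSums(response$R[, cols])
  if (response$method == "pr") v <- v / length(ids)
  score_tibble(response$ids, response$levels, as.numeric(v),
               method = response$method, n_in = length(ids))
}

#' Personalised PageRank scores on the level-directed view
#'
#' Random walks start on the input compounds (uniform restart
#' distribution) and follow edges directed towards the upper levels; at
#' each step the walk restarts with probability `1 - damping`. Pathway
#' nodes have no outgoing edges in this orientation, so their dangling
#' probability mass is redistributed to the restart distribution, keeping
#' the process a restart walk anchored on the input. Scores are the
#' stationary distribution and sum to 1.
#'
#' Two routes are available: a direct sparse linear solve of the restart
#' equations (default, exact up to solver tolerance) and classical power
#' iteration; they agree to tight tolerance and the iterative route exists
#' mainly as an internal cross-check.
#'
#' @param graph A [levelled_graph].
#' @param input An `input_set` or character vector of compound ids.
#' @param damping Continuation probability of the walk, in (0, 1); 0.85 by
#'   convention. `damping = 0` returns the restart distribution itself.
#' @param algorithm `"linear"` (sparse solve) or `"power"` (iteration,
#'   L1 tolerance 1e-12, at most 1000 iterations).
#' @return Tibble `id`, `level`, `score` with attributes `method = "pr"`,
#'   `n_in`, `damping`.
#' @export
pagerank_scores <- function(graph, input, damping = 0.85,
                            algorithm = c("linear", "power")) {
  stopifnot(inherits(graph, "levelled_graph"))
  algorithm <- match.arg(algorithm)
  if (damping < 0 || damping >= 1) abort("`damping` must be in [0, 1).")
  ids <- input_ids(input)
  compounds <- graph$nodes$id[graph$nodes$level == "compound"]
  check_input_ids(ids, compounds)
  nm <- graph$nodes$id
  n <- length(nm)
  v <- as.numeric(nm %in% ids)
  v <- v / sum(v)
  if (damping == 0) {
    return(score_tibble(nm, graph$nodes$level, v, method = "pr",
                        n_in = length(ids), damping = damping))
  }
  Pt <- transition_t(graph)
  s <- if (algorithm == "linear") {
    x <- as.numeric(Matrix::solve(Matrix::Diagonal(n) - damping * Pt, v))
    x / sum(x)
  } else {
    pagerank_power(Pt, v, damping)
  }
  score_tibble(nm, graph$nodes$level, s, method = "pr",
               n_in = length(ids), damping = damping)
}

# transpose of the out-degree-normalised transition matrix of the
# directed (upward) view; dangling columns are all zero
transition_t <- function(graph) {
  A <- igraph::as_adjacency_matrix(graph$directed, sparse = TRUE)
  dout <- Matrix::rowSums(A)
  inv <- ifelse(dout > 0, 1 / dout, 0)
  Matrix::t(Matrix::Diagonal(x = inv) %*% A)
}

# power iteration with dangling mass sent to the restart vector
pagerank_power <- function(Pt, v, damping, tol = 1e-12, max_iter = 1000) {
  s <- v
  dangling <- Matrix::colSums(Pt) == 0
  for (i in seq_len(max_iter)) {
    s_new <- as.numeric(damping * (Pt %*% s)) +
      (damping * sum(s[dangling]) + 1 - damping) * v
    if (sum(abs(s_new - s)) < tol) return(s_new / sum(s_new))
    s <- s_new
  }
  s / sum(s)
}

#' PageRank response matrix (linear restart response)
#'
#' Column `j` is the un-normalised solution of the restart equations for a
#' walk restarting only at compound `j`: `x_j = (I - d P')^-1 e_j`, where
#' `P'` is the transposed transition matrix of the upward-directed view
#' with dangling columns zero. The response is linear in the restart
#' vector, so the raw PageRank score of an input set (before normalising
#' the stationary distribution to sum 1) is the average of its columns --
#' the property the analytic null moments rely on.
#'
#' @inheritParams pagerank_scores
#' @param compound_ids Compound columns to compute; default all compounds.
#' @return A `response_matrix` with `method = "pr"`.
#' @export
pagerank_response_matrix <- function(graph, damping = 0.85,
                                     compound_ids = NULL) {
  stopifnot(inherits(graph, "levelled_graph"))
  if (damping < 0 || damping >= 1) abort("`damping` must be in [0, 1).")
  compounds <- graph$nodes$id[graph$nodes$level == "compound"]
  compound_ids <- compound_ids %||% compounds
  check_input_ids(compound_ids, compounds)
  nm <- graph$nodes$id
  n <- length(nm)
  Pt <- transition_t(graph)
  cols <- match(compound_ids, nm)
  E <- Matrix::sparseMatrix(i = cols, j = seq_along(cols), x = 1,
                            dims = c(n, length(cols)))
  R <- as.matrix(Matrix::solve(Matrix::Diagonal(n) - damping * Pt, E))
  dimnames(R) <- list(nm, compound_ids)
  out <- new_response_matrix(R, nm, graph$nodes$level, compound_ids, "pr")
  out$damping <- damping
  out
}

# ---- shared helpers ----

input_ids <- function(input) {
  if (inherits(input, "input_set")) input$compound_ids
  else unique(as.character(input))
}

check_input_ids <- function(ids, compounds) {
  if (length(ids) == 0) abort("Input set is empty.")
  bad <- setdiff(ids, compounds)
  if (length(bad) > 0) {
    abort(paste0("Input id(s) not among graph compounds: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  invisible(TRUE)
}

score_tibble <- function(ids, levels, values, method, n_in, damping = NULL) {
  out <- tibble::tibble(id = ids, level = levels, score = values)
  attr(out, "method") <- method
  attr(out, "n_in") <- n_in
  if (!is.null(damping)) attr(out, "damping") <- damping
  out
}
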