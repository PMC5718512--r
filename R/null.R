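#' Moments of the random-input indicator vector
#'
#' Under the null model, exactly `n_in` of the `n_compounds` compound
#' nodes are chosen uniformly at random without replacement. The indicator
#' `X_i` of compound `i` being chosen is a dependent Bernoulli variable
#' with `E(X_i) = p = n_in / n_compounds`, `Var(X_i) = p (1 - p)` and, for
#' distinct compounds, `Cov(X_i, X_j) = -p (1 - p) / (n_compounds - 1)`
#' (negative because the total number of chosen compounds is fixed). Rows
#' of the implied covariance matrix sum to zero.
#'
#' @param n_compounds Number of compound nodes in the graph.
#' @param n_in Input size, `1 <= n_in <= n_compounds`.
#' @return Object of class `input_moments`: list with `n_compounds`,
#'   `n_in`, `p`, `mean_x`, `var_x`, `cov_x`.
#' @export
null_input_moments <- function(n_compounds, n_in) {
  if (n_in < 1 || n_in > n_compounds) {
    abort("`n_in` must satisfy 1 <= n_in <= n_compounds.")
  }
  p <- n_in / n_compounds
  v <- p * (1 - p)
  structure(
    list(
      n_compounds = n_compounds, n_in = n_in, p = p,
      mean_x = p, var_x = v,
      cov_x = if (n_compounds > 1) -v / (n_compounds - 1) else 0
    ),
    class = "input_moments"
  )
}

#' Closed-form null moments of the diffusion scores
#'
#' Because scores are linear in the input indicator vector `X`
#' (`T = R X`, with the PageRank response additionally divided by `n_in`),
#' the null mean and covariance follow directly:
#' `E(T_null) = R E(X)` and `Sigma(T_null) = R Sigma(X) R'`. Only the
#' diagonal is needed for z-scores, and with the exchangeable covariance of
#' sampling without replacement it reduces to a row-wise formula --
#' no node-by-node covariance matrix is ever materialised:
#' `sigma_i^2 = var_x * (N/(N-1) * sum_j R_ij^2 - rowsum_i^2 / (N-1))`.
#'
#' @param response A [response_matrix][heat_response_matrix] over all
#'   compounds used by the null.
#' @param moments An [input_moments][null_input_moments] whose
#'   `n_compounds` matches the response's compound columns.
#' @return Tibble `id`, `level`, `mu`, `sigma` with attributes `method`,
#'   `n_in`.
#' @export
analytic_null_moments <- function(response, moments) {
  stopifnot(inherits(response, "response_matrix"),
            inherits(moments, "input_moments"))
  if (length(response$compound_ids) != moments$n_compounds) {
    abort(paste0(
      "Response matrix has ", length(response$compound_ids),
      " compound columns but moments assume ", moments$n_compounds, "."
    ))
  }
  R <- response$R
  scale <- if (response$method == "pr") 1 / moments$n_in else 1
  N <- moments$n_compounds
  rs <- rowSums(R)
  mu <- scale * moments$p * rs
  if (N > 1) {
    s2 <- moments$var_x * (N / (N - 1) * rowSums(R^2) - rs^2 / (N - 1))
  } else {
    s2 <- rep(0, nrow(R))
  }
  s2 <- pmax(s2, 0) * scale^2
  out <- tibble::tibble(
    id = response$ids, level = response$levels,
    mu = as.numeric(mu), sigma = sqrt(as.numeric(s2))
  )
  attr(out, "method") <- response$method
  attr(out, "n_in") <- moments$n_in
  out
}

#' z-score normalisation of observed scores
#'
#' `z_i = (T_i - mu_i) / sigma_i` compares each node's observed score to
#' its own null distribution, correcting the topology-driven bias of raw
#' scores (hubs and large pathways are systematically warmer under any
#' input). Nodes with a degenerate null (`sigma_i = 0`) get `z = NA` and
#' are flagged rather than assigned an infinite score; they are excluded
#' from ranking downstream.
#'
#' @param scores Score tibble from [heat_diffusion_scores()],
#'   [response_scores()] or [pagerank_scores()].
#' @param null Null-moment tibble from [analytic_null_moments()] over the
#'   same nodes.
#' @return Tibble `id`, `level`, `score`, `mu`, `sigma`, `z`, `degenerate`
#'   with attributes `method`, `approx = "norm"`, `n_in`.
#' @export
zscore_normalise <- function(scores, null) {
  if (!identical(scores$id, null$id)) {
    abort("`scores` and `null` must share the same node ordering.")
  }
  tol <- 1e-12
  degenerate <- null$sigma <= tol
  z <- ifelse(degenerate, NA_real_, (scores$score - null$mu) / null$sigma)
  if (any(degenerate)) {
    inform(paste0(sum(degenerate),
                  " node(s) have a degenerate null (sigma = 0);",
                  " excluded from ranking."))
  }
  out <- tibble::tibble(
    id = scores$id, level = scores$level, score = scores$score,
    mu = null$mu, sigma = null$sigma, z = z, degenerate = degenerate
  )
  attr(out, "method") <- attr(scores, "method")
  attr(out, "approx") <- "norm"
  attr(out, "n_in") <- attr(scores, "n_in")
  out
}

#' Monte-Carlo permutation p-values for node scores
#'
#' Draws `n_perm` random inputs of the same size as the observed one
#' (uniformly without replacement over compounds), scores each, and
#' reports per node the corrected empirical tail probability
#' `p_i = (r_i + 1) / (n_perm + 1)`, where `r_i` counts permutations whose
#' null score is greater than or equal to the observed score.
#'
#' Permutation streams are derived from the master seed by a counter
#' (`seed + permutation index`), so results are reproducible and
#' individual permutations are independent of how many are requested.
#'
#' @param graph A [levelled_graph].
#' @param input An `input_set` or character vector of compound ids.
#' @param method `"hd"` or `"pr"`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Master integer seed.
#' @param damping PageRank damping (ignored for `"hd"`).
#' @param response Optional precomputed [response_matrix] over all
#'   compounds; computed if missing. Supplying one makes repeated calls on
#'   the same graph cheap.
#' @param perm_offset Advanced: offset added to the permutation counter,
#'   used to make consensus runs draw disjoint streams.
#' @return Tibble `id`, `level`, `score`, `r`, `p` with attributes
#'   `method`, `approx = "sim"`, `n_perm`, `seed`, `n_in`.
#' @export
monte_carlo_pvalues <- function(graph, input, method = c("hd", "pr"),
                                n_perm = 10000, seed = 1, damping = 0.85,
                                response = NULL, perm_offset = 0) {
  stopifnot(inherits(graph, "levelled_graph"))
  method <- match.arg(method)
  if (n_perm < 1) abort("`n_perm` must be >= 1.")
  ids <- input_ids(input)
  compounds <- graph$nodes$id[graph$nodes$level == "compound"]
  check_input_ids(ids, compounds)
  n_in <- length(ids)

  response <- response %||% build_response(graph, method, damping)
  observed <- sim_score(response, match(ids, response$compound_ids))
  n_c <- length(response$compound_ids)

  eps <- 1e-9 * pmax(1, abs(observed))
  r <- integer(length(observed))
  for (b in seq_len(n_perm)) {
    idx <- with_seed_(seed + perm_offset + b,
                      sample.int(n_c, n_in, replace = FALSE))
    null_score <- sim_score(response, idx)
    r <- r + (null_score >= observed - eps)
  }
  out <- tibble::tibble(
    id = response$ids, level = response$levels,
    score = observed, r = as.integer(r),
    p = (r + 1) / (n_perm + 1)
  )
  attr(out, "method") <- method
  attr(out, "approx") <- "sim"
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "n_in") <- n_in
  out
}

build_response <- function(graph, method, damping = 0.85) {
  if (method == "hd") {
    heat_response_matrix(conductance_system(graph))
  } else {
    pagerank_response_matrix(graph, damping = damping)
  }
}

# score used in sim mode: HD temperatures; PR stationary distribution
sim_score <- function(response, idx) {
  v <- if (length(idx) == 1) response$R[, idx] else rowSums(response$R[, idx])
  v <- as.numeric(v)
  if (response$method == "pr") v / sum(v) else v
}

#' Majority-vote consensus over reported node sets
#'
#' Independent Monte-Carlo runs each report a top-k node set; the
#' consensus keeps a node when it appears in a strict majority,
#' `ceiling((n_vote + 1) / 2)`, of the sets. The consensus size may
#' therefore differ from k.
#'
#' @param solutions List of character vectors (node ids).
#' @param n_vote Number of votes; defaults to `length(solutions)`.
#' @return Character vector of consensus node ids (sorted).
#' @export
consensus_vote <- function(solutions, n_vote = length(solutions)) {
  if (length(solutions) == 0) abort("`solutions` is empty.")
  if (n_vote != length(solutions)) {
    abort("`n_vote` must equal the number of solutions supplied.")
  }
  counts <- table(unlist(lapply(solutions, unique)))
  need <- ceiling((n_vote + 1) / 2)
  sort(names(counts)[counts >= need])
}
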