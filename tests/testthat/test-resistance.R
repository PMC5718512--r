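# Independent oracle: effective resistance from commute times of the
# simple random walk, Omega(i, j) = C(i, j) / (2 |E|), with expected
# hitting times from the fundamental matrix.
commute_resistance <- function(g, i, j) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  P <- A / rowSums(A)
  nm <- igraph::V(g)$name
  hit <- function(a, b) {
    keep <- setdiff(seq_len(n), match(b, nm))
    Q <- P[keep, keep, drop = FALSE]
    t_ <- solve(diag(length(keep)) - Q, rep(1, length(keep)))
    t_[match(match(a, nm), keep)]
  }
  unname((hit(i, j) + hit(j, i)) / (2 * igraph::ecount(g)))
}

test_that("the reaction-compound graph strips annotation levels", {
  rc <- reaction_compound_graph(toy_chain())
  expect_setequal(rc$ids, c("c", "r"))
  expect_equal(igraph::ecount(rc$graph), 1)
})

test_that("only the largest reaction-compound island is kept", {
  nodes <- tibble::tibble(
    id = c("c1", "c2", "r1", "r2", "c3", "r3", "p"),
    level = c("compound", "compound", "reaction", "reaction",
              "compound", "reaction", "pathway")
  )
  edges <- tibble::tibble(
    source = c("c1", "c2", "c2", "c3", "r1"),
    target = c("r1", "r1", "r2", "r3", "p")
  )
  lg <- suppressWarnings(
    levelled_graph(nodes, edges, restrict_to_largest_cc = FALSE)
  )
  rc <- reaction_compound_graph(lg)
  expect_setequal(rc$ids, c("c1", "c2", "r1", "r2"))
})

test_that("graphs without reactions are rejected", {
  nodes <- tibble::tibble(id = c("c1", "p"), level = c("compound", "pathway"))
  lg <- suppressWarnings(levelled_graph(
    nodes, tibble::tibble(source = "c1", target = "p")
  ))
  expect_error(reaction_compound_graph(lg), "no reaction")
})

test_that("resistance distances match series-parallel circuit values", {
  edge <- rc_from_edges(tibble::tibble(source = "c1", target = "r1"))
  expect_equal(resistance_distance(edge, "c1", "r1"), 1, tolerance = 1e-10)
  expect_equal(resistance_distance(edge, "c1", "c1"), 0)

  # triangle (c1-r1, r1-c2, c2-... need bipartite: use 4-cycle instead for
  # levels; triangle built level-agnostically via a square is not the
  # textbook case, so use an explicit triangle with alternating levels
  # c1-r1-c2 plus the chord c1-c2 is not schema-legal; instead check the
  # triangle on a generic 3-node resistor network via the pseudoinverse
  # identity on a compound-reaction 6-cycle: opposite nodes of a cycle of
  # length n have resistance (n/2 * n/2) / n
  cyc <- rc_from_edges(tibble::tibble(
    source = c("c1", "c2", "c2", "c3", "c3", "c1"),
    target = c("r1", "r1", "r2", "r2", "r3", "r3")
  ))
  expect_equal(resistance_distance(cyc, "c1", "r2"), 9 / 6,
               tolerance = 1e-10)

  # path of 3 nodes: ends are two unit resistors in series
  path3 <- rc_from_edges(tibble::tibble(
    source = c("c1", "c2"), target = c("r1", "r1")
  ))
  expect_equal(resistance_distance(path3, "c1", "c2"), 2, tolerance = 1e-10)
})

test_that("triangle resistance is 2/3 between adjacent nodes", {
  # direct Laplacian-pseudoinverse computation on a plain triangle,
  # cross-checked against the series-parallel value 1*2/(1+2)
  L <- matrix(c(2, -1, -1, -1, 2, -1, -1, -1, 2), 3)
  Lp <- MASS::ginv(L)
  expect_equal(Lp[1, 1] + Lp[2, 2] - 2 * Lp[1, 2], 2 / 3,
               tolerance = 1e-10)
})

test_that("pseudoinverse, grounded solve and commute times agree", {
  for (s in 1:4) {
    lg <- small_synth(seed = 50 + s)
    rc <- reaction_compound_graph(lg)
    ids <- withr::with_seed(s, sample(rc$ids, 4))
    for (k in 1:3) {
      d_pinv <- resistance_distance(rc, ids[1], ids[1 + k])
      d_ground <- resistance_distance(rc, ids[1], ids[1 + k],
                                      method = "grounded")
      expect_equal(d_pinv, d_ground, tolerance = 1e-8)
      d_commute <- commute_resistance(rc$graph, ids[1], ids[1 + k])
      expect_equal(d_pinv, d_commute, tolerance = 1e-8)
    }
  }
})

test_that("resistance is a metric bounded by shortest-path distance", {
  lg <- small_synth(seed = 61)
  rc <- reaction_compound_graph(lg)
  ids <- withr::with_seed(2, sample(rc$ids, 3))
  d12 <- resistance_distance(rc, ids[1], ids[2])
  d13 <- resistance_distance(rc, ids[1], ids[3])
  d23 <- resistance_distance(rc, ids[2], ids[3])
  expect_lte(d13, d12 + d23 + 1e-10)
  sp <- igraph::distances(rc$graph, v = ids[1], to = ids[2])[1, 1]
  expect_lte(d12, sp + 1e-10)
})

test_that("resistance equals path length on trees", {
  # a star of reactions around one compound is a tree
  star <- rc_from_edges(tibble::tibble(
    source = rep("c1", 4), target = paste0("r", 1:4)
  ))
  expect_equal(resistance_distance(star, "r1", "r2"), 2, tolerance = 1e-10)
  expect_equal(
    resistance_distance(star, "r1", "r2"),
    igraph::distances(star$graph, v = "r1", to = "r2")[1, 1]
  )
})

test_that("distance summaries report per-target mean and SD", {
  edge <- rc_from_edges(tibble::tibble(
    source = c("c1", "c1"), target = c("r1", "r2")
  ))
  out <- reaction_distance_summary(edge, c("r1", "r2"), "c1")
  expect_equal(out$mean, 1)
  expect_equal(out$sd, 0)
  expect_warning(
    out2 <- reaction_distance_summary(edge, c("r1", "r2", "zz"), "c1"),
    "dropped"
  )
  expect_equal(out2$n_reactions, 2)
  expect_error(
    suppressWarnings(reaction_distance_summary(edge, "zz", "c1")),
    "No reactions"
  )
})

test_that("identical reported and neighbour sets are never significant", {
  lg <- small_synth(seed = 71)
  rc <- reaction_compound_graph(lg)
  comp <- rc$ids[rc$levels == "compound"]
  inputs <- comp[1:3]
  nb <- unique(unlist(lapply(
    igraph::adjacent_vertices(rc$graph, match(inputs, rc$ids)),
    function(v) v$name
  )))
  nb <- nb[nb %in% rc$ids[rc$levels == "reaction"]]
  targets <- utils::tail(comp, 3)
  out <- neighbour_comparison(rc, nb, inputs, targets)
  expect_true(all(out$p[!out$skipped] > 0.4))
})

test_that("clear separation yields significant adjusted p-values", {
  # reported reactions adjacent to the target, neighbours far away
  edges <- tibble::tibble(
    source = c("c1", "c1", "c2", "c2", "c3", "c3", "c4"),
    target = c("r1", "r2", "r2", "r3", "r3", "r4", "r4")
  )
  # long path c1-r1 ... r4-c4: reported {r4} close to c4, input at c1
  rc <- rc_from_edges(edges)
  out <- neighbour_comparison(
    rc, list(close = c("r3", "r4")), input_compounds = "c1",
    target_compounds = "c4"
  )
  expect_lt(out$mean_reported, out$mean_neighbour)
})

test_that("all solution-by-target comparisons are emitted with BH values", {
  lg <- mid_synth()
  rc <- reaction_compound_graph(lg)
  reacts <- rc$ids[rc$levels == "reaction"]
  comp <- rc$ids[rc$levels == "compound"]
  sols <- lapply(1:4, function(i) {
    withr::with_seed(i, sample(reacts, 10))
  })
  names(sols) <- paste0("sol", 1:4)
  targets <- withr::with_seed(9, sample(comp, 8))
  out <- neighbour_comparison(rc, sols, input_compounds = comp[1:5],
                              target_compounds = targets)
  expect_equal(nrow(out), 32)
  ok <- !out$skipped
  expect_true(all(out$p_adj[ok] >= out$p[ok] - 1e-12))
})
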