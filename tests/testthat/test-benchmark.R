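test_that("uniform probabilities are constant over compounds", {
  lg <- generate_synthetic_graph(
    level_sizes = c(pathway = 2, module = 2, enzyme = 4, reaction = 8,
                    compound = 12),
    seed = 1
  )
  p <- signal_probabilities(lg, lg$nodes$id[lg$nodes$level == "pathway"][1],
                            scheme = "uniform")
  expect_equal(nrow(p), 12)
  expect_true(all(abs(p$prob - 1 / 12) < 1e-15))
  expect_error(
    signal_probabilities(lg, lg$nodes$id[1], scheme = "uniform"),
    "not a pathway"
  )
})

test_that("proportional probabilities weight members k-fold", {
  # 3 in-pathway compounds of 10, k = 10: weights (10,10,10,1,...,1)/37
  lg <- ora_toy()
  p <- signal_probabilities(lg, "A", scheme = "proportional", k_factor = 10)
  memb <- pathway_compounds(lg)[["A"]]
  expect_equal(sort(unique(round(p$prob, 12))),
               round(c(1 / 37, 10 / 37), 12))
  expect_true(all(p$prob[p$id %in% memb] == 10 / 37))
  expect_equal(sum(p$prob), 1)
})

test_that("network probabilities follow the response row", {
  lg <- toy_chain()
  resp <- heat_response_matrix(conductance_system(lg))
  p <- signal_probabilities(lg, "p", scheme = "network", response = resp)
  expect_equal(p$prob, 1)  # the single compound takes all the mass
})

test_that("weighted sampling without replacement honours its contract", {
  probs <- tibble::tibble(id = letters[1:6], prob = rep(1 / 6, 6))
  expect_setequal(sample_signal(probs, n_in = 6, seed = 1), letters[1:6])
  degen <- tibble::tibble(id = c("a", "b"), prob = c(1, 0))
  expect_equal(sample_signal(degen, n_in = 1, seed = 1), "a")
  expect_error(sample_signal(degen, n_in = 2, seed = 1), "positive")
  s1 <- sample_signal(probs, n_in = 3, seed = 5)
  expect_identical(s1, sample_signal(probs, n_in = 3, seed = 5))
  # inclusion frequencies under uniform weights
  n_rep <- 3000
  counts <- table(unlist(lapply(seq_len(n_rep), function(i) {
    sample_signal(probs, n_in = 2, seed = i)
  })))
  p_inc <- 2 / 6
  se <- sqrt(p_inc * (1 - p_inc) / n_rep)
  expect_true(all(abs(counts / n_rep - p_inc) < 4 * se))
})

test_that("normalized ranks span (0, 1] with seeded random ties", {
  rk <- rank_pathways(c(p1 = 5, p2 = 1, p3 = 3, p4 = 0),
                      direction = "higher_better")
  expect_equal(rk$rank[rk$pathway == "p1"], 0.25)
  expect_setequal(rk$rank, (1:4) / 4)
  lo <- rank_pathways(c(a = 0.01, b = 0.5, c = 0.5),
                      direction = "lower_better", seed = 3)
  expect_equal(lo$rank[lo$pathway == "a"], 1 / 3)
  expect_setequal(lo$rank[lo$pathway != "a"], c(2 / 3, 1))
  # all tied: a random permutation with mean (n_p + 1) / (2 n_p)
  tied <- rank_pathways(setNames(rep(1, 5), paste0("q", 1:5)),
                        direction = "higher_better", seed = 11)
  expect_setequal(tied$rank, (1:5) / 5)
  expect_equal(mean(tied$rank), 6 / 10)
  expect_false(identical(
    tied$rank,
    rank_pathways(setNames(rep(1, 5), paste0("q", 1:5)),
                  direction = "higher_better", seed = 12)$rank
  ))
})

test_that("noise-signal mean ranks have the exact permutation grand mean", {
  lg <- mid_synth()
  bs <- run_bias_study(lg, methods = c("hd", "fisher"), n_signals = 40,
                       n_in = 10, seed = 3)
  n_p <- lg$level_counts[["pathway"]]
  for (m in c("hd", "fisher")) {
    expect_equal(mean(bs$mean_rank[bs$method == m]),
                 (n_p + 1) / (2 * n_p), tolerance = 1e-12)
  }
  # determinism
  bs2 <- run_bias_study(lg, methods = c("hd", "fisher"), n_signals = 40,
                        n_in = 10, seed = 3)
  expect_identical(bs$mean_rank, bs2$mean_rank)
})

test_that("raw-temperature ranking favours a planted mega-hub pathway", {
  # a pathway wired to every module dominates raw temperatures
  lg <- small_synth(seed = 41,
                    sizes = c(pathway = 4, module = 5, enzyme = 10,
                              reaction = 20, compound = 30))
  hub <- lg$nodes$id[lg$nodes$level == "pathway"][1]
  modules <- lg$nodes$id[lg$nodes$level == "module"]
  extra <- tibble::tibble(source = modules, target = hub)
  el <- igraph::as_edgelist(lg$graph)
  lg2 <- suppressWarnings(levelled_graph(
    lg$nodes, dplyr::bind_rows(
      tibble::tibble(source = el[, 1], target = el[, 2]), extra
    )
  ))
  bs <- run_bias_study(lg2, methods = "hd_raw", n_signals = 60, n_in = 6,
                       seed = 5)
  expect_lt(bs$mean_rank[bs$pathway == hub], 0.5)
  expect_equal(bs$degree[bs$pathway == hub], max(bs$degree))
})

test_that("decoy targets under uniform noise rank uniformly", {
  lg <- mid_synth()
  rt <- run_recovery_study(lg, methods = "hd", scheme = "uniform",
                           n_in = 15, signals_per_target = 8, seed = 7)
  n_p <- lg$level_counts[["pathway"]]
  expect_setequal(unique(rt$method), "hd")
  expect_true(all(rt$rank > 0 & rt$rank <= 1))
  # de-discretise: rank - U(0, 1/n_p) is exactly U(0,1) under the null
  u <- rt$rank - withr::with_seed(1, stats::runif(nrow(rt), 0, 1 / n_p))
  ks <- stats::ks.test(u, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("ranks within each signal are exact permutations", {
  lg <- small_synth(seed = 43)
  eng <- diffenr:::benchmark_engine(lg, c("hd", "pr", "fisher"), n_in = 5)
  ids <- sample_signal(
    signal_probabilities(lg, eng$pathways[1], "uniform"),
    n_in = 5, seed = 2
  )
  n_p <- length(eng$pathways)
  for (m in c("hd", "pr", "fisher")) {
    st <- diffenr:::signal_statistic(eng, m, ids)
    rk <- rank_pathways(setNames(st$value, eng$pathways),
                        direction = st$direction, seed = 4)
    expect_setequal(rk$rank, (1:n_p) / n_p)
  }
})

test_that("recovery study is reproducible and plots", {
  lg <- small_synth(seed = 47)
  rt <- run_recovery_study(lg, methods = c("hd", "fisher"),
                           scheme = "proportional", n_in = 5,
                           signals_per_target = 2, seed = 3)
  rt2 <- run_recovery_study(lg, methods = c("hd", "fisher"),
                            scheme = "proportional", n_in = 5,
                            signals_per_target = 2, seed = 3)
  expect_identical(rt$rank, rt2$rank)
  expect_s3_class(autoplot(rt), "ggplot")
})
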