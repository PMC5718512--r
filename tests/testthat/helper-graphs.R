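# Small graphs reused across the suite, built in code.

# compound - reaction - pathway chain
toy_chain <- function() {
  nodes <- tibble::tibble(
    id = c("c", "r", "p"),
    level = c("compound", "reaction", "pathway")
  )
  edges <- tibble::tibble(source = c("c", "r"), target = c("r", "p"))
  # the direct reaction-pathway link is off-schema on purpose; keep quiet
  suppressWarnings(levelled_graph(nodes, edges))
}

# Bipartite ORA toy: 10 compounds, each attached to exactly one pathway;
# pathway A holds 3 compounds, B 3, C 2, D 2. The canonical input has
# 4 compounds with 2 hits in A.
ora_toy <- function() {
  comp <- sprintf("c%02d", 1:10)
  paths <- c("A", "B", "C", "D")
  member <- c(rep("A", 3), rep("B", 3), rep("C", 2), rep("D", 2))
  nodes <- tibble::tibble(
    id = c(comp, paths),
    level = c(rep("compound", 10), rep("pathway", 4))
  )
  edges <- tibble::tibble(source = comp, target = member)
  suppressWarnings(
    levelled_graph(nodes, edges, restrict_to_largest_cc = FALSE)
  )
}

ora_toy_input <- c("c01", "c02", "c04", "c07")  # 2 hits in A

# small connected synthetic graph for property tests
small_synth <- function(seed = 1,
                        sizes = c(pathway = 3, module = 3, enzyme = 7,
                                  reaction = 15, compound = 22)) {
  generate_synthetic_graph(level_sizes = sizes, seed = seed)
}

# reaction-compound graph straight from an edge table; ids starting with
# "c" are compounds, the rest reactions; a dummy pathway keeps the schema
rc_from_edges <- function(edges_df, extra_nodes = NULL) {
  ids <- unique(c(edges_df$source, edges_df$target, extra_nodes))
  lev <- ifelse(grepl("^c", ids), "compound", "reaction")
  suppressWarnings(reaction_compound_graph(levelled_graph(
    tibble::tibble(
      id = c(ids, "pw"), level = c(lev, "pathway")
    ),
    dplyr::bind_rows(edges_df,
                     tibble::tibble(source = ids[1], target = "pw")),
    restrict_to_largest_cc = FALSE
  )))
}

# mid-size graph (~500 nodes) shared by the heavier statistical tests
mid_synth <- function(seed = 11) {
  generate_synthetic_graph(
    level_sizes = c(pathway = 14, module = 9, enzyme = 57,
                    reaction = 235, compound = 193),
    seed = seed
  )
}
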