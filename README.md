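# diffenr

Null-diffusion pathway enrichment for metabolomics on levelled knowledge
graphs.

## What it does, and for whom

Metabolomics studies typically end in a list of significantly affected
compounds. Classical over-representation analysis (ORA) intersects that
list with pathway memberships and ranks pathways by a one-tailed
hypergeometric p-value — ignoring everything else the knowledge base
knows (reactions, enzymes, modules, and how they wire pathways
together). `diffenr` is for researchers who want enrichment with
sub-pathway resolution: it scores **every node** of a five-level
knowledge graph (compound < reaction < enzyme < module < pathway) from
the affected-compound list and reports an interpretable multi-level
subgraph, not just a pathway p-value list.

Two diffusion scores are implemented:

* **Heat diffusion (HD)** on the undirected graph: input compounds
  inject unit flow, pathway nodes leak it through a boundary term, and
  node scores are the stationary temperatures solving
  `(L + B) T = G`, with `L` the unnormalised graph Laplacian and
  `B_ii = 1` on pathways.
* **Personalised PageRank (PR)** on the level-directed graph
  (damping `d = 0.85`), restarting on the input compounds.

Raw diffusion scores are biased by topology (hubs are always warm), so
each node is compared to its own null distribution under inputs of the
same size drawn uniformly at random without replacement: either in
closed form, `z_i = (T_i - mu_i) / sigma_i` with `mu = R E(X)` and
`Sigma = R Sigma(X) R'` (the `norm` approximation, using the linearity
of scores in the input indicator `X`), or by Monte-Carlo permutations
with `p_i = (r_i + 1) / (n_perm + 1)` and majority-vote consensus over
independent runs (`sim`). On bipartite single-membership graphs the
pipeline reduces *exactly* to hypergeometric ORA — which is also
available directly as the baseline (`ora_pathway_test()`).

The package also ships the machinery used to characterise such methods:
a synthetic five-level scale-free graph generator with modular
(community) structure, a three-scheme synthetic-signal benchmark of
pathway-rank recovery (uniform noise / membership-proportional /
network-proximity sampling), and resistance-distance validation of
reported reactions against an independent compound set on the
reaction-compound graph.

## Worked example

```r
library(diffenr)

# a synthetic knowledge graph scaled down ~10x from a curated human
# metabolic graph: 29 pathways, 1,019 nodes, heavy-tailed degrees
lg <- generate_synthetic_graph(level_sizes = default_benchmark_sizes(),
                               seed = 11)

# an input list of 35 compounds enriched for members of pathway P00001
probs <- signal_probabilities(lg, "P00001", scheme = "proportional")
inp   <- map_input(lg, sample_signal(probs, n_in = 35, seed = 2))

res <- enrich(lg, inp, method = "hd", approx = "norm", k = 150)
res
#> Enrichment result (HD norm)
#>   input compounds: 35
#>   selected nodes: 150 (k = 150)
#>   subgraph: 6 CC(s), largest 145 nodes
#>   pathways in solution: 2

head(res$pathways)
#> # A tibble: 2 x 5
#>   pathway statistic n_members  hits        ora_p
#>   <chr>       <dbl>     <int> <int>        <dbl>
#> 1 P00001       3.96       162    30 0.0000000286
#> 2 P00021       3.85        55    10 0.0158
```

Reading the output: 150 nodes were kept by z-score; 145 of them sit in
one connected component, the signature of a coherent perturbation
rather than scattered noise. The planted pathway `P00001` leads the
pathway table (z = 3.96; 30 of the 35 input compounds reach it in the
directed graph; the ORA baseline agrees at p ≈ 3e-8), and a
cross-talking pathway sharing part of the subgraph is reported next.
`tidy(res)` returns the full per-node score table, `glance(res)` a
one-row summary, and `autoplot(res)` a plot of the selected nodes'
statistics by level.

Other entry points: `heat_diffusion_scores()`, `pagerank_scores()`,
`analytic_null_moments()`, `monte_carlo_pvalues()`, `run_bias_study()`,
`run_recovery_study()`, `reaction_compound_graph()` /
`resistance_distance()` / `neighbour_comparison()`, and GraphML / TSV
import-export. Thin command-line wrappers live in `exec/`
(`generate-graph.R`, `enrich.R`, `benchmark.R`, `resistance.R`). The
vignette `vignettes/null-diffusion-enrichment.Rmd` documents the models,
the generator design and all numerical choices.

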