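# structdiv

Does a social network's wiring help or hinder the variety of opinions,
ideas and styles its population can sustain? `structdiv` answers this for
neutral imitation–innovation dynamics (the voter model with
infinite-alleles innovation, the cultural analogue of a neutral Moran
model) through a single network statistic, the **structural diversity
index**

$$\Delta(G) = \frac{\langle M_G \rangle}{|V(G)|},$$

where $\langle M_G\rangle$ is the expected *meeting time* of two
synchronous random walks started at independent uniform vertices of the
connected undirected graph $G$. By voter-model duality, meeting times are
pairwise meme-coalescence times, and the long-run Simpson diversity
$D_\infty = \lim_t \frac1t\sum_{s\le t} D(s)$ at per-capita innovation
rate $\alpha$ satisfies the saturation law
$D_\infty \approx 1 - e^{-2\alpha\Delta(G)}$. The complete graph has
$\Delta(K) = 1$ independent of size, so networks with $\Delta > 1$
*amplify* diversity and networks with $\Delta < 1$ *suppress* it:
heavy-tailed (scale-free) networks suppress, low-rewiring small-world
networks amplify.

The package is aimed at computational social scientists and network
scientists who want to score networks, reproduce the synthetic-network
analyses behind the index, or test interventions that raise it. It
provides:

* `estimate_delta()` — Monte-Carlo estimator of $\Delta(G)$ with
  right-censored geometric tail imputation, plus `exact_meeting_time()`,
  an exact pair-chain oracle for small graphs;
* `run_voter()`, `simpson_diversity()`, `duality_check()` — the voter
  model with innovation, its diversity trajectory, and a Monte-Carlo
  verification of the duality $1 - D(t) = p_r(t)$;
* `predicted_diversity()`, `classify_network()`,
  `complete_graph_index()`, `scale_free_bound()`,
  `ws_index_approximation()`, `heterogeneity_ratio_bound()`,
  `meeting_time_bounds()`, `fit_scalefree_scaling()` — closed forms,
  bounds and the size-exponent scaling fit;
* `graph_complete()`, `graph_watts_strogatz()`, `graph_scale_free()`,
  `read_edgelist()`/`write_edgelist()`, `network_statistics()`,
  `spectral_info()` — generators, plain-text edge-list I/O and the
  structural covariates (degree heterogeneity, Wiener index, edge
  density, clustering);
* `unfollow_top()`, `evaluate_intervention()`,
  `summarize_intervention_corpus()` — the decentralized "don't follow
  leaders" edge-removal intervention and its corpus-level summary;
* `synthetic_corpus()`, `standardized_loglog_ols()`, `run_experiment()` —
  reproducible synthetic corpora and the scripted experiments;
* a thin command line, `inst/cli/sdi.R`, for shell use
  (`index`, `voter`, `predict`, `bounds`, `stats`, `generate`,
  `unfollow`).

## Worked example

```r
library(structdiv)
set.seed(7)
g <- graph_watts_strogatz(500, 6, 0.01)   # small world, few long-range ties
est <- estimate_delta(g, n_realizations = 10000)
est
#> Structural diversity index estimate
#>   delta     4.4376 (se 0.0475)
#>   <M_G>     2218.81 steps (se 23.77), |V| = 500
#>   10000 realizations, 0 censored at smax = 50000
classify_network(est$delta, tolerance = 3 * est$std_error / 500)
#> [1] "amplifier"
run_voter(g, alpha = 1)
#> Voter-model diversity trajectory
#>   |V| = 500, r = 0.002 (alpha = 1), 5000 steps x 20 reps
#>   D_infinity = 0.8685
```

Two walkers need on average ~2219 steps to meet on this 500-vertex
network — 4.4 times the complete-graph benchmark — so the network
structurally amplifies diversity: simulated long-run Simpson diversity is
0.87, against 0.66 for an unstructured population of the same size and
innovation rate. (The saturation law's point prediction, 0.9999 here, is
an upper envelope; see the vignette on its accuracy.)

```r
network_statistics(g)
#> Network statistics
#>   size 500, edges 1500, <k> 6.000, <k^2> 36.040, Dmax 8
#>   kappa <k^2>/<k> 6.0067, normalized <k^2>/<k>^2 1.0011
#>   Wiener 2354521, edge density 0.0120
#>   clustering: global 0.5880, mean local 0.5895
#>   connected TRUE, bipartite FALSE
```

From the shell:

```sh
Rscript inst/cli/sdi.R generate --family ws --n 500 --k 6 --s 0.01 --seed 7 --out ws.edges
Rscript inst/cli/sdi.R index --graph ws.edges --realizations 10000 --seed 7
```

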