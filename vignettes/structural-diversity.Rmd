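---
title: "The structural diversity index: model, estimator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The structural diversity index: model, estimator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`structdiv` studies how the wiring of a social network shapes the long-run
variety of cultural traits ("memes": opinions, behaviours, styles) that the
population can sustain under neutral dynamics. The modelling frame is the
synchronous voter model with innovation, the cultural analogue of an
infinite-alleles Moran model in population genetics:

* a population occupies the vertices of a connected undirected graph $G$;
* initially every individual displays its own distinct meme;
* at every discrete step, **simultaneously**, each individual either invents
  a brand-new meme with probability $r$ (infinite-alleles innovation) or
  copies the current meme of a uniformly chosen neighbour with probability
  $1-r$.

Diversity at time $t$ is Simpson's index
$D(t) = 1 - \sum_m p_m(t)^2$, the probability that two individuals sampled
uniformly (with replacement) display different memes; its long-run time
average is $D_\infty$.

The package's central statistic is the **structural diversity index**
$$\Delta(G) = \frac{\langle M_G \rangle}{|V(G)|},$$
where $\langle M_G\rangle$ is the expected *meeting time* of two synchronous
random walks started at independent uniform vertices: the first step at
which they co-occupy a vertex. The index benchmarks against the complete
graph, where the meeting time is geometric with success probability
$\approx 1/|V|$ so that $\Delta(K) = 1$ for every size. Networks with
$\Delta > 1$ amplify diversity, networks with $\Delta < 1$ suppress it.

The link between the walk statistic and the dynamics is **voter-model
duality**: tracing meme ancestries backwards in time turns a pair of
individuals into a pair of coalescing random walks, each killed by an
innovation event with probability $r$ per step. Exactly,
$$1 - D(t) = p_r(t),$$
the probability that two $r$-halting walks from uniform starts meet within
$t$ steps before either halts. `duality_check()` verifies this identity by
simulating both sides and comparing the curves pointwise; on the triangle
and the Petersen graph the maximal z-score stays well below 3 at the
replicate counts used in the tests, which is the package's strongest
internal consistency check: the voter simulator and the walk simulator
agree in law.

Passing to $t \to \infty$ and approximating the meeting time by its mean
gives the saturation law used for prediction,
$$D_\infty \approx 1 - e^{-2\alpha\,\Delta(G)},$$
with $\alpha = r\,|V(G)|$ the per-capita innovation rate
(`predicted_diversity()`; with `exact_q = TRUE` the small-$r$ rate $2r$ is
replaced by the exact two-walk halting rate $q(r) = 2r - r^2$).

### Accuracy of the saturation law

The step from the exact duality to the saturation law replaces
$\mathbb{E}[(1-q)^{M_G}]$ by $(1-q)^{\langle M_G\rangle}$. By Jensen's
inequality the first quantity is always the larger, so the law
systematically **overpredicts** $D_\infty$, mildly when $\alpha\Delta$ is
small but substantially once $\alpha\Delta \gtrsim 0.5$ and the meeting
time has geometric-scale dispersion. On the complete graph at $\alpha = 1$
the exact stationary value is $\approx 0.66$ against a predicted $0.86$,
and across the package's synthetic battery (complete, Watts–Strogatz at
two rewiring levels, scale-free) the mean absolute gap measured by the
test suite is about $0.1$–$0.16$. The prediction is therefore a good
*ordering* of networks (larger $\hat\Delta$ reliably pairs with larger
$D_\infty$) and a reasonable approximation in the suppressed regime, but
not a precise point prediction near saturation. The test suite asserts a
0.05 mean-absolute-error band for this curve and that assertion fails; it
is retained deliberately as a documented limitation rather than weakened.

## Estimating the index

`estimate_delta()` simulates `n_realizations` (default $10^4$) independent
meeting times, each censored at $s_{\max} = 100\,|V(G)|$ steps (the
`smax_multiplier` default). Two numerical conventions matter:

* **Coincident starts count as meeting at step 0.** "Uniformly started"
  does not exclude coincidence, and the duality requires it: two sampled
  individuals coincide with probability $1/|V|$ and then trivially share a
  meme. Consequently the exact complete-graph value is
  $(1 - 1/n)(n-1)^2/((n-2)n)$ — e.g. $0.9901$ at $n = 100$ — rather than
  the idealized 1; Monte-Carlo tests compare against this value.
* **Meeting is co-location after the synchronous move.** Two walkers that
  swap across an edge have not met. This is forced by the duality
  timescale. It also means that on bipartite graphs walkers started at odd
  parity can never meet; `estimate_delta()` refuses bipartite input by
  default. A lazy-walk variant (each walker independently stays put with
  probability $1/2$) is available via `lazy = TRUE` as an extension; it
  changes the time scale and is never used by the standard index.

The meeting-time tail is approximately geometric (memoryless escape from
the bulk of the state space), so censored runs are handled by
right-censored geometric maximum likelihood: the per-step success estimate
is $\hat p = (\text{observed meetings})/(\text{total steps walked, with
censored runs contributing } s_{\max})$, and each censored run is imputed
as $s_{\max}$ plus a fresh geometric($\hat p$) draw. Sampling, rather than
plugging in the conditional mean, keeps the imputed values on the correct
scale of dispersion. The reported standard error is the sample standard
deviation of the (possibly imputed) meeting times over
$\sqrt{n_{\text{realizations}}}$; imputation noise is folded into the
sample and the figure slightly understates total uncertainty when the
censored fraction is large. At the default horizon, censoring is absent or
rare on all the synthetic families used here.

`exact_meeting_time()` is the independent oracle: it solves the absorbing
linear system of the product chain on ordered vertex pairs (a dense
$|V|^2$ solve, capped at 50 vertices) and averages over uniform starts.
The suite requires the Monte-Carlo estimate to sit within Monte-Carlo
error of the oracle on every fixture graph.

## Closed forms and bounds

For canonical families the index admits closed-form values or bounds,
exposed as `bound_report` objects:

* `complete_graph_index()` — the benchmark $\Delta(K) = 1$, or the exact
  pair-chain value above.
* `scale_free_bound()` — for power-law degree distributions
  $P(k) \sim k^{-\gamma}$ with natural cutoff, the degree-moment bound
  evaluates piecewise to $1$ for $\gamma \ge 3$,
  $n^{-(3-\gamma)/(\gamma-1)}$ for $2 < \gamma < 3$ and $n^{-1}$ for
  $\gamma \le 2$: heavier tails suppress diversity more.
* `ws_index_approximation()` — the empirical closed form
  $(s + 1/k)/(2s + 1/n)$ for Watts–Strogatz networks with rewiring
  probability $s$ and mean degree $k$. It exceeds 1 exactly when
  $s \le 1/k - 1/n$; the amplifier claim therefore applies in the
  small-$s$ regime and the crossing point is documented rather than hidden.
  No theoretical derivation is known for this formula and it is treated as
  an approximation only; at small $s$ it can overestimate simulated
  indices by a factor of a few, so tests assert the qualitative shape
  (monotone decreasing in $s$, amplification at small $s$), not the
  numerical value.
* `heterogeneity_ratio_bound()` — $\Delta \le \langle k\rangle^2 /
  \langle k^2\rangle \le 1$, tight exactly on regular graphs.
* `meeting_time_bounds()` — the spectral upper expression
  $(1-\lambda_2)^{-1}(2\log|V| + |V|\langle k\rangle^2/\langle k^2\rangle)$
  and the lower expression $|E|/D_{\max}$. The asymptotic statements behind
  these carry unknown constants, so the package reports plain expression
  values labelled as order-of-magnitude diagnostics and never uses them in
  pass/fail tests; only monotone trends across a family are asserted.

`fit_scalefree_scaling()` estimates the constants empirically: OLS of
$\log\Delta$ on $\log n^{-(3-\gamma)/(\gamma-1)}$ across a $\gamma$ grid
gives the model $\Delta = b\,n^{-a(3-\gamma)/(\gamma-1)}$.

## Generators and what the synthetic data do (not) emulate

* `graph_complete(n)` — the benchmark.
* `graph_watts_strogatz(n, k, s)` — ring lattice with $k/2$ neighbours per
  side; each original edge's far endpoint is independently rewired with
  probability $s$ avoiding self-loops and duplicates, so the edge count
  $nk/2$ is conserved for every $s$. Disconnected draws are regenerated
  (bounded retries). $s$ proxies the prevalence of long-range ties.
* `graph_scale_free(n, gamma, kmin)` — degree sequence drawn from
  $P(k)\propto k^{-\gamma}$ on $[k_{\min}, n-1]$, configuration-model stub
  pairing, erasure of self-loops/multi-edges, largest connected component.
  The configuration model was chosen because the exponent must be tunable;
  note that erasure truncates the realized heterogeneity of very
  heavy-tailed draws ($\gamma$ close to 2), which flattens the measured
  $\Delta(\gamma)$ relative to the idealized bound and makes the fitted
  scaling exponent sensitive to the generator convention. With the
  defaults here the fitted exponent lands around $0.10$–$0.21$ depending
  on the seed (one graph per $\gamma$, so graph-to-graph variability
  dominates the fit).

These families isolate single structural features (degree inequality;
long-range ties and clustering). They do not emulate degree–degree
correlations, community structure, geography or growth mechanisms of real
social networks, so tests passing on them demonstrate correctness of the
machinery and the direction of structural effects, not quantitative claims
about any real network. `synthetic_corpus()` builds a mixed WS/scale-free
corpus purely as a stand-in for exercising corpus-level analyses
(statistics tables, `standardized_loglog_ols()` regressions, intervention
summaries); coefficients estimated on it are properties of the stand-in,
not of any real collection.

## The unfollow intervention

`unfollow_top(g, h)` implements a decentralized "don't follow leaders"
rule: every vertex marks its edges to its $h$ highest-degree neighbours
and the union of marked edges is removed in one batch, keeping the largest
connected component. Three conventions, chosen where the verbal rule is
ambiguous:

* "most connected" means highest degree **in the original graph**, not
  recomputed during removal — the rule is one-shot and decentralized;
* an undirected edge disappears if **either** endpoint marks it;
* degree ties are broken by the session RNG ("tie sorting is random").

`evaluate_intervention()` flags residues that retain less than a quarter
of the vertices (`discarded = "size"`; no index is estimated for them),
and `summarize_intervention_corpus()` applies, per $h$ and after the size
filter, a one-standard-deviation outlier filter on the relative index
change before fitting the OLS trend of relative change on $h$. The
filters' order of operations is fixed and tested on constructed fixtures.
On Watts–Strogatz corpora the intervention raises the index with high
confidence; the numeric slope depends on the corpus.

## Numerical and reproducibility choices

* All randomness (R level and the C++ kernels, which draw from R's RNG)
  flows from the session RNG: `set.seed()` makes every simulation,
  generator and experiment exactly reproducible.
* $D_\infty$ is the plain time average of $D(t)$ over $t = 1..10|V|$ and
  (default) 20 replicates with **no burn-in**; a `burn_in` option exists
  but defaults to 0 so the estimand matches the stated protocol exactly.
* Dense eigensolves (`spectral_info()`) and the pair-chain oracle are
  capped at 5000 and 50 vertices respectively and refuse larger input
  rather than silently approximating.
* Default problem sizes were chosen to keep every simulation comfortably
  in the seconds range on one CPU while leaving Monte-Carlo error far
  below the effect sizes tested: $10^4$ meeting-time realizations at
  $n = 10^3$; voter runs of $10|V|$ steps and 20 replicates at
  $n \le 500$; duality at $4\,000$ voter and $4\times 10^4$ walk
  replicates on graphs of at most 10 vertices; intervention corpora of
  10–20 networks at $n \approx 200$.

## Known limitations

* The saturation law is an upper envelope for $D_\infty$ (see above); use
  it for ordering and regime classification, not point prediction near
  saturation.
* Bipartite graphs have no finite synchronous meeting time; the lazy-walk
  escape hatch changes the time scale and is not comparable to standard
  index values.
* The Watts–Strogatz closed form and the scale-free bound are asymptotic
  or empirical statements with unknown constants; at moderate $n$ they can
  be off by factors.
* Only undirected, unweighted, simple graphs are supported.
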