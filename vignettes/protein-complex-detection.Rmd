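---
title: "Detecting protein complexes with parametric local modularity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting protein complexes with parametric local modularity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mipalm)
```

## The problem

Protein complexes — groups of proteins that physically assemble to carry out
a cellular function — appear in protein–protein interaction (PPI) networks
as unusually dense sub-graphs. Finding them computationally is hard for two
reasons: PPI networks are noisy (both false and missing interactions are
common), and known complexes are small (median size below ten proteins),
which puts them below the resolution limit of global modularity
maximisation. `mipalm` implements the miPALM algorithm, which addresses the
resolution problem with a *parametric local modularity* score and addresses
noise with a topological-overlap seeding strategy.

## The score

For an undirected simple network with `m` edges, the global modularity of a
partition is

$$Q = \sum_s \left[ \frac{m_{ss}}{m} - \left(\frac{d_s}{2m}\right)^2 \right],$$

where $m_{ss}$ counts edges inside module $s$ and $d_s$ is the sum of its
members' degrees. The squared term is the expected fraction of intra-module
edges under a degree-preserving random rewiring of the *entire* network —
and that global expectation is what makes $Q$ blind to small modules. The
local variant of Muff and colleagues ($LQ$, available here as
`local_modularity_muff()`) replaces $m$ with the edge count of the module's
immediate neighbourhood, the opposite extreme.

The parametric score interpolates between the two. For a single candidate
sub-network $S$,

$$LQ_\alpha = \frac{m_{SS}}{m} -
  \left(\frac{d_S}{2\,m^{(\alpha+1)/2}}\right)^2, \qquad 0 \le \alpha \le 1,$$

where the *coarseness parameter* $\alpha$ acts like the resolution dial of a
microscope: $\alpha = 1$ recovers the global expectation, and smaller
$\alpha$ shrinks the effective background. The fraction of edges effectively
used as background is the edge-coverage ratio $r = m^{\alpha-1}$
(`edge_coverage_ratio()`); conversely a target coverage translates into
$\alpha = 1 + \log_m r$ (`alpha_for_coverage()`).

Merging a protein $v$ into $S$ changes the score by

$$\Delta LQ_\alpha(v, S) = \frac{1}{m}\left(m_{vS} -
  \frac{d_v\,d_S}{2\,m^\alpha}\right),$$

with $m_{vS}$ the number of edges from $v$ into $S$. All degrees refer to
the full input network, never to an induced sub-graph: the expectation is a
configuration-model quantity. Note that $\Delta LQ_\alpha$ is defined
relative to the scores of the two merged parts
($LQ_\alpha(S \cup v) - LQ_\alpha(S) - LQ_\alpha(\{v\})$, exactly as the
global $\Delta Q$ is), so the raw score of the growing sub-network can dip
slightly even when every accepted gain is non-negative; the test suite
checks the exact decomposition identity rather than naive monotonicity.

## The algorithm

1. **Edge weighting.** Every edge gets a topological-overlap weight
   $O_T(v,w) = |\Gamma(v,w)| / ((k_v + k_w)/2)$ — shared neighbours
   normalised by the average degree. The average (rather than the classical
   minimum) keeps hubs from being scored as topologically equal to their
   small partners.
2. **Seeding.** All triangles are enumerated with an edge-iterator scheme
   (for each edge, report the common neighbours of its endpoints, then
   delete the edge from a working copy; $O(k_{\max} m)$) and ranked by the
   mean weight of their three edges. Triangles whose edges share no further
   neighbours get weight 0; they are kept and ranked last.
3. **Greedy expansion.** Each seed not already covered by an earlier result
   (covered = all three proteins inside a single previously grown
   candidate; this definition deliberately allows overlapping complexes)
   is grown by repeatedly merging the frontier protein with the largest
   $\Delta LQ_\alpha$, while that maximum is non-negative. Gains are
   maintained incrementally — a merge updates a retained frontier
   protein's gain by $\Delta LQ_\alpha(v, \{v^*\})$ and initialises newly
   reachable proteins from the pre-merge degree sum — so a merge costs
   $O(d_S)$ rather than a full recomputation.
4. **Unpromising seeds.** Candidates that never grow past their three seed
   members are discarded.
5. **Merging.** Candidate pairs with overlap score
   $|S \cap T| / \min(|S|,|T|)$ *strictly* above 0.5 are unioned,
   highest-overlap-first, rescoring after every union. Without this step
   seed expansion in one dense region produces many near-duplicates.
6. **Density filter.** Each merged complex is scored by
   $\delta_s = [m_{ss} / \binom{n_s}{2}] \cdot n_s$ (a clique of size $n$
   scores $n$) and complexes with $\delta_s < \delta$ are removed;
   equality is kept.

## Parameters

* `alpha` (unitless, in $[0,1]$): background coarseness. The practical
  optimum sits in the middle of the range on real yeast networks; the
  synthetic benchmark here uses 0.5, which makes the background penalty
  scale as $1/\sqrt{m}$.
* `delta` (unitless, in $[0, n_{\max}]$): density-score cutoff. 2 is a
  sensible default — it admits, for example, any sub-network at least half
  as dense as a clique of size 4 — and `tune_mipalm()` searches
  $[0, 3.5]$ when a gold standard is available.
* `tune_mipalm()` reproduces the published tuning protocol: `alpha` over
  $[0,1]$ in steps of 0.01, refined to 0.001 within 0.01 of the coarse
  optimum, then `delta` over $[0, 3.5]$ in steps of 0.01 at the chosen
  `alpha`, maximising the F-measure at matching threshold 0.2. Because the
  density filter is the last pipeline stage, the `delta` sweep reuses one
  unfiltered run and refilters — an exact shortcut, not an approximation.

## Numerical and determinism choices

* The stop rule is the strict `< 0` of the pseudo-code: a frontier whose
  best gain is exactly 0 keeps growing. Because incrementally maintained
  gains accumulate rounding error of order $10^{-15}$ per merge, a cached
  maximum falling in $(-10^{-9}, 0)$ triggers one direct recomputation of
  the frontier gains before the search commits to stopping; this keeps the
  strict rule faithful at exact-zero boundaries.
* Every tie is broken deterministically: the greedy argmax by smallest
  protein ID, seed ranking by lexicographic member triple, merging by
  smaller combined size then lexicographic content. `run_mipalm()` on a
  fixed input is therefore bit-identical across runs — there is no
  randomness anywhere in the pipeline.
* The refine hook of the published pipeline ("refine S by looking around
  S") has no published definition; `run_mipalm(refine = TRUE)` is accepted
  but currently a documented no-op, kept so a refinement rule can be added
  without changing the interface.
* In `local_modularity_muff()`, the neighbourhood edge count $m_s$ is taken
  as the edges with at least one endpoint in the module; whether edges
  lying entirely among first neighbours should also count is ambiguous in
  the original formulation. The function is a comparison utility only — the
  pipeline never uses it — so the convention is documented rather than
  load-bearing.

## Evaluation stack

`evaluate_complexes()` uses the matching score $\omega = c^2/(ab)$ and
counts matched *entities*: precision is the fraction of predictions
matching at least one known complex at $\omega \ge 0.2$, recall the
fraction of known complexes matched by at least one prediction (this is the
reading adopted here; the alternative — counting matched predictions in the
recall numerator — would make recall exceed 1 when several predictions hit
one complex). F is the harmonic mean, with the convention $P = 0$ when
there are no predictions.

`go_enrichment()` is an exact hypergeometric upper-tail test per label,
Bonferroni-corrected by the number of labels actually tested for that
complex; the background defaults to all annotated proteins, the
conservative network-restricted choice.

`colocalization_log_odds()` compares the observed number of intra-complex
*edges* with both endpoints in a compartment against its expectation under
the complex's own connectivity $p_s = 2 m_{ss}/(n_s(n_s-1))$. The
edge-connected reading of "co-localized pairs" is a deliberate choice: if
all member pairs were counted instead, the observed/expected ratio would
reduce to $1/p_s$ for every compartment and the score could not
discriminate between compartments at all. One consequence worth knowing:
a perfect clique whose members all share a compartment scores exactly
$\log(m_{ss}/m_{ss}) = 0$ and is *not* called localized under the strict
`> 0` rule.

## The synthetic benchmark

`generate_synthetic()` plants dense Erdős–Rényi sub-graphs (re-drawn until
connected and containing a triangle — a triangle-free planting could never
be seeded and would make recovery tests vacuous) in a sparse Erdős–Rényi
background, wires each complex to the background with a few attachment
edges, and emits the planted sets as the gold standard plus an annotation
table with one private label per complex and uniform noise labels. The
defaults — 20 planted cliques of size 6–10, 500 background nodes at edge
probability 0.005, two attachment edges per complex — define the "easy
regime" the recovery tests use: at $\alpha = 0.5$, $\delta = 2$ the
pipeline recovers the planted complexes with mean F-measure above 0.8
across seeds.

What the generator does *not* emulate: scale-free degree distributions,
experiment-specific false-positive structure (spoke/matrix artefacts of
affinity purification), correlated noise, or complexes attached to each
other. Passing the recovery tests therefore shows the machinery is correct
and well-calibrated on idealised planted structure; it does not certify
performance on any particular real interactome, where parameters should be
re-tuned against a curated catalog with `tune_mipalm()`.

Problem sizes throughout the test suite are deliberately small — random
graphs up to 50 nodes for the algebraic identities (where brute-force
oracles are exact), and the 500-node easy regime for end-to-end recovery —
sizes at which every quantity can be cross-checked by direct enumeration.

## A worked example

```{r example}
sim <- generate_synthetic(synthetic_spec(seed = 1))
fit <- run_mipalm(sim$network, alpha = 0.5, delta = 2)
fit
glance(evaluate_complexes(fit, sim$gold))
```

## Known limitations

* Edge weights influence seeding only; the greedy expansion itself treats
  the network as unweighted. Extending $\Delta LQ_\alpha$ to weighted
  networks is a natural but unimplemented generalisation.
* Overlap handling is heuristic: the 0.5 merge threshold is fixed, and
  merged complexes are re-scored on the network but never re-grown.
* The hypergeometric test treats labels as flat and independent; no
  ontology structure is used, so enrichment fractions depend on the
  annotation granularity supplied.
* Greedy expansion finds a local optimum per seed; there is no backtracking
  and no global objective.
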