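# mipalm

Protein complexes appear in protein–protein interaction (PPI) networks as
small, unusually dense sub-graphs — typically fewer than ten proteins.
Global modularity maximisation cannot resolve structure that small, and
local search in noisy interactomes needs careful seeding. `mipalm`
implements the miPALM algorithm for this problem: it is aimed at anyone who
has an edge list of physical interactions (DIP/BioGRID-style exports) and
wants a ranked, reproducible set of candidate complexes plus the standard
evaluation stack to judge them.

## The method in brief

For a candidate sub-network *S* in a network with *m* edges, the score is
the **parametric local modularity**

> LQ<sub>α</sub> = m<sub>SS</sub>/m − (d<sub>S</sub> / 2m<sup>(α+1)/2</sup>)²,  0 ≤ α ≤ 1,

where m<sub>SS</sub> counts intra-*S* edges and d<sub>S</sub> sums member
degrees. The coarseness parameter α tunes the size of the background
neighbourhood used for the expected-edges term (α = 1 is global
Newman–Girvan modularity; smaller α covers a fraction
r = m<sup>α−1</sup> of the edges and favours smaller complexes). The
pipeline:

1. weight every edge by topological overlap
   O<sub>T</sub>(v,w) = |Γ(v,w)| / ((k<sub>v</sub>+k<sub>w</sub>)/2);
2. enumerate all triangles (edge-iterator, O(k<sub>max</sub>·m)) and rank
   them as seeds by mean edge weight;
3. greedily expand each uncovered seed by merging the neighbour with the
   largest gain ΔLQ<sub>α</sub>(v,S) = (1/m)(m<sub>vS</sub> −
   d<sub>v</sub>d<sub>S</sub>/2m<sup>α</sup>) while that gain is ≥ 0,
   with incremental O(d<sub>S</sub>) updates per merge;
4. drop candidates that never grow past their seed, merge pairs with
   overlap |S∩T|/min(|S|,|T|) > 0.5, and filter by the density score
   δ<sub>s</sub> = [m<sub>ss</sub>/C(n<sub>s</sub>,2)]·n<sub>s</sub>.

Everything is deterministic: fixed input, bit-identical output.

## Worked example

The package ships a seeded generator of benchmark networks with planted
complexes, so the full workflow runs without any downloads:

```r
library(mipalm)

sim <- generate_synthetic(synthetic_spec(seed = 1))
sim$network
#> <ppi_network> 620 proteins, 1225 interactions

fit <- run_mipalm(sim$network, alpha = 0.5, delta = 2)
fit
#> miPALM fit (alpha = 0.5, delta = 2)
#>   seeds: 1236 (495 covered, 612 unpromising size-3)
#>   candidates: 129 -> 21 after merging -> 21 after density filter
#> # A tibble: 10 × 5
#>    complex  size n_edges density_score members
#>    <chr>   <int>   <int>         <dbl> <list>
#>  1 M1         11      46           9.2 <chr [11]>
#>  2 M2         11      46           9.2 <chr [11]>
#>  3 M3         11      46           9.2 <chr [11]>
#>  4 M4          9      36           9   <chr [9]>
#> ...

glance(evaluate_complexes(fit, sim$gold))
#> # A tibble: 1 × 6
#>   precision recall f_measure threshold n_pred n_known
#>       <dbl>  <dbl>     <dbl>     <dbl>  <int>   <int>
#> 1     0.810   0.85     0.829       0.2     21      20
```

Of 1236 triangle seeds, most are either already covered by an earlier
expansion or fail to grow beyond three members; the 129 surviving
candidates collapse to 21 complexes after overlap merging, all of which
clear the density threshold δ = 2. Evaluated against the 20 planted
complexes at matching threshold ω ≥ 0.2, 17 of 21 predictions and 17 of 20
planted complexes are matched (precision 0.81, recall 0.85, F = 0.83).

`tidy(fit)` returns the complex table, `autoplot(fit)` plots size against
density score, `tune_mipalm(net, gold)` grid-searches (α, δ) against a
catalog, and `go_enrichment()` / `colocalization_log_odds()` score
biological coherence from annotation tables. Real networks are read with
`read_ppi_network("edges.tsv")` and catalogs with
`read_complex_catalog("complexes.tsv")`. A thin command-line wrapper with
`predict`, `tune`, `evaluate` and `simulate` subcommands ships at
`inst/cli/mipalm.R`.

See the vignette (`vignettes/protein-complex-detection.Rmd`) for the full
account of the score, the tie-break and stopping conventions, and what the
synthetic benchmark does and does not emulate.

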