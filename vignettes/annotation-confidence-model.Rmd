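---
title: "The neighborhood-based annotation confidence model"
author: "annopac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The neighborhood-based annotation confidence model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bacterial genomes are annotated at a pace that rules out manual curation, yet
most downstream biology — comparative genomics, metabolic models, experiment
design — is only as good as the functional assignments it consumes. `annopac`
scores the *internal consistency* of a genome's functional annotation by
exploiting one robust property of bacterial chromosomes: functionally related
genes sit close together, most strongly within operons. If a gene's annotated
function is similar to those of its chromosomal neighbors more often than
chance would predict, that annotation is more likely to be right.

The package turns this into a per-gene posterior probability (the PAC,
probability of annotation confidence) and a genome-level score (the AQS,
annotation quality score). It makes no attempt to *find* genes or to correct
start sites; the gene calls and their GO annotations are the input under
evaluation.

## The model

**Term similarity.** For two GO terms in the same namespace, let $S_1$ and
$S_2$ be their ancestor closures under is-a edges — the term itself plus every
is-a predecessor, excluding the namespace root, which every term reaches and
which therefore carries no information. Their similarity is the Jaccard index

$$\mathrm{GOsim}(t_1, t_2) = \frac{|S_1 \cap S_2|}{|S_1 \cup S_2|} \in [0, 1].$$

Only is-a edges are used; `part_of` and `regulates` semantics differ enough
that mixing them blurs the subclass hierarchy the score relies on.
Information-content similarities (Resnik, Lin) are deliberately out of scope:
the Jaccard form needs no corpus statistics beyond the ontology itself.

**Gene similarity.** Genes carry sets of terms, so the gene function
similarity (GFS) between two genes in one namespace is the *maximum* GOsim
over all cross pairs of their term sets. The maximum, rather than an average,
keeps multi-functional proteins from being penalized for their unrelated
roles. GFS is computed separately for biological process, molecular function
and cellular component; if either gene lacks terms in a namespace the
observation is *missing*, not zero.

**The observation profile.** Each gene $G$ is described by the GFS values
with its six neighbors at offsets $-3,\dots,+3$ on the chromosome, per
namespace — up to 18 observations. Replicons are treated as circular by
default (bacterial chromosomes and most plasmids are), with linear truncation
available per replicon. Windows never cross replicon boundaries, and on a
replicon shorter than seven genes an offset that wraps onto the focal gene
itself is dropped rather than scoring the gene against itself.

**Likelihoods.** For each offset, namespace (and strand stratum, in the
strand variant), the package estimates two empirical distributions of GFS:
one from the genome under its given annotation (assumed correct), one under a
randomized annotation in which every annotated gene receives the complete
term sets of a protein drawn uniformly from a background pool (assumed
incorrect). GFS is continuous, so each cell is discretized into 10
equal-width bins over $[0,1]$ (left-closed, last bin closed) and smoothed
with a Laplace pseudocount of 1:
$\Pr(\mathrm{bin}) = (n_{\mathrm{bin}} + \alpha)/(N + \alpha K)$. Binned
empirical frequencies are the minimal-assumption estimator for an unknown
density, and the smoothing prevents zero likelihoods that would otherwise pin
a posterior at exactly 0 or 1 on the strength of a single unprecedented
observation. Both the bin count and the pseudocount are configurable.

**Bayes combination.** With prior $\Pr(A_c) = 0.5$ (annotation equally
likely right or wrong, absent other evidence) and independence across
observations, the posterior that the annotation is correct is

$$\mathrm{PAC} = \frac{\Pr(A_c)\prod_i \Pr(O_i \mid A_c)}
{\Pr(A_c)\prod_i \Pr(O_i \mid A_c) + \Pr(A_{inc})\prod_i \Pr(O_i \mid A_{inc})}.$$

Missing observations are skipped from both products, on the grounds that the
absence of information arises equally under either hypothesis. Products of up
to 18 small factors underflow readily, so the implementation accumulates in
log space with a single stable normalization at the end. A gene with no
non-missing observation is *ineligible* and is excluded from genome summaries
rather than being given a default score. Each gene is scored against the
fixed annotations of its neighbors — there is no iterative joint relabeling.

**Genome summary.** PAC values are histogrammed into twenty bins of width
0.05, with $[0.95, 1]$ closed so the high-confidence category is exactly one
bin. The AQS is the fraction of eligible genes in that top bin.

## Model variants

* **Operon mode** keeps only the observations whose neighbor shares the focal
  gene's operon identifier. Fewer genes remain eligible, but the retained
  observations carry the strongest signal, so the high-confidence fraction
  among eligible genes rises. Operon assignments are taken verbatim from the
  caller (a predicted or curated partition); the package does not predict
  operons.
* **Strand mode** doubles every likelihood cell into same-strand and
  opposite-strand strata, letting the model learn that same-strand neighbors
  are more informative, without discarding the others.
* **Dependent (chain) mode** relaxes independence within each direction:
  $\Pr(O_{\pm1}|A)\,\Pr(O_{\pm2}|O_{\pm1},A)\,\Pr(O_{\pm3}|O_{\pm2},A)$, with
  first-order conditional bin tables estimated from profile pairs where both
  observations are present. When the conditioning observation is missing, the
  conditioned one falls back to its marginal table — the least-assumption
  fallback, and the one that makes the independent model the exact degenerate
  case of the chain. The conditioning is on the adjacent observation *toward*
  the focal gene; conditioning outward is the other defensible reading, but
  inward conditioning keeps the first factor (the most informative offset)
  unconditional.

## Abundant-term filtering

Very common terms (a generic "membrane" component, say) let random gene pairs
share function and inflate GFS. Terms whose background frequency — the
fraction of annotated background proteins listing the term directly — exceeds
5% are removed before profiling. The package removes them both from direct
annotation sets *and* from ancestor closures during similarity computation:
leaving an abundant ancestor inside the closure of a retained rare term would
re-introduce exactly the spurious overlap the filter targets. Removal from
direct sets only is available (`mask_closures = FALSE`) for comparison. A
gene left with no terms in a namespace after filtering is simply unannotated
there.

## The synthetic study conditions

The generator produces self-contained fixtures with the statistical structure
the method assumes, so every stage is testable without external databases:

* a rooted DAG per namespace (default 120 terms each, every non-root term
  attaching to 1–2 earlier terms), small enough to keep ancestor closures
  varied but overlapping;
* a circular 2,000-gene chromosome partitioned into operons with geometric
  sizes of mean 3 (typical of bacterial operon length distributions), one
  strand per operon;
* per namespace, each gene is annotated with probability 0.7 (roughly the
  GO coverage of a well-annotated bacterium); an annotated gene draws
  $1 + \mathrm{Pois}(1)$ terms, each from the sub-DAG under its operon's
  "theme" term with probability $\rho(1-\mathrm{noise}) = 0.8 \times 0.9$,
  and uniformly otherwise.

All randomness flows from one seed through named substreams (ontology,
genome, annotation), so stages regenerate independently. What the generator
does *not* emulate: realistic GO topology (GO is far deeper and bushier),
inter-operon functional clustering (pathways spanning adjacent operons),
evidence-code heterogeneity, and partially wrong annotations (terms near but
not in the right sub-DAG). Passing tests on this generator therefore
demonstrate that the estimator and the Bayes machinery recover planted
neighborhood signal and stay calibrated under the model's own assumptions —
not that any particular real genome will show the same AQS.

## Numerical and design choices

* Bin boundary convention: left-closed bins with the last bin closed, so 0
  and 1 both land in real bins; the PAC histogram adds a $10^{-9}$ fuzz so a
  value of exactly 0.95 lands in the closed top bin despite floating-point
  representation.
* Ancestor closures and term-pair similarities are memoized per ontology
  object; masking terms resets the caches. Correctness of the cache is part
  of the brute-force oracle test.
* Roots are detected structurally (no is-a parent) rather than by hard-coded
  identifiers, so synthetic ontologies work unchanged; when a namespace has
  several parentless terms (e.g. terms attached only by `part_of` in the
  source file), the one with the most descendants is the root and the rest
  are kept as orphans with a warning.
* Randomization draws pool entries with replacement across genes — each
  gene's random annotation is an independent draw; the without-replacement
  constraint applies to the shuffling experiment, where each annotation is
  used once per repeat.
* The shuffling experiment rescores with the likelihood model fixed at its
  unshuffled estimate: the experiment probes scoring sensitivity, not
  re-estimation. No check prevents swapping similar or identical
  annotations; the measured degradation is therefore a lower bound on
  sensitivity per swap.
* When no external background pool is supplied, the genome's own annotations
  serve as the pool (logged prominently). This is the fully self-contained
  default; with a large external pool, term frequencies and random draws are
  less tied to the genome under study.
* Problem sizes in the test suite and the reproduction script: the main
  study uses the default 2,000-gene genome; the shuffling experiment uses a
  600-gene genome with 20 repeats per grid point over
  $N_r \in \{0, 10, 25, 50, 100\}$, which resolves the monotone trend
  clearly.

## Known limitations

* Physical base-pair distance is not an available neighborhood definition;
  the window is counted in genes.
* The hybrid operon system (operon-derived likelihoods for within-operon
  pairs *plus* a second set for the rest) is not implemented; operon mode is
  restriction-only.
* Cross-namespace similarity is undefined by construction; a gene annotated
  in only one namespace contributes nothing in the others.
* The dependent model estimates $K \times K$ conditional tables per cell and
  needs substantially more data than the independent model; on sparse
  genomes its conditionals collapse toward the smoothing prior.
* The command-line interface maps GAF object identifiers to gene identifiers
  verbatim (with an optional alias table); database-specific identifier
  mapping is out of scope.

## A worked run

```{r, eval = FALSE}
library(annopac)

cfg <- simulation_config(seed = 1, n_genes = 2000)
graph <- simulate_ontology(cfg)
sim <- simulate_genome(cfg, graph)

freqs <- term_frequencies(background_pool(sim$annotations))
filt <- apply_term_filter(sim$annotations, graph, freqs, cutoff = 0.05)

prof <- build_profiles(sim$genome, filt$annotations, filt$graph)
rand <- random_annotation(filt$annotations,
                          background_pool(filt$annotations), seed = 2)
prof_rand <- build_profiles(sim$genome, rand, filt$graph)

model <- estimate_likelihoods(prof, prof_rand)
score <- score_profiles(prof, model, all_genes = sim$genome$gene_id)
score
calibration_curve(score,
                  score_profiles(prof_rand, model,
                                 all_genes = sim$genome$gene_id))
```
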