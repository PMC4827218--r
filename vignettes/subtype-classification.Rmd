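---
title: "Rank-based single-sample subtype classification: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based single-sample subtype classification: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbsubtyper)
```

## The problem

Medulloblastoma has four consensus molecular subtypes — WNT, SHH, Group3 and
Group4 — with very different prognoses and biology; Group3 and Group4 are the
least characterized and most aggressive. Two practical obstacles make
subtyping individual profiles hard. First, most expression classifiers need
a batch, replicates or a normal-cerebellum reference to normalize against,
which a single clinical sample or a one-off mouse-model profile does not
have. Second, mouse models are profiled on mouse platforms with mouse gene
symbols, so a classifier trained on human tumours cannot compare profiles
gene-by-gene across species.

This package addresses both by moving the comparison out of gene space into
gene-set rank space. Everything the classifier consumes from a sample is the
ordering of Gene Ontology Biological Process (GO BP) gene-set enrichments
within that one sample, which (a) makes the prediction independent of every
other sample and of the expression scale, and (b) lets human and mouse meet
on shared GO term names rather than orthologous genes.

## The model

### Per-sample enrichment

Within a sample, genes are ranked by expression (largest rank value = highest
expression, ties averaged). For a gene set $S$ among $G$ measured genes, the
enrichment score walks the genes in decreasing-expression order and
integrates the gap between two empirical distributions — set members,
weighted by rank to the power $\alpha$, against non-members:

$$\mathrm{ES}(S) \;=\; \sum_{i=1}^{G}\left[
\frac{\sum_{g \in S,\; \mathrm{pos}(g) \le i} r_g^{\alpha}}
     {\sum_{g \in S} r_g^{\alpha}}
\;-\;
\frac{\#\{g \notin S,\ \mathrm{pos}(g) \le i\}}{G - |S|}
\right]$$

Set members that are not measured on the platform are ignored (their count
is reported); a set with no measured members is dropped with a warning, and
a set covering every measured gene is an error because the non-member
distribution is undefined. A sample whose expression is constant across all
genes has no meaningful ordering and is rejected with an error rather than
given a silent uniform rank.

Two variants are exposed through `es_mode`: the default `"integrated"` sum
above (the single-sample GSEA statistic) and `"max"`, the classic
maximum-deviation running-sum value. Downstream only consumes ES *ranks*,
so the choice rarely changes calls, but the default matches the named
method.

### Training

`build_reference()` runs ssGSEA on a labelled cohort, scores every gene
set's between-class separation, keeps the `n_top` best, and ranks the kept
sets by descending ES within each sample. The separation statistic is the
Kruskal–Wallis $H$ of ES across classes — chosen because it is
distribution-free and rank-based like the rest of the pipeline, and it
degrades gracefully: a gene set with identical ES everywhere scores 0. Ties
in $H$ break by gene-set name so selection is fully deterministic. The
reference keeps only the rank matrix, labels and hyperparameters — not the
expression — so any labelled cohort can play the reference role.

The label vocabulary is closed over five classes (WNT, SHH, Group3, Group4,
Normal). A training cohort may cover any subset of at least two; the
prediction surface always reports votes over all five.

### Prediction

For a test sample: ssGSEA over its species' GMT, restriction of both sides
to the gene sets shared with the reference, re-ranking over the
intersection, then a $k$-nearest-neighbour vote (default $k = 5$, Euclidean
distance between rank vectors, Manhattan available). Each neighbour casts
one unweighted vote; the winning fraction is the confidence, and calls at
$\ge 80\,\%$ of votes are `high_confidence` while lower fractions are
`intermediate` — with $k = 5$ the confidence lattice is exactly
$\{0, 20, 40, 60, 80, 100\}$, so the rule separates 4/5 and 5/5 agreement
from everything below.

Two behaviours deserve emphasis:

* **Re-ranking after harmonization.** A rank is only meaningful within a
  fixed gene-set universe, so when the platform intersection shrinks the
  universe, the reference rank rows are recomputed over the surviving sets
  rather than subsetted (`rerank = FALSE` preserves the stale-rank
  behaviour for comparison). Overlaps below 10 sets trigger a warning.
* **Deterministic tie-breaks.** Equal distances at the $k$-th position
  resolve by reference sample id; vote ties resolve by smaller mean
  neighbour distance, then by canonical label order (WNT, SHH, Group3,
  Group4, Normal). Identical inputs give identical predictions across runs
  and platforms.

PCA (`pca_project()`, `plot_pca()`) is visualization only — a centred,
unscaled projection of the reference rank matrix with test samples mapped
into the same space. The KNN vote always operates in the full rank space,
never in the 2- or 3-component view.

## Tunable parameters

| parameter | default | units / range | role |
|---|---|---|---|
| `alpha` | 0.25 | unitless, $\ge 0$ | rank weight in ssGSEA; 0 = unweighted ECDF gap |
| `es_mode` | `"integrated"` | — | ES variant (integrated sum vs max deviation) |
| `n_top` | 100 | count | discriminative gene sets kept at training |
| `k` | 5 | count, $\le$ cohort size | neighbours voting per prediction |
| `metric` | `"euclidean"` | — | distance on rank vectors |
| `min_overlap` | 10 | count | shared-gene-set floor before a warning |

`alpha` and the ES variant are exposed rather than hard-coded because the
method family admits both and the downstream rank transform is the part
that matters. `k = 5` is the method's published operating point and makes
the 80 % rule equal "at least 4 of 5 neighbours agree".

## The synthetic cohort generator

`simulate_cohort()` emulates the structure the classifier assumes and
nothing more: genes partition into disjoint 20-gene blocks (50 blocks over
1000 genes), each class owns 3 signature blocks, and a sample of class $c$
is i.i.d. $\mathcal{N}(0, \sigma^2)$ noise plus a $+3\sigma$ mean shift on
$c$'s signature genes ($\sigma = 1$, 30 samples per class by default).
`mixing` splits the shift between a class and its cyclic partner to emulate
intermediate genotypes; `simulate_replicates()` draws many samples from one
class template, the situation of profiling replicates of a single mouse
model. `simulate_species_pair()` derives a mouse GMT with identical term
names and deterministically transformed member symbols plus the ortholog
map, supporting the cross-species equivalence check by construction.
Generation is bit-reproducible from the config seed (R's default
Mersenne-Twister) and leaves the caller's RNG stream untouched.

Gaussian noise on a log-like scale is a deliberate simplification: the
classifier is rank-based, so the noise family mainly controls tie
frequency, and Gaussian draws make exact ties almost surely absent. What
the generator does **not** emulate: heavy-tailed count noise,
platform/batch effects, correlated co-expression outside the signature
blocks, class imbalance, and real GO term content or overlap between sets.
Passing tests on synthetic cohorts therefore demonstrate the pipeline's
correctness and its behaviour under a known signal model — not clinical
accuracy on real tumours, which depends on the user's training cohort.

## Validation experiment sizes and choices

The recovery experiments (in the test suite and `scripts/acceptance.R`)
train on 30 samples per class and score 100 held-out samples — large enough
for stable percentages, small enough to run in seconds on one core. The
discriminative panel there is `n_top = 15`, the generating model's own
discriminative dimension (5 classes × 3 signature sets): a synthetic
validation asks whether the classifier recovers a known signal given a
correctly sized panel, mirroring how the real tool ships a trained
discriminative gene-set list. Admitting deliberately non-informative
background blocks dilutes the vote — background ranks contribute random
distance variance that signature positions must overcome — which degrades
confidence long before accuracy; users training on real cohorts should
size `n_top` generously only when their collection plausibly contains that
many informative sets. The null-calibration experiment re-trains on a
zero-shift cohort and checks that accuracy sits at the 20 % chance level
and predicted-class frequencies are uniform (chi-square).

## Numerical choices and degenerate inputs

* Expression ties get average ranks; tie order along the running sum
  follows input gene order, so results are reproducible across platforms.
* ES equality to the per-position oracle is asserted to $10^{-10}$
  *absolute* — ES values near zero make relative tolerances meaningless.
* The reference archive is a versioned plain-text TSV block format;
  unknown versions, missing sections and ragged rows are explicit errors,
  never reinterpreted.
* Readers reject rather than repair: duplicate gene rows, non-numeric
  cells, unknown labels and malformed GMT lines all error with a location.

## Known limitations

* Confidence is a vote fraction over 5 neighbours, not a calibrated
  probability; there is no rejection option beyond the `intermediate` call.
* Cross-species transfer rests entirely on the shared GO BP term namespace;
  terms annotated in only one species silently shrink the feature space
  (warned below 10).
* The package performs no normalization, probe collapsing or symbol
  aliasing; inputs are assumed to be normalized matrices keyed by the same
  symbol vocabulary as the GMTs.
* With tiny training cohorts (a few samples per class) the 5-NN vote
  saturates and confidences lose granularity; references should comfortably
  exceed $k$ samples per class.
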