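---
title: "Classifying ketosynthase domains by profile-HMM score space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying ketosynthase domains by profile-HMM score space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ksclass)
library(dplyr)
```

## The problem

Animal genomes and transcriptomes contain three score-wise entangled groups
of ketosynthase (KS) domains: cytoplasmic type I fatty acid synthases (FAS),
type I polyketide synthases (PKS), and — bridging the two — animal FAS-like
PKSs (AFPKs), enzymes with FAS-like sequences but polyketide products.
Maximum-likelihood phylogenetics separates them, but does not scale to
omics-mining workloads. `ksclass` implements the score-space alternative:
score every KS against a small set of profile hidden Markov models (HMMs)
and read the class off the geometry of the resulting bit scores, plus an
embedding-based classifier ("AFPK-Finder") for the cases the simple rules
cannot resolve.

## The scoring model

A profile HMM here is a Plan7-like chain of `M` match states with
position-specific emissions, insert states sharing one emission vector, and
delete states; node transitions are the usual 7-tuple
`(MM, MI, MD, IM, II, DM, DD)`. The score of a sequence is

$$\mathrm{bits}(x) = \log_2 \frac{P(x \mid \text{HMM})}{P(x \mid \text{null})},$$

with the numerator summed over all state paths by the forward algorithm and
the null model emitting every residue i.i.d. from the background. Two
alignment regimes are provided: *glocal* (whole model, whole sequence — the
"full sequence score" used for classification) and *local* (best single
contiguous model/sequence fragment, used by `locate_domain()` with a
Viterbi traceback to report the hit window).

Deliberate simplifications, chosen because classification needs relative
rather than HMMER-reproducing scores:

* no multihit mode, no bias-composition filter, no E-values;
* one shared insert-emission vector equal to the background, so insertions
  are score-neutral;
* the null model has the same length as the query with no length
  correction, making "model = background" score exactly 0 bits;
* `X` residues emit at background in numerator and denominator and
  contribute exactly 0 bits.

Consequently absolute bit scores differ from HMMER's: published absolute
thresholds (the 180-bit KS hit gate, the 400–600 mollusc AFPK band) are
meaningful only for full-scale models of that provenance, and the package
exposes every threshold as a parameter, with `calibrate_config()` to refit
them at whatever model scale is in use.

`build_profile()` estimates a profile from a seed alignment: columns with
gap fraction ≤ 0.5 (ties inclusive) become match states; emissions are
pseudocount-smoothed counts `(n_a + w\,bg_a)/(n + w)` with weight `w = 5`
by default; transitions blend observed path counts with fixed priors
(`MM .90, MI .05, MD .05, IM .60, II .40, DM .60, DD .40`). `X` residues
occupy match states on the path but contribute to no emission count. The
forward/Viterbi recursions run in log space with pairwise log-sum-exp (no
scaling tricks), implemented in C++ for speed; correctness is pinned by an
exhaustive path-enumeration oracle in the test suite, which agrees with
the dynamic program to below `1e-9` log2 units on all toy models.

## The rule classifier

`classify_ks()` applies a fixed cascade to the score triple
(FAS, PKS, FASII model bits, negatives clamped to 0):

1. all three scores below the hit gate → `NON_KS`;
2. FASII score above both type I scores → `MITO_FASII` (the type II system
   is a separate low-scoring band and is resolved first);
3. PKS score strictly above FAS score (the *y = x* rule) → `PKS`;
4. FAS score inside `[band_low, band_high)` → `AFPK`;
5. FAS score at or above `band_high` → `TYPE_I_FAS`;
6. otherwise → `PKS`.

Rule 6 is a declared default for the continuum tail: FAS-side sequences
below the AFPK band grade into the PKS cloud, and a rule classifier must
put them somewhere; callers needing certainty for these cases should use
the embedding path. Ties on *y = x* fall on the FAS/AFPK side, so rule 3
never claims a sequence scoring equally against both models. The two taxon
presets (`mollusc` 400–600, `arthropod` 200–500) are the two published
anchor bands; both are configurable because those are the only anchors the
literature provides.

## The synthetic generator and what it emulates

Because the real training corpora are bulk sequence databases, the package
ships a generator of labeled KS-like families so every pipeline stage is
testable at desk scale:

* a **family** (`family_spec()`) is a seeded profile with one preferred
  residue per column carrying `conservation` mass, the remainder spread
  proportionally to background; indels open at `indel_rate/2` per node;
* an **intermediate family** is the convex combination
  (`interpolate_models()`) of two parents at mixing fraction `lambda`,
  emulating the continuum of scores bridging FAS and PKS; interpolation is
  in model space rather than by sequence chimerism, because it gives a
  single tunable axis with exact endpoint behavior;
* sampled sequences receive i.i.d. substitution noise
  (`mutate_sequence()`).

Default study conditions, chosen once: match length `M = 420` (a typical
KS domain) for score-space experiments and `M = 120` for unit-scale
checks; `indel_rate = 0.02`; `noise_rate = 0.05`; the FAS-like parent is
**diffuse** (`conservation = 0.55`) and the PKS-like parent **tight**
(`conservation = 0.95`). The conservation asymmetry is what reproduces the
observed phenomenology that intermediates fall on the FAS side of
*y = x*: a diffuse profile tolerates mixed sequences (they retain positive,
if modest, FAS-model scores), while the tight parent's score for them
collapses below zero and clamps to 0. With symmetric parents the
intermediates would straddle the diagonal and no band rule could recover
them. This is a synthetic stand-in, not a claim about real FAS/PKS column
conservation.

What the generator does **not** emulate: phylogenetic correlation between
sequences, site-rate heterogeneity, domain architecture beyond the KS,
alignment uncertainty, or database contamination. Passing the synthetic
recovery tests therefore demonstrates that the machinery is correct and
well-calibrated on cleanly generated families, not that the published
biological assignments are reproduced.

## The embedding path (AFPK-Finder)

For harder cases the pipeline scores sequences against a panel of many
models (30 by default), z-scores each model column (population standard
deviation; constant columns become zero — the stated "normalization" step
made explicit), embeds the matrix in 2D, clusters, and evaluates clusters
against reference clades:

* **Embedding**: t-SNE (`Rtsne`, exact `theta = 0`, perplexity 30 — the
  standard default, used because the original parameterization is not
  published) is the workflow-faithful default; a PCA mode exists to give
  bit-reproducible, permutation-equivariant tests. Perplexities too large
  for the row count are shrunk with a warning.
* **Clustering**: DBSCAN semantics implemented directly (core point ≥
  `min_pts` neighbours within `eps`, clusters = connected core regions
  plus border points). The published clusters were read visually; an
  explicit, parameterized algorithm replaces that step. Default `eps` is
  3× the median 4-nearest-neighbour distance.
* **Congruence**: the adjusted Rand index between cluster and clade
  partitions over shared ids, with noise points as singletons so failing
  to cluster is penalized. The implementation uses the common-denominator
  pair-counting form, exact on small contingency tables.
* **Panel selection** (`select_panel()`): seeded random subsets of the
  candidate models, each evaluated by the full pipeline; the
  highest-congruence subset wins, ties to the first drawn. Candidate
  scores are computed once and subset per trial.
* **Query classification** (`classify_by_reference()`): majority vote of
  the `k = 5` nearest reference points in embedding space; vote ties break
  to the nearest tied clade; confidence is the winning vote fraction.

## Numerical and design choices

* Negative bit scores are encoded as 0 ("no alignment") throughout the
  classification and embedding paths, keeping matrices dense and the rules
  total.
* Dereplication is exact: a sequence equal to, or a substring of, another
  is removed, keeping the longest (ties to the smallest id). The original
  curation tool is cited without parameters, so the conservative testable
  rule is used; a similarity-threshold mode is deliberately out of scope.
* Stockholm support is minimal (sequence lines plus `//`), enough to read
  seed alignments; annotation lines are ignored.
* Profile JSON serialization writes 17 significant digits, making
  read-after-write exact for IEEE doubles.
* All stochastic stages (sampling, mutation, t-SNE, panel draws) are
  seed-deterministic; seeds are explicit arguments, never hidden state.

## Problem sizes used by the shipped experiments

The packaged experiments (test suite and `scripts/acceptance.R`) use
3 classes × 100 sequences at `M = 420` for label recovery with a 50/50
train/test split; 5 interpolation grid points × 50 sequences for the
continuum check; and 3 families × 60 sequences against a 30-model panel at
`M = 120`, plus 30 held-out queries, for the embedding path. These sizes
give stable statistics (binomial standard errors of a few percent) while
keeping a full run in the minutes range on one CPU.

## Known limitations

* Bit scores are not HMMER-compatible by design; cross-tool absolute
  thresholds must be recalibrated (`calibrate_config()`).
* The rule classifier cannot subtype AFPK clades (mo-clades/ar-clades);
  that remains the embedding path's job, with reference labels supplied by
  the user.
* t-SNE cluster geometry is seed-dependent; only PCA mode guarantees
  bitwise permutation equivariance.
* The generator's independence assumptions understate the hardness of real
  data; measured recoveries are upper bounds on field performance.

## A worked example

```{r example, eval = FALSE}
fams <- list(
  family_spec("FAS", M = 420, conservation = 0.55, indel_rate = 0.02, seed = 102),
  family_spec("PKS", M = 420, conservation = 0.95, indel_rate = 0.02, seed = 103)
)
ds <- generate_labeled_dataset(
  fams, list(mixture_spec("FAS", "PKS", 0.5, name = "AFPK")),
  n_per_class = 50, noise_rate = 0.05, seed = 1
)
fasii <- make_family_hmm(family_spec("FASII", M = 420, conservation = 0.75,
                                     seed = 104))
scores <- score_triple(ds$sequences, ds$models$FAS, ds$models$PKS, fasii)
truth <- c(FAS = "TYPE_I_FAS", PKS = "PKS", AFPK = "AFPK")[ds$sequences$label]
cfg <- calibrate_config(mutate(scores, label = truth))
table(truth, classify_ks(scores, cfg)$label)
plot_dotplot(dotplot_table(scores, cfg), cfg)
```
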