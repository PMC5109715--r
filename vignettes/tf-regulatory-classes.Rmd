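---
title: "Classifying transcription factors into chromatin-opening regulatory classes"
author: "tfregclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying transcription factors into chromatin-opening regulatory classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfregclass)
```

## The problem

DNase-I footprint modelling has suggested that transcription factors (TFs)
play different roles with respect to chromatin accessibility: **Pioneers**
bind their target sites even in inaccessible chromatin and are associated
with subsequent opening; **Settlers** bind nearly every motif match in
already-open chromatin; **Migrants** bind only a subset of their accessible
matches, and are split into positive and negative Migrants by the sign of
their chromatin opening index. Such labels exist experimentally for only a
few hundred TFs. `tfregclass` treats the extension of these labels to the
full annotated TF complement as a supervised multiclass problem over
annotation-derived binary features, and provides the enrichment statistics
used to characterise the resulting classes on TF properties, TF–TF
interactions and time-course gene sets.

The chromatin opening index itself is **not** computed here; labels
(including the M+/M− split) are consumed as input. Likewise, up/down
regulated gene sets from time-course experiments are inputs, not the output
of any differential-expression fit.

## Feature encoding

All properties are reduced to bits before analysis; the deliberate loss of
resolution makes the features robust to the noise and ascertainment biases
of protein annotation databases.

**TFClass block.** The TFClass hierarchy codes structure as dotted numbers
(superclass.class.family...). A code is encoded with one bit for its
superclass and one for its class, all other bits zero, so that Hamming
distance is 0 / 2 / 4 for identical codes, different classes of one
superclass, and different superclasses — a graded structural similarity.
The base registry has 10 superclasses and 37 classes (47 bits). Because
class 2.3 (C2H2 zinc fingers) is far larger than any other, the default
registry replaces its single bit by four family bits 2.3.1–2.3.4
(10 + 36 + 4 = 50 bits). Both variants are available
(`tfclass_registry("base47")`, `tfclass_registry("split50")`); which one a
published analysis actually used for its final vectors is not stated, so the
choice is explicit in the API and the base count is what the reference
quantities in `scripts/acceptance.R` report. One class code (`5.2`) carries
no members in the bundled examples; it is retained so the base registry has
the documented 10 + 37 dimension. Codes that resolve only to a superclass
(the `X.0` convention) encode with the superclass bit alone; an
unrecognised class under a known superclass does the same but warns.

**Count thermometers.** Counts of DNA-binding domains, protein–protein
interactions and phosphorylation sites are encoded as `[0 0]` (zero),
`[1 0]` (between one and the average, *inclusive*), `[1 1]` (strictly above
the average). The shipped reference averages are 4 DBDs, 9 PPIs and 14
phosphorylation sites; `build_encoding_config(..., averages = "empirical")`
recomputes them from the corpus instead. Frequent zinc-finger domains
(zf-C2H2 + zf-H2C2_2 copies) use the same scheme with a fixed threshold of
three. The boundary reading ("between one and the average" includes the
average; "higher than" is strict) is a deliberate, documented tie-break.

**Frequent Pfam domains.** A domain is frequent when more than
`min_pfam_freq` (default 20) TFs carry it; bits are ordered by decreasing
corpus frequency with alphabetical tie-break, purely for determinism.

The ten blocks are concatenated in the fixed order `TF_Class, PD, DBD,
N_DBD, PPI, N_PPI, N_PhS, PTM, Ind_PTM, N_ZFD`; `select_blocks()` restricts
a matrix to any named subset (feature sets selected by the forward search
are per-case subsets of these names). `encode_tf()` is a pure function:
identical inputs give bit-identical vectors.

## Balanced one-vs-rest ensemble

With class sizes as skewed as 45 vs 412, a single classifier mostly learns
the majority class. The package instead under-samples at the task level:
for each case, the larger of {specific class, rest} is randomly partitioned
(without replacement) into `k = max(1, round(larger / smaller))` near-equal
subsets, remainder spread one per subset, and each subset faces the entire
smaller side. This reproduces the canonical split plan — 9, 9, 5 and 2
tasks for training sizes 45/47/77/288, with the negative-Migrant case
splitting its own (majority) side into two subsets of 144 against a rest of
169. The `round()` rule is the package's reconstruction: it is the unique
simple rule consistent with all four published split counts.

One classifier is fitted per task (default random forest, Gini impurity,
500 trees — the tree count is a package default, chosen as the
conventional plateau value for a few hundred samples and ~100 features).
Scores are averaged per case; the final label is the argmax over the four
per-case averages with the fixed tie order P, S, M+, M− (ties are
measure-zero but must be deterministic; a tie warns); the margin is the
difference between the two largest averages. Splits are drawn independently
per case from the master seed — whether the original analysis re-used
splits across cases is unknowable, and independence is the cleaner default.
Plain averaging is used rather than any boosting wrapper; the ensemble
already averages over under-sampling noise, which is the purpose the
splits serve.

## Cross-validation, metrics and feature search

"Bootstrap cross-validation" is implemented as repeated stratified random
subsampling: each of `n_runs × n_folds` folds draws 80% of each class for
training and tests on the remaining 20%, so folds within a run are *not*
disjoint partitions. Per fold the package records precision, recall,
F-score, MCC (labels thresholded at probability 0.5) and AUC; AUC is the
Mann–Whitney pair statistic (ties count ½), which makes it invariant under
monotone score transforms. Degenerate denominators (e.g. no positive
predictions) yield 0 with a warning rather than an error, so sweeps over
weak feature sets complete.

Hyperparameter grids (`C` and `γ` in `2^-4..2^4`, polynomial degree in
{2, 3}, `k` in {3, 5, 7, 9}) are searched within each fold's training
portion on an inner stratified 75/25 split, scored by AUC — a deliberately
light inner protocol; nested full CV would multiply cost ~50× for little
gain at these sample sizes. Paired per-fold AUC vectors are compared with
the two-sided Wilcoxon signed-rank test (zero differences dropped; exact
null distribution up to n = 25 when the absolute differences are untied,
normal approximation with continuity correction otherwise; all-zero
differences return p = 1 with a warning).

`property_importance()` scores each block alone (CV AUC) and by the sum of
its bits' Gini importances, normalised to sum to one across blocks.
`forward_best_first()` starts from the best single block and greedily adds
the block that maximises mean AUC, recording the complete trace (including
deteriorating tails) and each step's Wilcoxon p against the previous step;
the selected subset is the trace prefix with maximal mean AUC, since no
stopping criterion is prescribed by the source analysis.

## Enrichment statistics

All enrichment questions reduce to 2×2 tables tested with the two-sided
Fisher exact test (the R `fisher.test` convention; one-sided alternatives
are available by argument). Expected counts are
`row_total × column_total / grand_total`; the enriched/depleted direction
always compares observed to expected, never the p-value's side. Log-ratios
`log2(observed / expected)` use base 2 by default (configurable — the base
used in published log-ratios is unstated); observed zero returns −Inf with
a warning rather than an error so tables can be assembled.

For class-pair interaction enrichment, the universe is **every** unordered
pair of classified TFs (`n(n−1)/2`), not merely pairs appearing in some
interaction list; the table crosses "pair is an (A, B) class combination"
with "pair interacts". Per-TF partner log-ratios compare a TF's observed
partners in a class with the class's share among all other classified TFs.

Time-course enrichment tests every property × direction × (class or
"All") combination of the pooled up/down sets against the annotated
background, then applies Benjamini–Hochberg correction **over the whole
analysis as one family** (default). The per-block alternative
(`adjust_scope = "per_block"`, one family per class–direction table) is
provided, but with ~10 blocks its family-wise null error is roughly the
sum of the per-block rates, and simulation under a null generator showed
spurious discoveries in ~15% of seeds versus 0/20 for the global family —
so the global scope is the default. Reported rows obey the occurrence
rule: observed ≥ 9 for enrichments, expected ≥ 9 for depletions. Note a
numerical quirk absorbed here: `fisher.test`'s two-sided p can exceed 1 by
floating-point epsilon, and BH is therefore applied to values clamped at 1.

GC and IC analyses of binding motifs only ever see the TFs that have a
motif; their marginals are computed from whatever universe is supplied,
never from a fixed table.

## Motif metrics

GC content is pooled over positions (total C+G counts / total counts);
a per-column mean is available by flag, and the two differ exactly when
column depths differ — pooling is the default because JASPAR matrices
frequently have unequal column totals. Information content is the classic
per-column `2 + Σ_b p_b log2 p_b` in bits, summed over columns, with
`0·log2 0 = 0`, uniform background, no pseudocounts and no small-sample
correction; this is the standard choice and gives per-class averages of
the magnitude (≈7–10 bits) the published tables show. Both classification
cutoffs are strict: GC > 40%, IC > 9.0 bits.

## The synthetic-data generator

No annotation matrix, interaction list or time-course set was ever
deposited with the source analysis, so the package generates its own, with
the published marginals as fixed conditions:

* class sizes 45 (P) / 47 (S) / 77 (M+) / 288 (M−);
* the class-conditional TFClass composition of the 457-TF training cohort,
  used as categorical weights at family resolution;
* per-class DBD-count means 7.05 / 2.87 / 4.80 / 1.23 (the published
  per-class averages) and overall PPI/phosphorylation means near 9 and 14;
* motif GC targets 0.60 / 0.58 / 0.52 / 0.24 per class;
* ~20 domains exceeding the frequent-domain threshold at n = 457.

Counts are negative binomial (dispersion 2) by default — annotation counts
are overdispersed in practice — with Poisson available by flag; the choice
is free because the pipeline only ever sees thresholded encodings. Marker
Pfam domains are drawn per class from Bernoulli rates chosen to mirror the
biology (zinc-finger/KRAB/Ets-heavy Pioneers, bHLH/bZIP Settlers,
nuclear-receptor positive Migrants, homeodomain/forkhead negative
Migrants) and strong enough that the classes are genuinely separable —
the generator's purpose is parameter recovery, so its default signal is
deliberately strong. Derived fields stay consistent (`has_dbd = n_dbd > 0`;
the phosphorylation flag tracks a positive site count; drawn zinc-finger
domain copies add to `n_zf_frequent`).

Interactions include each unordered TF pair independently with a
class-pair rate (baseline 0.02; planted: P:P 0.10, P:S and S:S 0.06,
M+:M+ 0.005), emulating enriched Pioneer/Settler DNA co-binding and
depleted positive-Migrant co-binding. Time-course up/down sets draw each
TF with a base rate (0.20 up / 0.25 down) multiplied by planted per-term
effects — up: Ets ×3, HLH ×2.5, Hormone_recep ×2; down: Fork_head ×2.5,
Ubiquitination ×2 — capped at 0.95 and mutually exclusive per TF. The up
and down effect terms are intentionally planted on *weakly co-occurring*
marker sets: if both directions pull on the same carriers (e.g. two
Pioneer markers), the first draw drains the second set and the planted
effect becomes unrecoverable by construction. The down-marker
(Fork_head) is also kept at moderate prevalence: a very prevalent marker
(e.g. Homeobox, carried by three quarters of negative Migrants) floods
the set and dilutes every other contrast.

**What the generator does not emulate.** Within a class, domain content is
drawn independently of the TFClass code, whereas in real TFs the DBD-type
domains *are* the classification — so synthetic features are somewhat less
internally correlated than real ones. Identifiers are opaque; there is no
sequence, no DNase signal, no chromatin opening index, no motif–TF
binding-site relationship beyond the planted GC/IC class targets.
Consequently, passing recovery tests demonstrates that the pipeline's
machinery is correct and sensitive at realistic sizes and effect
magnitudes; it does not certify accuracy figures on real annotation data,
whose inter-feature correlations and label noise differ.

## Numerical and protocol choices

* Fold sizes: 80/20 stratified, each class guaranteed at least one member
  on each side; classes need ≥ 2 members.
* Probability threshold for confusion counts: 0.5.
* Tie-breaks: argmax order P, S, M+, M−; Pfam bit order by frequency then
  name; thermometer boundary inclusive at the average.
* Test problem sizes: module tests use corpora of 80–457 TFs, CV tests
  2–10 runs × 5 folds, and the end-to-end recovery check averages three
  stratified 80/20 holdout splits of the 457-TF preset (a single 91-TF
  test split has ~2.7% binomial noise; averaging three brings the
  evaluation noise well under the margin to the 90% recovery criterion).
  Null calibration uses 20 generator seeds.
* All randomness flows from explicit integer seeds; generators are pure
  functions of `(config, seed)`.

## Known limitations

* The published real-data headline results (classified counts
  289/169/211/49 for the 718 unlabeled TFs, AUC 0.82–0.92, the concrete
  selected feature lists) are not reproducible without the undeposited
  annotation matrix; the package reproduces the *procedures* and validates
  them by parameter recovery instead.
* `bootstrap_cv` resamples rather than partitions; its folds are
  correlated, which the paired Wilcoxon comparison tolerates but which
  makes fold AUCs slightly optimistic relative to disjoint k-fold CV.
* Probabilities from the ensemble are averaged votes, not calibrated
  probabilities; margins are a ranking tool, not posterior gaps.
* kNN probability estimates from small `k` are coarse (multiples of
  `1/k`), so AUC grids over kNN are tie-heavy.
* The Fisher tests treat TF pairs as independent observations; for dense
  interaction graphs this understates variance.
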