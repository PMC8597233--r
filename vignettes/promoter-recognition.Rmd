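---
title: "Recognising bacterial promoters with random forests"
author: "promforest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising bacterial promoters with random forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promforest)
```

## The model

`promforest` treats promoter recognition as binary classification of
40-nt sequences. The biological anchor is the sigma-70 transcription
machinery: the holoenzyme footprint extends from roughly −55 to +15 around
the transcription start site (TSS), and after trimming 15 bp from each end
of that span the informative region is the 40 bp immediately upstream of
the TSS. Within it, the Pribnow–Schaller box — the degenerate `TATAAT`
hexamer near −10 — is the strongest single determinant, flanked by weaker
signals (the −35 element, the extended −10, UP-element AT-tracts).

A random forest is a good match for this signal structure: the features
are many, binary or compositional, individually weak and highly redundant,
and the forest's voting scheme is robust to both. Two encodings are
offered:

* **one-hot (RF-HOT)**: position `i` (labelled −39…0, with 0 adjacent to
  the TSS) contributes a 4-bit indicator in channel order A, G, C, T. The
  mapping is A→1000, G→0100, C→0010, T→0001; an `N` becomes an all-zero
  block, so ambiguity is represented as absence of evidence rather than a
  fifth symbol. 160 features.
* **tetra-frequency (RF-TETRA)**: the 256 overlapping 4-mer counts divided
  by the number of valid 4-mer windows (37 for an N-free 40-mer); windows
  containing `N` are dropped from numerator and denominator alike, keeping
  each row a probability vector. 256 features, lexicographic over
  A\<C\<G\<T.

The one-hot model sees *where* a base is; the tetramer model sees *what
words* occur regardless of position. Their importance rankings are
therefore complementary interpretations of the same motif.

## Datasets and class balance

Positives are deduplicated 40-bp windows upstream of each TSS on its own
strand; TSS whose window would cross a contig edge are dropped (the model
requires fixed-width input, and clipping would shift the motif register).
Negatives are uniform random fixed-width windows, strand drawn uniformly,
rejected if they share even one base with a positive — the rejection is
strand-blind, which is conservative: it costs a few legitimate negatives
rather than risking mislabelled promoters. Negatives may still contain
*unannotated* promoters; performance estimates are therefore conservative
too. Training sets use a 1:10 positive:negative ratio to echo the true
rarity of promoters among genomic windows while keeping training
tractable; validation sets are 1:1 so that threshold metrics (MCC,
accuracy) are interpretable. The same exclusion rule is applied when
sampling validation negatives, avoiding label noise there as well.

Class imbalance is handled by inverse-frequency ("balanced") weights
$w_c = N / (2 N_c)$, computed from the data at fit time — for an exact
1:10 set this gives 0.55 and 5.5. We deliberately compute rather than
hard-code these: published figures for this protocol (0.53 / 10.28) imply
a ratio no standard formula reproduces from 1:10 data, so the rule, not
the constants, is the contract.

## Fitting and model selection

`promoter_rf()` runs stratified k-fold grid-search CV over forest size
and the feature-subsampling rule (`all`, `sqrt`, `log2` — the `max_features`
vocabulary of the ecosystem this protocol originated in), selects by mean
AUPRC with AUROC and then the smaller forest as tie-breakers, and refits
on all rows. AUPRC is the primary metric because under heavy imbalance it
is far more sensitive than AUROC to the quality of the top of the ranking.

Probability estimates come from a probability forest grown to purity
(`min.node.size = 1`): each tree contributes its terminal-node class
fractions and the forest averages them. This matches the predict-proba
semantics of scikit-learn's `RandomForestClassifier`, whose trees are
likewise grown to single-sample leaves by default. The impurity criterion
is Gini.

Two profiles are used throughout: the *paper-faithful* search space
(10 folds, 1000–3000 trees) and a *fast* profile (3 folds, 100 trees) used
by the command-line tool's default, the test-suite and the worked
examples. On the synthetic benchmark the fast profile already saturates
(held-out AUROC ≈ 0.99), so the vignette and tests report fast-profile
numbers; nothing in the code limits the full grid.

## Genome scanning

`scan_genome()` slides a 40-nt window with a configurable step (default 1)
across every contig and scores each window twice: as-is for the `+`
strand, reverse-complemented for the `-` strand. Per contig of length
$L$ this yields $\lfloor (L-40)/\mathrm{step} \rfloor + 1$ windows per
strand; windows never span contig boundaries and circular genomes are
treated as linear (no wrap-around window is generated, as no published
handling exists for the wrap case). Encoding and prediction run in
batches so memory stays bounded regardless of genome size; batched and
unbatched scans are bit-identical. Increasing the step divides runtime
proportionally but coarsens localisation, which mostly hurts the
overlap-mode assessment below.

## Evaluation

Three schemes, chosen to answer different questions:

* **Overlap mode** asks "does a high-scoring window lie *on* a promoter?".
  A window is positive when it shares at least 10% of its length with a
  same-strand true promoter (`intersect -s -f 0.1` semantics, the fraction
  measured against the query window; both are 40 nt here so the
  orientation of the fraction is moot). PR and ROC curves come from a full
  sweep of the distinct scores; the PR area uses step-wise (right-constant
  precision) integration, the ROC area the trapezoid rule.
* **Cluster mode** asks "does a high-scoring window lie *near* a
  promoter?". For each true promoter the five nearest predictions closer
  than 100 nt (gap distance: 0 when overlapping, 1 when bookended; the
  cutoff is strict) are true positives. Matching is strand-blind — the
  protocol this mirrors applied its strandedness flag only to the overlap
  assessment. Because each truth can legitimise up to five predictions,
  recall is defined as the fraction of true promoters with at least one
  surviving match (keeping it in [0, 1]) while precision keeps matched
  *predictions* in its numerator; the false-positive-rate denominator is
  the window count minus the truth count. Curves are assembled by
  re-matching at each threshold of a 200-point score-quantile grid —
  re-matching is the honest reading of "evaluate the thresholded track",
  and the grid keeps the quadratic k-nearest work tractable; its density
  is configurable.
* **Balanced mode** reports AUPRC/AUROC plus MCC and accuracy at
  probability 0.5 (the conventional threshold; MCC is defined as 0 when
  its denominator vanishes).

The random-classifier AUPRC equals the positive prevalence, so for a
genome-wide scan (thousands of promoters among millions of windows,
baseline ≈ 0.0003) an overlap-mode AUPRC of a few percent is already
orders of magnitude above chance, and the gap between overlap- and
cluster-mode AUPRC measures how much of the model's signal is "near miss"
rather than "exact hit".

## Interpretation

Impurity importance is computed per tree by routing each tree's in-bag
samples through its stored splits and accumulating class-weighted Gini
decreases; each tree's vector is normalised to sum 1 and the report gives
mean ± sd across trees (so means again sum to 1 — the normalised
mean-decrease-in-impurity convention). Computing per tree is what makes an
across-tree spread available at all; the aggregate agrees with the
ensemble's built-in impurity importance (Pearson r > 0.95 in the
test-suite). Permutation importance ("mean decrease in accuracy") shuffles
one feature column at a time, five repeats by default, and measures the
drop in accuracy at threshold 0.5 on the held-out split — held-out rather
than training data, so the score reflects generalisable signal.
Redundancy among motif features makes permutation importance sparse: a
forest that can read the Pribnow box from six positions loses little
accuracy when any one channel is shuffled, so only the strongest channels
show positive drops. `position_profile()` folds the 160 one-hot scores
into a 40 × 4 position-by-nucleotide matrix for plotting.

## The synthetic benchmark

`simulate_genome()` plants `n_promoters` non-overlapping 40-nt promoters
in an i.i.d. background of configurable GC content (bacterial genomes span
roughly 30–72% GC; the default is 0.5). Each promoter carries `TATAAT`
with its first base at position −12 (1-based offset 28 of the 40-mer), the
canonical −10 placement; each motif base is independently randomised with
probability 0.15, so the motif is degenerate and classifiers cannot be
trivially perfect — PR curves keep shape. Strands alternate along the
genome so both strand code paths are exercised, and TSS records are
constructed to be exactly inverse to the promoter-window rule (the
test-suite asserts bit-for-bit recovery). `default_benchmark()` fixes the
canonical conditions: 1 Mbp, GC 0.5, 500 promoters, mutation rate 0.15,
seed 42, TSS split alternately into 250 training (1:10) and 250 validation
(1:1) records.

What the simulator does *not* emulate: real promoter heterogeneity
(alternative sigma factors, −35/extended −10 variants), compositional
structure of real genomes (operons, skews, repeats), TSS-mapping noise,
and unannotated promoters contaminating the negatives. Passing the
benchmark therefore demonstrates that the machinery — extraction,
encodings, training, scanning, both assessment geometries, importance —
is correct and sensitive to a planted upstream motif at realistic
prevalence; it does not certify real-genome AUPRC values, which depend on
the biology above.

Problem sizes used in the shipped tests and the acceptance script — 1 Mbp
genomes, hundreds of promoters, 100-tree forests, scan step 5 — were
chosen as the smallest conditions at which every qualitative phenomenon of
interest (above-chance held-out AUPRC, the cluster/overlap gap,
Pribnow-box recovery, chance-level nulls) is stable across seeds.

## Numerical and design choices

* Coordinates are 0-based half-open BED throughout; a TSS is a width-1
  interval. Softmasked FASTA is uppercased on read; the alphabet is
  restricted to A, C, G, T, N.
* "Delete duplicates" is implemented as exact-coordinate deduplication of
  promoter intervals — the simplest reading that yields unique records.
* Grid-search ties break toward higher AUROC, then fewer trees (cheaper
  model at equal quality).
* The 200-point cluster threshold grid uses score quantiles, not
  equidistant probabilities, so resolution concentrates where scores
  actually lie.
* Determinism: every stochastic step (simulation, sampling, shuffling,
  fold assignment, forest growth, permutation) flows from an explicit
  seed; single-threaded prediction is the default so runs are
  reproducible to the byte.

## Known limitations

Only the 40-bp upstream definition of a promoter is supported; models are
sigma-factor-agnostic (they learn whatever upstream signal the TSS map
reflects, which in practice is dominated by sigma-70-like promoters);
genome scanning at step 1 over a multi-Mbp genome is minutes-to-hours of
single-core work; and cluster-mode evaluation with very dense prediction
tracks inherits the quantised threshold grid described above.
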