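---
title: "Predicting phage-bacterium interactions: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting phage-bacterium interactions: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagehost)
```

# The problem and the model

A phage infects a bacterium through molecular recognition — typically a
receptor-binding protein (RBP) on the phage docking onto a surface
receptor of the host. `phagehost` predicts whether a (phage, bacterium)
pair interacts using only genome-derived information: the two proteomes,
per-protein domain annotations, and a table of domain–domain interaction
(DDI) quality scores.

Every cross-proteome protein pair is treated as a candidate PPI and
scored by the sum of DDI scores over its domain pairs (with domain
multiplicity — a domain annotated twice contributes twice; a
`unique-domains` variant is deliberately *not* the default because the
annotation count is informative). A production-scale pair has on the
order of 74 × 3417 ≈ 2.5 × 10⁵ PPIs, and the count varies across pairs,
so the score vector is reduced to a fixed-length histogram. The
alternative "chemical composition" (CH) representation ignores domains
entirely and summarises protein primary structure (amino-acid
frequencies, C/H/N/O/S atom fractions, molecular weight) over the PPI
grid.

# Tunable parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `target_per_family` | 300 | oversampling target per bacterial family (records) |
| `exempt_species` | — | species whose family is never replicated (the dominant host) |
| `test_fraction` | 0.10 | stratified held-out share |
| histogram `mode`/`value` | per dataset | fixed bin *count* (5–50) or fixed bin *width* (1–20 normalized; 1e-6–5e-6 absolute) |
| `include_zero_scores` | TRUE | keep the (dominant) zero PPI scores in the histogram |
| CV `folds` | 10 | cross-validation folds |
| ANN `learning_rate` | 1e-4 | "0.01%" as a fraction; sigmoid single hidden layer |

# Numerical and procedural choices

**Histogram binning.** Bins are right-closed with 0 included in the
first bin (the `hist()` convention): `[0, w], (w, 2w], …`. In
fixed-number mode the N bins span *this pair's own* `[0, max]` score
range — per-pair adaptive, because no global range exists without a
corpus-wide pass; an all-zero vector spans `[0, 1]`. This choice affects
comparability across pairs and is therefore stated prominently. In
fixed-size mode the bins span a *global* `[0, upper_bound)` plus one
overflow bin; when no bound is supplied the dataset builder uses the
maximum PPI score of the training split and reuses it for the test split
(recorded in the dataset manifest), so train and test rows always have
identical length and test exceedances land in the overflow bin rather
than leaking test statistics into the featurization.

**Oversampling.** The replication factor is `max(1, round(target/n))`
with half-away-from-zero rounding (platform-independent, and it
reproduces the canonical worked example 300/4 → 75). Families containing
an exempt species appear once: the exemption is keyed by *species*, not
by a hard-coded organism name, so synthetic corpora work unchanged.

**Negatives.** A putative negative is any unobserved pair whose
bacterium species differs from the phage's known host species — an
assumption, not an observation; phages are specific enough that the
label noise introduced is considered acceptable. Draws are per bacterial
species to match the positive counts exactly, without replacement until
the candidate pool is exhausted, then with replacement (small pools occur
exactly where one species dominates the positives).

**Split leakage.** All replicates of a distinct pair travel to the same
split. A consequence: with replicate grouping plus with-replacement
negatives, *exact* per-split label balance is not always attainable —
overall balance is exact, per-split balance is within the replicate
multiplicity. We accept this rather than breaking stratification or the
leakage guard.

**Cross-validation.** Fold assignment is stratified and seeded; features
are standardized per fold using training-fold statistics only. Two fold
protocols exist: row-level (the historical protocol) and group-aware
(replicates of a pair confined to one fold). On oversampled corpora the
row-level protocol lets memorising learners read replicates across
folds: k-NN with k = 1 scores far above its group-aware counterpart —
the package reproduces this inflation as a property test rather than
hiding it. `signal_recovery_experiment()` defaults to group-aware
folding because its purpose is to measure genuine planted signal;
`group_aware = FALSE` restores the historical protocol.

**Classifier backends.** k-NN delegates to FNN; the random forest
(bagged CART, gini impurity, √p feature subsampling, minimum leaf size),
RBF-SVM (soft-margin dual solved as a QP with quadprog; "momentum" in
the historical grid is read as the RBF kernel width, the only standard
SVM hyperparameter spanning 10⁻⁴–10⁴), and the ANN (one hidden sigmoid
layer, sigmoid output, cross-entropy, minibatch SGD with momentum,
learning rate 1e-4 for "0.01%") are implemented in-package — the
deployment environment provides no dedicated ML library, and the
bespoke content of the modelling module is in any case the harness:
metrics, fold hygiene, phase logic. Model selection keys on mean
validation F1, ties broken by accuracy, then by the smaller model.

**Chemistry.** "Abundance" of C/H/N/O/S is implemented as atom-count
fractions (length-invariant, consistent with the frequency framing of
the other features); residue masses and formulas are the standard
published average values, with one water per chain. Unknown residues
(X, B, Z, J, U, O, …) are imputed with the mean of the 20 standard
residues for mass and elements, while the 21st frequency bin records how
much was imputed. The population (not sample) standard deviation makes
the single-PPI case well-defined (0).

# What the synthetic generator emulates — and what it does not

`synth_generate()` mirrors the *composition* of the corpus the method
was designed around: 19 bacterial families with two single-species
bacteria each, 1064 positives of which 86% share one dominant host
species, and scaled-down proteomes (10 × 50 instead of 74 × 3417) so the
full pipeline runs in seconds; a paper-scale check of the PPI-grid
cardinality is still performed at 74 × 3417. Each host species owns one
planted receptor–RBP domain pair whose DDI score (2–3) strictly exceeds
every background score (< 0.5); with probability `signal_strength` a
positive pair carries it. Assigning receptor pairs per *species* (not
per family) keeps same-family negatives clean.

Sequences are i.i.d. uniform over the 20 amino acids — adequate because
no pipeline stage models residue order — and domain architectures are
random. A green end-to-end test therefore establishes that the pipeline
*can recover a planted domain-level signal through the full corpus →
features → CV chain*; it does not establish that real phage–host
signals have this form, that DOMINE-era DDI scores are current, or that
the historical performance figures are reproducible (they depended on
2016 database snapshots and are explicitly out of scope).

Default generator values chosen where no published value exists:
protein lengths 60–200 residues (typical small-protein range), domain
vocabulary 150, 1–3 background domains per protein, background DDI
density 0.02, `signal_strength` 0.9 (strong but imperfect signal — a
scientist's "most true pairs are explained by a receptor interaction").
These were fixed once, before the acceptance thresholds were evaluated.

The end-to-end acceptance experiments run at a reduced scale (8
families, 200 phages, oversampling target 50) purely for the CPU
budget; below ~100 phages the dominant species' negative candidate pool
collapses to a handful of distinct pairs and the null accuracy becomes
noisy, so the scale was set by pool-size considerations, not by
threshold chasing.

# Known limitations

- Fixed-number histograms are per-pair adaptive; two pairs' bins cover
  different score ranges, which limits cross-pair interpretability of
  individual bins.
- Organism-level information can still straddle CV folds even under
  group-aware folding (the same phage occurs in several distinct pairs);
  fully organism-disjoint evaluation is future work.
- The per-split label balance is exact only up to replicate granularity
  (see above).
- The historical end-to-end performance (≈90% on real data) is not an
  acceptance surface here: it required 2016 snapshots of the interaction
  and DDI databases.
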