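---
title: "Reduced amino acid alphabets: feature extraction and classification methods"
author: "raackit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced amino acid alphabets: feature extraction and classification methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raackit)
```

## The model

A reduced amino acid alphabet (RAAC) is a partition of the 20 standard
residues into R clusters of similar amino acids — similar by substitution
statistics (e.g. the BLOSUM50-derived Murphy alphabets), hydropathy,
charge, or other physico-chemical criteria. Rewriting a protein over one
representative letter per cluster compresses its complexity: conserved
regions stand out, the feature space shrinks from $20^K$ to $R^K$ for
K-tuple counting, information redundancy drops, and small-sample
classifiers overfit less.

`raackit` represents a scheme as an ordered list of cluster strings; the
representative of a cluster is its first letter as written. This is a
deliberate design choice: published alphabets rarely name representatives,
and taking the first letter is deterministic, reproducible from the scheme
table alone, and consistent with common practice in reduced-composition
feature generators. All scheme tables are validated on load: the clusters
must form a disjoint, exhaustive partition of the 20 standard residues,
and a table line that fails this check is either a hard error (default)
or, in non-strict mode, dropped with its line number reported.

## K-tuple composition under three correlation parameters

The feature vector of a protein is the normalized count of reduced
K-tuples over a set of sliding windows governed by three parameters:

* **K** — tuple size. K = 1 counts single residues (plain composition),
  K = 2 dipeptides, K = 3 tripeptides. Dimension is $R^K$.
* **g** — inter-window gap. Successive window *start* positions differ by
  $g + 1$; $g = 0$ gives the familiar fully overlapping walk
  (positions 1–2, 2–3, 3–4, …), $g = 1$ skips one residue between slides
  (1–2, 3–4, 5–6, …). Gapped counting emphasises motifs that recur
  periodically rather than contiguously.
* **λ** — intra-window spacing. Adjacent residues *inside* a window are
  $\lambda + 1$ positions apart; $\lambda = 0$ means contiguous. With
  $K = 2, \lambda = 2$ a window reads positions $i$ and $i + 3$, which is
  exactly the CxxC pattern of zinc-finger-like domains: the two C anchors
  are conserved while the interior is free.

A window starting at $s$ covers $s, s + (\lambda+1), \dots,
s + (K-1)(\lambda+1)$, so the span is $(K-1)(\lambda+1) + 1$ and a
sequence of length $L$ yields $\lfloor (L - \mathrm{span})/(g+1) \rfloor
+ 1$ windows when $L \ge \mathrm{span}$, else none. With $K=3, g=2,
\lambda=1$ the walk visits positions (1,3,5), (4,6,8), (7,9,11).

Two semantic decisions were genuinely open and are worth stating:

* λ is accepted for any integer $\ge 0$, bounded only by the requirement
  that the span fit inside the sequence. Textual descriptions of this
  parameter family sometimes impose narrower ranges, but the worked
  patterns above (λ = 1 and the CxxC case λ = 2) require the permissive
  reading, so the implementation follows the patterns.
* g is measured between successive window *starts* (step $g+1$), not from
  a window's end. The alternative reading contradicts the spaced
  tripeptide pattern (starts 1, 4, 7 with $g = 2$) and is rejected.

**Normalization.** Rows are divided by the number of *counted* windows,
not by sequence length. Under the default `mask` policy a window touching
a non-standard residue is skipped entirely and removed from the
denominator, which keeps every feature row on the probability simplex
regardless of how many positions were masked.

**Column ordering.** Columns are the lexicographic product of the
scheme's own cluster order (first tuple position most significant), not
alphabetical order. This keeps feature columns aligned with the scheme
file and is deterministic across runs — important because libsvm export
refers to columns by 1-based index only.

**Ambiguity codes.** B, Z, U, O are treated as non-standard by default
rather than silently translated to D/E/C/K: silent translation would
alter compositions invisibly. The CLI offers `--translate-ambiguous` for
the conventional mapping when the user asks for it explicitly. `*` is a
stop codon, stripped at FASTA read time, never a residue. Degenerate
inputs (a sequence shorter than the window span, or fully masked) are
dropped from feature matrices with a warning and listed per id; an error
is raised only when nothing survives.

## Classification protocol

The evaluation pipeline follows the standard five-step protocol for
sequence predictors: a benchmark dataset of positive and negative FASTA
files, feature formulation as K-tuple RAAC composition, a classifier
(SVM, KNN or random forest), cross-validation, and a reproducible report.

* **Folds** are stratified: within each class, rows are shuffled under
  the run seed and assigned cyclically, so per-fold class counts differ by
  at most one from proportionality. Leave-one-out is available; k-fold
  with k exceeding the smaller class is refused with a pointer to LOO.
* **Pooling.** Sn, Sp, Acc and MCC are computed from confusion counts
  pooled over all held-out predictions, giving a single value per run
  (per-fold values are retained in the report for inspection). Pooling is
  the natural reading of protocols that report one Sn/Sp/Acc/MCC per
  experiment; fold-averaging is a close but distinct estimator.
* **Thresholds.** Confusion counts use each classifier's native decision
  boundary — the zero margin for SVM, majority vote for KNN and RF. No
  ROC-optimized cut is applied, because threshold tuning would leak the
  evaluation into the decision rule.
* **Scores.** The ROC is computed over pooled continuous scores: the SVM
  margin, the positive-class vote fraction for KNN (k = 5 by default, so
  scores take six levels), and the positive-class tree fraction for RF.
  AUC is computed by the rank (Mann–Whitney) formula with half credit for
  ties; trapezoidal integration of the step curve is algebraically equal
  and serves as an independent route in the tests.
* **MCC convention.** When any marginal of the confusion table is zero
  the MCC denominator vanishes; the package returns 0, the usual
  convention for an uninformative table.
* **Defaults.** SVM: RBF kernel, $C = 1$, $\gamma = 1/\text{n features}$
  (without feature scaling — rows already live on the simplex). KNN:
  $k = 5$. RF: 100 trees. One global seed drives fold shuffling and
  classifier randomness and is printed in every report.

Models are saved with their metadata (scheme key, tuple parameters,
classifier, hyperparameters, seed, format version) and an md5 checksum of
the serialized payload; loading verifies both the version and the
checksum rather than silently reinterpreting a stale artifact.

## Visualization data products

All visual products are computed as plain tables first, so they can be
tested without touching pixels.

* **Logo matrices** give per-position letter frequencies over a
  pre-aligned set, over the natural alphabet or — after reduction — over
  the representatives. Gaps and masked residues are excluded from each
  position's denominator; an all-gap column is flagged empty with zero
  information. Information content follows the WebLogo convention,
  $\log_2 A - H_p$ bits for an A-letter alphabet, without small-sample
  correction (the input size is user-controlled, and the default display
  is the plain frequency stack anyway).
* **Alignment views** pair the natural and reduced rows and color each
  residue by the rank of its cluster, drawn from a fixed 20-entry
  qualitative palette. Because representatives inherit their cluster's
  index, the reduced row's palette is by construction a subset of the
  natural row's.
* **Mergence tables** tabulate the natural→representative frequency flow
  (the data behind a Sankey-style view), and **heat-map tables** pass the
  feature matrix through unchanged together with each sequence's top-n
  tuples, ties broken by column order.

Pre-aligned input is required for logos and alignment views; the package
does not align sequences itself.

## The synthetic generator and what it does (not) show

`generate_synthetic()` emulates a two-class benchmark with a planted
compositional signal: negatives are i.i.d. draws from a background
residue distribution (Swiss-Prot average frequencies by default);
positives multiply the probabilities of the planted cluster — the
aromatic group FWY by default — by an `effect` factor and renormalize.
Defaults are 100 sequences per class with lengths uniform on 80–120,
the scale of a small curated benchmark of globular domains. `effect = 1`
makes the classes exchangeable, giving an exact null for calibration;
the package's evaluation study uses effects 1, 2 and 5 across 10 seeds
(3,000 windows of CV in total at n = 200 per run), where mean 5-fold SVM
AUC runs from chance (≈ 0.49) through ≈ 0.74 to ≈ 0.98.

What this emulates well: composition-level signal of tunable strength,
class exchangeability under the null, and the dependence of detection on
effect size. What it does not emulate: positional motifs, sequence-order
correlation, phylogenetic relatedness between sequences, length
confounding between classes, or label noise. Passing the planted-signal
study therefore shows that the feature extraction and CV machinery
recover a known compositional difference at realistic problem sizes — it
does not certify performance on real benchmarks, whose signal structure
is richer.

## Numerical and reproducibility choices

* Feature rows sum to 1 within 1e-9 by construction; equality tests
  against independent counters use 1e-12.
* All serialized frequencies (CSV, libsvm, TSV) use full double
  round-trip precision; human-readable reports round to 4 decimals.
* Every random step (fold shuffling, classifier internals, the
  generator) flows from an explicit integer seed; package internals save
  and restore the caller's RNG state. Reports contain no timestamps or
  absolute paths, so a re-run from the echoed `config.json` reproduces
  `report.json` byte-identically.
* The registry-scale table bundled as `raac_table_synthetic_673.tsv` is a
  deterministic synthetic stand-in (74 type families, 673 schemes,
  near-equal contiguous blocks of per-type residue permutations from a
  fixed linear congruential generator). It exercises registry browsing,
  filtering and validation at full scale; its clusters carry no
  biological meaning, so analyses that depend on cluster quality should
  use the curated table or a user-supplied one.

## Known limitations

* Tier-correlation ("pseudo") components beyond plain tuple composition
  are out of scope; the feature space is composition-only.
* KNN decision scores are vote fractions with few distinct levels, which
  coarsens its ROC relative to SVM/RF.
* No hyperparameter search is provided; defaults are recorded in every
  report so external tuning remains reproducible.
* Multi-class problems, resampling for imbalance (a warning fires beyond
  3:1), and web-service infrastructure are out of scope.
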