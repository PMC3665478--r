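---
title: "Predicting disease-related amino acid substitutions: model, features and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting disease-related amino acid substitutions: model, features and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sappred)
```

## Scope and assumptions

`sappred` classifies single amino acid polymorphisms (SAPs) as
disease-related or neutral. The model assumes that three kinds of evidence
carry most of the signal: evolutionary conservation of the mutated position
(read from a homolog-derived sequence profile), the functional context of
the protein (read from its Gene Ontology annotation), and — when a structure
is available — the local packing and solvent exposure of the wild-type
residue. A support vector machine combines these with the identity of the
substitution itself and, optionally, the output of an external
substitution-tolerance predictor.

The package takes files, not accessions: homology searches, structure
retrieval and external predictor runs happen upstream, and their results
enter through documented readers (`read_fasta()`, `read_alignment_hits()`,
`read_obo()`, `read_annotations()`, `read_structure()`,
`read_accessibility()`, `read_panther()`). Every interface position is
1-based.

## Feature extraction

**Mutation block (20).** A signed indicator over the alphabetically ordered
standard residues: −1 at the wild type, +1 at the mutant. Variants whose
wild type is an ambiguity code (X/B/Z/U) are rejected as unpredictable
rather than silently encoded.

**Environment block (20).** For the sequence preset, residue frequencies in
a 19-residue window centred on the position, truncated at the termini; the
central residue is included in the count, and ambiguity codes are excluded
from both numerator and denominator. For the structure preset, the
frequencies of residue types whose Cα lies within 6 Å (closed ball,
Cα–Cα Euclidean distance) of the variant's Cα, over all chains of the
model, excluding the centre residue itself — the substitution identity is
already carried by the mutation block, so including the centre would only
duplicate it. An isolated residue yields the all-zero composition.

**Relative solvent accessibility (1, structure preset).** Absolute
accessible area divided by the per-residue-type theoretical Gly-X-Gly
maximum (Tien et al. 2013 values, swappable via the `reference` argument),
clamped to [0, 1] because chain termini routinely exceed the reference.
File-based accessibility (DSSP output or a two-column fallback dialect) is
authoritative; a built-in Shrake–Rupley rolling-probe computation
(`compute_accessibility()`, probe 1.4 Å, 92 lattice points per atom) covers
the case where no file is supplied. On Cα-only traces the built-in route is
a coarse burial estimate, which is all the synthetic fixtures need.

**Profile block (5).** Profiles tally, per query position, the residues
observed across pairwise alignment hits with E-value strictly below 1e-9
(a hit at exactly the threshold is excluded). The query itself is always
counted, so a hitless protein still has a well-defined profile. Gaps and
ambiguity codes contribute to neither counts nor depth. The five features
are, in fixed order: mutant-residue frequency, wild-type frequency,
per-position depth, whole-alignment sequence count, and the conservation
index `CI = 1 − H/log2(20)` with `H` the Shannon entropy of the position's
frequency row (`0·log 0 := 0`; a zero-depth column scores 0). The
entropy-based index was chosen because it is parameter-free, bounded in
[0, 1] and depends only on the frequency multiset. Depth counts are
unbounded, so they are saturation-scaled as `n/(n + k)` with `k = 100`
before entering the kernel; the value `k = 100` puts the half-saturation
point at a typical alignment depth.

**External predictor block (4).** Probability of a deleterious change,
wild-type and mutant frequencies, and the scaled number of independent
counts. When the external tool produced no output the block is the fixed
fallback `(0.5, 0, 0, 0)` — an uninformative probability and zeroed
remainder — with no separate presence flag.

**GO block (2).** The functional score is an additive log-odds over the
ancestor closure of the protein's annotation (both `is_a` and `part_of`
edges are followed; a switch restricts to `is_a`). Per closure term,
`log2[((d_t+π)/(D+2π)) / ((n_t+π)/(N+2π))]`, where `d_t` and `n_t` count
disease and neutral *training variants* on proteins whose closure contains
the term. Counting variants rather than proteins keeps large disease-heavy
families from vanishing into a single vote, and matches the per-variant
classifier the score feeds. The pseudocount `π = 1` and base 2 are pinned
defaults, exposed in `fit_term_stats()`; smoothing makes the score total —
terms never seen in training contribute `log2(1) = 0`. The second feature is
the closure size, saturation-scaled like the depth counts. A protein with no
annotation yields exactly `(0, 0)`.

The blocks concatenate in the fixed order mutation → environment (→ RSA) →
profile → external predictor → GO, giving 51 features for the sequence
preset and 52 for the structure preset; `profile_seq` (45) and `profile_3d`
(46) drop the external-predictor and GO blocks as ablations approximating
older profile-only predictors. Each vector and each trained model carries a
versioned `layout_tag`, and tags are checked at prediction time, so a model
can never silently consume vectors with a different layout.

## Classifier and calibration

`train_sap_model()` z-scales features (statistics stored in the model;
constant features keep scale 1 — the original implementations' scaling is
unknown, so the choice is recorded in the layout tag), fits an RBF-kernel
SVM (defaults `cost = 1`, `gamma = 1/d`; both exposed) and calibrates a
Platt sigmoid on cross-validated decision values (5 seeded folds), so the
calibration never sees resubstitution scores. The sigmoid fit uses Platt's
regularised targets with Newton iterations and backtracking, which is
robust on separable data. Everything is deterministic given data order,
parameters and seed — repeated training writes byte-identical model files.

Predictions report `O(D)`, the probability of the disease class; the label
is Disease iff `O(D) > 0.5` — a probability of exactly 0.5 is Neutral, per
the strict inequality — and the reliability index is
`RI = floor(20·|O(D) − 0.5|)`, an integer 0–10. A tolerance of 1e-9 is
added before flooring so that grade boundaries are not decided by binary
representation noise.

## Evaluation

`confusion_counts()` produces per-class counts (correct, correctly
rejected, false negatives, false positives) satisfying the class-symmetry
identities by construction. On top of it: overall accuracy `Qtot`,
per-class sensitivity and precision (zero denominators raise errors,
distinct from a value of 0), and the Matthews correlation with the standard
square-rooted normaliser (without the root the coefficient would not be
bounded in [−1, 1]); a zero marginal defines MCC as 0. The ROC sweeps all
distinct scores, with TPR the disease-class sensitivity and FPR one minus
the neutral-class sensitivity (the standard specificity complement), and
integrates by trapezoid — the tests pin its equality with the tie-aware
Mann–Whitney statistic. `ri_stratified()` reports every metric on the
subset at or above an RI cutoff together with the retained coverage.

Homology leaks inflate variant-prediction benchmarks, so evaluation is
cluster-aware throughout. `cluster_folds()` deals whole sequence clusters
(e.g. 30 % identity / 80 % coverage groups, consumed from a two-column
file — the clustering tool itself is not reimplemented) to `k` folds,
largest variant-weight first onto the lightest fold; the assignment is
deterministic given the seed and invariant to input order.
`cross_validate()` refits the GO term statistics inside every fold, and a
leakage guard in `go_features()` refuses to score a protein that
contributed to the statistics it is being scored with. `blind_eval()`
applies the same rule across a train/test split, excluding (and reporting)
test variants whose protein clusters with any training protein.
Reverse-neutral augmentation (`augment_reverse_neutral()`) adds B→A for
every neutral A→B, deduplicated, never touching disease rows; it is off by
default and, in the CLI, applied after clustering so augmented copies stay
in their protein's fold.

## The synthetic generator

`generate_synthetic()` emulates, at toy scale, every input the pipeline
consumes: random sequences; alignment hits whose per-position agreement
with the query follows a planted conservation level (plus two decoy hits
above the E-value threshold to exercise the filter); a random acyclic
GO-like graph with a designated disease-enriched term subset; self-avoiding
Cα traces with 3.8 Å spacing; accessibility records derived from trace
burial; external-predictor records correlated with the realised label; and
sequence clusters with a configurable fraction of paired proteins. Labels
come from a logistic model over the planted conservation, functional
enrichment and burial signals, so discrimination is quantifiable: zero
effect sizes make labels independent of all features, and the recovery
tests verify that held-out AUC is near 0.5 under the null and rises
monotonically with each effect. The `strong_v1` preset (effects 3, 3, 2.5,
2.5 across 120 proteins × 25 variants) defines the planted-signal study
condition; `null_v1` is its matched null.

What the generator does **not** emulate: realistic GO topology or
annotation depth, real substitution matrices, structured correlation
between conservation and burial, or database label noise. Passing the
recovery tests therefore demonstrates that the machinery extracts planted
signals without leaks — not that the method attains any particular accuracy
on real variant databases, which would require genuine large-scale profiles
and annotations.

## Problem sizes and numerical choices

The end-to-end checks train on 2000 variants and score 1000 cluster-disjoint
held-out variants (the `strong_v1`/`null_v1` conditions above); unit checks
run on fixtures of tens of variants. Other pinned choices, each surfaced as
a default argument rather than a constant buried in code: first PDB model
only, HETATM excluded, alternate locations resolved by highest occupancy
then alphabetical; neighbour ties at exactly 6 Å included; window length
must be odd; residues missing from an accessibility record raise an error
by default (`missing_policy = "impute"` substitutes 0.5 with a warning);
model files carry a magic header and format version, and loading anything
else is a compatibility error.

## Known limitations

Profiles use raw frequencies, not position-specific scoring matrices;
per-position depth counts only non-gap standard residues, one of several
defensible conventions. The ablation presets approximate the historical
profile-only predictors with this package's blocks rather than reproducing
those tools. The structural environment is Cα-based; side-chain-aware
definitions would see different neighbourhoods. Probability calibration
quality degrades on tiny training sets (the sigmoid has only two
parameters, but cross-validated decision values get noisy); reliability
indexes from models trained on a few dozen examples should be read
qualitatively.
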