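# sappred

Pathogenicity prediction for single amino acid polymorphisms (SAPs) from
protein sequence, structure and function.

## The problem

A missense variant substitutes one residue of a protein; a small fraction of
these substitutions cause disease while most are neutral polymorphisms.
`sappred` implements a support-vector-machine classifier that decides, for a
variant *wt→mut* at position *p* of a protein, whether it is **Disease** or
**Neutral**, and reports a calibrated probability together with an integer
confidence grade. It is aimed at people building or evaluating variant-effect
predictors: every stage — feature extraction, functional scoring,
classification, and the complete evaluation protocol (including cluster-aware
cross-validation and blind-set guards) — is an exported, tested function.

## The model

Each variant is encoded as a fixed-length feature vector:

| block | length | content |
|---|---|---|
| mutation | 20 | −1 at the wild-type residue, +1 at the mutant (alphabetical residue order) |
| environment | 20 | residue frequencies of a 19-residue sequence window **or** of the residues whose Cα lies within 6 Å of the variant's Cα |
| RSA | 1 | relative solvent accessibility of the wild-type residue (structure preset only) |
| profile | 5 | f(mut), f(wt), scaled per-position depth, scaled alignment size, conservation index CI = 1 − H/log₂20 |
| external predictor | 4 | deleteriousness probability, wt/mut frequencies, scaled independent counts; fixed fallback (0.5, 0, 0, 0) |
| GO | 2 | functional log-odds score and the number of GO terms used |

The sequence preset has 51 features, the structure preset 52. The functional
score sums, over the ancestor closure *C* of the protein's GO annotation,

```
score = Σ_{t∈C} log2 [ (d_t + π)/(D + 2π) ÷ (n_t + π)/(N + 2π) ]
```

where `d_t`/`n_t` count Disease/Neutral *training variants* on proteins whose
closure contains `t`, `D`/`N` are the class totals and `π = 1` is a
pseudocount. An RBF-kernel SVM with Platt-calibrated probabilities produces
`O(D)`; the decision rule is Disease iff `O(D) > 0.5` and the reliability
index is `RI = floor(20·|O(D) − 0.5|)` ∈ 0…10.

Evaluation follows the conventional indexes: overall accuracy `Qtot = C/T`,
per-class sensitivity `S = p/(p+u)` and precision `P = p/(p+o)`, the Matthews
correlation coefficient, and the trapezoid ROC AUC (identical to the
tie-aware rank statistic). Cross-validation deals whole sequence clusters to
folds so homologous proteins never straddle a train/test boundary.

## Worked example

The synthetic generator plants conservation, functional and burial signals
with known effect sizes, so the whole pipeline can be exercised without any
external data:

```r
library(sappred)

ds <- generate_synthetic(synth_preset("strong_v1", seed = 42))
#> <synth_dataset> 120 proteins, 3000 variants (1405 Disease / 1595 Neutral), 60 GO terms

folds    <- cluster_folds(ds$clusters, ds$variants, k = 3, seed = 1)
test_ids <- folds$protein_id[folds$fold == 1]
train <- dplyr::filter(ds$variants, !protein_id %in% test_ids)
test  <- dplyr::filter(ds$variants,  protein_id %in% test_ids)

model <- train_pipeline(train, ds, preset = "snpsgo_seq", seed = 1)
#> <sap_model> layout snpsgo_seq_v1; 2000 training variants (Disease=896, Neutral=1104);
#>   RBF cost=1 gamma=0.01961; 642 SVs

preds <- predict_pipeline(model, test, ds, preset = "snpsgo_seq")
metrics_report(preds, test$label)
#> # A tibble: 1 × 9
#>   q_tot   p_d   s_d   p_n   s_n   mcc   auc n_total n_correct
#> 1 0.996 0.994 0.998 0.998 0.994 0.992 1.000    1000       996
```

`q_tot` is the fraction of the 1000 held-out variants labelled correctly,
`mcc` the Matthews correlation, `auc` the ROC area; `p_*`/`s_*` are per-class
precision and sensitivity. Restricting to confident predictions trades
coverage for accuracy:

```r
ri_stratified(preds, test$label, ri_min = c(0, 5))
#>   q_tot ... ri_min coverage
#> 1 0.996 ...      0    1
#> 2 0.999 ...      5    0.985
```

A single-protein, server-style prediction table:

```r
prot <- ds$proteins[1, ]
predict_variant_table(model, prot, "P5W", sap_data(proteins = prot,
                      hits = ds$hits, graph = ds$graph,
                      annotations = ds$annotations), "snpsgo_seq")
#>   variant prediction    ri   o_d method     error
#> 1 P5W     Neutral        2 0.353 snpsgo_seq NA
```

A command-line wrapper with `predict-seq`, `predict-3d`, `train`,
`evaluate`, `simulate` and `features` subcommands is installed under
`inst/cli/sappred`.

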