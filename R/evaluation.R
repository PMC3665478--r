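# Classifier evaluation: class-wise confusion counts, overall accuracy,
# Matthews correlation, sensitivity/precision, ROC/AUC, reliability-index
# stratification, cluster-aware k-fold assignment and leakage-safe blind
# evaluation.

#' Class-wise confusion counts
#'
#' For each class `s` in {Disease, Neutral}: `p(s)` correct predictions of
#' `s`, `n(s)` correct rejections, `u(s)` false negatives, `o(s)` false
#' positives, under the decision rule Disease iff `o_d > threshold`. The
#' symmetric identities `p(D) = n(N)`, `o(D) = u(N)` etc. hold by
#' construction.
#'
#' @param o_d Numeric vector of disease probabilities (or a prediction tibble
#'   from [predict.sap_model()]).
#' @param labels True labels over `{"Disease", "Neutral"}`.
#' @param threshold Decision threshold (default 0.5, strict).
#' @return A `class_counts`: tibble with columns `class`, `p`, `n`, `u`, `o`.
#' @export
confusion_counts <- function(o_d, labels, threshold = 0.5) {
  if (is.data.frame(o_d)) o_d <- o_d$o_d
  if (length(o_d) != length(labels)) {
    abort("Predictions and labels differ in length.",
          class = "sappred_input_error")
  }
  stopifnot(all(labels %in% c("Disease", "Neutral")))
  pred_d <- o_d > threshold
  true_d <- labels == "Disease"
  tp <- sum(pred_d & true_d); tn <- sum(!pred_d & !true_d)
  fn <- sum(!pred_d & true_d); fp <- sum(pred_d & !true_d)
  out <- tibble(class = c("Disease", "Neutral"),
                p = c(tp, tn), n = c(tn, tp),
                u = c(fn, fp), o = c(fp, fn))
  class(out) <- c("class_counts", class(out))
  out
}

counts_row <- function(counts, s) {
  r <- counts[counts$class == s, , drop = FALSE]
  if (!nrow(r)) abort(sprintf("Unknown class '%s'.", s))
  as.list(r)
}

#' Overall accuracy
#'
#' Fraction `C / T` of correctly predicted variants.
#'
#' @param counts A `class_counts`.
#' @return Numeric in `[0, 1]`.
#' @export
q_tot <- function(counts) {
  r <- counts_row(counts, "Disease")
  total <- r$p + r$n + r$u + r$o
  if (total == 0) {
    abort("Accuracy undefined on an empty prediction set.",
          class = "sappred_metric_error")
  }
  (r$p + r$n) / total
}

#' Matthews correlation coefficient
#'
#' `MCC(s) = (p n - u o) / sqrt((p+u)(p+o)(n+u)(n+o))`. If any marginal sum
#' is zero the coefficient is defined as 0. By the confusion-count
#' identities, `MCC(Disease) == MCC(Neutral)`.
#'
#' @param counts A `class_counts`.
#' @param s Class (default Disease; the value is class-symmetric).
#' @return Numeric in `[-1, 1]`.
#' @export
mcc <- function(counts, s = "Disease") {
  r <- lapply(counts_row(counts, s)[c("p", "n", "u", "o")], as.numeric)
  w2 <- (r$p + r$u) * (r$p + r$o) * (r$n + r$u) * (r$n + r$o)
  if (w2 == 0) return(0)
  (r$p * r$n - r$u * r$o) / sqrt(w2)
}

#' Per-class sensitivity (coverage) and precision
#'
#' Sensitivity `S(s) = p / (p + u)`; precision (positive predictive value)
#' `P(s) = p / (p + o)`. A zero denominator raises an undefined-metric error
#' rather than returning 0.
#'
#' @param counts A `class_counts`.
#' @param s Class name.
#' @return Numeric in `[0, 1]`.
#' @export
sensitivity <- function(counts, s) {
  r <- counts_row(counts, s)
  if (r$p + r$u == 0) {
    abort(sprintf("Sensitivity undefined for class %s: no true members.", s),
          class = "sappred_metric_error")
  }
  r$p / (r$p + r$u)
}

#' @rdname sensitivity
#' @export
precision <- function(counts, s) {
  r <- counts_row(counts, s)
  if (r$p + r$o == 0) {
    abort(sprintf("Precision undefined for class %s: no predictions.", s),
          class = "sappred_metric_error")
  }
  r$p / (r$p + r$o)
}

#' ROC curve and area under the curve
#'
#' Sweeps the decision threshold over all distinct scores, plotting the true
#' positive rate `S(Disease)` against the false positive rate
#' `1 - S(Neutral)`, and integrates by the trapezoid rule. The result equals
#' the tie-aware rank (concordance) statistic on the same data.
#'
#' @param o_d Disease probabilities/scores.
#' @param labels True labels over `{"Disease", "Neutral"}`.
#' @return A `sap_roc`: list with `curve` (tibble `threshold`, `fpr`, `tpr`)
#'   and `auc`.
#' @export
roc_curve <- function(o_d, labels) {
  if (is.data.frame(o_d)) o_d <- o_d$o_d
  true_d <- labels == "Disease"
  n1 <- sum(true_d); n0 <- sum(!true_d)
  if (n1 == 0 || n0 == 0) {
    abort("ROC undefined: both classes must be present.",
          class = "sappred_metric_error")
  }
  thr <- sort(unique(o_d), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(o_d >= t & true_d) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(o_d >= t & !true_d) / n0, numeric(1))
  curve <- tibble(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
  structure(list(curve = curve, auc = auc), class = "sap_roc")
}

#' @export
print.sap_roc <- function(x, ...) {
  cat(sprintf("<sap_roc> AUC = %.4f over %d thresholds\n",
              x$auc, nrow(x$curve) - 1))
  invisible(x)
}

#' @rdname roc_curve
#' @param ... Unused.
#' @param object A `sap_roc`.
#' @export
autoplot.sap_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Full performance report
#'
#' One-row tibble in the conventional column order: overall accuracy, per-
#' class precision and sensitivity, Matthews correlation and AUC, plus the
#' total and correct counts.
#'
#' @param o_d Disease probabilities (or prediction tibble).
#' @param labels True labels.
#' @param threshold Decision threshold.
#' @return Tibble with columns `q_tot`, `p_d`, `s_d`, `p_n`, `s_n`, `mcc`,
#'   `auc`, `n_total`, `n_correct`.
#' @export
metrics_report <- function(o_d, labels, threshold = 0.5) {
  if (is.data.frame(o_d)) o_d <- o_d$o_d
  cc <- confusion_counts(o_d, labels, threshold)
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  r <- counts_row(cc, "Disease")
  tibble(q_tot = q_tot(cc),
         p_d = safe(precision(cc, "Disease")),
         s_d = safe(sensitivity(cc, "Disease")),
         p_n = safe(precision(cc, "Neutral")),
         s_n = safe(sensitivity(cc, "Neutral")),
         mcc = mcc(cc),
         auc = safe(roc_curve(o_d, labels)$auc),
         n_total = r$p + r$n + r$u + r$o,
         n_correct = r$p + r$n)
}

#' Performance stratified by reliability index
#'
#' Restricts the evaluation to predictions with `ri >= ri_min` and reports
#' the metrics together with the retained coverage fraction. With
#' `ri_min = 0` this equals the unstratified report at coverage 1.
#'
#' @param predictions Prediction tibble (`o_d`, `ri`) from
#'   [predict.sap_model()].
#' @param labels True labels.
#' @param ri_min Minimum reliability index, 0..10. May be a vector, giving
#'   one row per cutoff.
#' @return Tibble: one row per `ri_min` with the metric columns and
#'   `coverage`.
#' @export
ri_stratified <- function(predictions, labels, ri_min = 0:9) {
  stopifnot(all(ri_min %in% 0:10))
  bind_rows(lapply(ri_min, function(r) {
    keep <- predictions$ri >= r
    cov <- mean(keep)
    if (!any(keep)) {
      abort(sprintf(
        "No predictions at RI >= %d (coverage 0); metrics undefined.", r),
        class = "sappred_metric_error")
    }
    rep_ <- tryCatch(
      metrics_report(predictions$o_d[keep], labels[keep]),
      error = function(e) tibble(q_tot = NA_real_))
    mutate(rep_, ri_min = r, coverage = cov)
  }))
}

#' Cluster-aware fold assignment
#'
#' Deals protein clusters to `k` folds so that proteins sharing a sequence
#' cluster (e.g. 30% identity / 80% coverage groups) never straddle folds,
#' while balancing per-fold variant counts greedily: clusters are processed
#' in decreasing variant-count order and each is assigned to the currently
#' lightest fold. Ties among equal-count clusters are broken by a seeded
#' shuffle; the assignment is invariant to the input row order.
#'
#' @param clusters Tibble with `protein_id`, `cluster_id`.
#' @param variants Labelled variant tibble (used for per-protein variant
#'   counts); proteins without variants weigh 0.
#' @param k Number of folds (default 20).
#' @param seed Integer seed for tie-breaking.
#' @return Tibble with `protein_id`, `cluster_id`, `fold` (1..k).
#' @export
cluster_folds <- function(clusters, variants, k = 20, seed = 1) {
  stopifnot(all(c("protein_id", "cluster_id") %in% names(clusters)))
  if (anyDuplicated(clusters$protein_id)) {
    abort("A protein may belong to exactly one cluster.",
          class = "sappred_input_error")
  }
  missing <- setdiff(unique(variants$protein_id), clusters$protein_id)
  if (length(missing)) {
    abort(sprintf("Protein(s) without cluster assignment: %s",
                  paste(head(missing, 5), collapse = ", ")),
          class = "sappred_input_error")
  }
  w <- count(variants, .data$protein_id, name = "n_var")
  cl <- left_join(clusters, w, by = "protein_id")
  cl$n_var[is.na(cl$n_var)] <- 0L
  sizes <- summarise(group_by(cl, .data$cluster_id),
                     weight = sum(.data$n_var), .groups = "drop")
  if (k > nrow(sizes)) {
    abort(sprintf("Cannot deal %d clusters into %d folds.", nrow(sizes), k),
          class = "sappred_input_error")
  }
  sizes <- arrange(sizes, dplyr::desc(.data$weight), .data$cluster_id)
  # seeded tie-break among equal-weight clusters, invariant to input order
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sizes <- bind_rows(lapply(split(sizes, sizes$weight), function(g) {
    g[sample(nrow(g)), , drop = FALSE]
  }))
  sizes <- arrange(sizes, dplyr::desc(.data$weight))
  load <- numeric(k)
  fold_of <- setNames(integer(nrow(sizes)), sizes$cluster_id)
  for (i in seq_len(nrow(sizes))) {
    f <- which.min(load)
    fold_of[[as.character(sizes$cluster_id[i])]] <- f
    load[f] <- load[f] + sizes$weight[i]
  }
  mutate(cl, fold = unname(fold_of[as.character(.data$cluster_id)]))[,
    c("protein_id", "cluster_id", "fold")]
}

#' Leakage-safe blind evaluation
#'
#' Scores a labelled test set with a trained model, refusing to score any
#' variant whose protein shares a sequence cluster with a protein the model
#' was trained on. Excluded variants are reported, not silently dropped.
#'
#' @param model A `sap_model` whose `training_proteins` field names the
#'   proteins used in training (recorded by the pipeline helpers).
#' @param test_x Feature matrix of the test variants.
#' @param test Labelled test variant tibble (`protein_id`, `label`).
#' @param clusters Tibble `protein_id`, `cluster_id` covering both sets.
#' @return List with `report` (a [metrics_report()] tibble), `predictions`,
#'   and `excluded` (test rows sharing a training cluster).
#' @export
blind_eval <- function(model, test_x, test, clusters) {
  train_prot <- model$training_proteins
  if (is.null(train_prot)) {
    abort("Model carries no training-protein fingerprint; cannot guarantee a blind evaluation.",
          class = "sappred_input_error")
  }
  cl_of <- setNames(clusters$cluster_id, clusters$protein_id)
  train_clusters <- unique(cl_of[intersect(train_prot, names(cl_of))])
  shared <- cl_of[test$protein_id] %in% train_clusters
  excluded <- test[shared, , drop = FALSE]
  if (all(shared)) {
    abort("Every test variant shares a cluster with the training set.",
          class = "sappred_metric_error")
  }
  keep_x <- test_x[!shared, , drop = FALSE]
  attr(keep_x, "layout_tag") <- attr(test_x, "layout_tag")
  preds <- predict(model, keep_x)
  list(report = metrics_report(preds, test$label[!shared]),
       predictions = preds, excluded = excluded)
}
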