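# Kernel classifier with Platt-calibrated probability output, the strict
# 0.5 decision rule, and the reliability index.

#' Train the pathogenicity classifier
#'
#' Fits an RBF-kernel support vector machine on feature vectors labelled
#' Disease/Neutral, then calibrates a Platt sigmoid on cross-validated
#' decision values so the classifier emits `O(D)`, the probability that a
#' variant is disease-related. Features are z-scaled with statistics learned
#' here and stored in the model (constant features keep scale 1). Training is
#' deterministic given the data order, parameters and seed.
#'
#' @param x Numeric matrix (variants x features) or tibble of feature
#'   columns. A `layout_tag` attribute, if present, is recorded and enforced
#'   at prediction time.
#' @param labels Character/factor vector over `{"Disease", "Neutral"}`.
#' @param cost SVM cost parameter (default 1).
#' @param gamma RBF kernel width (default `1 / ncol(x)`).
#' @param calibration_folds Folds for the cross-validated decision values the
#'   sigmoid is fitted on (default 5).
#' @param seed Integer seed for the calibration fold shuffle.
#' @param layout_tag Overrides the tag read from `x`.
#' @return A `sap_model`.
#' @export
train_sap_model <- function(x, labels, cost = 1, gamma = NULL,
                            calibration_folds = 5, seed = 1,
                            layout_tag = NULL) {
  layout_tag <- layout_tag %||% attr(x, "layout_tag") %||% "untagged"
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels),
            all(labels %in% c("Disease", "Neutral")))
  if (length(unique(labels)) < 2) {
    abort("Training needs at least two examples of each class.",
          class = "sappred_training_error")
  }
  if (min(table(labels)) < 2) {
    abort("Training needs at least two examples of each class.",
          class = "sappred_training_error")
  }
  if (!all(is.finite(x))) {
    abort("Feature matrix contains non-finite values.",
          class = "sappred_input_error")
  }
  gamma <- gamma %||% (1 / ncol(x))

  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  xs <- scale(x, center = center, scale = scale_)

  y <- factor(labels, levels = c("Neutral", "Disease"))
  fit_svm <- function(xm, yv) {
    e1071::svm(xm, yv, type = "C-classification", kernel = "radial",
               cost = cost, gamma = gamma, scale = FALSE,
               probability = FALSE)
  }
  svm_fit <- fit_svm(xs, y)

  # cross-validated decision values for the sigmoid, so calibration is not
  # fitted on resubstitution scores
  n <- nrow(xs)
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  folds <- withr_seed(sample(rep_len(seq_len(calibration_folds), n)))
  dv <- numeric(n)
  for (f in seq_len(calibration_folds)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) {
      dv[!tr] <- decision_values(fit_svm(xs, y), xs[!tr, , drop = FALSE])
      next
    }
    m <- fit_svm(xs[tr, , drop = FALSE], y[tr])
    dv[!tr] <- decision_values(m, xs[!tr, , drop = FALSE])
  }
  platt <- fit_platt(dv, y == "Disease")

  structure(list(svm = svm_fit, platt = platt,
                 center = center, scale = scale_,
                 layout_tag = layout_tag,
                 cost = cost, gamma = gamma, seed = seed,
                 n_train = n,
                 class_counts = table(labels),
                 feature_names = colnames(x),
                 training_proteins = attr(x, "protein_ids")),
            class = "sap_model")
}

decision_values <- function(svm_fit, x) {
  dv <- attr(predict(svm_fit, x, decision.values = TRUE), "decision.values")
  v <- as.numeric(dv[, 1])
  # orient so that larger values favour Disease
  if (grepl("^Neutral/", colnames(dv)[1])) v <- -v
  v
}

# Platt (2000) sigmoid fit with regularised targets, Newton iterations as in
# the reference pseudo-code (Lin, Lin & Weng 2007 variant for stability).
fit_platt <- function(f, y, max_iter = 100, tol = 1e-10) {
  prior1 <- sum(y); prior0 <- sum(!y)
  hi <- (prior1 + 1) / (prior1 + 2)
  lo <- 1 / (prior0 + 2)
  t <- ifelse(y, hi, lo)
  a <- 0; b <- log((prior0 + 1) / (prior1 + 1))
  for (it in seq_len(max_iter)) {
    fApB <- a * f + b
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
    d1 <- t - p
    d2 <- p * (1 - p)
    g1 <- sum(f * d1); g2 <- sum(d1)
    if (abs(g1) < tol && abs(g2) < tol) break
    h11 <- sum(f * f * d2) + 1e-12
    h22 <- sum(d2) + 1e-12
    h21 <- sum(f * d2)
    det <- h11 * h22 - h21 * h21
    da <- -(h22 * g1 - h21 * g2) / det
    db <- -(-h21 * g1 + h11 * g2) / det
    # simple backtracking on the NLL
    nll <- function(aa, bb) {
      z <- aa * f + bb
      sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
    }
    step <- 1
    base <- nll(a, b)
    while (step >= 1e-10 && nll(a + step * da, b + step * db) > base + 1e-12) {
      step <- step / 2
    }
    a <- a + step * da; b <- b + step * db
  }
  # orientation: P(D) = 1 / (1 + exp(a f + b)) must increase with f
  list(a = a, b = b)
}

platt_probability <- function(platt, f) {
  z <- platt$a * f + platt$b
  ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
}

#' Reliability index of a prediction
#'
#' `RI = floor(20 * |O(D) - 0.5|)`, an integer confidence grade from 0
#' (coin-flip) to 10 (certain).
#'
#' @param o_d Probability of the disease-related class, in `[0, 1]`.
#' @return Integer vector over 0..10.
#' @export
reliability_index <- function(o_d) {
  if (any(!is.finite(o_d)) || any(o_d < 0) || any(o_d > 1)) {
    abort("O(D) must lie in [0, 1].", class = "sappred_domain_error")
  }
  # guard against binary-representation noise at grade boundaries
  # (e.g. 20 * |0.7 - 0.5| evaluating just below 4)
  pmin(pmax(as.integer(floor(20 * abs(o_d - 0.5) + 1e-9)), 0L), 10L)
}

#' Predict variants with a trained model
#'
#' Applies the stored z-scaling, the SVM decision function and the Platt
#' sigmoid, then labels each variant by the strict rule: Disease iff
#' `O(D) > 0.5` (a probability of exactly 0.5 yields Neutral).
#'
#' @param object A `sap_model`.
#' @param newdata Feature matrix/tibble with the model's layout.
#' @param ... Unused.
#' @return Tibble with columns `o_d`, `prediction`, `ri`.
#' @export
predict.sap_model <- function(object, newdata, ...) {
  tag <- attr(newdata, "layout_tag")
  if (!is.null(tag) && !identical(tag, object$layout_tag)) {
    abort(sprintf("Feature layout mismatch: model '%s' vs data '%s'.",
                  object$layout_tag, tag),
          class = "sappred_compat_error")
  }
  x <- if (is.null(dim(newdata))) {
    matrix(as.numeric(newdata), nrow = 1)
  } else {
    as.matrix(newdata)
  }
  if (ncol(x) != length(object$center)) {
    abort(sprintf("Model expects %d features, got %d.",
                  length(object$center), ncol(x)),
          class = "sappred_compat_error")
  }
  if (!all(is.finite(x))) {
    abort("Feature matrix contains non-finite values.",
          class = "sappred_input_error")
  }
  xs <- scale(x, center = object$center, scale = object$scale)
  f <- decision_values(object$svm, xs)
  o_d <- platt_probability(object$platt, f)
  tibble(o_d = o_d,
         prediction = ifelse(o_d > 0.5, "Disease", "Neutral"),
         ri = reliability_index(o_d))
}

#' @export
print.sap_model <- function(x, ...) {
  cat(sprintf(
    "<sap_model> layout %s; %d training variants (%s); RBF cost=%g gamma=%.4g; %d SVs\n",
    x$layout_tag, x$n_train,
    paste(names(x$class_counts), as.integer(x$class_counts),
          sep = "=", collapse = ", "),
    x$cost, x$gamma, nrow(x$svm$SV)))
  invisible(x)
}

#' @rdname sap_model_summaries
#' @export
tidy.sap_model <- function(x, ...) {
  tibble(feature = x$feature_names %||% paste0("f", seq_along(x$center)),
         center = unname(x$center), scale = unname(x$scale))
}

#' Summaries of a trained pathogenicity model
#'
#' `tidy()` returns the per-feature normalisation statistics; `glance()` a
#' one-row overview (training size, class balance, hyperparameters, Platt
#' coefficients).
#'
#' @param x A `sap_model`.
#' @param ... Unused.
#' @name sap_model_summaries
#' @export
glance.sap_model <- function(x, ...) {
  tibble(layout_tag = x$layout_tag, n_train = x$n_train,
         n_disease = as.integer(x$class_counts[["Disease"]]),
         n_neutral = as.integer(x$class_counts[["Neutral"]]),
         cost = x$cost, gamma = x$gamma,
         n_support = nrow(x$svm$SV),
         platt_a = x$platt$a, platt_b = x$platt$b)
}

model_magic <- function() "sappred-model"

#' Persist and restore trained models
#'
#' Models are serialised with a versioned magic header, the feature layout
#' tag, the normalisation statistics, optional GO term statistics and the
#' classifier parameters. Loading verifies the header; predicting with a
#' vector of a different layout raises a compatibility error.
#'
#' @param model A `sap_model` (optionally carrying `go_stats`).
#' @param path File path.
#' @return `load_model()` returns the restored `sap_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sap_model"))
  payload <- list(magic = model_magic(), format_version = 1L, model = model)
  saveRDS(payload, path, version = 3)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e) {
    abort(sprintf("Not a model file: %s", conditionMessage(e)),
          class = "sappred_compat_error")
  })
  if (!is.list(payload) || !identical(payload$magic, model_magic())) {
    abort("Not a sappred model file (magic header mismatch).",
          class = "sappred_compat_error")
  }
  if (!identical(payload$format_version, 1L)) {
    abort(sprintf("Unsupported model format version: %s",
                  payload$format_version),
          class = "sappred_compat_error")
  }
  payload$model
}
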