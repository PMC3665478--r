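# High-level wiring: per-variant feature matrices from a data bundle,
# end-to-end prediction tables, and cluster-aware cross-validation.

#' Bundle prediction inputs
#'
#' Collects the per-protein inputs the feature builders need. Every field
#' except `proteins` is optional; absent inputs trigger the documented
#' fallbacks (query-only profile, external-predictor fallback block, zero GO
#' features, computed accessibility).
#'
#' @param proteins Tibble `id`, `sequence`.
#' @param hits Named list (by protein id) of alignment-hit tibbles.
#' @param graph A `go_graph`.
#' @param annotations Tibble `protein_id`, `term`.
#' @param structures Named list (by protein id) of `structure_model`s.
#' @param accessibility Named list (by protein id) of accessibility tibbles.
#' @param panther Tibble `protein_id`, `variant`, `p_deleterious`, `f_wt`,
#'   `f_mut`, `n_counts`.
#' @param chain Chain used when mapping variants onto structures.
#' @param structure_mapping Optional named list (by protein id) of `pos` ->
#'   `resno` mapping tibbles.
#' @return A `sap_data` list.
#' @export
sap_data <- function(proteins, hits = NULL, graph = NULL, annotations = NULL,
                     structures = NULL, accessibility = NULL, panther = NULL,
                     chain = "A", structure_mapping = NULL) {
  structure(list(proteins = proteins, hits = hits, graph = graph,
                 annotations = annotations, structures = structures,
                 accessibility = accessibility, panther = panther,
                 chain = chain, structure_mapping = structure_mapping),
            class = "sap_data")
}

as_sap_data <- function(x) {
  if (inherits(x, "sap_data")) return(x)
  if (inherits(x, "synth_dataset")) {
    return(sap_data(proteins = x$proteins, hits = x$hits, graph = x$graph,
                    annotations = x$annotations, structures = x$structures,
                    accessibility = x$accessibility, panther = x$panther))
  }
  abort("Expected a sap_data or synth_dataset object.",
        class = "sappred_input_error")
}

#' Build the feature matrix for a set of variants
#'
#' Computes, for every variant row, the blocks of the chosen preset from the
#' data bundle: mutation encoding, sequence or structural environment (plus
#' RSA), profile features (profiles are built once per protein and shared by
#' its variants), external-predictor features with fallback, and GO features
#' (zeros when annotation or statistics are absent).
#'
#' @param variants Tibble `protein_id`, `wt`, `pos`, `mut` (resolved against
#'   the bundle's sequences).
#' @param data A `sap_data` (or `synth_dataset`).
#' @param preset Feature preset name (see [feature_preset()]).
#' @param go_stats Optional `go_term_stats` for the GO block.
#' @param k Saturation constant for count scaling.
#' @param guard_go Apply the GO leakage guard (refuse variants whose protein
#'   contributed to `go_stats`).
#' @return Numeric matrix (variants x features) with attributes `layout_tag`
#'   and `protein_ids`.
#' @export
build_feature_matrix <- function(variants, data, preset = "snpsgo_seq",
                                 go_stats = NULL, k = 100,
                                 guard_go = FALSE) {
  data <- as_sap_data(data)
  ps <- feature_preset(preset)
  needs_struct <- "struct_env" %in% names(ps$blocks)
  seq_of <- setNames(data$proteins$sequence, data$proteins$id)

  profile_cache <- new.env(parent = emptyenv())
  get_profile <- function(pid) {
    p <- get0(pid, envir = profile_cache)
    if (is.null(p)) {
      p <- build_profile(seq_of[[pid]], data$hits[[pid]])
      assign(pid, p, envir = profile_cache)
    }
    p
  }
  go_cache <- new.env(parent = emptyenv())
  get_go <- function(pid) {
    g <- get0(pid, envir = go_cache)
    if (is.null(g)) {
      g <- if (is.null(go_stats) || is.null(data$graph)) {
        c(go_score = 0, n_terms = 0)
      } else {
        terms <- if (is.null(data$annotations)) character() else
          data$annotations$term[data$annotations$protein_id == pid]
        go_features(terms, go_stats, data$graph,
                    protein_id = if (guard_go) pid else NULL)
      }
      assign(pid, g, envir = go_cache)
    }
    g
  }
  acc_cache <- new.env(parent = emptyenv())
  get_acc <- function(pid) {
    a <- get0(pid, envir = acc_cache)
    if (is.null(a)) {
      a <- data$accessibility[[pid]] %||%
        compute_accessibility(data$structures[[pid]])
      assign(pid, a, envir = acc_cache)
    }
    a
  }

  rows <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    pid <- v$protein_id
    if (is.null(seq_of[[pid]])) {
      abort(sprintf("Unknown protein id '%s'.", pid),
            class = "sappred_lookup_error")
    }
    prof <- get_profile(pid)
    blocks <- list(
      mutation = encode_mutation(v$wt, v$mut),
      profile = profile_features(prof, v, k = k),
      panther = panther_features(panther_record_for(data$panther, v), k = k),
      go = {
        g <- get_go(pid)
        c(go_score = unname(g[["go_score"]]),
          n_terms = scale_count(unname(g[["n_terms"]]), k))
      }
    )
    if (needs_struct) {
      model <- data$structures[[pid]]
      if (is.null(model)) {
        abort(sprintf("No structure for protein '%s'.", pid),
              class = "sappred_lookup_error")
      }
      res <- map_variant_to_structure(v, model, data$chain,
                                      data$structure_mapping[[pid]])
      blocks$struct_env <- structural_environment(model, res)
      blocks$rsa <- relative_accessibility(get_acc(pid), res)
    } else {
      blocks$seq_env <- sequence_environment(seq_of[[pid]], v$pos)
    }
    rows[[i]] <- do.call(assemble_features, c(list(preset = ps), blocks))
  }
  x <- do.call(rbind, rows)
  rownames(x) <- NULL
  attr(x, "layout_tag") <- ps$layout_tag
  attr(x, "protein_ids") <- variants$protein_id
  x
}

panther_record_for <- function(panther, v) {
  if (is.null(panther)) return(NULL)
  token <- paste0(v$wt, v$pos, v$mut)
  hit <- panther[panther$protein_id == v$protein_id &
                   panther$variant == token, , drop = FALSE]
  if (nrow(hit)) hit[1, ] else NULL
}

#' Train a model on a labelled variant set with GO statistics
#'
#' Fits the GO term statistics on the training variants, builds the feature
#' matrix, trains the calibrated classifier and attaches the GO statistics
#' and training-protein fingerprint to the returned model, so downstream
#' prediction and blind evaluation can enforce leakage safety.
#'
#' @param train Labelled variant tibble.
#' @param data A `sap_data`/`synth_dataset`.
#' @param preset Feature preset.
#' @param seed Seed for the calibration folds.
#' @param ... Passed to [train_sap_model()].
#' @return A `sap_model` with `go_stats` attached.
#' @export
train_pipeline <- function(train, data, preset = "snpsgo_seq", seed = 1,
                           ...) {
  data <- as_sap_data(data)
  go_stats <- if (!is.null(data$graph) && !is.null(data$annotations)) {
    fit_term_stats(train, data$annotations, data$graph)
  } else NULL
  x <- build_feature_matrix(train, data, preset, go_stats = go_stats)
  model <- train_sap_model(x, train$label, seed = seed, ...)
  model$go_stats <- go_stats
  model$training_proteins <- unique(train$protein_id)
  model
}

#' Predict a labelled or unlabelled variant set with a trained model
#'
#' @param model A `sap_model` from [train_pipeline()].
#' @param variants Variant tibble.
#' @param data A `sap_data`/`synth_dataset`.
#' @param preset Feature preset (must match the model layout).
#' @return Prediction tibble (`o_d`, `prediction`, `ri`) aligned with
#'   `variants`.
#' @export
predict_pipeline <- function(model, variants, data, preset = "snpsgo_seq") {
  x <- build_feature_matrix(variants, data, preset,
                            go_stats = model$go_stats)
  predict(model, x)
}

#' Cluster-aware k-fold cross-validation
#'
#' Assigns protein clusters to folds with [cluster_folds()], then, for each
#' fold: fits the GO term statistics and the classifier on the fold
#' complement and predicts the held-out fold. GO statistics are refitted per
#' fold, so no held-out protein ever contributes to the statistics used to
#' score it.
#'
#' @param variants Labelled variant tibble.
#' @param data A `sap_data`/`synth_dataset`.
#' @param clusters Tibble `protein_id`, `cluster_id`.
#' @param preset Feature preset.
#' @param k Number of folds (default 20).
#' @param seed Seed (fold dealing and calibration).
#' @param ... Passed to [train_sap_model()].
#' @return List with `predictions` (variants + `fold`, `o_d`, `prediction`,
#'   `ri`), `report` (pooled [metrics_report()]), `folds`.
#' @export
cross_validate <- function(variants, data, clusters, preset = "snpsgo_seq",
                           k = 20, seed = 1, ...) {
  data <- as_sap_data(data)
  folds <- cluster_folds(clusters, variants, k = k, seed = seed)
  fold_of <- setNames(folds$fold, folds$protein_id)
  vfold <- unname(fold_of[variants$protein_id])
  preds <- vector("list", k)
  for (f in sort(unique(vfold))) {
    tr <- variants[vfold != f, , drop = FALSE]
    te <- variants[vfold == f, , drop = FALSE]
    model <- train_pipeline(tr, data, preset, seed = seed, ...)
    # the per-fold GO statistics must not have seen any held-out protein
    stopifnot(!any(te$protein_id %in% model$go_stats$proteins %||% character()))
    preds[[f]] <- dplyr::bind_cols(mutate(te, fold = f),
                                   predict_pipeline(model, te, data, preset))
  }
  predictions <- bind_rows(preds)
  list(predictions = predictions,
       report = metrics_report(predictions$o_d, predictions$label),
       folds = folds)
}

#' Server-style prediction table for one protein
#'
#' Emits the five-column table of the sequence workflow — the variant token,
#' the predicted class (Disease iff `O(D) > 0.5`), the reliability index, the
#' disease probability and the method name — plus an `rsa` column for the
#' structure workflow. Variants failing the wild-type residue check are
#' flagged in an `error` column and left unpredicted rather than aborting the
#' batch.
#'
#' @param model A `sap_model` (layout must match `preset`).
#' @param protein One-row protein tibble (or sequence string for the
#'   sequence workflow).
#' @param variant_tokens Character vector of substitution tokens.
#' @param data A `sap_data` with the optional inputs for this protein.
#' @param preset Feature preset.
#' @return Tibble with columns `variant`, `prediction`, `ri`, `o_d`,
#'   `method` (and `rsa` for structure presets), plus `error` where a row
#'   failed.
#' @export
predict_variant_table <- function(model, protein, variant_tokens, data,
                                  preset = "snpsgo_seq") {
  if (is.character(protein)) {
    protein <- tibble(id = "query", sequence = toupper(protein))
  }
  parsed <- parse_variant(variant_tokens)
  variants <- mutate(parsed, protein_id = protein$id[[1]],
                     variant = variant_tokens)
  res <- resolve_variants(variants, protein)
  ps <- feature_preset(preset)
  out <- tibble(variant = variants$variant,
                prediction = NA_character_, ri = NA_integer_,
                o_d = NA_real_, method = ps$name, error = NA_character_)
  if (nrow(res$rejected)) {
    out$error[match(res$rejected$variant, out$variant)] <- res$rejected$reason
  }
  if (nrow(res$resolved)) {
    pred <- predict_pipeline(model, res$resolved, data, preset)
    idx <- match(res$resolved$variant, out$variant)
    out$prediction[idx] <- pred$prediction
    out$ri[idx] <- pred$ri
    out$o_d[idx] <- pred$o_d
    if ("rsa" %in% names(ps$blocks)) {
      x <- build_feature_matrix(res$resolved, data, preset,
                                go_stats = model$go_stats)
      rsa_col <- sum(ps$blocks[seq_len(which(names(ps$blocks) == "rsa") - 1)]) + 1
      out$rsa <- NA_real_
      out$rsa[idx] <- unname(x[, rsa_col])
    }
  }
  out
}
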