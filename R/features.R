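# Assembly of the classifier input vectors: mutation block, sequence /
# structural environment, profile, external-predictor and GO blocks, fixed
# presets, versioned layout tags.

#' Feature presets
#'
#' Four fixed layouts are supported:
#' * `snpsgo_seq` — mutation (20) + sequence environment (20) + profile (5) +
#'   external predictor (4) + GO (2) = 51 features;
#' * `snpsgo_3d` — mutation (20) + structural environment (20) + RSA (1) +
#'   profile (5) + external predictor (4) + GO (2) = 52 features;
#' * `profile_seq` / `profile_3d` — profile-only ablations that drop the
#'   external-predictor and GO blocks (45 / 46 features), approximating the
#'   older profile-and-environment-only predictors.
#'
#' Block order within a vector is fixed as mutation, environment (then RSA
#' for structure presets), profile, external predictor, GO, and is versioned
#' through the layout tag carried on every vector and trained model.
#'
#' @param preset Preset name.
#' @return List with `name`, `blocks` (named block lengths, in order),
#'   `length`, `layout_tag`.
#' @export
feature_preset <- function(preset = c("snpsgo_seq", "snpsgo_3d",
                                      "profile_seq", "profile_3d")) {
  preset <- match.arg(preset)
  blocks <- switch(preset,
    snpsgo_seq = c(mutation = 20L, seq_env = 20L, profile = 5L,
                   panther = 4L, go = 2L),
    snpsgo_3d = c(mutation = 20L, struct_env = 20L, rsa = 1L, profile = 5L,
                  panther = 4L, go = 2L),
    profile_seq = c(mutation = 20L, seq_env = 20L, profile = 5L),
    profile_3d = c(mutation = 20L, struct_env = 20L, rsa = 1L, profile = 5L)
  )
  list(name = preset, blocks = blocks, length = sum(blocks),
       layout_tag = paste0(preset, "_v1"))
}

#' Encode a substitution as a signed indicator block
#'
#' 20-element block over [aa_alphabet()]: `-1` at the wild-type residue, `+1`
#' at the mutant residue, `0` elsewhere. Identity substitutions and ambiguity
#' codes are rejected (variants with ambiguous wild types are not
#' predictable).
#'
#' @param wt,mut One-letter standard residue codes.
#' @return Named numeric vector of length 20.
#' @export
encode_mutation <- function(wt, mut) {
  aa <- aa_alphabet()
  wt <- toupper(wt); mut <- toupper(mut)
  if (!(wt %in% aa) || !(mut %in% aa)) {
    abort(sprintf("Mutation encoding needs standard residues, got %s -> %s.",
                  wt, mut), class = "sappred_encoding_error")
  }
  if (wt == mut) {
    abort("Identity substitution cannot be encoded.",
          class = "sappred_encoding_error")
  }
  block <- setNames(numeric(20), aa)
  block[[wt]] <- -1
  block[[mut]] <- 1
  block
}

#' Residue frequencies of a sequence window
#'
#' Frequencies of the 20 standard residues over a `window`-residue segment
#' centred on the variant position (the central residue included), truncated
#' at the termini. Ambiguity codes count in neither numerator nor
#' denominator.
#'
#' @param sequence Protein sequence string.
#' @param pos 1-based centre position.
#' @param window Odd window length (default 19).
#' @return Named numeric vector of length 20 summing to 1 (all zero if no
#'   standard residue falls in the window).
#' @export
sequence_environment <- function(sequence, pos, window = 19) {
  if (window %% 2 == 0) {
    abort("Window length must be odd.", class = "sappred_config_error")
  }
  L <- nchar(sequence)
  stopifnot(pos >= 1, pos <= L)
  half <- (window - 1) / 2
  seg <- substr(toupper(sequence), max(1, pos - half), min(L, pos + half))
  chars <- strsplit(seg, "", fixed = TRUE)[[1]]
  aa <- aa_alphabet()
  counts <- table(factor(chars[chars %in% aa], levels = aa))
  comp <- as.numeric(counts)
  if (sum(comp) > 0) comp <- comp / sum(comp)
  setNames(comp, aa)
}

#' External-predictor feature block with fixed fallback
#'
#' Packs the four external substitution-tolerance predictor quantities into a
#' feature block: deleteriousness probability, wild-type and mutant residue
#' frequencies, and the saturation-scaled number of independent counts. When
#' no record is available the fixed fallback `(0.5, 0, 0, 0)` is emitted
#' (uninformative probability, zeroed remainder); there is no separate
#' presence-indicator element.
#'
#' @param record One-row tibble/list with `p_deleterious`, `f_wt`, `f_mut`,
#'   `n_counts`, or `NULL` when the predictor produced no output.
#' @param k Saturation constant for `n_counts`.
#' @return Named numeric vector of length 4.
#' @export
panther_features <- function(record = NULL, k = 100) {
  if (is.null(record) || (is.data.frame(record) && !nrow(record))) {
    return(c(p_del = 0.5, f_wt = 0, f_mut = 0, n_counts = 0))
  }
  p <- record$p_deleterious[[1]]
  if (!is.finite(p) || p < 0 || p > 1) {
    abort("p_deleterious must lie in [0, 1].",
          class = "sappred_validation_error")
  }
  c(p_del = p, f_wt = record$f_wt[[1]], f_mut = record$f_mut[[1]],
    n_counts = scale_count(record$n_counts[[1]], k))
}

#' Assemble a classifier input vector
#'
#' Concatenates the supplied blocks in the preset's fixed order and stamps
#' the layout tag. Every block required by the preset must be present with
#' its exact dimension; a missing or mis-sized block raises an assembly error
#' naming it.
#'
#' @param preset Preset name or the result of [feature_preset()].
#' @param mutation,seq_env,struct_env,rsa,profile,panther,go Numeric blocks.
#' @return Numeric feature vector with attribute `layout_tag`.
#' @export
assemble_features <- function(preset, mutation = NULL, seq_env = NULL,
                              struct_env = NULL, rsa = NULL, profile = NULL,
                              panther = NULL, go = NULL) {
  if (is.character(preset)) preset <- feature_preset(preset)
  supplied <- list(mutation = mutation, seq_env = seq_env,
                   struct_env = struct_env, rsa = rsa, profile = profile,
                   panther = panther, go = go)
  out <- numeric(0)
  for (b in names(preset$blocks)) {
    v <- supplied[[b]]
    if (is.null(v)) {
      abort(sprintf("Preset %s requires block '%s'.", preset$name, b),
            class = "sappred_assembly_error")
    }
    if (length(v) != preset$blocks[[b]]) {
      abort(sprintf("Block '%s' must have length %d, got %d.",
                    b, preset$blocks[[b]], length(v)),
            class = "sappred_assembly_error")
    }
    if (!all(is.finite(v))) {
      abort(sprintf("Block '%s' contains non-finite values.", b),
            class = "sappred_assembly_error")
    }
    names(v) <- paste(b, if (is.null(names(v))) seq_along(v) else names(v),
                      sep = ".")
    out <- c(out, v)
  }
  attr(out, "layout_tag") <- preset$layout_tag
  out
}
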