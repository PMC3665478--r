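# Variant tokens, labelled SAP dataset tables, and variant resolution
# against sequences.

#' Parse substitution tokens in wtPOSmut notation
#'
#' Tokens such as `"A52V"` name the wild-type residue, the 1-based sequence
#' position and the mutant residue. Parsing is case-insensitive. Identity
#' substitutions (wild-type equal to mutant) and position 0 are rejected.
#'
#' @param tokens Character vector of substitution tokens.
#' @return Tibble with columns `wt` (character), `pos` (integer), `mut`
#'   (character), one row per token.
#' @export
parse_variant <- function(tokens) {
  m <- regmatches(tokens, regexec("^\\s*([A-Za-z])(\\d+)([A-Za-z])\\s*$", tokens))
  bad <- vapply(m, length, integer(1)) == 0
  if (any(bad)) {
    abort(sprintf("Malformed variant token(s): %s (expected e.g. 'A52V').",
                  paste(sQuote(tokens[bad]), collapse = ", ")),
          class = "sappred_format_error")
  }
  wt <- toupper(vapply(m, `[[`, character(1), 2))
  pos <- as.integer(vapply(m, `[[`, character(1), 3))
  mut <- toupper(vapply(m, `[[`, character(1), 4))
  if (any(wt == mut)) {
    abort(sprintf("Identity substitution(s): %s (wild-type equals mutant).",
                  paste(sQuote(tokens[wt == mut]), collapse = ", ")),
          class = "sappred_format_error")
  }
  if (any(pos < 1)) {
    abort("Variant positions are 1-based; position 0 is invalid.",
          class = "sappred_format_error")
  }
  tibble(wt = wt, pos = pos, mut = mut)
}

#' Normalise free-text variant labels to Disease/Neutral
#'
#' Source databases use a drifting vocabulary (`Disease`, `Polymorphism`,
#' `Neutral`, ...). An explicit dictionary maps each raw label to one of the
#' two classes; unmapped labels are rejected rather than guessed.
#'
#' @param labels Character vector of raw labels.
#' @param dictionary Named character vector mapping lowercased raw labels to
#'   `"Disease"` or `"Neutral"`.
#' @return Character vector over `{"Disease", "Neutral"}`.
#' @export
normalize_labels <- function(labels,
                             dictionary = default_label_dictionary()) {
  out <- unname(dictionary[tolower(trimws(labels))])
  if (anyNA(out)) {
    abort(sprintf("Unmapped variant label(s): %s. Extend the label dictionary.",
                  paste(sQuote(unique(labels[is.na(out)])), collapse = ", ")),
          class = "sappred_config_error")
  }
  out
}

#' @rdname normalize_labels
#' @export
default_label_dictionary <- function() {
  c(disease = "Disease", `disease-related` = "Disease", d = "Disease",
    pathogenic = "Disease",
    neutral = "Neutral", polymorphism = "Neutral", n = "Neutral",
    benign = "Neutral")
}

sniff_sap_dialect <- function(header) {
  cols <- tolower(header)
  find <- function(cands) {
    hit <- which(cols %in% cands)
    if (length(hit)) hit[[1]] else NA_integer_
  }
  list(
    protein_col = find(c("protein", "protein_id", "accession", "uniprot", "id")),
    variant_col = find(c("variant", "variation", "mutation", "sap", "aa_change")),
    label_col   = find(c("label", "class", "type", "effect", "annotation"))
  )
}

#' Read a labelled SAP dataset table
#'
#' Reads a delimited text table of labelled single amino acid polymorphisms
#' (one protein id + substitution token + class label per row). The column
#' mapping is dialect-driven: by default it is sniffed from the header line;
#' a `dialect` list with `protein_col`, `variant_col`, `label_col` (names or
#' 1-based indices) overrides the sniffing. Rows whose variant token fails to
#' parse are collected into a skipped-row report, never silently dropped.
#'
#' @param source Path to a delimited file, or a character vector of lines.
#' @param dialect Optional list overriding the sniffed column mapping.
#' @param label_dictionary Label normalisation map; see [normalize_labels()].
#' @param delim Field delimiter (default tab).
#' @param provenance Free-text tag stored on the result.
#' @return A tibble with columns `protein_id`, `wt`, `pos`, `mut`, `label`
#'   and attributes `provenance` and `skipped` (tibble of unparseable rows
#'   with the parse message).
#' @export
read_sap_dataset <- function(source, dialect = NULL,
                             label_dictionary = default_label_dictionary(),
                             delim = "\t", provenance = "unspecified") {
  raw <- readr::read_delim(
    if (length(source) == 1 && file.exists(source)) source else I(paste(source, collapse = "\n")),
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (is.null(dialect)) dialect <- sniff_sap_dialect(names(raw))
  resolve_col <- function(x, what) {
    if (is.character(x)) x <- match(tolower(x), tolower(names(raw)))
    if (is.na(x) || x < 1 || x > ncol(raw)) {
      abort(sprintf("Dataset dialect: cannot locate the %s column.", what),
            class = "sappred_config_error")
    }
    as.integer(x)
  }
  pc <- resolve_col(dialect$protein_col, "protein id")
  vc <- resolve_col(dialect$variant_col, "variant")
  lc <- resolve_col(dialect$label_col, "label")

  n <- nrow(raw)
  parsed <- vector("list", n)
  msgs <- character(n)
  for (i in seq_len(n)) {
    parsed[i] <- list(tryCatch(parse_variant(raw[[vc]][i]),
                               error = function(e) {
                                 msgs[i] <<- conditionMessage(e)
                                 NULL
                               }))
  }
  ok <- !vapply(parsed, is.null, logical(1))
  skipped <- tibble(row = which(!ok),
                    token = raw[[vc]][!ok],
                    message = msgs[!ok])
  out <- tibble(
    protein_id = raw[[pc]][ok],
    bind_rows(parsed[ok]),
    label = normalize_labels(raw[[lc]][ok], label_dictionary)
  )
  attr(out, "provenance") <- provenance
  attr(out, "skipped") <- skipped
  out
}

#' Check variants against their protein sequences
#'
#' Verifies, for every variant, that the named protein exists and that its
#' sequence carries the stated wild-type residue at the stated 1-based
#' position. Violations are collected into a rejection report and returned
#' alongside the clean rows — never silently repaired.
#'
#' @param variants Tibble with `protein_id`, `wt`, `pos`, `mut`.
#' @param proteins Tibble with `id`, `sequence` (as from [read_fasta()]).
#' @return List with `resolved` (clean variant rows) and `rejected` (rows
#'   plus a `reason` column).
#' @export
resolve_variants <- function(variants, proteins) {
  seq_of <- setNames(proteins$sequence, proteins$id)
  reason <- rep(NA_character_, nrow(variants))
  for (i in seq_len(nrow(variants))) {
    s <- unname(seq_of[variants$protein_id[i]])
    if (is.na(s)) {
      reason[i] <- "unknown protein id"
    } else if (variants$pos[i] > nchar(s)) {
      reason[i] <- sprintf("position %d beyond sequence length %d",
                           variants$pos[i], nchar(s))
    } else {
      found <- substr(s, variants$pos[i], variants$pos[i])
      if (found != variants$wt[i]) {
        reason[i] <- sprintf("wild-type mismatch: expected %s, sequence has %s",
                             variants$wt[i], found)
      }
    }
  }
  ok <- is.na(reason)
  list(resolved = variants[ok, , drop = FALSE],
       rejected = mutate(variants[!ok, , drop = FALSE], reason = reason[!ok]))
}

#' Reverse-neutral dataset augmentation
#'
#' For every neutral substitution A->B, adds the reverse substitution B->A at
#' the same position as an additional neutral example (the reverse of a
#' neutral change is assumed neutral). Reverses already present in the table
#' are not duplicated; disease rows are never touched.
#'
#' @param dataset Labelled variant tibble (`protein_id`, `wt`, `pos`, `mut`,
#'   `label`).
#' @return The augmented tibble; added rows carry `augmented = TRUE`.
#' @export
augment_reverse_neutral <- function(dataset) {
  key <- function(d) paste(d$protein_id, d$wt, d$pos, d$mut)
  neu <- filter(dataset, .data$label == "Neutral")
  rev <- mutate(neu, wt = neu$mut, mut = neu$wt)
  rev <- rev[!duplicated(key(rev)) & !(key(rev) %in% key(dataset)), , drop = FALSE]
  out <- bind_rows(mutate(dataset, augmented = FALSE),
                   mutate(rev, augmented = TRUE))
  out
}
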