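# FASTA / raw sequence input and output.

legal_sequence_chars <- function() c(aa_alphabet(), aa_ambiguity())

validate_sequences <- function(ids, seqs, lines = NULL) {
  if (any(!nzchar(ids))) abort("Every sequence record needs a non-empty id.")
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate sequence ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (any(!nzchar(seqs))) {
    abort(paste0("Empty sequence for id(s): ",
                 paste(ids[!nzchar(seqs)], collapse = ", ")))
  }
  ok <- legal_sequence_chars()
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(chars), ok)
    if (length(bad)) {
      abort(sprintf(
        "Illegal sequence character(s) %s in record '%s'.",
        paste(sQuote(bad), collapse = ", "), ids[[i]]
      ), class = "sappred_format_error")
    }
  }
  invisible(TRUE)
}

#' Read protein sequences from FASTA or raw text
#'
#' Accepts a file path or a character vector of lines. Input starting with a
#' `>` header is parsed as FASTA (any number of records); input without
#' headers is treated as one raw sequence and assigned a generated id.
#' Sequences are uppercased and whitespace-stripped. Only the 20 standard
#' one-letter codes plus the ambiguity codes X, B, Z and U are accepted;
#' anything else raises a format error naming the offending character.
#'
#' @param source Path to a FASTA file, or a character vector of input lines.
#' @param raw_id Id assigned to a raw (headerless) sequence.
#' @return A tibble with columns `id` and `sequence`; zero rows for empty
#'   input.
#' @export
read_fasta <- function(source, raw_id = "query") {
  lines <- if (length(source) == 1 && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- lines[!grepl("^\\s*$", lines)]
  if (!length(lines)) return(tibble(id = character(), sequence = character()))

  if (!startsWith(trimws(lines[[1]]), ">")) {
    seq <- toupper(gsub("\\s", "", paste(lines, collapse = "")))
    validate_sequences(raw_id, seq)
    return(tibble(id = raw_id, sequence = seq))
  }

  # FASTA proper: delegate record splitting to Biostrings, then validate
  # against the package's tolerated alphabet.
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  set <- Biostrings::readBStringSet(tmp)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1)
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  validate_sequences(ids, seqs)
  tibble(id = unname(ids), sequence = unname(seqs))
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins Tibble with columns `id` and `sequence`.
#' @param path Output file path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60) {
  validate_sequences(proteins$id, proteins$sequence)
  set <- Biostrings::BStringSet(setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
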