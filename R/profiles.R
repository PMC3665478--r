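# Sequence profiles from E-value-filtered pairwise alignment hits, the
# entropy-based conservation index, and the five profile-derived features.

#' Build a per-position residue-frequency profile
#'
#' Tallies, at every query position, the residues observed across a set of
#' pairwise alignment hits, after discarding hits whose E-value is not
#' strictly below `e_max`. The query sequence itself is always counted, so a
#' profile exists even with no hits. Gap characters and ambiguity codes
#' contribute to neither the residue counts nor the per-position depth.
#'
#' @param query Single-row protein tibble (`id`, `sequence`) or a plain
#'   sequence string.
#' @param hits Tibble of alignment records with columns `subject_id`,
#'   `evalue`, `qstart`, `qend` (1-based inclusive query span), `qseq`,
#'   `sseq` (aligned strings of equal length, gaps as `-`). May be empty or
#'   `NULL`.
#' @param e_max Inclusion threshold: hits are kept iff `evalue < e_max`
#'   (default `1e-9`).
#' @return A `sequence_profile`: list with `freq` (L x 20 matrix, rows
#'   summing to 1 where depth > 0), `n_pos` (per-position aligned-sequence
#'   depth, query included), `n_all` (number of sequences in the profile) and
#'   `length`.
#' @export
build_profile <- function(query, hits = NULL, e_max = 1e-9) {
  seq <- if (is.data.frame(query)) query$sequence[[1]] else query
  seq <- toupper(seq)
  L <- nchar(seq)
  aa <- aa_alphabet()
  counts <- matrix(0L, L, 20, dimnames = list(NULL, aa))
  depth <- integer(L)
  qchars <- strsplit(seq, "", fixed = TRUE)[[1]]
  std <- qchars %in% aa
  counts[cbind(which(std), match(qchars[std], aa))] <- 1L
  depth[std] <- 1L
  n_all <- 1L

  if (!is.null(hits) && nrow(hits)) {
    hits <- filter(hits, .data$evalue < e_max)
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      qa <- strsplit(h$qseq, "", fixed = TRUE)[[1]]
      sa <- strsplit(toupper(h$sseq), "", fixed = TRUE)[[1]]
      if (length(qa) != length(sa)) {
        abort(sprintf("Hit %s: aligned strings differ in length.",
                      h$subject_id), class = "sappred_integrity_error")
      }
      ungapped <- toupper(paste(qa[qa != "-"], collapse = ""))
      if (ungapped != substr(seq, h$qstart, h$qend)) {
        abort(sprintf(
          "Hit %s: aligned query segment disagrees with the query sequence over [%d, %d].",
          h$subject_id, h$qstart, h$qend), class = "sappred_integrity_error")
      }
      qpos <- h$qstart - 1L + cumsum(qa != "-")
      keep <- qa != "-" & sa %in% aa
      if (any(keep)) {
        idx <- cbind(qpos[keep], match(sa[keep], aa))
        for (r in seq_len(nrow(idx))) {
          counts[idx[r, 1], idx[r, 2]] <- counts[idx[r, 1], idx[r, 2]] + 1L
        }
        pos_seen <- unique(qpos[keep])
        depth[pos_seen] <- depth[pos_seen] + 1L
      }
      n_all <- n_all + 1L
    }
  }
  freq <- counts / pmax(rowSums(counts), 1L)
  structure(list(freq = freq, n_pos = depth, n_all = n_all, length = L),
            class = "sequence_profile")
}

#' @export
print.sequence_profile <- function(x, ...) {
  cat(sprintf("<sequence_profile> length %d, %d sequences, mean depth %.1f\n",
              x$length, x$n_all, mean(x$n_pos)))
  invisible(x)
}

#' Conservation index of a profile position
#'
#' `CI = 1 - H / log2(20)` where `H` is the Shannon entropy (bits) of the
#' 20-residue frequency row at the position, with `0 * log(0) := 0`. A fully
#' conserved column scores 1, a uniform column 0, and a zero-depth column is
#' defined as 0.
#'
#' @param profile A `sequence_profile`.
#' @param pos 1-based position(s).
#' @return Numeric in `[0, 1]`, vectorised over `pos`.
#' @export
conservation_index <- function(profile, pos) {
  stopifnot(all(pos >= 1), all(pos <= profile$length))
  vapply(pos, function(p) {
    f <- profile$freq[p, ]
    if (sum(f) == 0) return(0)
    f <- f[f > 0]
    h <- -sum(f * log2(f))
    1 - h / log2(20)
  }, numeric(1))
}

#' The five profile-derived features of a variant
#'
#' In fixed order: frequency of the mutant residue at the position, frequency
#' of the wild-type residue, per-position aligned depth and whole-alignment
#' sequence count (both saturation-scaled by `n / (n + k)`), and the
#' conservation index.
#'
#' @param profile A `sequence_profile` built from the variant's protein.
#' @param variant One-row tibble (or list) with `wt`, `pos`, `mut`.
#' @param k Saturation constant for the two depth counts.
#' @return Named numeric vector of length 5:
#'   `c(f_mut, f_wt, n_pos, n_all, ci)`.
#' @export
profile_features <- function(profile, variant, k = 100) {
  pos <- variant$pos
  if (pos < 1 || pos > profile$length) {
    abort(sprintf("Variant position %d outside profile length %d.",
                  pos, profile$length), class = "sappred_integrity_error")
  }
  aa <- aa_alphabet()
  if (!(variant$wt %in% aa) || !(variant$mut %in% aa)) {
    abort("Profile features need standard wild-type and mutant residues.",
          class = "sappred_integrity_error")
  }
  c(f_mut = unname(profile$freq[pos, variant$mut]),
    f_wt = unname(profile$freq[pos, variant$wt]),
    n_pos = scale_count(profile$n_pos[pos], k),
    n_all = scale_count(profile$n_all, k),
    ci = conservation_index(profile, pos))
}

#' Read tabular pairwise-alignment hits
#'
#' Tab-separated dialect with columns `subject_id`, `evalue`, `qstart`,
#' `qend`, `qseq`, `sseq` — the fields of one pairwise alignment against the
#' query, compatible with common alignment-export formats.
#'
#' @param source Path or character vector of lines.
#' @return Tibble of alignment records for [build_profile()].
#' @export
read_alignment_hits <- function(source) {
  readr::read_tsv(
    if (length(source) == 1 && file.exists(source)) source else I(paste(source, collapse = "\n")),
    col_types = readr::cols(
      subject_id = readr::col_character(),
      evalue = readr::col_double(),
      qstart = readr::col_integer(),
      qend = readr::col_integer(),
      qseq = readr::col_character(),
      sseq = readr::col_character()
    ), progress = FALSE, show_col_types = FALSE)
}

#' Build a profile from an aligned multi-FASTA
#'
#' Convenience reader for pre-aligned sequence sets (query first, full
#' length, gaps as `-`). No E-value filtering applies; every aligned sequence
#' enters the profile.
#'
#' @param source Path or lines of an aligned FASTA file.
#' @return A `sequence_profile` for the first (query) sequence.
#' @export
profile_from_alignment <- function(source) {
  aln <- read_fasta_gapped(source)
  if (!nrow(aln)) abort("Empty alignment.", class = "sappred_format_error")
  qaln <- aln$sequence[[1]]
  query <- gsub("-", "", qaln, fixed = TRUE)
  hits <- if (nrow(aln) > 1) {
    tibble(subject_id = aln$id[-1], evalue = 0,
           qstart = 1L, qend = nchar(query),
           qseq = qaln, sseq = aln$sequence[-1])
  } else NULL
  build_profile(query, hits)
}

# FASTA reader tolerating gap characters (alignment FASTA).
read_fasta_gapped <- function(source) {
  lines <- if (length(source) == 1 && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- lines[!grepl("^\\s*$", lines)]
  if (!length(lines)) return(tibble(id = character(), sequence = character()))
  hdr <- grepl("^>", lines)
  id <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), function(x)
    toupper(gsub("\\s", "", paste(x, collapse = ""))), character(1))
  tibble(id = id, sequence = unname(seqs))
}
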