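# PDB coordinate input/output (via bio3d) and the structure_model container.
# Contract: first model only; HETATM excluded from the residue list; altloc
# resolved by highest occupancy then alphabetical; insertion codes preserved.

new_structure_model <- function(atoms) {
  stopifnot(all(c("chain", "resno", "insert", "resid", "elety",
                  "x", "y", "z") %in% names(atoms)))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("Non-finite atom coordinates.", class = "sappred_format_error")
  }
  structure(list(atoms = as_tibble(atoms)), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  r <- structure_residues(x)
  cat(sprintf("<structure_model> %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms), nrow(r),
              paste(sort(unique(r$chain)), collapse = " ")))
  invisible(x)
}

#' Residue table of a structure model
#'
#' One row per (chain, residue number, insertion code), with the 3-letter
#' residue type, its 1-letter translation (`NA` for non-standard types) and
#' the C-alpha coordinates when a CA atom is present.
#'
#' @param model A `structure_model`.
#' @return Tibble with columns `chain`, `resno`, `insert`, `resid`, `aa`,
#'   `ca_x`, `ca_y`, `ca_z`.
#' @export
structure_residues <- function(model) {
  a <- model$atoms
  key <- paste(a$chain, a$resno, a$insert, sep = "|")
  first <- !duplicated(key)
  res <- tibble(chain = a$chain[first], resno = a$resno[first],
                insert = a$insert[first], resid = a$resid[first],
                aa = aa_three_to_one(a$resid[first]))
  ca <- a[a$elety == "CA", , drop = FALSE]
  ca_key <- paste(ca$chain, ca$resno, ca$insert, sep = "|")
  idx <- match(paste(res$chain, res$resno, res$insert, sep = "|"), ca_key)
  res$ca_x <- ca$x[idx]; res$ca_y <- ca$y[idx]; res$ca_z <- ca$z[idx]
  res
}

#' Read a PDB coordinate file
#'
#' Parses ATOM records of the first model only. HETATM residues are excluded
#' from the protein residue list; alternate locations are resolved to the
#' highest-occupancy conformer (ties broken alphabetically by altloc code);
#' insertion codes are preserved as part of the residue key.
#'
#' @param source Path to a PDB file, or a character vector of PDB lines.
#' @return A `structure_model` (list with an `atoms` tibble).
#' @export
read_structure <- function(source) {
  path <- if (length(source) == 1 && file.exists(source)) source else {
    tmp <- tempfile(fileext = ".pdb")
    writeLines(source, tmp)
    tmp
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) abort(paste0("Cannot parse PDB input: ",
                                     conditionMessage(e)),
                              class = "sappred_format_error"))
  a <- as_tibble(pdb$atom)
  a <- filter(a, .data$type == "ATOM")
  if (!nrow(a)) {
    abort("No ATOM records found in PDB input.",
          class = "sappred_format_error")
  }
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$o[is.na(a$o)] <- 1
  a$chain[is.na(a$chain)] <- " "
  # altloc: keep, per (residue, atom name), the highest-occupancy record,
  # ties broken alphabetically by the altloc code
  a <- arrange(a, .data$chain, .data$resno, .data$insert, .data$elety,
               dplyr::desc(.data$o), .data$alt)
  akey <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
  a <- a[!duplicated(akey), , drop = FALSE]
  a <- arrange(a, .data$eleno)
  new_structure_model(select(a, "chain", "resno", "insert", "resid",
                             "elety", "x", "y", "z"))
}

#' Write a structure model to PDB text
#'
#' @param model A `structure_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
    seq_len(nrow(a)),
    sprintf(" %-3s", substr(a$elety, 1, 3)),
    a$resid, a$chain, a$resno,
    ifelse(nzchar(a$insert), a$insert, " "),
    a$x, a$y, a$z, 1, 0
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read per-residue absolute solvent accessibility
#'
#' Accepts either DSSP output (fixed-column format; the ACC field is parsed
#' from columns 35-38 of residue lines) or a documented two-column fallback
#' dialect: `chain:resno<whitespace>ACC`, one residue per line, ACC in
#' squared angstroms. A residue listed twice raises an integrity error.
#'
#' @param source Path or character vector of lines.
#' @return Tibble with columns `chain`, `resno`, `acc`.
#' @export
read_accessibility <- function(source) {
  lines <- if (length(source) == 1 && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else source
  lines <- lines[nzchar(trimws(lines))]
  empty <- tibble(chain = character(), resno = integer(), acc = double())
  if (!length(lines)) return(empty)

  out <- if (any(grepl("^\\s*#\\s+RESIDUE", lines))) {
    hdr <- grep("^\\s*#\\s+RESIDUE", lines)[[1]]
    body <- lines[-seq_len(hdr)]
    body <- body[nchar(body) >= 38]
    resno <- suppressWarnings(as.integer(substr(body, 6, 10)))
    keep <- !is.na(resno)  # chain breaks have a blank residue field
    tibble(chain = trimws(substr(body, 12, 12))[keep],
           resno = resno[keep],
           acc = as.numeric(substr(body, 35, 38))[keep])
  } else {
    parts <- strsplit(trimws(lines), "\\s+")
    if (any(vapply(parts, length, integer(1)) < 2)) {
      abort("Accessibility fallback lines must be 'chain:resno ACC'.",
            class = "sappred_format_error")
    }
    key <- strsplit(vapply(parts, `[[`, character(1), 1), ":", fixed = TRUE)
    if (any(vapply(key, length, integer(1)) != 2)) {
      abort("Accessibility residue keys must be 'chain:resno'.",
            class = "sappred_format_error")
    }
    tibble(chain = vapply(key, `[[`, character(1), 1),
           resno = as.integer(vapply(key, `[[`, character(1), 2)),
           acc = as.numeric(vapply(parts, `[[`, character(1), 2)))
  }
  if (any(out$acc < 0) || anyNA(out$acc)) {
    abort("Accessibility values must be non-negative numbers.",
          class = "sappred_format_error")
  }
  if (anyDuplicated(paste(out$chain, out$resno))) {
    abort("Residue listed twice in accessibility input.",
          class = "sappred_integrity_error")
  }
  out
}

#' Write accessibility records in the two-column fallback dialect
#'
#' @param acc Tibble with `chain`, `resno`, `acc`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_accessibility <- function(acc, path) {
  writeLines(sprintf("%s:%d %.2f", acc$chain, acc$resno, acc$acc), path)
  invisible(path)
}

#' Read a per-variant external predictor (PANTHER-style) record table
#'
#' Tab-separated adapter for the four per-variant quantities an external
#' substitution-tolerance predictor emits: the probability that the change is
#' deleterious, the wild-type and mutant residue frequencies at the position,
#' and the number of independent observation counts. Expected columns:
#' `protein_id`, `variant`, `p_deleterious`, `f_wt`, `f_mut`, `n_counts`.
#'
#' @param source Path or character vector of lines.
#' @return Tibble keyed by `protein_id` and `variant` token.
#' @export
read_panther <- function(source) {
  raw <- readr::read_tsv(
    if (length(source) == 1 && file.exists(source)) source else I(paste(source, collapse = "\n")),
    col_types = readr::cols(
      protein_id = readr::col_character(),
      variant = readr::col_character(),
      p_deleterious = readr::col_double(),
      f_wt = readr::col_double(),
      f_mut = readr::col_double(),
      n_counts = readr::col_double()
    ), progress = FALSE, show_col_types = FALSE)
  bad <- !is.finite(raw$p_deleterious) | raw$p_deleterious < 0 |
    raw$p_deleterious > 1
  if (any(bad)) {
    abort("p_deleterious must lie in [0, 1].",
          class = "sappred_format_error")
  }
  if (any(raw$n_counts < 0)) {
    abort("n_counts must be non-negative.", class = "sappred_format_error")
  }
  raw
}
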