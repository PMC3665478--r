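# Structural microenvironment composition around the mutated residue's
# C-alpha, relative solvent accessibility, and a rolling-probe surface-area
# fallback.

#' Map a variant to a structure residue
#'
#' Resolves a sequence variant to a residue of a structure model. By default
#' the sequence position is assumed to equal the PDB residue number; an
#' explicit `mapping` table (`pos` -> `resno`) overrides this for structures
#' with offset numbering. The residue's type must match the variant's
#' wild-type residue, otherwise a mapping error reporting both types is
#' raised.
#'
#' @param variant One-row tibble/list with `wt`, `pos`.
#' @param model A `structure_model`.
#' @param chain Chain identifier.
#' @param mapping Optional tibble with columns `pos`, `resno` (and optional
#'   `insert`).
#' @return One-row residue tibble (as in [structure_residues()]).
#' @export
map_variant_to_structure <- function(variant, model, chain, mapping = NULL) {
  res <- structure_residues(model)
  if (!chain %in% res$chain) {
    abort(sprintf("Chain '%s' absent; available chains: %s", chain,
                  paste(sort(unique(res$chain)), collapse = ", ")),
          class = "sappred_lookup_error")
  }
  target_resno <- variant$pos
  target_insert <- ""
  if (!is.null(mapping)) {
    hit <- mapping[mapping$pos == variant$pos, , drop = FALSE]
    if (!nrow(hit)) {
      abort(sprintf("No mapping entry for sequence position %d.", variant$pos),
            class = "sappred_mapping_error")
    }
    target_resno <- hit$resno[[1]]
    if ("insert" %in% names(hit)) target_insert <- hit$insert[[1]]
  }
  r <- res[res$chain == chain & res$resno == target_resno &
             res$insert == target_insert, , drop = FALSE]
  if (!nrow(r)) {
    abort(sprintf("Residue %d%s not found in chain %s.",
                  target_resno, target_insert, chain),
          class = "sappred_mapping_error")
  }
  if (is.na(r$aa) || r$aa != variant$wt) {
    abort(sprintf(
      "Residue type mismatch at %s:%d — variant expects %s, structure has %s (%s).",
      chain, target_resno, variant$wt,
      ifelse(is.na(r$aa), "non-standard", r$aa), r$resid),
      class = "sappred_mapping_error")
  }
  r
}

#' Residue composition of the structural microenvironment
#'
#' Counts the protein residues whose C-alpha lies within `radius` angstroms
#' (closed ball; Euclidean C-alpha to C-alpha distance) of the centre
#' residue's C-alpha, across all chains of the model, excluding the centre
#' residue itself, and normalises the counts of the 20 standard residue types
#' into frequencies. Non-standard neighbour types are ignored. An isolated
#' residue yields the all-zero composition.
#'
#' @param model A `structure_model`.
#' @param center One-row residue tibble (from [map_variant_to_structure()] or
#'   [structure_residues()]).
#' @param radius Sphere radius in angstroms (default 6).
#' @param same_chain_only If `TRUE`, restrict neighbours to the centre's
#'   chain.
#' @return Named numeric vector of length 20 over [aa_alphabet()] with
#'   attribute `n_neighbors`.
#' @export
structural_environment <- function(model, center, radius = 6,
                                   same_chain_only = FALSE) {
  if (is.na(center$ca_x)) {
    abort("Centre residue has no C-alpha atom.",
          class = "sappred_structure_error")
  }
  res <- structure_residues(model)
  res <- res[!is.na(res$ca_x), , drop = FALSE]
  if (same_chain_only) res <- res[res$chain == center$chain, , drop = FALSE]
  self <- res$chain == center$chain & res$resno == center$resno &
    res$insert == center$insert
  res <- res[!self, , drop = FALSE]
  d2 <- (res$ca_x - center$ca_x)^2 + (res$ca_y - center$ca_y)^2 +
    (res$ca_z - center$ca_z)^2
  nb <- res[d2 <= radius^2, , drop = FALSE]
  aa <- aa_alphabet()
  counts <- table(factor(nb$aa, levels = aa))
  comp <- as.numeric(counts)
  if (sum(comp) > 0) comp <- comp / sum(comp)
  names(comp) <- aa
  attr(comp, "n_neighbors") <- nrow(nb)
  comp
}

#' Relative solvent accessibility of a residue
#'
#' Divides the absolute accessible surface area by the per-residue-type
#' reference maximum and clamps to `[0, 1]` (termini routinely exceed the
#' reference). A residue missing from the accessibility record either raises
#' an error (default) or imputes 0.5 with a warning, per `missing_policy`.
#'
#' @param acc Accessibility tibble (`chain`, `resno`, `acc`) from
#'   [read_accessibility()] or [compute_accessibility()].
#' @param residue One-row residue tibble with `chain`, `resno`, `aa`.
#' @param reference Named maxima per residue type; default
#'   [max_asa_reference()].
#' @param missing_policy `"error"` or `"impute"`.
#' @return RSA value in `[0, 1]`.
#' @export
relative_accessibility <- function(acc, residue,
                                   reference = max_asa_reference(),
                                   missing_policy = c("error", "impute")) {
  missing_policy <- match.arg(missing_policy)
  hit <- acc[acc$chain == residue$chain & acc$resno == residue$resno, ,
             drop = FALSE]
  if (!nrow(hit)) {
    if (missing_policy == "error") {
      abort(sprintf("No accessibility value for %s:%d.",
                    residue$chain, residue$resno),
            class = "sappred_lookup_error")
    }
    warn(sprintf("No accessibility value for %s:%d; imputing RSA = 0.5.",
                 residue$chain, residue$resno))
    return(0.5)
  }
  mx <- reference[[residue$aa]]
  if (is.null(mx) || is.na(mx)) {
    abort(sprintf("No reference maximum ASA for residue type '%s'.",
                  residue$aa), class = "sappred_lookup_error")
  }
  min(max(hit$acc[[1]] / mx, 0), 1)
}

#' Rolling-probe accessible surface area (fallback)
#'
#' Shrake-Rupley style numerical accessible-surface computation over the
#' atoms present in the model, used when no accessibility file is supplied.
#' Each atom is covered with a quasi-uniform point lattice on its
#' solvent-expanded sphere (van der Waals radius + probe radius); the exposed
#' fraction times the sphere area is the atom's contribution, summed per
#' residue. For C-alpha-trace models this is a coarse per-residue burial
#' estimate; a file-based accessibility record is authoritative when
#' available.
#'
#' @param model A `structure_model`.
#' @param probe Probe radius in angstroms (default 1.4, water).
#' @param n_points Lattice points per atom (default 92).
#' @return Accessibility tibble (`chain`, `resno`, `acc`) consumable by
#'   [relative_accessibility()].
#' @export
compute_accessibility <- function(model, probe = 1.4, n_points = 92) {
  a <- model$atoms
  radii <- vdw_radius(a$elety)
  # golden-spiral lattice on the unit sphere
  i <- seq_len(n_points) - 0.5
  phi <- acos(1 - 2 * i / n_points)
  theta <- pi * (1 + sqrt(5)) * i
  sphere <- cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
  xyz <- cbind(a$x, a$y, a$z)
  r_ext <- radii + probe
  exposed <- numeric(nrow(a))
  for (j in seq_len(nrow(a))) {
    pts <- sweep(sphere * r_ext[j], 2, xyz[j, ], `+`)
    free <- rep(TRUE, n_points)
    d2 <- colSums((t(xyz) - xyz[j, ])^2)
    nb <- which(d2 <= (r_ext[j] + r_ext + probe)^2 & seq_along(d2) != j)
    for (k in nb) {
      if (!any(free)) break
      dd <- (pts[, 1] - xyz[k, 1])^2 + (pts[, 2] - xyz[k, 2])^2 +
        (pts[, 3] - xyz[k, 3])^2
      free <- free & dd > r_ext[k]^2
    }
    exposed[j] <- 4 * pi * r_ext[j]^2 * mean(free)
  }
  per_res <- tibble(chain = a$chain, resno = a$resno, acc = exposed)
  summarise(group_by(per_res, .data$chain, .data$resno),
            acc = sum(.data$acc), .groups = "drop")
}

vdw_radius <- function(elety) {
  element <- substr(trimws(elety), 1, 1)
  r <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, H = 1.2, P = 1.8)
  out <- r[element]
  out[is.na(out)] <- 1.7
  unname(out)
}
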