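# Self-contained synthetic data with planted pathogenicity signals:
# sequences, alignment hits, a random GO DAG with a disease-enriched term
# set, C-alpha trace structures with burial-derived accessibility, external
# predictor records, and labelled variants drawn from a logistic model over
# (conservation, functional enrichment, burial).

#' Synthetic dataset configuration
#'
#' The label model is logistic: for a variant at position `j` of protein `i`,
#' `logit P(Disease) = b_ci (2 c_j - 1) + b_go (2 g_i - 1) + b_rsa (1 - 2 rsa_j)`
#' where `c_j` is the planted conservation level, `g_i` the fraction of the
#' protein's direct GO terms drawn from the disease-enriched term set, and
#' `rsa_j` the planted relative accessibility. The external-predictor record,
#' when enabled, is generated from the realised label with strength
#' `b_panther`. Zero effect sizes give labels independent of every feature.
#'
#' @param seed Mandatory integer seed.
#' @param n_proteins Number of proteins.
#' @param length_range Sequence length range (inclusive).
#' @param variants_per_protein Variants drawn per protein.
#' @param n_terms GO DAG size.
#' @param n_risk_terms Size of the disease-enriched term set.
#' @param depth_range Alignment depth range (homologs per protein).
#' @param b_ci,b_go,b_rsa,b_panther Non-negative effect sizes.
#' @param pair_fraction Fraction of proteins placed into two-protein sequence
#'   clusters (the rest are singletons).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed, n_proteins = 40, length_range = c(60, 120),
                         variants_per_protein = 25, n_terms = 60,
                         n_risk_terms = 12, depth_range = c(15, 40),
                         b_ci = 0, b_go = 0, b_rsa = 0, b_panther = 0,
                         pair_fraction = 0.2) {
  stopifnot(!missing(seed), is.numeric(seed),
            b_ci >= 0, b_go >= 0, b_rsa >= 0, b_panther >= 0,
            length_range[1] >= 20, variants_per_protein >= 1)
  if (variants_per_protein > length_range[1]) {
    abort("More variants per protein than the shortest sequence has positions.",
          class = "sappred_config_error")
  }
  structure(as.list(environment()), class = "synth_config")
}

#' Named generator presets
#'
#' `strong_v1` plants strong conservation, functional, burial and external-
#' predictor signals (effect sizes 3, 3, 2.5, 2.5) across 120 proteins;
#' `null_v1` is the matched configuration with every effect size 0, so labels
#' are independent of all features.
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @return A `synth_config`.
#' @export
synth_preset <- function(name = c("strong_v1", "null_v1"), seed) {
  name <- match.arg(name)
  base <- list(seed = seed, n_proteins = 120, variants_per_protein = 25)
  eff <- switch(name,
    strong_v1 = list(b_ci = 3, b_go = 3, b_rsa = 2.5, b_panther = 2.5),
    null_v1 = list(b_ci = 0, b_go = 0, b_rsa = 0, b_panther = 0))
  do.call(synth_config, c(base, eff))
}

#' Generate a synthetic dataset
#'
#' Fully reproducible from the config seed. Every variant resolves against
#' its protein sequence, every protein has a structure whose residue numbers
#' equal sequence positions, and every emitted object satisfies the
#' invariants of the module that consumes it.
#'
#' @param config A `synth_config`.
#' @return A `synth_dataset` list: `proteins`, `variants` (labelled, with
#'   `variant` token column), `hits` (per-protein alignment tibbles),
#'   `graph`, `annotations`, `structures`, `accessibility`, `panther`,
#'   `clusters`, `truth` (per-variant planted signals), `config`.
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  aa <- aa_alphabet()
  np <- config$n_proteins
  ids <- sprintf("SYNP%03d", seq_len(np))

  graph <- synth_go_dag(config$n_terms)
  risk_terms <- sample(graph$terms$id[!graph$terms$obsolete],
                       config$n_risk_terms)

  proteins <- tibble(
    id = ids,
    sequence = vapply(seq_len(np), function(i) {
      L <- sample(seq(config$length_range[1], config$length_range[2]), 1)
      paste(sample(aa, L, replace = TRUE), collapse = "")
    }, character(1))
  )

  # protein-level functional signal: fraction of direct terms from the
  # disease-enriched set
  n_direct <- sample(3:6, np, replace = TRUE)
  risk_prone <- runif(np)
  annotations <- bind_rows(lapply(seq_len(np), function(i) {
    k_risk <- rbinom(1, n_direct[i], risk_prone[i])
    terms <- c(sample(risk_terms, min(k_risk, length(risk_terms))),
               sample(setdiff(graph$terms$id[!graph$terms$obsolete],
                              risk_terms), n_direct[i] - min(k_risk, length(risk_terms))))
    tibble(protein_id = ids[i], term = unique(terms))
  }))
  g_signal <- vapply(seq_len(np), function(i) {
    t <- annotations$term[annotations$protein_id == ids[i]]
    mean(t %in% risk_terms)
  }, numeric(1))

  # per-position conservation levels and alignment hits
  conservation <- lapply(proteins$sequence, function(s) {
    stats::rbeta(nchar(s), 0.6, 0.6)
  })
  hits <- lapply(seq_len(np), function(i) {
    synth_hits(proteins$sequence[i], conservation[[i]],
               depth = sample(seq(config$depth_range[1],
                                  config$depth_range[2]), 1),
               subject_prefix = paste0(ids[i], "_h"))
  })
  names(hits) <- ids

  structures <- lapply(proteins$sequence, function(s)
    toy_structure(nchar(s), sequence = s))
  names(structures) <- ids

  # burial from the trace: neighbour count within 8 A, mapped to RSA
  accessibility <- lapply(seq_len(np), function(i) {
    res <- structure_residues(structures[[i]])
    nb <- vapply(seq_len(nrow(res)), function(j) {
      d2 <- (res$ca_x - res$ca_x[j])^2 + (res$ca_y - res$ca_y[j])^2 +
        (res$ca_z - res$ca_z[j])^2
      sum(d2 <= 64) - 1L
    }, integer(1))
    rsa <- pmin(pmax(1 - nb / max(nb, 1) + rnorm(nrow(res), 0, 0.05), 0), 1)
    tibble(chain = res$chain, resno = res$resno,
           acc = round(unname(rsa * max_asa_reference()[res$aa]), 2))
  })
  names(accessibility) <- ids

  # variants and labels
  variants <- bind_rows(lapply(seq_len(np), function(i) {
    s <- proteins$sequence[i]
    L <- nchar(s)
    pos <- sample(seq_len(L), config$variants_per_protein)
    wt <- substring(s, pos, pos)
    mut <- vapply(wt, function(w) sample(setdiff(aa, w), 1), character(1))
    res <- structure_residues(structures[[i]])
    acc <- accessibility[[i]]
    rsa <- vapply(seq_along(pos), function(j) {
      min(acc$acc[acc$resno == pos[j]] /
            max_asa_reference()[[wt[j]]], 1)
    }, numeric(1))
    tibble(protein_id = ids[i], wt = unname(wt), pos = pos,
           mut = unname(mut),
           ci_true = conservation[[i]][pos],
           go_true = g_signal[i], rsa_true = rsa)
  }))
  eta <- config$b_ci * (2 * variants$ci_true - 1) +
    config$b_go * (2 * variants$go_true - 1) +
    config$b_rsa * (1 - 2 * variants$rsa_true)
  y <- rbinom(nrow(variants), 1, plogis(eta))
  variants$label <- ifelse(y == 1, "Disease", "Neutral")
  variants$variant <- paste0(variants$wt, variants$pos, variants$mut)

  panther <- tibble(
    protein_id = variants$protein_id,
    variant = variants$variant,
    p_deleterious = plogis(config$b_panther * (2 * y - 1) + rnorm(length(y))),
    f_wt = pmin(pmax(variants$ci_true + rnorm(length(y), 0, 0.1), 0), 1),
    f_mut = pmin(pmax(0.3 * (1 - variants$ci_true) +
                        rnorm(length(y), 0, 0.05), 0), 1),
    n_counts = stats::rpois(length(y), 30)
  )

  # sequence clusters: a fraction of proteins paired, the rest singletons
  n_pairs <- floor(config$pair_fraction * np / 2)
  cluster_id <- seq_len(np)
  if (n_pairs > 0) {
    paired <- sample(np, 2 * n_pairs)
    cluster_id[paired[seq_len(n_pairs) * 2]] <-
      cluster_id[paired[seq_len(n_pairs) * 2 - 1]]
  }
  clusters <- tibble(protein_id = ids,
                     cluster_id = sprintf("CL%03d", match(cluster_id,
                                                          unique(cluster_id))))

  truth <- select(variants, "protein_id", "variant", "ci_true", "go_true",
                  "rsa_true")
  variants <- select(variants, "protein_id", "variant", "wt", "pos", "mut",
                     "label")
  structure(list(proteins = proteins, variants = variants, hits = hits,
                 graph = graph, annotations = annotations,
                 structures = structures, accessibility = accessibility,
                 panther = panther, clusters = clusters, truth = truth,
                 risk_terms = risk_terms, config = config),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf(
    "<synth_dataset> %d proteins, %d variants (%d Disease / %d Neutral), %d GO terms\n",
    nrow(x$proteins), nrow(x$variants),
    sum(x$variants$label == "Disease"), sum(x$variants$label == "Neutral"),
    nrow(x$graph$terms)))
  invisible(x)
}

# Random GO-like DAG: term i > 1 links to 1-2 earlier terms, which keeps the
# graph acyclic by construction; a couple of terms are marked obsolete.
synth_go_dag <- function(n_terms) {
  ids <- sprintf("GO:%07d", seq_len(n_terms))
  ns <- c("molecular_function", "biological_process", "cellular_component")
  edges <- bind_rows(lapply(2:n_terms, function(i) {
    parents <- sample(seq_len(i - 1), min(sample(1:2, 1), i - 1))
    tibble(child = ids[i], parent = ids[parents],
           relation = sample(c("is_a", "part_of"), length(parents),
                             replace = TRUE, prob = c(0.8, 0.2)))
  }))
  obsolete <- rep(FALSE, n_terms)
  if (n_terms > 10) obsolete[sample(4:n_terms, 2)] <- TRUE
  new_go_graph(
    tibble(id = ids, name = paste("synthetic term", seq_len(n_terms)),
           namespace = ns[1 + (seq_len(n_terms) %% 3)], obsolete = obsolete),
    edges)
}

# Alignment hits for one query: each homolog keeps the query residue with the
# position's conservation probability, otherwise substitutes a random
# residue; a few positions are gapped. Two decoy hits above the E-value
# threshold are appended to exercise the filter.
synth_hits <- function(sequence, conservation, depth, subject_prefix) {
  L <- nchar(sequence)
  q <- strsplit(sequence, "", fixed = TRUE)[[1]]
  aa <- aa_alphabet()
  make_hit <- function(j, evalue) {
    keep <- runif(L) < conservation
    subj <- ifelse(keep, q, sample(aa, L, replace = TRUE))
    subj[runif(L) < 0.03] <- "-"
    tibble(subject_id = paste0(subject_prefix, j),
           evalue = evalue, qstart = 1L, qend = L,
           qseq = sequence, sseq = paste(subj, collapse = ""))
  }
  bind_rows(c(
    lapply(seq_len(depth), function(j) make_hit(j, 10^-runif(1, 15, 60))),
    lapply(seq_len(2), function(j) make_hit(depth + j, 10^-runif(1, 2, 6)))
  ))
}

#' Generate a C-alpha trace structure
#'
#' Builds a self-avoiding random C-alpha trace with ~3.8 angstrom consecutive
#' spacing (non-consecutive residues kept at least 3.5 angstroms apart) and
#' assigns residue types from the paired sequence.
#'
#' @param n_residues Number of residues (>= 2).
#' @param sequence Optional sequence string of length `n_residues`; random
#'   residues otherwise.
#' @param chain Chain identifier.
#' @return A `structure_model` with one CA atom per residue, residue numbers
#'   1..n.
#' @export
toy_structure <- function(n_residues, sequence = NULL, chain = "A") {
  stopifnot(n_residues >= 2)
  if (is.null(sequence)) {
    sequence <- paste(sample(aa_alphabet(), n_residues, replace = TRUE),
                      collapse = "")
  }
  stopifnot(nchar(sequence) == n_residues)
  coords <- matrix(NA_real_, n_residues, 3)
  coords[1, ] <- c(0, 0, 0)
  dir <- c(1, 0, 0)
  for (i in 2:n_residues) {
    placed <- FALSE
    for (try in seq_len(200)) {
      # propose a direction correlated with the previous one (chain-like)
      prop <- dir + rnorm(3, 0, 0.9)
      prop <- prop / sqrt(sum(prop^2))
      cand <- coords[i - 1, ] + 3.8 * prop
      prev <- coords[seq_len(max(i - 2, 1)), , drop = FALSE]
      if (i == 2 || all(colSums((t(prev) - cand)^2) >= 3.5^2)) {
        coords[i, ] <- cand
        dir <- prop
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      # fall back to extending straight out, which cannot clash
      coords[i, ] <- coords[i - 1, ] + 3.8 * dir
    }
  }
  res3 <- aa_one_to_three(strsplit(sequence, "", fixed = TRUE)[[1]])
  res3[is.na(res3)] <- "GLY"
  new_structure_model(tibble(
    chain = chain, resno = seq_len(n_residues), insert = "",
    resid = res3, elety = "CA",
    x = round(coords[, 1], 3), y = round(coords[, 2], 3),
    z = round(coords[, 3], 3)))
}

#' Write a synthetic dataset to a fixture directory
#'
#' Emits exactly the file formats the prediction pipeline consumes — FASTA
#' sequences, OBO ontology, tab-separated annotation/variant/cluster/
#' external-predictor tables, per-protein alignment-hit tables, PDB
#' structures and two-column accessibility files — so generated fixtures
#' double as format documentation.
#'
#' @param dataset A `synth_dataset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_synth_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in c("hits", "structures", "accessibility")) {
    dir.create(file.path(dir, sub), showWarnings = FALSE)
  }
  write_fasta(dataset$proteins, file.path(dir, "proteins.fasta"))
  write_obo(dataset$graph, file.path(dir, "ontology.obo"))
  readr::write_tsv(dataset$annotations, file.path(dir, "annotations.tsv"),
                   col_names = FALSE)
  readr::write_tsv(select(dataset$variants, "protein_id", "variant", "label"),
                   file.path(dir, "variants.tsv"))
  readr::write_tsv(dataset$clusters, file.path(dir, "clusters.tsv"))
  readr::write_tsv(dataset$panther, file.path(dir, "panther.tsv"))
  for (id in dataset$proteins$id) {
    readr::write_tsv(dataset$hits[[id]],
                     file.path(dir, "hits", paste0(id, ".tsv")))
    write_structure(dataset$structures[[id]],
                    file.path(dir, "structures", paste0(id, ".pdb")))
    write_accessibility(dataset$accessibility[[id]],
                        file.path(dir, "accessibility", paste0(id, ".acc")))
  }
  invisible(dir)
}
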