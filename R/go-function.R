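# Ancestor closure over the GO graph and the disease/neutral log-odds
# functional score with its term-count companion feature.

#' Ancestor closure of a GO term set
#'
#' Returns the input terms together with every ancestor reachable through
#' `is_a` and (by default) `part_of` edges. Obsolete terms are dropped from
#' the closure; root terms are included. Unknown term ids raise a lookup
#' error listing them.
#'
#' @param graph A `go_graph`.
#' @param terms Character vector (or set) of GO term ids; may be empty.
#' @param relations Edge types followed (default `is_a` and `part_of`).
#' @return Character vector: the closure, sorted.
#' @export
ancestor_closure <- function(graph, terms,
                             relations = c("is_a", "part_of")) {
  terms <- unique(as.character(terms))
  if (!length(terms)) return(character())
  unknown <- setdiff(terms, graph$terms$id)
  if (length(unknown)) {
    abort(sprintf("Unknown GO term id(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "sappred_lookup_error")
  }
  e <- graph$edges[graph$edges$relation %in% relations, , drop = FALSE]
  parents_of <- split(e$parent, e$child)
  closure <- character()
  frontier <- terms
  while (length(frontier)) {
    closure <- c(closure, frontier)
    nxt <- unique(unlist(parents_of[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, closure)
  }
  obsolete <- graph$terms$id[graph$terms$obsolete]
  sort(setdiff(unique(closure), obsolete))
}

#' Fit per-term disease/neutral variant counts on a training set
#'
#' For every GO term appearing in the annotation closure of any training
#' protein, counts the training variants (not proteins) of each class whose
#' protein closure contains the term. Together with the class totals and a
#' pseudocount these counts define the functional log-odds score. The ids of
#' the proteins that contributed are recorded so that a leakage guard can
#' refuse to score them later with these same statistics.
#'
#' @param train Labelled variant tibble (`protein_id`, `label`).
#' @param annotations Direct-annotation tibble (`protein_id`, `term`).
#' @param graph A `go_graph`.
#' @param pseudocount Additive smoothing constant (default 1).
#' @param fold Optional identifier of the fold these statistics were fitted
#'   for, recorded on the object.
#' @return A `go_term_stats`: list with `counts` (tibble `term`, `d`, `n`),
#'   `d_tot`, `n_tot`, `pseudocount`, `proteins`, `fold`.
#' @export
fit_term_stats <- function(train, annotations, graph, pseudocount = 1,
                           fold = NA) {
  if (!nrow(train)) {
    abort("Cannot fit GO term statistics on an empty training set.",
          class = "sappred_fit_error")
  }
  stopifnot(all(train$label %in% c("Disease", "Neutral")))
  prots <- unique(train$protein_id)
  closures <- lapply(setNames(prots, prots), function(p) {
    ancestor_closure(graph, annotations$term[annotations$protein_id == p])
  })
  tally <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(train))) {
    cl <- closures[[train$protein_id[i]]]
    is_d <- train$label[i] == "Disease"
    for (t in cl) {
      cur <- get0(t, envir = tally, ifnotfound = c(d = 0L, n = 0L))
      cur[[if (is_d) "d" else "n"]] <- cur[[if (is_d) "d" else "n"]] + 1L
      assign(t, cur, envir = tally)
    }
  }
  terms <- sort(ls(tally))
  counts <- tibble(
    term = terms,
    d = vapply(terms, function(t) get(t, envir = tally)[["d"]], integer(1)),
    n = vapply(terms, function(t) get(t, envir = tally)[["n"]], integer(1))
  )
  structure(list(counts = counts,
                 d_tot = sum(train$label == "Disease"),
                 n_tot = sum(train$label == "Neutral"),
                 pseudocount = pseudocount,
                 proteins = prots,
                 fold = fold),
            class = "go_term_stats")
}

#' @export
print.go_term_stats <- function(x, ...) {
  cat(sprintf(
    "<go_term_stats> %d terms; %d disease / %d neutral training variants; pseudocount %g\n",
    nrow(x$counts), x$d_tot, x$n_tot, x$pseudocount))
  invisible(x)
}

#' GO functional features of a protein
#'
#' Computes the two functional features fed to the classifier: the additive
#' log-odds score over the annotation ancestor closure, and the number of GO
#' terms used. Per closure term `t`, the score contribution is
#' `log2( ((d_t + pi) / (D + 2 pi)) / ((n_t + pi) / (N + 2 pi)) )` with
#' pseudocount `pi`; terms unseen in training count as `d_t = n_t = 0`. A
#' protein with no annotation yields `(0, 0)`.
#'
#' When `protein_id` is supplied, a leakage guard rejects scoring a protein
#' that contributed to the supplied statistics, so cross-validation folds
#' cannot silently leak.
#'
#' @param protein_terms Direct GO annotations of the protein (possibly
#'   empty).
#' @param stats A `go_term_stats` fitted on training data.
#' @param graph A `go_graph`.
#' @param protein_id Optional id for the leakage guard.
#' @param guard If `TRUE` (default) and `protein_id` is given, refuse to
#'   score proteins in the statistics' training set.
#' @return Named numeric vector `c(go_score, n_terms)` with `n_terms` the raw
#'   closure size (scale with [scale_count()] before classifier input).
#' @export
go_features <- function(protein_terms, stats, graph, protein_id = NULL,
                        guard = TRUE) {
  if (!is.null(protein_id) && guard && protein_id %in% stats$proteins) {
    abort(sprintf(
      "Leakage guard: protein '%s' contributed to these GO term statistics (fold %s).",
      protein_id, as.character(stats$fold)),
      class = "sappred_leakage_error")
  }
  cl <- ancestor_closure(graph, protein_terms)
  if (!length(cl)) return(c(go_score = 0, n_terms = 0))
  idx <- match(cl, stats$counts$term)
  d <- ifelse(is.na(idx), 0, stats$counts$d[idx])
  n <- ifelse(is.na(idx), 0, stats$counts$n[idx])
  pi <- stats$pseudocount
  score <- sum(log2(((d + pi) / (stats$d_tot + 2 * pi)) /
                      ((n + pi) / (stats$n_tot + 2 * pi))))
  c(go_score = score, n_terms = length(cl))
}
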