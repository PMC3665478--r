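# OBO 1.2 ontology input/output and the go_graph container.
# No installed R package reads OBO, so the (line-oriented, simple) stanza
# format is parsed here directly.

new_go_graph <- function(terms, edges) {
  stopifnot(all(c("id", "name", "namespace", "obsolete") %in% names(terms)),
            all(c("child", "parent", "relation") %in% names(edges)))
  unknown <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(unknown)) {
    abort(sprintf("Ontology edges reference unknown term(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "sappred_integrity_error")
  }
  g <- structure(list(terms = as_tibble(terms), edges = as_tibble(edges)),
                 class = "go_graph")
  assert_acyclic(g)
  g
}

# Kahn's algorithm; cycles over is_a/part_of make ancestor closure undefined.
assert_acyclic <- function(graph) {
  ids <- graph$terms$id
  indeg <- table(factor(graph$edges$parent, levels = ids))
  indeg <- setNames(as.integer(indeg), ids)
  children_of <- split(graph$edges$parent, graph$edges$child)
  queue <- names(indeg)[indeg == 0]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (p in children_of[[v]] %||% character()) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (seen < length(ids)) {
    abort("Ontology graph contains a cycle over is_a/part_of edges.",
          class = "sappred_integrity_error")
  }
  invisible(TRUE)
}

#' @export
print.go_graph <- function(x, ...) {
  cat(sprintf("<go_graph> %d terms (%d obsolete), %d edges\n",
              nrow(x$terms), sum(x$terms$obsolete), nrow(x$edges)))
  invisible(x)
}

#' Read an OBO 1.2 ontology
#'
#' Parses `[Term]` stanzas into a directed acyclic graph over `is_a` and
#' `part_of` (from `relationship:` lines) edges. Obsolete terms are kept in
#' the term table with a flag and excluded from ancestor closures by default.
#' A cyclic graph raises an integrity error.
#'
#' @param source Path to an OBO file, or a character vector of lines.
#' @return A `go_graph`: list of tibbles `terms` (`id`, `name`, `namespace`,
#'   `obsolete`) and `edges` (`child`, `parent`, `relation`).
#' @export
read_obo <- function(source) {
  lines <- if (length(source) == 1 && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- trimws(lines)
  stanza_starts <- which(lines == "[Term]")
  terms <- list(); edges <- list()
  bounds <- c(grep("^\\[.*\\]$", lines), length(lines) + 1L)
  for (s in stanza_starts) {
    end <- min(bounds[bounds > s]) - 1L
    body <- lines[seq(s + 1L, end)]
    field <- function(tag) sub(paste0("^", tag, ":\\s*"), "",
                               grep(paste0("^", tag, ":"), body, value = TRUE))
    id <- field("id")
    if (!length(id)) next
    id <- strip_obo_comment(id[[1]])
    isa <- strip_obo_comment(field("is_a"))
    rel <- field("relationship")
    partof <- sub("^part_of\\s+", "",
                  grep("^part_of\\s", strip_obo_comment(rel), value = TRUE))
    first_or_na <- function(x) if (length(x)) x[[1]] else NA_character_
    terms[[length(terms) + 1L]] <- tibble(
      id = id,
      name = first_or_na(field("name")),
      namespace = first_or_na(field("namespace")),
      obsolete = any(field("is_obsolete") == "true")
    )
    if (length(isa)) {
      edges[[length(edges) + 1L]] <- tibble(child = id, parent = isa,
                                            relation = "is_a")
    }
    if (length(partof)) {
      edges[[length(edges) + 1L]] <- tibble(child = id, parent = partof,
                                            relation = "part_of")
    }
  }
  terms <- if (length(terms)) bind_rows(terms) else {
    tibble(id = character(), name = character(), namespace = character(),
           obsolete = logical())
  }
  edges <- if (length(edges)) bind_rows(edges) else {
    tibble(child = character(), parent = character(), relation = character())
  }
  new_go_graph(distinct(terms, .data$id, .keep_all = TRUE), distinct(edges))
}

strip_obo_comment <- function(x) trimws(sub("\\s*!.*$", "", x))

#' Write a `go_graph` to OBO 1.2 text
#'
#' @param graph A `go_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(graph$terms))) {
    t <- graph$terms[i, ]
    e <- filter(graph$edges, .data$child == t$id)
    isa <- e$parent[e$relation == "is_a"]
    partof <- e$parent[e$relation == "part_of"]
    writeLines(c(
      "[Term]",
      paste0("id: ", t$id),
      if (!is.na(t$name)) paste0("name: ", t$name),
      if (!is.na(t$namespace)) paste0("namespace: ", t$namespace),
      if (t$obsolete) "is_obsolete: true",
      if (length(isa)) paste0("is_a: ", isa),
      if (length(partof)) paste0("relationship: part_of ", partof),
      ""
    ), con)
  }
  invisible(path)
}

#' Read protein GO annotations
#'
#' Two-column tab-separated format: protein id, GO term id; one direct
#' annotation per line. Duplicate (protein, term) pairs collapse to one.
#'
#' @param source Path or character vector of lines.
#' @return Tibble with columns `protein_id`, `term`.
#' @export
read_annotations <- function(source) {
  lines <- if (length(source) == 1 && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else source
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(tibble(protein_id = character(), term = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(parts, length, integer(1)) < 2)) {
    abort("Annotation lines must be tab-separated: protein_id<TAB>term.",
          class = "sappred_format_error")
  }
  distinct(tibble(protein_id = vapply(parts, `[[`, character(1), 1),
                  term = vapply(parts, `[[`, character(1), 2)))
}
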