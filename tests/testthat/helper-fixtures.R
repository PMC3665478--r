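# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately naive (brute-force tallies, pair counting,
# exhaustive reachability) and never call the code paths they check.

# -- independent AUC oracle: Mann-Whitney pair counting, ties as 1/2 --------
auc_pair_count <- function(scores, labels) {
  d <- scores[labels == "Disease"]
  n <- scores[labels == "Neutral"]
  total <- 0
  for (x in d) for (y in n) {
    total <- total + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  total / (length(d) * length(n))
}

# -- independent confusion tally -------------------------------------------
confusion_brute <- function(o_d, labels, thr = 0.5) {
  pred <- ifelse(o_d > thr, "Disease", "Neutral")
  list(tp = sum(pred == "Disease" & labels == "Disease"),
       tn = sum(pred == "Neutral" & labels == "Neutral"),
       fn = sum(pred == "Neutral" & labels == "Disease"),
       fp = sum(pred == "Disease" & labels == "Neutral"))
}

# -- brute-force DAG reachability (via igraph, independent of the package) --
reachable_ancestors <- function(graph, terms) {
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("child", "parent")], directed = TRUE,
    vertices = graph$terms$id)
  out <- character()
  for (t in terms) {
    out <- union(out, names(igraph::subcomponent(g, t, mode = "out")))
  }
  sort(setdiff(out, graph$terms$id[graph$terms$obsolete]))
}

# -- tiny hand-checkable inputs --------------------------------------------
toy_proteins <- function() {
  tibble::tibble(id = c("P1", "P2"),
                 sequence = c("ACDEFGHIKL", "MNPQRSTVWY"))
}

toy_obo_lines <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root", "namespace: molecular_function", "",
    "[Term]", "id: GO:0000002", "name: mid", "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: leaf", "is_a: GO:0000002", "",
    "[Term]", "id: GO:0000004", "name: old", "is_obsolete: true", "")
}

toy_pdb_lines <- function() {
  c(sprintf("ATOM  %5d  CA  %s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            1:3, c("ALA", "VAL", "GLY"), 1:3,
            c(0, 3.8, 7.6), c(0, 0, 0), c(0, 0, 0), 1, 0),
    "END")
}

# a random rigid motion for invariance probes
random_rigid_motion <- function() {
  m <- matrix(rnorm(9), 3)
  qr_ <- qr(m)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, 0, 20))
}

apply_rigid_motion <- function(model, motion) {
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(motion$R)
  a$x <- xyz[, 1] + motion$t[1]
  a$y <- xyz[, 2] + motion$t[2]
  a$z <- xyz[, 3] + motion$t[3]
  sappred:::new_structure_model(a)
}

# small labelled dataset on a star-shaped annotation graph, used by the GO
# scoring tests; counts are re-derived by hand in the tests
go_fixture <- function() {
  graph <- read_obo(c(
    "[Term]", "id: t1", "",
    "[Term]", "id: t2", "is_a: t1", "",
    "[Term]", "id: t3", "is_a: t2", "",
    "[Term]", "id: t4", "is_a: t1", ""))
  annotations <- tibble::tibble(
    protein_id = c("A", "B", "C"),
    term = c("t3", "t4", "t2"))
  train <- tibble::tibble(
    protein_id = c("A", "A", "A", "B", "B", "B", "B", "C", "C", "C"),
    wt = "A", pos = 1:10, mut = "V",
    label = c("Disease", "Disease", "Neutral", "Neutral", "Neutral",
              "Neutral", "Disease", "Disease", "Disease", "Neutral"))
  list(graph = graph, annotations = annotations, train = train)
}
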