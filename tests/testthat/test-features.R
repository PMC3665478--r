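test_that("the mutation block places -1 at wild-type and +1 at mutant", {
  b <- encode_mutation("A", "V")
  expect_equal(unname(b[["A"]]), -1)
  expect_equal(unname(b[["V"]]), 1)
  expect_equal(sum(b != 0), 2)
  expect_equal(sum(b), 0)
  expect_error(encode_mutation("A", "A"), class = "sappred_encoding_error")
  expect_error(encode_mutation("X", "V"), class = "sappred_encoding_error")
  # any valid pair sums to zero
  set.seed(2)
  for (i in 1:10) {
    pair <- sample(aa_alphabet(), 2)
    expect_equal(sum(encode_mutation(pair[1], pair[2])), 0)
  }
})

test_that("the sequence window is centred, truncated and normalised", {
  homo <- paste(rep("A", 19), collapse = "")
  w <- sequence_environment(homo, 10)
  expect_equal(unname(w[["A"]]), 1)
  expect_equal(sum(w), 1)

  # truncated terminus: 10 distinct residues at frequency 0.1 each
  w2 <- sequence_environment("ACDEFGHIKL", 1)
  expect_equal(sum(w2), 1)
  expect_equal(unname(w2[c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")]),
               rep(0.1, 10))

  # ambiguity codes drop from numerator and denominator
  w3 <- sequence_environment("AXAXA", 3)
  expect_equal(unname(w3[["A"]]), 1)

  expect_error(sequence_environment("ACDEF", 2, window = 4),
               class = "sappred_config_error")

  # normalisation holds for random windows
  set.seed(31)
  for (i in 1:10) {
    s <- paste(sample(aa_alphabet(), 40, replace = TRUE), collapse = "")
    expect_equal(sum(sequence_environment(s, sample(40, 1))), 1)
  }
})

test_that("the external-predictor block passes through or falls back to (0.5, 0, 0, 0)", {
  expect_equal(unname(panther_features(NULL)), c(0.5, 0, 0, 0))
  expect_equal(length(panther_features(NULL)), 4)
  rec <- tibble::tibble(p_deleterious = 0.9, f_wt = 0.6, f_mut = 0.1,
                        n_counts = 25)
  got <- panther_features(rec)
  expect_equal(unname(got), c(0.9, 0.6, 0.1, 25 / 125))
  expect_error(panther_features(tibble::tibble(p_deleterious = 1.4, f_wt = 0,
                                               f_mut = 0, n_counts = 1)),
               class = "sappred_validation_error")
})

test_that("presets assemble to their exact lengths with stamped layout tags", {
  blocks <- list(
    mutation = encode_mutation("A", "V"),
    seq_env = sequence_environment("ACDEFGHIKL", 5),
    struct_env = setNames(c(1, rep(0, 19)), aa_alphabet()),
    rsa = 0.3,
    profile = profile_features(build_profile("ACDEFGHIKL", NULL),
                               list(wt = "F", pos = 5L, mut = "W")),
    panther = panther_features(NULL),
    go = c(go_score = 0, n_terms = 0))
  vseq <- do.call(assemble_features, c(list(preset = "snpsgo_seq"),
                                       blocks[c("mutation", "seq_env",
                                                "profile", "panther", "go")]))
  expect_length(vseq, 51)
  expect_equal(attr(vseq, "layout_tag"), "snpsgo_seq_v1")
  v3d <- do.call(assemble_features, c(list(preset = "snpsgo_3d"),
                                      blocks[c("mutation", "struct_env", "rsa",
                                               "profile", "panther", "go")]))
  expect_length(v3d, 52)
  expect_equal(attr(v3d, "layout_tag"), "snpsgo_3d_v1")
  vp <- do.call(assemble_features, c(list(preset = "profile_seq"),
                                     blocks[c("mutation", "seq_env",
                                              "profile")]))
  expect_length(vp, 45)
  expect_length(do.call(assemble_features,
                        c(list(preset = "profile_3d"),
                          blocks[c("mutation", "struct_env", "rsa",
                                   "profile")])), 46)

  # missing and mis-sized blocks are named in the error
  expect_error(assemble_features("snpsgo_seq", mutation = blocks$mutation),
               "seq_env", class = "sappred_assembly_error")
  expect_error(do.call(assemble_features,
                       c(list(preset = "snpsgo_seq"),
                         modifyList(blocks[c("mutation", "seq_env", "profile",
                                             "panther", "go")],
                                    list(panther = c(1, 2, 3))))),
               "panther", class = "sappred_assembly_error")

  # idempotence
  expect_identical(vseq, do.call(assemble_features,
                                 c(list(preset = "snpsgo_seq"),
                                   blocks[c("mutation", "seq_env", "profile",
                                            "panther", "go")])))
})

test_that("full-preset vectors stay in [-1, 1] and blocks are isolated", {
  set.seed(17)
  ds <- generate_synthetic(synth_config(seed = 23, n_proteins = 6,
                                        variants_per_protein = 6))
  stats <- fit_term_stats(ds$variants, ds$annotations, ds$graph)
  x <- build_feature_matrix(ds$variants, ds, "snpsgo_seq", go_stats = stats)
  expect_equal(dim(x), c(36, 51))
  no_go <- x[, setdiff(seq_len(51), 50)]  # all but the raw GO score column
  expect_true(all(no_go >= -1 & no_go <= 1))
  x3 <- build_feature_matrix(ds$variants, ds, "snpsgo_3d", go_stats = stats)
  expect_equal(dim(x3), c(36, 52))

  # block isolation: removing the GO statistics changes only the last 2 cols
  x0 <- build_feature_matrix(ds$variants, ds, "snpsgo_seq", go_stats = NULL)
  expect_equal(x0[, 1:49], x[, 1:49])
  expect_false(isTRUE(all.equal(x0[, 50:51], x[, 50:51])))
  # and dropping the external predictor changes only its 4 columns
  ds2 <- ds; ds2$panther <- NULL
  xp <- build_feature_matrix(ds2$variants, ds2, "snpsgo_seq", go_stats = stats)
  expect_equal(xp[, c(1:45, 50:51)], x[, c(1:45, 50:51)])
  expect_false(isTRUE(all.equal(xp[, 46:49], x[, 46:49])))
})
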