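test_that("confusion counts satisfy the class-symmetry identities", {
  o_d <- c(0.9, 0.8, 0.7, 0.6, 0.2, 0.3, 0.1)
  labels <- c(rep("Disease", 4), rep("Neutral", 3))
  cc <- confusion_counts(o_d, labels)
  d <- as.list(cc[cc$class == "Disease", ])
  n <- as.list(cc[cc$class == "Neutral", ])
  expect_equal(d$p, 4); expect_equal(d$n, 3)
  expect_equal(d$u, 0); expect_equal(d$o, 0)
  expect_equal(d$p, n$n); expect_equal(d$o, n$u)
  expect_equal(d$u, n$o); expect_equal(d$n, n$p)
  # all wrong
  ccw <- confusion_counts(1 - o_d, labels)
  dw <- as.list(ccw[ccw$class == "Disease", ])
  expect_equal(c(dw$p, dw$n), c(0, 0))
  expect_error(confusion_counts(o_d, labels[-1]),
               class = "sappred_input_error")
})

test_that("confusion, accuracy, sensitivity and precision match brute-force tallies", {
  set.seed(55)
  for (i in 1:10) {
    n <- 50
    o_d <- runif(n)
    labels <- sample(c("Disease", "Neutral"), n, replace = TRUE)
    cc <- confusion_counts(o_d, labels)
    or <- confusion_brute(o_d, labels)
    d <- as.list(cc[cc$class == "Disease", ])
    expect_equal(d$p, or$tp); expect_equal(d$n, or$tn)
    expect_equal(d$u, or$fn); expect_equal(d$o, or$fp)
    expect_equal(q_tot(cc), (or$tp + or$tn) / n)
    if (or$tp + or$fn > 0) {
      expect_equal(sensitivity(cc, "Disease"), or$tp / (or$tp + or$fn))
    }
    if (or$tp + or$fp > 0) {
      expect_equal(precision(cc, "Disease"), or$tp / (or$tp + or$fp))
    }
    # q_tot recoverable through the Neutral-class identities too
    nn <- as.list(cc[cc$class == "Neutral", ])
    expect_equal(q_tot(cc), (nn$p + nn$n) / n)
  }
})

test_that("undefined metrics raise errors distinct from zero", {
  cc <- confusion_counts(c(0.9, 0.8), c("Disease", "Disease"))
  expect_error(sensitivity(cc, "Neutral"), class = "sappred_metric_error")
  cc2 <- confusion_counts(c(0.1, 0.2), c("Disease", "Disease"))
  expect_error(precision(cc2, "Disease"), class = "sappred_metric_error")
  expect_error(q_tot(confusion_counts(numeric(), character())),
               class = "sappred_metric_error")
})

test_that("the MCC formula matches hand evaluation and its conventions", {
  # hand case: p=4, n=3, u=1, o=2 -> (12 - 2) / sqrt(5*6*4*5)
  o_d <- c(0.9, 0.9, 0.9, 0.9, 0.1, 0.9, 0.9, 0.1, 0.1, 0.1)
  labels <- c(rep("Disease", 5), rep("Neutral", 5))
  cc <- confusion_counts(o_d, labels)
  d <- as.list(cc[cc$class == "Disease", ])
  expect_equal(c(d$p, d$n, d$u, d$o), c(4, 3, 1, 2))
  expect_equal(mcc(cc), 10 / sqrt(600))
  # class symmetry
  expect_equal(mcc(cc, "Disease"), mcc(cc, "Neutral"))
  # perfect predictions
  expect_equal(mcc(confusion_counts(c(0.9, 0.1),
                                    c("Disease", "Neutral"))), 1)
  # zero marginal -> defined as 0
  expect_equal(mcc(confusion_counts(c(0.9, 0.8),
                                    c("Disease", "Disease"))), 0)
})

test_that("the trapezoid AUC equals the tie-aware pair-count statistic", {
  skip_if_not_installed("pROC")
  # 8-point hand fixture with a tie across classes
  scores <- c(0.9, 0.8, 0.7, 0.5, 0.5, 0.4, 0.2, 0.1)
  labels <- c("Disease", "Disease", "Neutral", "Disease", "Neutral",
              "Disease", "Neutral", "Neutral")
  r <- roc_curve(scores, labels)
  expect_equal(r$auc, auc_pair_count(scores, labels), tolerance = 1e-12)
  expect_equal(r$auc, as.numeric(pROC::auc(pROC::roc(
    labels, scores, levels = c("Neutral", "Disease"), direction = "<",
    quiet = TRUE))))
  # perfectly separated scores
  expect_equal(roc_curve(c(0.9, 0.8, 0.2, 0.1),
                         c("Disease", "Disease", "Neutral", "Neutral"))$auc, 1)
  expect_error(roc_curve(c(0.5, 0.6), c("Disease", "Disease")),
               class = "sappred_metric_error")
  # random fixtures, including heavy ties
  set.seed(66)
  for (i in 1:10) {
    s <- sample(seq(0, 1, 0.25), 40, replace = TRUE)
    l <- sample(c("Disease", "Neutral"), 40, replace = TRUE,
                prob = c(0.6, 0.4))
    if (length(unique(l)) < 2) next
    expect_equal(roc_curve(s, l)$auc, auc_pair_count(s, l),
                 tolerance = 1e-12)
  }
})

test_that("labels independent of scores give a null AUC near one half", {
  set.seed(77)
  n <- 2000
  s <- runif(n)
  l <- sample(c("Disease", "Neutral"), n, replace = TRUE)
  expect_lt(abs(roc_curve(s, l)$auc - 0.5), 0.03)
})

test_that("RI stratification reproduces the unstratified report at cutoff 0", {
  set.seed(88)
  n <- 400
  o_d <- runif(n)
  labels <- ifelse(runif(n) < o_d, "Disease", "Neutral")  # calibrated
  preds <- tibble::tibble(o_d = o_d, ri = reliability_index(o_d))
  strata <- ri_stratified(preds, labels, ri_min = 0:9)
  expect_equal(strata$coverage[1], 1)
  expect_equal(strata$q_tot[1], metrics_report(o_d, labels)$q_tot)
  expect_true(all(diff(strata$coverage) <= 0))
  # calibrated scores: accuracy non-decreasing in the cutoff
  expect_true(all(diff(strata$q_tot) >= -1e-9))
  # cutoff 10 keeps only |o_d - 0.5| = 0.5 predictions
  certain <- tibble::tibble(o_d = c(0, 1, 0.7), ri = reliability_index(c(0, 1, 0.7)))
  s10 <- ri_stratified(certain, c("Neutral", "Disease", "Disease"),
                       ri_min = 10)
  expect_equal(s10$coverage, 2 / 3)
  expect_error(ri_stratified(preds[preds$ri < 9, ], labels[preds$ri < 9],
                             ri_min = 10),
               class = "sappred_metric_error")
})

test_that("cluster folds never split a cluster and balance variant counts", {
  clusters <- tibble::tibble(protein_id = paste0("P", 1:40),
                             cluster_id = paste0("C", 1:40))
  variants <- tibble::tibble(protein_id = rep(paste0("P", 1:40), each = 3),
                             label = "Disease")
  f <- cluster_folds(clusters, variants, k = 20, seed = 1)
  expect_equal(sort(unique(f$fold)), 1:20)
  expect_true(all(table(f$fold) == 2))  # uniform weights -> 2 proteins each

  # multi-protein clusters stay together
  cl2 <- tibble::tibble(protein_id = paste0("P", 1:40),
                        cluster_id = paste0("C", rep(1:10, each = 4)))
  f2 <- cluster_folds(cl2, variants, k = 5, seed = 3)
  spans <- tapply(f2$fold, f2$cluster_id, function(x) length(unique(x)))
  expect_true(all(spans == 1))

  # deterministic given the seed, invariant to input row order
  f3 <- cluster_folds(cl2[sample(40), ], variants, k = 5, seed = 3)
  expect_equal(dplyr::arrange(f3, protein_id), dplyr::arrange(f2, protein_id))

  expect_error(cluster_folds(cl2, variants, k = 11),
               class = "sappred_input_error")
  expect_error(cluster_folds(cl2, tibble::tibble(protein_id = "P99",
                                                 label = "Disease"), k = 2),
               class = "sappred_input_error")
})

test_that("blind evaluation excludes cluster-sharing test proteins", {
  set.seed(101)
  ds <- generate_synthetic(synth_config(seed = 31, n_proteins = 10,
                                        variants_per_protein = 8,
                                        b_ci = 3, b_panther = 2.5,
                                        pair_fraction = 0))
  train <- ds$variants[ds$variants$protein_id %in% ds$proteins$id[1:6], ]
  test <- ds$variants[ds$variants$protein_id %in% ds$proteins$id[7:10], ]
  model <- train_pipeline(train, ds, "snpsgo_seq", seed = 1)
  x_test <- build_feature_matrix(test, ds, "snpsgo_seq",
                                 go_stats = model$go_stats)
  # disjoint clusters: everything scored
  be <- blind_eval(model, x_test, test, ds$clusters)
  expect_equal(nrow(be$excluded), 0)
  expect_equal(be$report$n_total, nrow(test))
  expect_lte(be$report$n_correct, be$report$n_total)

  # force a shared cluster: that protein's variants are excluded and logged
  cl <- ds$clusters
  cl$cluster_id[cl$protein_id == ds$proteins$id[7]] <-
    cl$cluster_id[cl$protein_id == ds$proteins$id[1]]
  be2 <- blind_eval(model, x_test, test, cl)
  expect_equal(unique(be2$excluded$protein_id), ds$proteins$id[7])
  expect_equal(be2$report$n_total, nrow(test) - nrow(be2$excluded))

  # total exclusion is an error
  cl3 <- ds$clusters
  cl3$cluster_id <- cl3$cluster_id[1]
  expect_error(blind_eval(model, x_test, test, cl3),
               class = "sappred_metric_error")
})
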