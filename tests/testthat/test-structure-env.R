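test_that("variants map onto structure residues with type checking", {
  m <- read_structure(toy_pdb_lines())  # ALA VAL GLY at 1..3
  r <- map_variant_to_structure(list(wt = "V", pos = 2L), m, "A")
  expect_equal(r$resno, 2L)
  expect_error(map_variant_to_structure(list(wt = "K", pos = 2L), m, "A"),
               "mismatch", class = "sappred_mapping_error")
  expect_error(map_variant_to_structure(list(wt = "V", pos = 2L), m, "B"),
               "available chains", class = "sappred_lookup_error")
  # explicit mapping table reroutes positions
  m2 <- m
  m2$atoms$resno <- m2$atoms$resno + 1050L
  r2 <- map_variant_to_structure(list(wt = "V", pos = 2L), m2, "A",
                                 mapping = tibble::tibble(pos = 2L,
                                                          resno = 1052L))
  expect_equal(r2$resno, 1052L)
})

test_that("the 6 A sphere uses a closed C-alpha cutoff excluding the centre", {
  mk <- function(xs, types) {
    sappred:::new_structure_model(tibble::tibble(
      chain = "A", resno = seq_along(xs), insert = "",
      resid = types, elety = "CA", x = xs, y = 0, z = 0))
  }
  m <- mk(c(0, 5, 7), c("ALA", "VAL", "LEU"))
  center <- structure_residues(m)[1, ]
  env <- structural_environment(m, center)
  expect_equal(unname(env[["V"]]), 1)  # 5 A in, 7 A out
  expect_equal(sum(env), 1)
  expect_equal(attr(env, "n_neighbors"), 1L)
  # ties at exactly the radius are included
  m6 <- mk(c(0, 6), c("ALA", "TRP"))
  env6 <- structural_environment(m6, structure_residues(m6)[1, ])
  expect_equal(unname(env6[["W"]]), 1)
  # isolated residue: all-zero composition
  mi <- mk(c(0, 50), c("ALA", "TRP"))
  envi <- structural_environment(mi, structure_residues(mi)[1, ])
  expect_equal(sum(envi), 0)
  expect_equal(attr(envi, "n_neighbors"), 0L)
})

test_that("environment composition equals an exhaustive distance scan and is rigid-motion invariant", {
  set.seed(21)
  for (rep in 1:20) {
    m <- toy_structure(30)
    res <- structure_residues(m)
    center <- res[sample(nrow(res), 1), ]
    env <- structural_environment(m, center)
    # brute-force all-pairs oracle
    d <- sqrt((res$ca_x - center$ca_x)^2 + (res$ca_y - center$ca_y)^2 +
                (res$ca_z - center$ca_z)^2)
    nb_aa <- res$aa[d <= 6 & res$resno != center$resno]
    oracle <- table(factor(nb_aa, levels = aa_alphabet()))
    oracle <- as.numeric(oracle) / max(sum(oracle), 1)
    expect_equal(as.numeric(env), oracle, tolerance = 1e-12)
    # rigid motion leaves the composition unchanged
    moved <- apply_rigid_motion(m, random_rigid_motion())
    res_m <- structure_residues(moved)
    center_m <- res_m[res_m$resno == center$resno, ]
    expect_equal(as.numeric(structural_environment(moved, center_m)),
                 as.numeric(env), tolerance = 1e-9)
  }
})

test_that("neighbour count is non-decreasing in the radius", {
  set.seed(4)
  m <- toy_structure(40)
  center <- structure_residues(m)[20, ]
  counts <- vapply(c(4, 6, 8, 10, 14), function(r)
    attr(structural_environment(m, center, radius = r), "n_neighbors"),
    integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("relative accessibility normalises and clamps against the reference table", {
  res <- tibble::tibble(chain = "A", resno = 1L, aa = "A")
  mx <- max_asa_reference()[["A"]]
  acc <- tibble::tibble(chain = "A", resno = 1L, acc = mx)
  expect_equal(relative_accessibility(acc, res), 1)
  acc$acc <- 0
  expect_equal(relative_accessibility(acc, res), 0)
  acc$acc <- mx * 1.4  # termini routinely exceed the reference
  expect_equal(relative_accessibility(acc, res), 1)
  acc$acc <- mx / 2
  expect_equal(relative_accessibility(acc, res), 0.5)
  # missing residue: error by default, 0.5 imputation on request
  none <- tibble::tibble(chain = "A", resno = 9L, acc = 10)
  expect_error(relative_accessibility(none, res),
               class = "sappred_lookup_error")
  expect_warning(rsa <- relative_accessibility(none, res,
                                               missing_policy = "impute"))
  expect_equal(rsa, 0.5)
})

test_that("the rolling-probe fallback produces sane, burial-ordered areas", {
  # a central atom caged by six octahedral neighbours must be far less
  # exposed than the cage atoms themselves
  pts <- rbind(c(0, 0, 0),
               c(-3.8, 0, 0), c(3.8, 0, 0), c(0, -3.8, 0), c(0, 3.8, 0),
               c(0, 0, -3.8), c(0, 0, 3.8))
  m <- sappred:::new_structure_model(tibble::tibble(
    chain = "A", resno = seq_len(nrow(pts)), insert = "", resid = "ALA",
    elety = "CA", x = pts[, 1], y = pts[, 2], z = pts[, 3]))
  acc <- compute_accessibility(m)
  expect_true(all(acc$acc >= 0))
  expect_lt(acc$acc[acc$resno == 1], min(acc$acc[acc$resno != 1]))
  # an isolated atom exposes its whole solvent-expanded sphere
  lone <- sappred:::new_structure_model(tibble::tibble(
    chain = "A", resno = 1L, insert = "", resid = "GLY", elety = "CA",
    x = 0, y = 0, z = 0))
  a <- compute_accessibility(lone)$acc
  expect_equal(a, 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-6)
})
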