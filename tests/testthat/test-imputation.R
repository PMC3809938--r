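test_that("row average equals the per-row mean oracle exactly", {
  m <- masked_matrix(rbind(c(2, NA, 4, NA, 6), c(1, 1, 1, 1, 1)))
  r <- impute_row_average(m)
  expect_equal(unname(r$values[1, c(2, 4)]), c(4, 4))
  # one observed value fills the whole row with it
  m2 <- masked_matrix(rbind(c(NA, 7, NA), c(1, 2, 3)))
  expect_equal(unname(impute_row_average(m2)$values[1, ]), c(7, 7, 7))
  # fully missing row falls back to the overall observed mean
  m3 <- masked_matrix(rbind(c(NA, NA), c(5, 10)))
  expect_message(r3 <- impute_row_average(m3), "global mean")
  expect_equal(unname(r3$values[1, ]), c(7.5, 7.5))
  expect_error(masked_matrix(matrix(NA_real_, 2, 2)), "all entries")
})

test_that("KNN imputes from hand-checkable neighbor sets", {
  X <- rbind(g1 = c(1, 2, 3), g2 = c(1, 2, NA), g3 = c(10, 10, 10))
  r <- impute_knn(masked_matrix(X), k = 1)
  expect_equal(unname(r$values["g2", 3]), 3)   # g1 at distance 0
  # duplicate row: zero distance regardless of k order
  X2 <- rbind(c(5, 6, 7, 8), c(5, 6, 7, NA), c(50, 60, 70, 80))
  expect_equal(unname(impute_knn(masked_matrix(X2), 1)$values[2, 4]), 8)
  # k = 2 averages the two nearest candidates' values (4 and 6 -> 5)
  X3 <- rbind(c(1, 2, NA), c(1.1, 2.1, 4), c(0.9, 1.9, 6), c(90, 95, 99))
  expect_equal(unname(impute_knn(masked_matrix(X3), 2)$values[1, 3]), 5)
  # single-row matrix warns and falls back to the row average
  expect_warning(r1 <- impute_knn(masked_matrix(matrix(c(2, NA, 4), 1)), 1),
                 "single row")
  expect_equal(unname(r1$values[1, 2]), 3)
  # pearson distance uses 1 - |r|
  X4 <- rbind(c(1, 2, 3, NA), c(10, 20, 30, 40), c(3, 3, 1, 100))
  expect_equal(unname(impute_knn(masked_matrix(X4), 1, "pearson")$values[1, 4]),
               40)
})

test_that("SVD imputation recovers model-matched data and obeys its contract", {
  m <- rank1_masked(G = 30, S = 5, seed = 3)
  r <- impute_svd(m, 1, threshold = 1e-10, max_iter = 500)
  expect_lt(max_rel_err(r, m), 1e-6)
  expect_true(r$converged)
  # no missing entries: unchanged, zero iterations
  full <- matrix(runif(20, 1, 9), 4, 5)
  r0 <- impute_svd(masked_matrix(full), 2)
  expect_identical(r0$values, full)
  expect_identical(r0$iterations, 0L)
  # the stopping rule is on the total absolute change
  r2 <- impute_svd(m, 1, threshold = 1e6, max_iter = 50)
  expect_identical(r2$iterations, 1L)
  expect_error(impute_svd(m, 5), "n_components")
})

test_that("LLS solves the neighbor regression exactly in constructed cases", {
  # single neighbor, coefficient 1
  m <- masked_matrix(rbind(c(1, 2, 3), c(1, 2, NA)))
  expect_equal(unname(impute_lls(m, 1)$values[2, 3]), 3)
  # target equals a linear combination of two complete neighbors
  n1 <- c(2, 5, 1, 7, 3); n2 <- c(4, 1, 6, 2, 8)
  tgt <- 0.3 * n1 + 0.6 * n2
  vals <- rbind(n1, n2, tgt, c(9, 9, 9, 9, 9))
  vals[3, 4:5] <- NA
  r <- impute_lls(masked_matrix(vals, check_positive = FALSE), 2)
  expect_equal(unname(r$values[3, 4:5]), (0.3 * n1 + 0.6 * n2)[4:5],
               tolerance = 1e-9)
  # anticorrelated neighbor enters with a negative coefficient
  va <- rbind(c(1, 2, 3), c(-2, -4, -6))
  va[2, 3] <- NA
  ra <- impute_lls(masked_matrix(va, check_positive = FALSE), 1)
  expect_equal(unname(ra$values[2, 3]), -6, tolerance = 1e-9)
  # the k < S restriction is enforced with the restriction cited
  expect_error(impute_lls(masked_matrix(rank1_masked(10, 5)$values), 5),
               "less than the number of replicates")
})

test_that("LSA combines gene- and array-based estimates sensibly", {
  # closed-form mixing weight
  expect_equal(imputebench:::optimal_mix_weight(c(2, 0), c(0, 2), c(1, 1)), 0.5)
  expect_equal(imputebench:::optimal_mix_weight(c(5, 5), c(5, 5), c(1, 1)), 0.5)
  expect_equal(imputebench:::optimal_mix_weight(c(1, 1), c(9, 9), c(1, 1)), 1)
  # duplicated rows make the gene-based estimate (and any mix) exact
  base <- c(3, 8, 2, 9, 4)
  vals <- rbind(base, base, base, base * 2, base * 5, c(7, 1, 8, 2, 6))
  vals[1, 3] <- NA
  r <- suppressMessages(impute_lsa(
    masked_matrix(vals, check_positive = FALSE),
    method_config("LSA", lsa_n_genes = 3, seed = 4)))
  expect_equal(unname(r$values[1, 3]), 2, tolerance = 1e-6)
  # realistic matrix: complete output preserving observations
  em <- small_expr_matrix(seed = 21)
  mm <- delete_entries(em, 0.05, seed = 6)
  rl <- suppressMessages(impute_lsa(mm, method_config("LSA", seed = 2)))
  expect_false(anyNA(rl$values))
  expect_equal(rl$values[!mm$mask], em[!mm$mask])
})

test_that("BPCA recovers near-low-rank data and is seed-deterministic", {
  m <- rank1_masked(G = 40, S = 5, seed = 13)
  r <- impute_bpca(m, max_iter = 500, tol = 1e-7, seed = 1)
  expect_lt(max_rel_err(r, m), 1e-3)
  # identical seed, identical output; different seed may differ
  r2 <- impute_bpca(m, max_iter = 500, tol = 1e-7, seed = 1)
  expect_identical(r$values, r2$values)
  # no missing entries returned unchanged
  full <- matrix(runif(30, 1, 9), 6, 5)
  expect_identical(impute_bpca(masked_matrix(full))$values, full)
  expect_error(impute_bpca(m, n_components = 5), "n_components")
})

test_that("NIPALS reconstructs rank-deficient data from observed cells only", {
  m <- rank1_masked(G = 30, S = 5, seed = 17)
  expect_lt(max_rel_err(impute_nipals(m, 1), m), 1e-6)
  # full-rank reconstruction identity on complete centered data
  set.seed(3)
  x <- matrix(rnorm(24), 6, 4)
  x[2, 3] <- NA
  # late components iterate on a numerically zero residual and may stop at
  # the iteration cap with a warning, per the degenerate-case contract
  r <- suppressWarnings(impute_nipals(masked_matrix(x, check_positive = FALSE),
                                      4, center = TRUE))
  expect_equal(r$values[!is.na(x)], x[!is.na(x)])
  expect_false(anyNA(r$values))
})

test_that("impute() dispatch covers the ten canonical configurations", {
  meths <- table1_methods()
  expect_identical(sort(names(meths)),
                   c("BPCA", "KNN1", "KNN5", "LLS1", "LLS3", "LLS4", "LSA",
                     "NIPALS", "ROW", "SVD"))
  em <- small_expr_matrix(seed = 33)
  m <- delete_entries(em, 0.08, seed = 9)
  for (nm in names(meths)) {
    r <- suppressMessages(suppressWarnings(impute(m, meths[[nm]])))
    expect_false(anyNA(r$values), info = nm)
    expect_equal(r$values[!m$mask], em[!m$mask], info = nm)
    expect_identical(r$method, nm)
  }
  # ROW dispatch equals the direct row-average path
  expect_equal(impute(m, meths$ROW)$values, impute_row_average(m)$values)
  # invalid configurations
  expect_error(method_config("MAGIC"), "unknown")
  expect_error(method_config("KNN"), "k >= 1")
  expect_error(impute(m, method_config("LLS", k = 5)),
               "less than the number of replicates")
})

test_that("tidy and glance views of imputation results are well-formed", {
  em <- small_expr_matrix(G = 20, seed = 3)
  m <- delete_entries(em, 0.1, seed = 2)
  r <- impute_row_average(m)
  g <- glance(r)
  expect_identical(g$method, "ROW")
  expect_identical(g$n_row, 20L)
  td <- tidy(m)
  expect_equal(nrow(td), 20 * 5)
  expect_equal(sum(td$missing), sum(m$mask))
  expect_true(all(td$truth[td$missing] > 0))
})
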