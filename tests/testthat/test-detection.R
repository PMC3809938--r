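test_that("discrimination scores follow the (PM-MM)/(PM+MM) contract", {
  expect_equal(discrimination_scores(c(100, 7, 0.5), c(100, 7, 0.5)),
               c(0, 0, 0))
  expect_equal(discrimination_scores(300, 100), 0.5)
  expect_equal(discrimination_scores(100, 300), -0.5)
  s <- discrimination_scores(runif(30, 1, 1e4), runif(30, 1, 1e4))
  expect_true(all(s > -1 & s < 1))
  expect_error(discrimination_scores(c(1, 2), 1), "length")
  expect_error(discrimination_scores(c(1, -2), c(1, 2)), "positive")
})

test_that("exact signed-rank p-values match the worked cases", {
  # all three scores above tau, distinct: only the all-positive assignment
  # reaches the observed rank sum -> 1/8
  expect_equal(wilcoxon_one_sided_p(c(0.5, 0.4, 0.3), 0.015), 0.125)
  # one above, one below tau with distinct magnitudes -> 2 of 4 assignments
  expect_equal(wilcoxon_one_sided_p(c(0.015 + 0.2, 0.015 - 0.1), 0.015), 0.5)
  # with tied magnitudes the midranked exact distribution gives 3 of 4
  expect_equal(wilcoxon_one_sided_p(c(0.115, -0.085), 0.015), 0.75)
  # everything below tau: observed positive-rank sum 0, largest possible p
  expect_equal(wilcoxon_one_sided_p(seq(-0.5, -0.1, by = 0.1), 0.015), 1.0)
  # all scores exactly tau: zero differences dropped, p = 1 with a warning
  expect_warning(p <- wilcoxon_one_sided_p(rep(0.015, 4), 0.015), "tau")
  expect_equal(p, 1.0)
  expect_error(wilcoxon_one_sided_p(numeric(0)), "empty")
})

test_that("exact test equals brute-force sign enumeration for n <= 12", {
  set.seed(421)
  for (i in 1:200) {
    n <- sample(1:12, 1)
    scores <- round(rnorm(n, 0.05, 0.3), 2)   # rounding induces ties
    p_fast <- suppressWarnings(wilcoxon_one_sided_p(scores, 0.015))
    p_brute <- brute_signed_rank_p(scores, 0.015)
    expect_equal(p_fast, p_brute, tolerance = 1e-12)
  }
})

test_that("raising a PM raises its score and cannot raise the p-value", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(5:15, 1)
    pm <- runif(n, 50, 500); mm <- runif(n, 50, 500)
    j <- sample(n, 1)
    pm2 <- pm; pm2[j] <- pm[j] * 1.5
    s1 <- discrimination_scores(pm, mm)
    s2 <- discrimination_scores(pm2, mm)
    expect_gt(s2[j], s1[j])
    expect_lte(suppressWarnings(wilcoxon_one_sided_p(s2)),
               suppressWarnings(wilcoxon_one_sided_p(s1)))
  }
})

test_that("calls partition by the half-open alpha thresholds", {
  expect_error(detection_params(alpha1 = 0.06, alpha2 = 0.04), "alpha")
  cfg <- generator_config(n_probe_sets = 40, n_sites = 1, seed = 2)
  d <- generate_dataset(cfg)
  calls <- detect(d)
  expect_equal(nrow(calls), 40 * nrow(d$samples))
  expect_true(all(calls$p_value >= 0 & calls$p_value <= 1))
  expect_identical(levels(calls$call), c("Present", "Marginal", "Absent"))
  expect_identical(calls$call == "Present", calls$p_value < 0.04)
  expect_identical(calls$call == "Marginal",
                   calls$p_value >= 0.04 & calls$p_value < 0.06)
  expect_identical(calls$call == "Absent", calls$p_value >= 0.06)
})

test_that("percent present does the stated arithmetic", {
  # one array: 200 probe sets, 110 Present -> 55.0%
  mk_calls <- function(sample_id, n_present, n_total = 200) {
    tibble::tibble(
      probe_set_id = sprintf("ps%03d", seq_len(n_total)),
      sample_id = sample_id,
      p_value = c(rep(0.01, n_present), rep(0.5, n_total - n_present)),
      call = factor(c(rep("Present", n_present),
                      rep("Absent", n_total - n_present)),
                    levels = c("Present", "Marginal", "Absent"))
    )
  }
  pct <- c(50, 52, 54, 56, 58)
  calls <- dplyr::bind_rows(lapply(1:5, function(r)
    mk_calls(sprintf("a%d", r), pct[r] * 2)))
  samples <- tibble::tibble(sample_id = sprintf("a%d", 1:5), site = "site1",
                            pool = "A", replicate = 1:5)
  pp <- percent_present(calls, samples)
  expect_equal(pp$per_array$percent[pp$per_array$sample_id == "a1"], 50)
  expect_equal(pp$per_cell$mean_percent, 54.0)
  # all Present -> 100%
  calls2 <- mk_calls("b1", 200)
  pp2 <- percent_present(calls2, tibble::tibble(sample_id = "b1",
                                                site = "s", pool = "A",
                                                replicate = 1))
  expect_equal(pp2$per_array$percent, 100)
  # a sample without calls is an error
  expect_error(percent_present(calls, dplyr::bind_rows(
    samples, tibble::tibble(sample_id = "zz", site = "site1", pool = "A",
                            replicate = 6))), "zz")
})

test_that("the all-replicates filter retains exactly all-Present probe sets", {
  lv <- c("Present", "Marginal", "Absent")
  enum <- list(ps1 = "PPPPP", ps2 = "PPPPA", ps3 = "PPMPP")
  calls <- dplyr::bind_rows(lapply(names(enum), function(ps) {
    st <- strsplit(enum[[ps]], "")[[1]]
    tibble::tibble(
      probe_set_id = ps, sample_id = sprintf("a%d", 1:5),
      p_value = c(P = 0.01, M = 0.05, A = 0.5)[st],
      call = factor(c(P = "Present", M = "Marginal", A = "Absent")[st],
                    levels = lv))
  }))
  samples <- tibble::tibble(sample_id = sprintf("a%d", 1:5), site = "site1",
                            pool = "A", replicate = 1:5)
  expect_identical(filter_complete(calls, samples, "site1", "A"), "ps1")
  expect_error(filter_complete(calls, samples, "site9", "A"), "unknown")
})
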