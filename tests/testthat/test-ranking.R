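mk_reports <- function(errors_by_method, site = "site1", pool = "A",
                       sims = 1) {
  dplyr::bind_rows(lapply(seq_len(sims), function(s)
    tibble::tibble(site = site, pool = pool, sim = s,
                   method = names(errors_by_method),
                   rmse = unname(errors_by_method),
                   lrmse = unname(errors_by_method),
                   rae = unname(errors_by_method),
                   rae_l2 = unname(errors_by_method),
                   n_missing = 10L, ok = TRUE)))
}

test_that("simulation averaging is an arithmetic mean that drops flags", {
  rep <- mk_reports(c(A = 1, B = 2), sims = 2)
  rep$rmse[rep$sim == 2 & rep$method == "A"] <- 3.0
  me <- average_over_sims(rep)
  expect_equal(me$mean_error[me$method == "A" & me$metric == "rmse"], 2.0)
  expect_equal(me$n_sims[me$method == "A" & me$metric == "rmse"], 2L)
  # a flagged report is excluded, with a message
  rep$ok[rep$sim == 1 & rep$method == "B"] <- FALSE
  expect_message(me2 <- average_over_sims(rep), "excluded")
  expect_equal(me2$mean_error[me2$method == "B" & me2$metric == "rmse"], 2.0)
  expect_equal(me2$n_sims[me2$method == "B" & me2$metric == "rmse"], 1L)
})

test_that("method ranking is ascending with midranks for ties", {
  expect_equal(rank_methods(c(0.5, 1.5, 1.0)), c(1, 3, 2))
  expect_equal(rank_methods(c(1.0, 1.0, 2.0)), c(1.5, 1.5, 3))
  set.seed(31)
  for (i in 1:20) {
    v <- runif(sample(3:10, 1))
    expect_setequal(rank_methods(v), seq_along(v))
  }
  expect_error(rank_methods(5), "two methods")
  expect_error(rank_methods(c(1, NA)), "missing")
})

test_that("two-level aggregation averages sites within pools first", {
  # 2 sites x 2 pools, one method with ranks 1,2,3,4 (other method mirrors)
  errs <- tibble::tibble(
    site = rep(c("s1", "s2"), each = 2),
    pool = rep(c("A", "B"), 2),
    method = "M1",
    metric = "rmse",
    mean_error = 0, n_sims = 1L
  )
  errs2 <- errs; errs2$method <- "M2"; errs2$mean_error <- 1
  # give M1 rank 1,2,3,4 across (s1A, s1B, s2A, s2B) via per-cell error flips
  errs$mean_error <- c(0, 0, 2, 2)
  errs2$mean_error <- c(1, 1, 1, 1)
  me <- dplyr::bind_rows(errs, errs2)
  rt <- aggregate_ranks(me)
  # M1 ranks: 1, 1, 2, 2 -> pools A (1+2)/2, B (1+2)/2 -> 1.5
  expect_equal(rt$RMSE[rt$method == "M1"], 1.5)
  # degenerate single-cell aggregation equals the raw ranks
  one <- mk_reports(c(A = 0.4, B = 0.9, C = 0.7))
  rt1 <- aggregate_ranks(average_over_sims(one))
  expect_equal(rt1$Average[rt1$method == "A"], 1)
  expect_equal(rt1$Average[rt1$method == "B"], 3)
  # incomplete factorial coverage errors, naming missing cells
  expect_error(aggregate_ranks(me[-1, ]), "incomplete factorial")
})

test_that("rank sums are conserved and ranks survive monotone transforms", {
  set.seed(77)
  for (i in 1:50) {
    n_m <- sample(3:10, 1)
    me <- tidyr::expand_grid(site = c("s1", "s2", "s3"), pool = c("A", "B"),
                             method = paste0("m", seq_len(n_m)),
                             metric = c("rmse", "lrmse", "rae", "rae_l2"))
    me$mean_error <- runif(nrow(me))
    me$n_sims <- 1L
    rt <- aggregate_ranks(me)
    # conservation of the total rank at the top level, per metric column
    for (cl in c("RMSE", "LRMSE", "RAE", "RAEL2", "Average"))
      expect_equal(sum(rt[[cl]]), n_m * (n_m + 1) / 2)
    # a strictly increasing transform leaves the whole table unchanged
    me2 <- me
    me2$mean_error <- exp(3 * me2$mean_error) + 1
    rt2 <- aggregate_ranks(me2)
    expect_equal(dplyr::arrange(rt, .data$method),
                 dplyr::arrange(rt2, .data$method))
  }
})

test_that("sites-then-pools order matters on an unbalanced design", {
  # pool A measured at two sites, pool B at one; two methods
  me <- tibble::tibble(
    site = c("s1", "s2", "s1", "s1", "s2", "s1"),
    pool = c("A", "A", "B", "A", "A", "B"),
    method = rep(c("m1", "m2"), each = 3),
    metric = "rmse",
    mean_error = c(1, 2, 2, 2, 1, 1),   # m1 wins s1A and loses s2A, loses B
    n_sims = 1L
  )
  me <- dplyr::bind_rows(me, dplyr::mutate(me, metric = "lrmse"),
                         dplyr::mutate(me, metric = "rae"),
                         dplyr::mutate(me, metric = "rae_l2"))
  expect_error(aggregate_ranks(me), "incomplete")
  rt <- aggregate_ranks(me, allow_unbalanced = TRUE)
  # sites-then-pools: m1 pool A mean (1+2)/2 = 1.5, pool B 2 -> 1.75
  expect_equal(rt$RMSE[rt$method == "m1"], 1.75)
  # the flat mean over the 3 cells would give (1+2+2)/3 = 5/3 instead
  expect_false(isTRUE(all.equal(rt$RMSE[rt$method == "m1"], 5 / 3)))
})

test_that("best and worst methods are reported with tie sets", {
  rt <- aggregate_ranks(average_over_sims(
    mk_reports(c(A = 0.2, B = 0.8, C = 0.5))))
  bw <- best_worst(rt)
  expect_identical(bw$best[[which(bw$column == "Average")]], "A")
  expect_identical(bw$worst[[which(bw$column == "Average")]], "B")
  # exact tie at the minimum reports both
  rt2 <- aggregate_ranks(average_over_sims(
    mk_reports(c(A = 0.3, B = 0.3, C = 0.9))))
  expect_setequal(bw2 <- best_worst(rt2)$best[[1]], c("A", "B"))
  # tidy / glance / autoplot views
  expect_identical(glance(rt)$best, "A")
  long <- tidy(rt)
  expect_equal(nrow(long), 3 * 5)
  expect_s3_class(autoplot(rt), "ggplot")
})
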