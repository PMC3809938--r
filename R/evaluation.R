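#' Monte-Carlo evaluation configuration
#'
#' @param deletion_fraction Fraction of cells deleted per simulation,
#'   in (0, 1); the study uses 0.05 and 0.10.
#' @param n_simulations Number of Monte-Carlo simulations (the full study
#'   uses 1000; scale down for quick runs).
#' @param epsilon Floor of the RAE denominator (default 0.20).
#' @param log_base Base of the LRMSE logarithm: `"e"`, `"2"` or `"10"`
#'   (rank order is invariant to the choice).
#' @param rae_l2_root If `TRUE`, apply an outer square root to RAE-L2
#'   (default `FALSE`: mean of squared error over true value).
#' @param est_floor Positive floor applied to imputed values before scoring,
#'   or `NULL` (default) for half the smallest observed value of the masked
#'   matrix. Regression-based methods can overshoot into nonpositive
#'   territory where a log-scale error is undefined; projecting estimates
#'   back into the plausible expression range keeps all four measures
#'   computable while still penalizing such estimates on the log scale.
#' @param seed Master seed; each simulation derives its own seed as
#'   `xor(seed, sim_index)`.
#' @return Object of class `eval_config`.
#' @export
eval_config <- function(deletion_fraction = 0.05, n_simulations = 1000L,
                        epsilon = 0.20, log_base = "e",
                        rae_l2_root = FALSE, est_floor = NULL, seed = 1L) {
  if (deletion_fraction <= 0 || deletion_fraction >= 1)
    stop("deletion_fraction must lie in (0, 1)", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  if (!log_base %in% c("e", "2", "10"))
    stop("log_base must be one of e, 2, 10", call. = FALSE)
  structure(
    list(deletion_fraction = deletion_fraction,
         n_simulations = as.integer(n_simulations), epsilon = epsilon,
         log_base = log_base, rae_l2_root = rae_l2_root,
         est_floor = est_floor, seed = as.integer(seed)),
    class = "eval_config"
  )
}

log_fun <- function(base) {
  switch(base, e = log, `2` = log2, `10` = log10)
}

#' Randomly delete entries from a complete matrix
#'
#' Masks exactly `round(fraction * G * S)` distinct cells drawn uniformly
#' without replacement (round half to even), stashing the true values so
#' imputations can be scored. Deterministic per seed.
#'
#' @param cd Complete positive expression matrix.
#' @param fraction Deletion fraction in (0, 1).
#' @param seed Integer seed.
#' @return A [masked_matrix()] with `truth` stashed.
#' @export
delete_entries <- function(cd, fraction, seed = 1L) {
  stopifnot(is.matrix(cd))
  if (anyNA(cd)) stop("input matrix must be complete", call. = FALSE)
  n_cells <- length(cd)
  n_del <- round(fraction * n_cells)
  if (n_del < 1)
    stop("deletion fraction yields zero cells", call. = FALSE)
  if (n_del >= n_cells)
    stop("deletion fraction leaves no observed cells", call. = FALSE)
  idx <- withr::with_seed(seed, sample(n_cells, n_del))
  vals <- cd
  vals[idx] <- NA
  masked_matrix(vals, truth = cd)
}

check_measure_input <- function(truth, est) {
  if (length(truth) != length(est))
    stop("truth and estimate must have the same length", call. = FALSE)
  if (length(truth) == 0) stop("empty input", call. = FALSE)
}

#' Imputation error measures
#'
#' The four summary statistics comparing imputed values with the stashed
#' truth over the masked cells:
#' * `rmse`: root mean squared error, `sqrt(mean((est - truth)^2))`.
#' * `rae`: relative estimation error, `mean(|est - truth| / phi(truth))`
#'   with `phi(y) = max(|y|, epsilon)`.
#' * `lrmse`: RMSE on the log scale, `sqrt(mean((log est - log truth)^2))`.
#' * `rae_l2`: mean squared error relative to the true value,
#'   `mean((est - truth)^2 / truth)` (an outer square root is available via
#'   `root = TRUE`).
#'
#' @param truth,est Numeric vectors of equal nonzero length (`lrmse` and
#'   `rae_l2` require strictly positive values).
#' @param epsilon Positive floor of the RAE denominator.
#' @param log_base `"e"`, `"2"` or `"10"`.
#' @param root Apply an outer square root to `rae_l2`.
#' @return Nonnegative scalar.
#' @name error_measures
NULL

#' @rdname error_measures
#' @export
rmse <- function(truth, est) {
  check_measure_input(truth, est)
  sqrt(mean((est - truth)^2))
}

#' @rdname error_measures
#' @export
rae <- function(truth, est, epsilon = 0.20) {
  check_measure_input(truth, est)
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  mean(abs(est - truth) / pmax(abs(truth), epsilon))
}

#' @rdname error_measures
#' @export
lrmse <- function(truth, est, log_base = "e") {
  check_measure_input(truth, est)
  if (any(truth <= 0) || any(est <= 0)) {
    bad <- which(truth <= 0 | est <= 0)[1]
    stop("nonpositive value at cell ", bad, "; log-scale error undefined",
         call. = FALSE)
  }
  lf <- log_fun(log_base)
  sqrt(mean((lf(est) - lf(truth))^2))
}

#' @rdname error_measures
#' @export
rae_l2 <- function(truth, est, root = FALSE) {
  check_measure_input(truth, est)
  if (any(truth <= 0)) {
    bad <- which(truth <= 0)[1]
    stop("nonpositive true value at cell ", bad, call. = FALSE)
  }
  v <- mean((est - truth)^2 / truth)
  if (root) sqrt(v) else v
}

score_imputation <- function(m, imputed, cfg) {
  truth <- m$truth[m$mask]
  floor_val <- cfg$est_floor %||% (min(m$values[!m$mask]) / 2)
  est <- pmax(imputed$values[m$mask], floor_val)
  tibble::tibble(
    rmse = rmse(truth, est),
    lrmse = lrmse(truth, est, cfg$log_base),
    rae = rae(truth, est, cfg$epsilon),
    rae_l2 = rae_l2(truth, est, cfg$rae_l2_root),
    n_missing = sum(m$mask)
  )
}

#' Run the Monte-Carlo imputation benchmark on one complete matrix
#'
#' For each simulation, one deletion mask is drawn (the same mask for every
#' method, so all methods face identical missingness), each method imputes
#' the masked matrix, and the four error measures are recorded. Simulation
#' seeds derive from the master seed as `xor(seed, sim_index)`, so any
#' single simulation can be re-run in isolation. A method failure flags the
#' report (`ok = FALSE`) instead of aborting the benchmark.
#'
#' @param cd Complete positive expression matrix (one site-by-pool cell).
#' @param methods List of [method_config()]s (default [table1_methods()]).
#' @param cfg An [eval_config()].
#' @param site,pool Labels recorded in the reports.
#' @return Tibble of class `benchmark_result`: one row per simulation per
#'   method with `site, pool, sim, method, rmse, lrmse, rae, rae_l2,
#'   n_missing, ok`.
#' @export
run_benchmark <- function(cd, methods = table1_methods(),
                          cfg = eval_config(), site = "site1", pool = "A") {
  stopifnot(is.matrix(cd), !anyNA(cd))
  labels <- vapply(methods, function(m) m$label, "")
  if (anyDuplicated(labels)) stop("method labels must be unique", call. = FALSE)
  out <- vector("list", cfg$n_simulations)
  for (sim in seq_len(cfg$n_simulations)) {
    sim_seed <- bitwXor(cfg$seed, sim)
    m <- delete_entries(cd, cfg$deletion_fraction, seed = sim_seed)
    rows <- purrr::imap(methods, function(mc, i) {
      mc$seed <- bitwXor(sim_seed, 1000L + match(i, names(methods)))
      res <- tryCatch(
        suppressMessages(suppressWarnings(impute(m, mc))),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        message("method ", mc$label, " failed on simulation ", sim, ": ",
                conditionMessage(res))
        return(tibble::tibble(rmse = NA_real_, lrmse = NA_real_,
                              rae = NA_real_, rae_l2 = NA_real_,
                              n_missing = sum(m$mask), method = mc$label,
                              ok = FALSE))
      }
      sc <- score_imputation(m, res, cfg)
      sc$method <- mc$label
      sc$ok <- TRUE
      sc
    })
    out[[sim]] <- dplyr::bind_rows(rows) |>
      dplyr::mutate(sim = sim, site = site, pool = pool)
  }
  res <- dplyr::bind_rows(out) |>
    dplyr::select("site", "pool", "sim", "method", "rmse", "lrmse", "rae",
                  "rae_l2", "n_missing", "ok")
  class(res) <- c("benchmark_result", class(res))
  res
}
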