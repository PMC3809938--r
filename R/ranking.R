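#' Average error per method, metric, site and pool
#'
#' Arithmetic mean of each error measure over the simulations of every
#' (method, site, pool) cell. Flagged (failed) reports are excluded and the
#' exclusion count is reported via `message()`.
#'
#' @param reports Benchmark tibble from [run_benchmark()] (rows from several
#'   cells can be concatenated).
#' @return Tibble `site, pool, method, metric, mean_error, n_sims`.
#' @export
average_over_sims <- function(reports) {
  flagged <- !reports$ok
  if (any(flagged))
    message(sum(flagged), " flagged simulation report(s) excluded from averages")
  valid <- reports[!flagged, ]
  if (nrow(valid) == 0)
    stop("no valid reports to average", call. = FALSE)
  long <- tidyr::pivot_longer(valid, cols = c("rmse", "lrmse", "rae", "rae_l2"),
                              names_to = "metric", values_to = "error")
  out <- long |>
    dplyr::summarise(mean_error = mean(.data$error), n_sims = dplyr::n(),
                     .by = c("site", "pool", "method", "metric"))
  empty <- out[!is.finite(out$mean_error), ]
  if (nrow(empty) > 0)
    stop("no valid reports for cell(s): ",
         paste(sprintf("%s/%s/%s/%s", empty$site, empty$pool, empty$method,
                       empty$metric), collapse = ", "), call. = FALSE)
  out
}

#' Rank methods by error, 1 = lowest
#'
#' Ascending ranks over one metric-by-site-by-pool group of mean errors:
#' the method with the lowest error is ranked 1, the highest is ranked
#' `n_methods`. Ties receive midranks, so the rank sum `n(n+1)/2` is
#' preserved.
#'
#' @param errors Named (or unnamed) numeric vector of mean errors, one per
#'   method, length >= 2.
#' @return Numeric rank vector in the same order.
#' @export
rank_methods <- function(errors) {
  if (length(errors) < 2) stop("need at least two methods", call. = FALSE)
  if (anyNA(errors)) stop("missing method error value", call. = FALSE)
  rank(errors, ties.method = "average")
}

#' Aggregate per-cell ranks into the overall rank table
#'
#' For every metric, methods are ranked within each site-by-pool cell; the
#' ranks are then averaged across sites within each pool, and the resulting
#' pool values are averaged — in that order — into one number per method per
#' metric. The `Average` column is the row-wise mean of the four metric
#' columns. With a balanced design the two-level average equals the flat
#' mean over cells; with an unbalanced one it does not, and the sequential
#' order is the one implemented.
#'
#' @param mean_errors Tibble from [average_over_sims()].
#' @param allow_unbalanced Permit pools observed at different site sets
#'   (default `FALSE`: incomplete factorial coverage is an error).
#' @return Tibble of class `rank_table`: `method, RMSE, LRMSE, RAE, RAEL2,
#'   Average`, sorted by `Average`.
#' @export
aggregate_ranks <- function(mean_errors, allow_unbalanced = FALSE) {
  grid <- tidyr::expand_grid(
    site = unique(mean_errors$site), pool = unique(mean_errors$pool),
    method = unique(mean_errors$method), metric = unique(mean_errors$metric)
  )
  have <- dplyr::semi_join(grid, mean_errors,
                           by = c("site", "pool", "method", "metric"))
  if (nrow(have) < nrow(grid) && !allow_unbalanced) {
    miss <- dplyr::anti_join(grid, mean_errors,
                             by = c("site", "pool", "method", "metric"))
    stop("incomplete factorial coverage; missing cells: ",
         paste(utils::head(
           sprintf("%s/%s/%s/%s", miss$site, miss$pool, miss$method,
                   miss$metric), 10), collapse = ", "), call. = FALSE)
  }
  ranked <- mean_errors |>
    dplyr::mutate(rk = rank_methods(.data$mean_error),
                  .by = c("site", "pool", "metric"))
  per_pool <- ranked |>
    dplyr::summarise(rk = mean(.data$rk), .by = c("pool", "method", "metric"))
  overall <- per_pool |>
    dplyr::summarise(rk = mean(.data$rk), .by = c("method", "metric"))
  metric_cols <- c(rmse = "RMSE", lrmse = "LRMSE", rae = "RAE",
                   rae_l2 = "RAEL2")
  wide <- overall |>
    dplyr::mutate(metric = metric_cols[.data$metric]) |>
    tidyr::pivot_wider(names_from = "metric", values_from = "rk")
  cols <- intersect(unname(metric_cols), names(wide))
  wide$Average <- rowMeans(wide[, cols, drop = FALSE])
  wide <- dplyr::arrange(wide, .data$Average)
  class(wide) <- c("rank_table", class(wide))
  wide
}

#' Best and worst method per column
#'
#' Smaller average rank means a more accurate imputation method; the best
#' (argmin) and worst (argmax) are reported per metric column and overall,
#' with ties reported as sets.
#'
#' @param rt A `rank_table` from [aggregate_ranks()].
#' @return Tibble `column, best, worst` (best/worst are list-columns of
#'   character vectors).
#' @export
best_worst <- function(rt) {
  cols <- setdiff(names(rt), "method")
  purrr::map_dfr(cols, function(cl) {
    v <- rt[[cl]]
    tibble::tibble(
      column = cl,
      best = list(rt$method[v == min(v)]),
      worst = list(rt$method[v == max(v)])
    )
  })
}

#' @export
print.rank_table <- function(x, ...) {
  cat("<rank_table> average ranks (1 = best)\n")
  NextMethod()
}

#' Tidy a rank table to long format
#'
#' @param x A `rank_table`.
#' @param ... Unused.
#' @return Tibble `method, metric, avg_rank`.
#' @export
tidy.rank_table <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), cols = -"method",
                      names_to = "metric", values_to = "avg_rank")
}

#' One-row summary of a rank table
#'
#' @param x A `rank_table`.
#' @param ... Unused.
#' @return Tibble `n_methods, best, worst, best_average, worst_average`.
#' @export
glance.rank_table <- function(x, ...) {
  tibble::tibble(
    n_methods = nrow(x),
    best = x$method[which.min(x$Average)],
    worst = x$method[which.max(x$Average)],
    best_average = min(x$Average),
    worst_average = max(x$Average)
  )
}

#' Plot a rank table as a bar chart of average ranks
#'
#' @param object A `rank_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rank_table <- function(object, ...) {
  long <- tidy.rank_table(object)
  long$method <- factor(long$method,
                        levels = object$method[order(object$Average)])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$avg_rank)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = "average rank (1 = best)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot benchmark error distributions per method
#'
#' @param reports Tibble from [run_benchmark()].
#' @param metric One of `"rmse", "lrmse", "rae", "rae_l2"`.
#' @return A ggplot object.
#' @export
plot_benchmark_errors <- function(reports, metric = "rmse") {
  stopifnot(metric %in% c("rmse", "lrmse", "rae", "rae_l2"))
  ggplot2::ggplot(reports[reports$ok, ],
                  ggplot2::aes(x = .data$method, y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
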