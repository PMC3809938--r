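#' Detection-call parameters
#'
#' Thresholds of the Present/Marginal/Absent detection-call algorithm. The
#' defaults are the MAS 5.0 presets: `tau = 0.015`, `alpha1 = 0.04`,
#' `alpha2 = 0.06`.
#'
#' @param tau Small nonnegative offset the median discrimination score is
#'   tested against.
#' @param alpha1,alpha2 Significance cutoffs; a probe set is Present when
#'   `p < alpha1`, Marginal when `alpha1 <= p < alpha2`, Absent when
#'   `p >= alpha2`. Requires `0 < alpha1 < alpha2 < 1`.
#' @return Object of class `detection_params`.
#' @export
detection_params <- function(tau = 0.015, alpha1 = 0.04, alpha2 = 0.06) {
  if (!(alpha1 > 0 && alpha1 < alpha2 && alpha2 < 1))
    stop("detection params require 0 < alpha1 < alpha2 < 1", call. = FALSE)
  if (tau < 0) stop("tau must be nonnegative", call. = FALSE)
  structure(list(tau = tau, alpha1 = alpha1, alpha2 = alpha2),
            class = "detection_params")
}

#' Discrimination scores of PM/MM probe pairs
#'
#' Element-wise `(PM - MM) / (PM + MM)`; for strictly positive intensities the
#' score lies in (-1, 1). The per-probe-set median of these scores is what the
#' detection call tests against `tau`.
#'
#' @param pm,mm Strictly positive intensity vectors of equal length.
#' @return Numeric score vector.
#' @export
discrimination_scores <- function(pm, mm) {
  if (length(pm) != length(mm))
    stop("pm and mm must have the same length", call. = FALSE)
  if (length(pm) < 1) stop("need at least one probe pair", call. = FALSE)
  if (any(pm <= 0) || any(mm <= 0))
    stop("intensities must be strictly positive", call. = FALSE)
  (pm - mm) / (pm + mm)
}

# Exact null distribution of the positive-rank sum over doubled ranks:
# counts[w + 1] = number of sign assignments with positive-rank sum w.
# Shift/convolution dynamic programme; identical to enumerating all 2^n
# sign vectors but O(n * W) instead of O(2^n). Doubling keeps midranks
# integral under ties.
signed_rank_null_counts <- function(ranks2) {
  total <- sum(ranks2)
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  counts
}

#' One-sided exact Wilcoxon signed-rank p-value against tau
#'
#' Tests H0: median score equals `tau` against H1: median score greater than
#' `tau`, using the exact null distribution of the positive-rank sum
#' (uniform over all 2^n sign assignments). Zero differences are dropped
#' before ranking; tied magnitudes receive midranks, and the exact
#' distribution is evaluated over the midranked magnitudes.
#'
#' @param scores Discrimination-score vector, length 1 to 20.
#' @param tau Offset tested against.
#' @return p-value in `[0, 1]`: the null probability that the positive-rank
#'   sum is at least the observed one.
#' @export
wilcoxon_one_sided_p <- function(scores, tau = 0.015) {
  if (length(scores) < 1) stop("empty score vector", call. = FALSE)
  d <- scores - tau
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all discrimination scores equal tau; returning p = 1")
    return(1.0)
  }
  r2 <- 2 * rank(abs(d), ties.method = "average")  # doubled midranks, integral
  w_obs <- sum(r2[d > 0])
  counts <- signed_rank_null_counts(round(r2))
  sum(counts[seq(round(w_obs) + 1, length(counts))]) / sum(counts)
}

call_from_p <- function(p, params) {
  factor(
    ifelse(p < params$alpha1, "Present",
           ifelse(p < params$alpha2, "Marginal", "Absent")),
    levels = c("Present", "Marginal", "Absent")
  )
}

#' Detection calls for every probe set on every array
#'
#' Computes discrimination scores per probe pair, the exact one-sided
#' signed-rank p-value per probe set per array, and the
#' Present/Marginal/Absent call at the `alpha1`/`alpha2` cutoffs.
#'
#' @param data A `probe_level_data` object (or a list with a `probes` tibble).
#' @param params A [detection_params()].
#' @return Tibble `probe_set_id, sample_id, n_pairs, p_value, call`.
#' @export
detect <- function(data, params = detection_params()) {
  probes <- data$probes
  stopifnot(all(c("probe_set_id", "probe_pair_index", "sample_id",
                  "pm", "mm") %in% names(probes)))
  if (any(probes$pm <= 0) || any(probes$mm <= 0))
    stop("probe intensities must be strictly positive", call. = FALSE)
  scores <- (probes$pm - probes$mm) / (probes$pm + probes$mm)
  out <- probes |>
    dplyr::mutate(.score = scores) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      p_value = wilcoxon_one_sided_p(.data$.score, params$tau),
      .by = c("probe_set_id", "sample_id")
    )
  out$call <- call_from_p(out$p_value, params)
  out
}

#' Percent-present summaries
#'
#' Per array, the percentage of probe sets called Present; per site-by-pool
#' cell, the mean of that percentage over the cell's replicates.
#'
#' @param calls Tibble from [detect()].
#' @param samples Sample sheet tibble (`sample_id, site, pool, replicate`).
#' @return List of class `percent_present` with tibbles `per_array`
#'   (`sample_id, site, pool, replicate, percent`) and `per_cell`
#'   (`site, pool, mean_percent`).
#' @export
percent_present <- function(calls, samples) {
  n_sets <- dplyr::n_distinct(calls$probe_set_id)
  missing_samples <- setdiff(samples$sample_id, calls$sample_id)
  if (length(missing_samples) > 0)
    stop("samples without detection calls: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  per_array <- calls |>
    dplyr::summarise(
      percent = 100 * sum(.data$call == "Present") / n_sets,
      .by = "sample_id"
    ) |>
    dplyr::left_join(samples, by = "sample_id") |>
    dplyr::select("sample_id", "site", "pool", "replicate", "percent")
  per_cell <- per_array |>
    dplyr::summarise(mean_percent = mean(.data$percent), .by = c("site", "pool"))
  structure(list(per_array = per_array, per_cell = per_cell),
            class = "percent_present")
}

#' @export
print.percent_present <- function(x, ...) {
  cat("<percent_present>\n")
  print(x$per_cell, n = Inf)
  invisible(x)
}

#' All-replicates-present filter
#'
#' For one site-by-pool cell, retains exactly the probe sets called Present
#' in every replicate of the cell; probe sets Absent or Marginal in one or
#' more replicates are removed. The retained set defines the rows of the
#' cell's complete expression matrix.
#'
#' @param calls Tibble from [detect()].
#' @param samples Sample sheet tibble.
#' @param site,pool Identifiers of the cell.
#' @return Character vector of retained probe-set ids.
#' @export
filter_complete <- function(calls, samples, site, pool) {
  cell_samples <- samples$sample_id[samples$site == site & samples$pool == pool]
  if (length(cell_samples) == 0)
    stop(sprintf("unknown site/pool cell: %s / %s", site, pool), call. = FALSE)
  cell <- calls[calls$sample_id %in% cell_samples, ]
  tab <- cell |>
    dplyr::summarise(
      all_present = dplyr::n() == length(cell_samples) &&
        all(.data$call == "Present"),
      .by = "probe_set_id"
    )
  sort(tab$probe_set_id[tab$all_present])
}
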