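#' Preprocessing parameters
#'
#' Constants of the ideal-mismatch / Tukey-biweight summarization and the
#' trimmed-mean scale normalization. Defaults follow the documented defaults
#' of the classic Affymetrix signal algorithm.
#'
#' @param contrast_tau Contrast threshold of the ideal-mismatch rule
#'   (default 0.03).
#' @param scale_tau Scale constant of the smooth ideal-mismatch branch
#'   (default 10).
#' @param target_intensity Trimmed-mean target every array is scaled to
#'   (default 500).
#' @param trim_fraction Fraction trimmed from each tail of a column before
#'   taking its mean (default 0.02), in `[0, 0.5)`.
#' @param delta_floor Floor applied to `PM - IM` before taking logs
#'   (default `2^-20`).
#' @param biweight_c Tukey biweight tuning constant (default 5).
#' @param biweight_epsilon Additive guard in the biweight denominator
#'   (default 1e-4).
#' @param baseline_mode If `TRUE`, scale to column 1's trimmed mean instead
#'   of `target_intensity`.
#' @return Object of class `preprocess_params`.
#' @export
preprocess_params <- function(contrast_tau = 0.03, scale_tau = 10,
                              target_intensity = 500, trim_fraction = 0.02,
                              delta_floor = 2^-20, biweight_c = 5,
                              biweight_epsilon = 1e-4, baseline_mode = FALSE) {
  p <- list(contrast_tau = contrast_tau, scale_tau = scale_tau,
            target_intensity = target_intensity, trim_fraction = trim_fraction,
            delta_floor = delta_floor, biweight_c = biweight_c,
            biweight_epsilon = biweight_epsilon, baseline_mode = baseline_mode)
  nums <- p[setdiff(names(p), "baseline_mode")]
  if (any(vapply(nums, function(v) !is.numeric(v) || v <= 0, TRUE) &
          names(nums) != "trim_fraction"))
    stop("preprocess params must be positive", call. = FALSE)
  if (trim_fraction < 0 || trim_fraction >= 0.5)
    stop("trim_fraction must lie in [0, 0.5)", call. = FALSE)
  structure(p, class = "preprocess_params")
}

#' One-step Tukey biweight location estimate
#'
#' Robust average: center at the median, scale by the median absolute
#' deviation, down-weight each value by the bounded quartic
#' `w = (1 - u^2)^2` for `|u| <= 1` (zero outside), with
#' `u = (v - median) / (c * MAD + epsilon)`. One step, not iterated.
#'
#' @param values Numeric vector, length >= 1.
#' @param c,epsilon Tuning constant and guard; see [preprocess_params()].
#' @return Weighted mean (scalar).
#' @export
tukey_biweight <- function(values, c = 5, epsilon = 1e-4) {
  if (length(values) < 1) stop("empty vector", call. = FALSE)
  m <- stats::median(values)
  s <- stats::median(abs(values - m))
  u <- (values - m) / (c * s + epsilon)
  w <- ifelse(abs(u) <= 1, (1 - u^2)^2, 0)
  sum(w * values) / sum(w)
}

#' Ideal mismatch
#'
#' A surrogate for the MM intensity guaranteed to stay below PM, so that
#' `PM - IM` is always positive at summarization. When `MM < PM` the ideal
#' mismatch is MM itself; otherwise it is PM shrunk by the probe set's
#' specific background `SB = tukey_biweight(log2(PM/MM))` when that contrast
#' is informative (`SB > contrast_tau`), and by a smooth floor approaching
#' `contrast_tau` otherwise.
#'
#' @param pm,mm Positive intensity vectors for one probe set on one array.
#' @param params A [preprocess_params()].
#' @return Vector `im` with `0 < im < pm` element-wise.
#' @export
ideal_mismatch <- function(pm, mm, params = preprocess_params()) {
  if (length(pm) != length(mm))
    stop("pm and mm must have the same length", call. = FALSE)
  im <- numeric(length(pm))
  lt <- mm < pm
  im[lt] <- mm[lt]
  if (any(!lt)) {
    sb <- tukey_biweight(log2(pm / mm), params$biweight_c,
                         params$biweight_epsilon)
    expo <- if (sb > params$contrast_tau) {
      sb
    } else {
      params$contrast_tau / (1 + (params$contrast_tau - sb) / params$scale_tau)
    }
    im[!lt] <- pm[!lt] / 2^expo
  }
  im
}

#' Summarize probe-level data to one signal per probe set per array
#'
#' For each retained probe set on each array:
#' `signal = 2 ^ tukey_biweight(log2(max(PM - IM, delta_floor)))`, with IM
#' the [ideal_mismatch()]. Homogeneous of degree one: scaling all intensities
#' scales all signals.
#'
#' @param data A `probe_level_data` object (or list with `probes`).
#' @param retained Character vector of probe-set ids to summarize (rows of the
#'   output); must all be present in the table.
#' @param params A [preprocess_params()].
#' @param samples Optional character vector restricting the arrays
#'   (columns); defaults to all arrays in the table.
#' @return Positive numeric matrix, probe sets x arrays.
#' @export
summarize_expression <- function(data, retained, params = preprocess_params(),
                                 samples = NULL) {
  probes <- data$probes
  missing_ps <- setdiff(retained, unique(probes$probe_set_id))
  if (length(missing_ps) > 0)
    stop("retained probe sets absent from table: ",
         paste(utils::head(missing_ps, 5), collapse = ", "), call. = FALSE)
  if (is.null(samples)) samples <- unique(probes$sample_id)
  sub <- probes[probes$probe_set_id %in% retained &
                  probes$sample_id %in% samples, ]
  sig <- sub |>
    dplyr::summarise(
      signal = {
        im <- ideal_mismatch(.data$pm, .data$mm, params)
        2^tukey_biweight(log2(pmax(.data$pm - im, params$delta_floor)),
                         params$biweight_c, params$biweight_epsilon)
      },
      .by = c("probe_set_id", "sample_id")
    )
  wide <- tidyr::pivot_wider(sig, names_from = "sample_id",
                             values_from = "signal")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$probe_set_id
  m[sort(rownames(m)), intersect(samples, colnames(m)), drop = FALSE]
}

trimmed_col_means <- function(m, trim) {
  apply(m, 2, mean, trim = trim)
}

#' Trimmed-mean scale normalization
#'
#' Multiplies every column by `target / trimmed_mean(column)` so each array's
#' trimmed mean equals the target intensity. Idempotent. In baseline mode the
#' target is the first column's trimmed mean.
#'
#' @param m Positive expression matrix.
#' @param params A [preprocess_params()].
#' @return Matrix of the same shape, plus attribute `scale_factors`.
#' @export
scale_normalize <- function(m, params = preprocess_params()) {
  tm <- trimmed_col_means(m, params$trim_fraction)
  if (any(tm <= 0)) stop("column with nonpositive trimmed mean", call. = FALSE)
  target <- if (params$baseline_mode) tm[1] else params$target_intensity
  sf <- target / tm
  out <- sweep(m, 2, sf, `*`)
  attr(out, "scale_factors") <- sf
  out
}
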