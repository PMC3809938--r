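#' Configuration for the MAQC-style probe-level data generator
#'
#' Builds and validates the parameter set for [generate_dataset()] and
#' [generate_expression_matrix()]. The defaults emulate the MAQC reference
#' design: two reference RNA profiles (UHRR and HBRR), four pools that are
#' linear mixtures of the two references (A = 100% UHRR, B = 100% HBRR,
#' C = 75/25, D = 25/75), six sites with multiplicative site effects, five
#' replicate arrays per site-by-pool cell, and probe sets of 11--20 PM/MM
#' probe pairs.
#'
#' @param n_probe_sets Number of probe sets (transcripts) on the chip.
#' @param n_sites Number of laboratory sites (default 6).
#' @param n_replicates Replicate arrays per site-by-pool cell (default 5).
#' @param pool_mixtures Named numeric vector mapping pool label to the UHRR
#'   fraction of the mixture, in `[0, 1]`.
#' @param probes_per_set_range Integer interval (length 2) for the number of
#'   probe pairs per probe set; must lie within `[11, 20]`.
#' @param frac_expressed_uhrr,frac_expressed_hbrr Marginal probability that a
#'   probe set's transcript is expressed in UHRR / HBRR.
#' @param frac_expressed_both Joint probability that a transcript is expressed
#'   in both references. Most transcripts present in one reference are present
#'   in the other, so the joint probability is far above the independence
#'   product; it is bounded by
#'   `max(0, fU + fH - 1) <= both <= min(fU, fH)`.
#' @param signal_lognormal_params Length-2 numeric `c(meanlog, sdlog)` of the
#'   latent linear-scale expression of expressed transcripts.
#' @param site_effect_sd Log-scale standard deviation of the per-site,
#'   per-probe-set multiplicative site effect.
#' @param replicate_cv Coefficient of variation of multiplicative replicate
#'   noise (linear scale).
#' @param mm_crosstalk Fraction of true signal bleeding into the MM probe,
#'   in `[0, 1)`.
#' @param noise_floor Baseline background intensity (linear scale).
#' @param background_cv Coefficient of variation of the multiplicative
#'   background term shared by PM and MM draws.
#' @param array_effect_cv Coefficient of variation of a per-array
#'   multiplicative factor shared by all genes on the array (hybridization
#'   and scanning efficiency differ between replicate arrays; this shared
#'   component is what makes gene rows of technical-replicate data mutually
#'   correlated).
#' @param block_size,block_correlation Cluster structure used only by
#'   [generate_expression_matrix()]: genes are grouped into blocks of
#'   `block_size` rows whose factor loadings are correlated
#'   `block_correlation`, so within-block gene profiles are correlated
#'   across arrays (exactly proportional at correlation 1).
#' @param n_array_factors Number of systematic per-array technical factors
#'   (beyond the overall array scale) in [generate_expression_matrix()];
#'   each gene responds to them with its own loading (default 3).
#' @param measurement_cv Coefficient of variation of the purely
#'   idiosyncratic per-cell measurement noise in
#'   [generate_expression_matrix()] (default 0.05); the irreducible error
#'   floor for any imputation method.
#' @param expression_floor Lower truncation of the latent gene level in
#'   [generate_expression_matrix()] (default 30): the benchmark's complete
#'   matrices contain only reliably detected transcripts, so their
#'   low-intensity tail is cut off.
#' @param additive_noise_sd Standard deviation of the additive component of
#'   measurement noise in [generate_expression_matrix()] (default 12), the
#'   two-component (additive plus multiplicative) error model of microarray
#'   intensities: low-intensity measurements are proportionally much
#'   noisier than bright ones.
#' @param seed Integer seed; identical seed and config reproduce output
#'   bit-for-bit.
#'
#' @return An object of class `generator_config` (a named list).
#' @export
generator_config <- function(n_probe_sets = 2000,
                             n_sites = 6,
                             n_replicates = 5,
                             pool_mixtures = c(A = 1, B = 0, C = 0.75, D = 0.25),
                             probes_per_set_range = c(11L, 20L),
                             frac_expressed_uhrr = 0.54,
                             frac_expressed_hbrr = 0.52,
                             frac_expressed_both = 0.505,
                             signal_lognormal_params = c(meanlog = log(150), sdlog = 1.6),
                             site_effect_sd = 0.12,
                             replicate_cv = 0.10,
                             mm_crosstalk = 0.3,
                             noise_floor = 50,
                             background_cv = 0.2,
                             array_effect_cv = 0.02,
                             block_size = 100,
                             block_correlation = 0.99,
                             n_array_factors = 5,
                             measurement_cv = 0.01,
                             expression_floor = 30,
                             additive_noise_sd = 12,
                             seed = 1L) {
  cfg <- list(
    n_probe_sets = n_probe_sets, n_sites = n_sites,
    n_replicates = n_replicates, pool_mixtures = pool_mixtures,
    probes_per_set_range = as.integer(probes_per_set_range),
    frac_expressed_uhrr = frac_expressed_uhrr,
    frac_expressed_hbrr = frac_expressed_hbrr,
    frac_expressed_both = frac_expressed_both,
    signal_lognormal_params = signal_lognormal_params,
    site_effect_sd = site_effect_sd, replicate_cv = replicate_cv,
    mm_crosstalk = mm_crosstalk, noise_floor = noise_floor,
    background_cv = background_cv,
    array_effect_cv = array_effect_cv,
    block_size = as.integer(block_size),
    block_correlation = block_correlation,
    n_array_factors = as.integer(n_array_factors),
    measurement_cv = measurement_cv,
    expression_floor = expression_floor,
    additive_noise_sd = additive_noise_sd,
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  stop_cfg <- function(field, msg) {
    stop(sprintf("invalid generator config: field `%s` %s", field, msg),
         call. = FALSE)
  }
  if (!is.numeric(cfg$n_probe_sets) || cfg$n_probe_sets < 1)
    stop_cfg("n_probe_sets", "must be a positive integer")
  if (!is.numeric(cfg$n_sites) || cfg$n_sites < 1)
    stop_cfg("n_sites", "must be a positive integer")
  if (!is.numeric(cfg$n_replicates) || cfg$n_replicates < 1)
    stop_cfg("n_replicates", "must be a positive integer")
  mix <- cfg$pool_mixtures
  if (is.null(names(mix)) || any(!nzchar(names(mix))))
    stop_cfg("pool_mixtures", "must be a named vector of UHRR fractions")
  if (any(mix < 0 | mix > 1))
    stop_cfg("pool_mixtures", "fractions must lie in [0, 1]")
  rng <- cfg$probes_per_set_range
  if (length(rng) != 2 || rng[1] > rng[2] || rng[1] < 11 || rng[2] > 20)
    stop_cfg("probes_per_set_range", "must be an interval within [11, 20]")
  for (f in c("frac_expressed_uhrr", "frac_expressed_hbrr")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop_cfg(f, "must lie in [0, 1]")
  }
  fu <- cfg$frac_expressed_uhrr; fh <- cfg$frac_expressed_hbrr
  fb <- cfg$frac_expressed_both
  if (fb > min(fu, fh) + 1e-12 || fb < max(0, fu + fh - 1) - 1e-12)
    stop_cfg("frac_expressed_both", "incompatible with the marginal expressed fractions")
  if (cfg$mm_crosstalk < 0 || cfg$mm_crosstalk >= 1)
    stop_cfg("mm_crosstalk", "must lie in [0, 1)")
  if (cfg$noise_floor <= 0) stop_cfg("noise_floor", "must be positive")
  if (cfg$site_effect_sd < 0) stop_cfg("site_effect_sd", "must be nonnegative")
  if (cfg$replicate_cv < 0) stop_cfg("replicate_cv", "must be nonnegative")
  if (cfg$array_effect_cv < 0) stop_cfg("array_effect_cv", "must be nonnegative")
  if (cfg$block_correlation < 0 || cfg$block_correlation > 1)
    stop_cfg("block_correlation", "must lie in [0, 1]")
  if (cfg$n_array_factors < 1)
    stop_cfg("n_array_factors", "must be a positive integer")
  if (cfg$measurement_cv < 0)
    stop_cfg("measurement_cv", "must be nonnegative")
  if (cfg$expression_floor < 0)
    stop_cfg("expression_floor", "must be nonnegative")
  if (cfg$additive_noise_sd < 0)
    stop_cfg("additive_noise_sd", "must be nonnegative")
  invisible(cfg)
}

# sd of log(X) for a lognormal X with E[X]=1 and the given linear-scale CV
lognormal_sdlog <- function(cv) sqrt(log(1 + cv^2))

# unit-mean multiplicative lognormal noise
rlnorm_unit <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- lognormal_sdlog(cv)
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Generate a seeded MAQC-style probe-level dataset
#'
#' Draws latent linear-scale expression for every probe set once for UHRR and
#' once for HBRR (zero for unexpressed transcripts), forms each pool's latent
#' signal as the linear mixture `mix * UHRR + (1 - mix) * HBRR` (pools are
#' physical RNA mixtures, so mixing happens on the linear scale before any
#' noise), applies per-site-by-probe-set multiplicative effects and
#' per-measurement replicate noise, and renders PM/MM probe intensities with
#' per-probe affinities that are fixed across arrays:
#' `PM = background + affinity * signal`,
#' `MM = background' + mm_crosstalk * affinity * signal`.
#'
#' @param config A [generator_config()].
#' @return A list of class `probe_level_data` with elements
#'   * `probes`: tibble `probe_set_id, probe_pair_index, sample_id, pm, mm`,
#'   * `samples`: tibble `sample_id, site, pool, replicate`,
#'   * `latents`: tibble of per-probe-set latent expression
#'     (`uhrr`, `hbrr`, one column per pool) for verification.
#' @export
generate_dataset <- function(config) {
  validate_generator_config(config)
  withr::with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  G <- cfg$n_probe_sets
  pools <- names(cfg$pool_mixtures)

  # expressed status with the prescribed joint distribution over (UHRR, HBRR)
  p_both <- cfg$frac_expressed_both
  p_u_only <- cfg$frac_expressed_uhrr - p_both
  p_h_only <- cfg$frac_expressed_hbrr - p_both
  cat_probs <- c(both = p_both, u_only = p_u_only, h_only = p_h_only,
                 neither = 1 - p_both - p_u_only - p_h_only)
  category <- sample(names(cat_probs), G, replace = TRUE, prob = cat_probs)
  expr_u <- category %in% c("both", "u_only")
  expr_h <- category %in% c("both", "h_only")

  mlog <- cfg$signal_lognormal_params[[1]]
  slog <- cfg$signal_lognormal_params[[2]]
  lat_u <- ifelse(expr_u, stats::rlnorm(G, mlog, slog), 0)
  lat_h <- ifelse(expr_h, stats::rlnorm(G, mlog, slog), 0)

  probe_set_id <- sprintf("ps%05d", seq_len(G))
  latents <- tibble::tibble(probe_set_id = probe_set_id,
                            uhrr = lat_u, hbrr = lat_h)
  for (p in pools) {
    mix <- cfg$pool_mixtures[[p]]
    latents[[paste0("pool_", p)]] <- mix * lat_u + (1 - mix) * lat_h
  }

  n_pairs <- sample(seq(cfg$probes_per_set_range[1], cfg$probes_per_set_range[2]),
                    G, replace = TRUE)
  # per-probe affinities, lognormal, fixed across arrays
  affinity <- rlnorm_unit(sum(n_pairs), cv = 0.4)

  samples <- tidyr::expand_grid(
    site = sprintf("site%d", seq_len(cfg$n_sites)),
    pool = pools,
    replicate = seq_len(cfg$n_replicates)
  )
  samples$sample_id <- sprintf("%s_%s_r%d", samples$site, samples$pool,
                               samples$replicate)
  samples <- samples[, c("sample_id", "site", "pool", "replicate")]

  # site effects: per site x probe set, multiplicative lognormal
  site_eff <- matrix(
    stats::rlnorm(cfg$n_sites * G, -cfg$site_effect_sd^2 / 2, cfg$site_effect_sd),
    nrow = G, ncol = cfg$n_sites,
    dimnames = list(probe_set_id, sprintf("site%d", seq_len(cfg$n_sites)))
  )
  pool_latent <- as.matrix(latents[paste0("pool_", pools)])
  colnames(pool_latent) <- pools

  set_index <- rep(seq_len(G), times = n_pairs)
  pair_index <- sequence(n_pairs)
  n_probes <- length(set_index)
  S <- nrow(samples)

  array_factor <- rlnorm_unit(S, cfg$array_effect_cv)
  per_sample <- vector("list", S)
  for (s in seq_len(S)) {
    sm <- samples[s, ]
    signal_set <- pool_latent[, sm$pool] * site_eff[, sm$site]
    sig <- array_factor[s] * affinity * signal_set[set_index] *
      rlnorm_unit(n_probes, cfg$replicate_cv)
    bg_pm <- cfg$noise_floor * rlnorm_unit(n_probes, cfg$background_cv)
    bg_mm <- cfg$noise_floor * rlnorm_unit(n_probes, cfg$background_cv)
    per_sample[[s]] <- tibble::tibble(
      probe_set_id = probe_set_id[set_index],
      probe_pair_index = pair_index,
      sample_id = sm$sample_id,
      pm = bg_pm + sig,
      mm = bg_mm + cfg$mm_crosstalk * sig
    )
  }

  structure(
    list(probes = dplyr::bind_rows(per_sample), samples = samples,
         latents = latents),
    class = "probe_level_data"
  )
}

#' @export
print.probe_level_data <- function(x, ...) {
  cat(sprintf(
    "<probe_level_data> %d probe sets, %d arrays (%d sites x %d pools x %d reps)\n",
    dplyr::n_distinct(x$probes$probe_set_id), nrow(x$samples),
    dplyr::n_distinct(x$samples$site), dplyr::n_distinct(x$samples$pool),
    max(x$samples$replicate)
  ))
  invisible(x)
}

#' Generate a complete expression matrix directly
#'
#' Shortcut generator that skips the probe level: returns a complete positive
#' genes-by-samples matrix for a single site-by-pool cell. Replicate arrays
#' differ by an overall multiplicative scale (`array_effect_cv`) and by
#' `n_array_factors` systematic technical factors; every gene responds to the
#' factors with its own loading vector of overall magnitude `replicate_cv`
#' (log scale). Loadings are correlated `block_correlation` within blocks of
#' `block_size` genes, giving the correlated gene clusters of real arrays;
#' at correlation 1 (and zero measurement noise) rows within a block are
#' exactly proportional. On top sits purely idiosyncratic per-cell
#' measurement noise (`measurement_cv`), the irreducible error floor. With
#' all four noise terms zero the replicate columns are identical.
#'
#' @param config A [generator_config()]; fields used: `n_probe_sets` (rows),
#'   `n_replicates` (columns), `signal_lognormal_params`, `replicate_cv`,
#'   `array_effect_cv`, `n_array_factors`, `measurement_cv`, `block_size`,
#'   `block_correlation`, `seed`.
#' @return Numeric matrix with rownames `ps*` and colnames `rep*`.
#' @export
generate_expression_matrix <- function(config) {
  validate_generator_config(config)
  withr::with_seed(config$seed, {
    G <- config$n_probe_sets
    S <- config$n_replicates
    q <- config$n_array_factors
    mlog <- config$signal_lognormal_params[[1]]
    slog <- config$signal_lognormal_params[[2]]
    # detection-filtered matrices carry no low-intensity tail: draw the
    # latent level from the lognormal truncated at expression_floor
    p_lo <- stats::plnorm(config$expression_floor, mlog, slog)
    base <- stats::qlnorm(stats::runif(G, p_lo, 1), mlog, slog)
    block <- (seq_len(G) - 1L) %/% config$block_size + 1L
    n_block <- max(block)
    s_rep <- lognormal_sdlog(config$replicate_cv)
    rho <- config$block_correlation
    # per-array factor scores with a harmonically decaying amplitude
    # spectrum (one dominant technical factor, progressively smaller ones),
    # normalized so the total factor variance is replicate_cv^2
    decay <- 1 / seq_len(q)
    decay <- decay * sqrt(q / sum(decay^2))
    u <- decay * matrix(stats::rnorm(q * S), q, S)
    w_block <- matrix(stats::rnorm(n_block * q, sd = sqrt(1 / q)), n_block, q)
    w_gene <- matrix(stats::rnorm(G * q, sd = sqrt(1 / q)), G, q)
    w <- sqrt(rho) * w_block[block, , drop = FALSE] + sqrt(1 - rho) * w_gene
    logn <- s_rep * (w %*% u) - s_rep^2 / 2
    meas <- matrix(rlnorm_unit(G * S, config$measurement_cv), G, S)
    array_factor <- rlnorm_unit(S, config$array_effect_cv)
    m <- base * exp(logn) * meas * rep(array_factor, each = G)
    if (config$additive_noise_sd > 0) {
      add <- matrix(stats::rnorm(G * S, 0, config$additive_noise_sd), G, S)
      m <- pmax(m + add, 0.5)
    }
    dimnames(m) <- list(sprintf("ps%05d", seq_len(G)), sprintf("rep%d", seq_len(S)))
    m
  })
}

#' Write / read the probe-level TSV pair
#'
#' Long-format probe-level table (`probe_set_id probe_pair_index sample_id pm
#' mm`) and companion sample sheet (`sample_id site pool replicate`).
#'
#' @param data A `probe_level_data` object.
#' @param prefix Output path prefix; writes `<prefix>_probes.tsv` and
#'   `<prefix>_samples.tsv`.
#' @return `prefix`, invisibly.
#' @export
write_probe_level <- function(data, prefix) {
  readr::write_tsv(data$probes, paste0(prefix, "_probes.tsv"))
  readr::write_tsv(data$samples, paste0(prefix, "_samples.tsv"))
  invisible(prefix)
}

#' @rdname write_probe_level
#' @export
read_probe_level <- function(prefix) {
  structure(
    list(
      probes = readr::read_tsv(paste0(prefix, "_probes.tsv"),
                               show_col_types = FALSE),
      samples = readr::read_tsv(paste0(prefix, "_samples.tsv"),
                                show_col_types = FALSE),
      latents = NULL
    ),
    class = "probe_level_data"
  )
}

#' Write / read an expression matrix TSV
#'
#' First column `probe_set_id`, remaining columns one per array, values
#' positive reals; missing cells encoded as `NA`.
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output TSV path.
#' @return `path` (write) or a numeric matrix (read).
#' @export
write_expression_matrix <- function(m, path) {
  df <- tibble::as_tibble(m, rownames = "probe_set_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}
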