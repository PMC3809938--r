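#' Full-study configuration
#'
#' Bundles every stage's parameters for [run_study()]: generator, detection,
#' preprocessing, evaluation, the imputation method list, and the deletion
#' fractions.
#'
#' @param generator A [generator_config()].
#' @param detection A [detection_params()].
#' @param preprocess A [preprocess_params()].
#' @param eval A [eval_config()] (its `deletion_fraction` is overridden per
#'   entry of `deletion_fractions`).
#' @param methods List of [method_config()]s with unique labels (default the
#'   ten of [table1_methods()]).
#' @param deletion_fractions Numeric vector of deletion fractions in (0, 1)
#'   (default `c(0.05, 0.10)`).
#' @param seed Master seed; stage seeds derive from it.
#' @return Object of class `study_config`.
#' @export
study_config <- function(generator = generator_config(),
                         detection = detection_params(),
                         preprocess = preprocess_params(),
                         eval = eval_config(),
                         methods = table1_methods(),
                         deletion_fractions = c(0.05, 0.10),
                         seed = 1L) {
  labels <- vapply(methods, function(m) m$label, "")
  if (anyDuplicated(labels))
    stop("method labels must be unique", call. = FALSE)
  if (any(deletion_fractions <= 0 | deletion_fractions >= 1))
    stop("deletion fractions must lie in (0, 1)", call. = FALSE)
  structure(
    list(generator = generator, detection = detection,
         preprocess = preprocess, eval = eval, methods = methods,
         deletion_fractions = deletion_fractions, seed = as.integer(seed)),
    class = "study_config"
  )
}

# stable small-integer seed for a site/pool cell, independent of execution order
cell_seed <- function(master, site, pool) {
  h <- sum(utf8ToInt(paste(site, pool, sep = "/")) *
             seq_along(utf8ToInt(paste(site, pool, sep = "/"))))
  bitwXor(as.integer(master), as.integer(h %% 1000003L))
}

#' Run the end-to-end imputation study
#'
#' Executes every stage per site-by-pool cell: generate the probe-level
#' dataset, make detection calls, filter to the probe sets Present in all
#' replicates of the cell, summarize and scale-normalize to a complete
#' expression matrix, then for each deletion fraction run the Monte-Carlo
#' benchmark over all configured methods and aggregate the ranks into one
#' rank table per fraction. All outputs are written as TSV under
#' `output_dir`, together with a JSON manifest from which the whole run can
#' be reproduced bit-for-bit.
#'
#' @param cfg A [study_config()].
#' @param output_dir Writable output directory (created if needed).
#' @return Invisibly, a list with `percent_present`, `retained` (named list
#'   of probe-set id vectors per cell), `matrices` (named list of complete
#'   matrices), `reports` (benchmark tibble), `rank_tables` (one
#'   `rank_table` per deletion fraction), `manifest_path`.
#' @export
run_study <- function(cfg, output_dir) {
  stopifnot(inherits(cfg, "study_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  gen_cfg <- cfg$generator
  gen_cfg$seed <- bitwXor(cfg$seed, 97L)
  data <- generate_dataset(gen_cfg)
  calls <- detect(data, cfg$detection)
  pp <- percent_present(calls, data$samples)
  readr::write_tsv(pp$per_array, file.path(output_dir, "percent_present.tsv"))

  cells <- unique(data$samples[, c("site", "pool")])
  retained <- list()
  matrices <- list()
  dir.create(file.path(output_dir, "expression"), showWarnings = FALSE)
  for (i in seq_len(nrow(cells))) {
    site <- cells$site[i]; pool <- cells$pool[i]
    key <- paste(site, pool, sep = "_")
    keep <- filter_complete(calls, data$samples, site, pool)
    if (length(keep) < 2)
      stop(sprintf("stage filter failed for cell %s: fewer than 2 probe sets retained",
                   key), call. = FALSE)
    retained[[key]] <- keep
    arrays <- data$samples$sample_id[data$samples$site == site &
                                       data$samples$pool == pool]
    mat <- summarize_expression(data, keep, cfg$preprocess, samples = arrays)
    mat <- scale_normalize(mat, cfg$preprocess)
    attr(mat, "scale_factors") <- NULL
    matrices[[key]] <- mat
    write_expression_matrix(mat, file.path(output_dir, "expression",
                                           paste0(key, ".tsv")))
    writeLines(keep, file.path(output_dir, "expression",
                               paste0(key, "_retained.txt")))
  }

  all_reports <- list()
  rank_tables <- list()
  for (frac in cfg$deletion_fractions) {
    frac_key <- sprintf("%g", frac)
    reports <- purrr::imap(matrices, function(mat, key) {
      parts <- strsplit(key, "_")[[1]]
      ec <- cfg$eval
      ec$deletion_fraction <- frac
      ec$seed <- cell_seed(cfg$seed, parts[1], parts[2])
      run_benchmark(mat, cfg$methods, ec, site = parts[1], pool = parts[2])
    }) |> dplyr::bind_rows()
    readr::write_tsv(reports,
                     file.path(output_dir, sprintf("results_%s.tsv", frac_key)))
    rt <- aggregate_ranks(suppressMessages(average_over_sims(reports)))
    readr::write_tsv(rt,
                     file.path(output_dir, sprintf("ranks_%s.tsv", frac_key)))
    all_reports[[frac_key]] <- dplyr::mutate(reports, deletion_fraction = frac)
    rank_tables[[frac_key]] <- rt
  }

  manifest <- list(
    package = "imputebench",
    version = as.character(utils::packageVersion("imputebench")),
    seed = cfg$seed,
    config = serialize_study_config(cfg),
    n_cells = length(matrices),
    retained_counts = vapply(retained, length, 1L)
  )
  manifest_path <- file.path(output_dir, "manifest.json")
  # 17 significant digits: doubles survive the JSON round-trip bit-for-bit
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)

  invisible(list(percent_present = pp, retained = retained,
                 matrices = matrices,
                 reports = dplyr::bind_rows(all_reports),
                 rank_tables = rank_tables, manifest_path = manifest_path))
}

serialize_study_config <- function(cfg) {
  gen <- unclass(cfg$generator)
  # keep the names of named vectors through JSON (objects, not arrays)
  gen$pool_mixtures <- as.list(gen$pool_mixtures)
  gen$signal_lognormal_params <- as.list(
    stats::setNames(gen$signal_lognormal_params, c("meanlog", "sdlog")))
  list(
    generator = gen,
    detection = unclass(cfg$detection),
    preprocess = unclass(cfg$preprocess),
    eval = Filter(Negate(is.null), unclass(cfg$eval)),
    methods = lapply(cfg$methods,
                     function(m) Filter(Negate(is.null), unclass(m))),
    deletion_fractions = cfg$deletion_fractions,
    seed = cfg$seed
  )
}

#' Rebuild a study configuration from a run manifest
#'
#' Reads the JSON manifest written by [run_study()] and reconstructs the
#' `study_config`, so the run can be reproduced exactly.
#'
#' @param path Path to `manifest.json`.
#' @return A [study_config()].
#' @export
read_manifest <- function(path) {
  mf <- jsonlite::read_json(path, simplifyVector = TRUE)
  cf <- mf$config
  gen <- cf$generator
  gen$pool_mixtures <- unlist(gen$pool_mixtures)
  gen$signal_lognormal_params <- unlist(gen$signal_lognormal_params)
  gen$probes_per_set_range <- as.integer(unlist(gen$probes_per_set_range))
  generator <- do.call(generator_config, gen)
  detection <- do.call(detection_params, cf$detection)
  preprocess <- do.call(preprocess_params, cf$preprocess)
  drop_empty <- function(x)
    x[!vapply(x, function(v) is.null(v) || (is.list(v) && length(v) == 0),
              TRUE)]
  eval_cfg <- do.call(eval_config, drop_empty(cf$eval))
  methods <- lapply(cf$methods, function(mc)
    do.call(method_config, drop_empty(mc)))
  study_config(generator = generator, detection = detection,
               preprocess = preprocess, eval = eval_cfg, methods = methods,
               deletion_fractions = unlist(cf$deletion_fractions),
               seed = cf$seed)
}
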