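#' Imputation method configuration
#'
#' Describes one imputation method and its tuning parameters. The ten
#' canonical configurations of the benchmark are produced by
#' [table1_methods()].
#'
#' @param method One of `"ROW"`, `"KNN"`, `"SVD"`, `"LSA"`, `"LLS"`,
#'   `"BPCA"`, `"NIPALS"`.
#' @param k Neighbor count (KNN) or regression cluster size (LLS). For LLS,
#'   `k` must be less than the number of columns.
#' @param distance KNN distance: `"euclidean"` (default; reported the more
#'   accurate choice) or `"pearson"` (`1 - |r|`).
#' @param n_components Number of eigen genes / principal components
#'   (SVD, NIPALS, BPCA). `NULL` means the method default: 2 for SVD and
#'   NIPALS, `ncol - 1` for BPCA.
#' @param convergence_threshold Convergence threshold. For SVD this is the
#'   total absolute change in the matrix (default 0.01 on the expression
#'   scale); for BPCA/NIPALS it is relative to the observed value scale
#'   (default 1e-4).
#' @param max_iter Iteration cap (default 200).
#' @param lsa_n_genes Neighbors used by the LSA gene-based estimate
#'   (default 10).
#' @param lsa_probe_fraction Fraction of observed cells hidden to calibrate
#'   the LSA adaptive mixing weight (default 0.05).
#' @param seed Integer seed for the method's stochastic steps (BPCA
#'   initialization jitter, LSA probe set).
#' @param label Display label; defaults to the method name.
#' @return Object of class `method_config`.
#' @export
method_config <- function(method, k = NULL, distance = "euclidean",
                          n_components = NULL, convergence_threshold = NULL,
                          max_iter = 200L, lsa_n_genes = 10L,
                          lsa_probe_fraction = 0.05, seed = 1L,
                          label = NULL) {
  methods <- c("ROW", "KNN", "SVD", "LSA", "LLS", "BPCA", "NIPALS")
  if (!method %in% methods)
    stop("unknown imputation method: ", method, call. = FALSE)
  if (!distance %in% c("euclidean", "pearson"))
    stop("unknown KNN distance: ", distance, call. = FALSE)
  if (method %in% c("KNN", "LLS") && (is.null(k) || k < 1))
    stop(method, " requires k >= 1", call. = FALSE)
  structure(
    list(method = method, k = k, distance = distance,
         n_components = n_components,
         convergence_threshold = convergence_threshold,
         max_iter = as.integer(max_iter), lsa_n_genes = as.integer(lsa_n_genes),
         lsa_probe_fraction = lsa_probe_fraction, seed = as.integer(seed),
         label = label %||% method),
    class = "method_config"
  )
}

#' The ten canonical benchmark configurations
#'
#' ROW, KNN with k = 1 and 5 (Euclidean), SVD, LSA, LLS with k = 1, 3, 4,
#' BPCA, and NIPALS — the ten rows of the benchmark's rank table.
#'
#' @param seed Base seed stored in each configuration.
#' @return Named list of [method_config()] objects, names
#'   `BPCA, KNN1, KNN5, LLS1, LLS3, LLS4, LSA, NIPALS, ROW, SVD`.
#' @export
table1_methods <- function(seed = 1L) {
  cfgs <- list(
    BPCA = method_config("BPCA", seed = seed, label = "BPCA"),
    KNN1 = method_config("KNN", k = 1, seed = seed, label = "KNN1"),
    KNN5 = method_config("KNN", k = 5, seed = seed, label = "KNN5"),
    LLS1 = method_config("LLS", k = 1, seed = seed, label = "LLS1"),
    LLS3 = method_config("LLS", k = 3, seed = seed, label = "LLS3"),
    LLS4 = method_config("LLS", k = 4, seed = seed, label = "LLS4"),
    LSA = method_config("LSA", seed = seed, label = "LSA"),
    NIPALS = method_config("NIPALS", seed = seed, label = "NIPALS"),
    ROW = method_config("ROW", seed = seed, label = "ROW"),
    SVD = method_config("SVD", seed = seed, label = "SVD")
  )
  cfgs
}

new_imputed <- function(values, m, cfg_or_label, iterations = 0L,
                        converged = TRUE) {
  # observed entries are always returned untouched
  values[!m$mask] <- m$values[!m$mask]
  stopifnot(!anyNA(values))
  structure(
    list(values = values, method = if (is.character(cfg_or_label))
      cfg_or_label else cfg_or_label$label,
      config = if (is.character(cfg_or_label)) NULL else cfg_or_label,
      iterations = as.integer(iterations), converged = converged),
    class = "imputed_matrix"
  )
}

#' @export
print.imputed_matrix <- function(x, ...) {
  cat(sprintf("<imputed_matrix> %s: %d x %d, %d iterations, converged: %s\n",
              x$method, nrow(x$values), ncol(x$values), x$iterations,
              x$converged))
  invisible(x)
}

#' @rdname tidy.masked_matrix
#' @export
tidy.imputed_matrix <- function(x, ...) {
  tibble::tibble(
    probe_set_id = rownames(x$values) %||% sprintf("g%d", seq_len(nrow(x$values))),
  ) |>
    tidyr::expand_grid(sample_id = colnames(x$values) %||%
                         sprintf("s%d", seq_len(ncol(x$values)))) |>
    dplyr::mutate(value = as.vector(t(x$values))) |>
    dplyr::arrange(.data$sample_id)
}

#' One-line summary of an imputation result
#'
#' @param x An `imputed_matrix`.
#' @param ... Unused.
#' @return One-row tibble: `method, n_row, n_col, n_imputed, iterations,
#'   converged`.
#' @export
glance.imputed_matrix <- function(x, ...) {
  tibble::tibble(method = x$method, n_row = nrow(x$values),
                 n_col = ncol(x$values),
                 iterations = x$iterations, converged = x$converged)
}

# Moore-Penrose pseudoinverse via SVD (rank-deficiency safe)
pinv <- function(a, tol = 1e-10) {
  s <- svd(a)
  keep <- s$d > tol * max(s$d, 1e-300)
  if (!any(keep)) return(matrix(0, ncol(a), nrow(a)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

row_means_observed <- function(values, mask) {
  rm <- rowMeans(values, na.rm = TRUE)
  if (any(!is.finite(rm))) {
    gm <- mean(values[!mask])
    rm[!is.finite(rm)] <- gm
  }
  rm
}

#' Row-average imputation
#'
#' Each missing entry is replaced by the mean of the observed entries in its
#' row; a fully missing row falls back to the overall observed mean (logged).
#'
#' @param m A `masked_matrix` (or numeric matrix with `NA`s).
#' @return An `imputed_matrix`.
#' @export
impute_row_average <- function(m) {
  m <- as_masked_matrix(m)
  out <- m$values
  if (any(m$mask)) {
    empty <- rowSums(!m$mask) == 0
    if (any(empty))
      message(sum(empty), " fully missing row(s) filled with the global mean")
    rm <- row_means_observed(m$values, m$mask)
    idx <- which(m$mask, arr.ind = TRUE)
    out[idx] <- rm[idx[, 1]]
  }
  new_imputed(out, m, "ROW")
}

#' k-nearest-neighbor imputation
#'
#' For each missing cell (g, s), candidate neighbors are the other rows
#' observed at column s; the distance between two rows is computed over the
#' columns observed in both — root mean squared difference (`euclidean`) or
#' `1 - |Pearson r|` (`pearson`) — so rows with different overlap sizes are
#' comparable. The missing value is the unweighted mean of the k nearest
#' candidates' values at s; ties in distance break by row order. With fewer
#' than k candidates all are used; with none, the row average steps in.
#'
#' @inheritParams impute_row_average
#' @param k Number of neighbors.
#' @param distance `"euclidean"` or `"pearson"`.
#' @return An `imputed_matrix`.
#' @export
impute_knn <- function(m, k = 1, distance = "euclidean") {
  m <- as_masked_matrix(m)
  out <- m$values
  if (!any(m$mask)) return(new_imputed(out, m, paste0("KNN", k)))
  if (nrow(out) < 2) {
    warning("matrix has a single row; falling back to row average")
    res <- impute_row_average(m)
    return(new_imputed(res$values, m, paste0("KNN", k)))
  }
  rm_fallback <- row_means_observed(m$values, m$mask)
  target_rows <- which(rowSums(m$mask) > 0)
  for (g in target_rows) {
    og <- which(!m$mask[g, ])
    if (length(og) == 0) {            # fully missing row
      out[g, m$mask[g, ]] <- rm_fallback[g]
      next
    }
    sub <- m$values[, og, drop = FALSE]
    xg <- m$values[g, og]
    if (distance == "euclidean") {
      d <- sqrt(rowMeans((sub - rep(xg, each = nrow(sub)))^2, na.rm = TRUE))
    } else {
      r <- suppressWarnings(
        stats::cor(xg, t(sub), use = "pairwise.complete.obs")
      )[1, ]
      d <- 1 - abs(r)
    }
    overlap <- rowSums(!is.na(sub) & rep(TRUE, nrow(sub)))
    d[!is.finite(d)] <- NA
    d[g] <- NA
    for (s in which(m$mask[g, ])) {
      cand <- which(!m$mask[, s] & !is.na(d))
      if (length(cand) == 0) {
        out[g, s] <- rm_fallback[g]
        next
      }
      ord <- cand[order(d[cand], cand)]
      use <- ord[seq_len(min(k, length(ord)))]
      out[g, s] <- mean(m$values[use, s])
    }
  }
  new_imputed(out, m, paste0("KNN", k))
}

#' SVD (eigen-gene) imputation
#'
#' EM loop of the classic SVD imputation: missing cells start at the row
#' average; each iteration takes the top `n_components` right-singular
#' vectors (eigen genes) of the completed matrix, least-squares regresses
#' every incomplete row's observed entries on the eigen genes restricted to
#' the observed columns (pseudoinverse, no intercept), and re-estimates the
#' missing entries from the fit, until the total absolute change in the
#' matrix falls below the threshold (default 0.01) or `max_iter`.
#'
#' @inheritParams impute_row_average
#' @param n_components Number of eigen genes (must be `< min(dim)`).
#' @param threshold Total-absolute-change stopping threshold.
#' @param max_iter Iteration cap.
#' @return An `imputed_matrix` (with `converged` flag).
#' @export
impute_svd <- function(m, n_components = 2, threshold = 0.01,
                       max_iter = 200) {
  m <- as_masked_matrix(m)
  if (!any(m$mask)) return(new_imputed(m$values, m, "SVD"))
  if (n_components < 1 || n_components >= min(dim(m$values)))
    stop("n_components must satisfy 1 <= n_components < min(G, S)",
         call. = FALSE)
  filled <- impute_row_average(m)$values
  target_rows <- which(rowSums(m$mask) > 0)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    sv <- svd(filled, nu = 0, nv = n_components)
    v <- sv$v
    old <- filled
    for (g in target_rows) {
      og <- which(!m$mask[g, ])
      mg <- which(m$mask[g, ])
      if (length(og) == 0) next     # fully missing row: keep row-average fill
      coef <- pinv(v[og, , drop = FALSE]) %*% m$values[g, og]
      filled[g, mg] <- v[mg, , drop = FALSE] %*% coef
    }
    if (sum(abs(filled - old)) < threshold) {
      converged <- TRUE
      break
    }
  }
  new_imputed(filled, m, "SVD", iterations = iter, converged = converged)
}

#' Local least squares imputation
#'
#' For a target row with observed columns O and missing columns M, the k
#' rows most |Pearson|-correlated with the target over O — among rows
#' observed on all columns — are the neighbors. The coefficients solve the
#' least squares problem `min || A' x - w ||` with `A` the neighbors on O
#' and `w` the target on O (pseudoinverse, no intercept); the imputation is
#' `B' x` with `B` the neighbors on M. Anticorrelated neighbors are ranked
#' by |r| and enter with negative coefficients. Requires `k < ncol`.
#'
#' Because the most-correlated neighbors of expression data are often nearly
#' collinear, the pseudoinverse truncates singular values below `rcond_tol`
#' times the largest one; directions at the noise level would otherwise
#' amplify measurement noise without constraining the fit.
#'
#' @inheritParams impute_row_average
#' @param k Cluster size (number of neighbor rows in the regression).
#' @param rcond_tol Relative singular-value cutoff of the pseudoinverse.
#' @return An `imputed_matrix`.
#' @export
impute_lls <- function(m, k = 1, rcond_tol = 0.05) {
  m <- as_masked_matrix(m)
  S <- ncol(m$values)
  if (k >= S)
    stop("LLS restricts k to be less than the number of replicates/columns (k < ",
         S, ")", call. = FALSE)
  out <- m$values
  if (!any(m$mask)) return(new_imputed(out, m, paste0("LLS", k)))
  complete_rows <- which(rowSums(m$mask) == 0)
  rm_fallback <- row_means_observed(m$values, m$mask)
  target_rows <- which(rowSums(m$mask) > 0)
  n_fallback <- 0
  for (g in target_rows) {
    og <- which(!m$mask[g, ])
    mg <- which(m$mask[g, ])
    cand <- setdiff(complete_rows, g)
    r <- NULL
    if (length(og) >= 2 && length(cand) > 0) {
      r <- suppressWarnings(stats::cor(
        m$values[g, og],
        t(m$values[cand, og, drop = FALSE])
      ))[1, ]
      cand <- cand[is.finite(r)]
      r <- r[is.finite(r)]
    }
    if (is.null(r) || length(cand) == 0) {
      out[g, mg] <- rm_fallback[g]
      n_fallback <- n_fallback + 1
      next
    }
    ord <- order(-abs(r), cand)
    nb <- cand[ord][seq_len(min(k, length(cand)))]
    a <- m$values[nb, og, drop = FALSE]              # k x |O|
    b <- m$values[nb, mg, drop = FALSE]              # k x |M|
    x <- pinv(t(a), tol = rcond_tol) %*% m$values[g, og]
    out[g, mg] <- as.vector(t(b) %*% x)
  }
  if (n_fallback > 0)
    message(n_fallback, " row(s) without valid LLS neighbors used the row average")
  new_imputed(out, m, paste0("LLS", k))
}

# closed-form minimizer of sum((p*a + (1-p)*b - y)^2) over p, clipped to [0,1]
optimal_mix_weight <- function(a, b, y) {
  keep <- is.finite(a) & is.finite(b) & is.finite(y)
  a <- a[keep]; b <- b[keep]; y <- y[keep]
  den <- sum((a - b)^2)
  if (length(a) == 0 || den == 0) return(0.5)
  min(1, max(0, sum((y - b) * (a - b)) / den))
}

lsa_weight <- function(r) (r^2 / (1 - r^2 + 1e-6))^2

# gene-based estimate for all missing cells of row g; returns list(pred, rstar)
lsa_gene_estimate <- function(values, mask, g, complete_rows, n_genes) {
  og <- which(!mask[g, ])
  mg <- which(mask[g, ])
  cand <- setdiff(complete_rows, g)
  if (length(og) < 2 || length(cand) == 0)
    return(list(pred = rep(NA_real_, length(mg)), rstar = NA_real_))
  w <- values[g, og]
  r <- suppressWarnings(stats::cor(w, t(values[cand, og, drop = FALSE])))[1, ]
  ok <- is.finite(r)
  cand <- cand[ok]; r <- r[ok]
  if (length(cand) == 0)
    return(list(pred = rep(NA_real_, length(mg)), rstar = NA_real_))
  ord <- order(-abs(r), cand)
  take <- ord[seq_len(min(n_genes, length(ord)))]
  nb <- cand[take]; rj <- r[take]
  # univariate regressions of the target on each neighbor over O
  preds <- matrix(NA_real_, length(nb), length(mg))
  for (i in seq_along(nb)) {
    xj <- values[nb[i], og]
    vx <- stats::var(xj)
    bcoef <- if (vx > 0) stats::cov(xj, w) / vx else 0
    acoef <- mean(w) - bcoef * mean(xj)
    preds[i, ] <- acoef + bcoef * values[nb[i], mg]
  }
  wj <- lsa_weight(pmin(abs(rj), 1 - 1e-9))
  if (sum(wj) == 0) wj <- rep(1, length(wj))
  list(pred = as.vector(crossprod(preds, wj) / sum(wj)),
       rstar = max(abs(rj)))
}

# per-ordered-column-pair univariate regressions (target column ~ source
# column over rows complete in both); computed once per imputation pass
lsa_column_regressions <- function(values, mask) {
  S <- ncol(values)
  acoef <- matrix(NA_real_, S, S)
  bcoef <- matrix(NA_real_, S, S)
  wt <- matrix(NA_real_, S, S)
  for (s in seq_len(S)) {
    for (s2 in seq_len(S)) {
      if (s == s2) next
      rows <- which(!mask[, s] & !mask[, s2])
      if (length(rows) < 3) next
      x <- values[rows, s2]; y <- values[rows, s]
      vx <- stats::var(x)
      if (!is.finite(vx) || vx == 0) next
      r <- suppressWarnings(stats::cor(x, y))
      if (!is.finite(r)) next
      bcoef[s, s2] <- stats::cov(x, y) / vx
      acoef[s, s2] <- mean(y) - bcoef[s, s2] * mean(x)
      wt[s, s2] <- lsa_weight(min(abs(r), 1 - 1e-9))
    }
  }
  list(a = acoef, b = bcoef, w = wt)
}

# array-based estimate for one missing cell (g, s) from precomputed fits
lsa_array_estimate <- function(values, mask, g, s, colreg) {
  s2s <- which(!mask[g, ] & is.finite(colreg$b[s, ]))
  if (length(s2s) == 0) return(NA_real_)
  preds <- colreg$a[s, s2s] + colreg$b[s, s2s] * values[g, s2s]
  ws <- colreg$w[s, s2s]
  if (sum(ws) == 0) ws <- rep(1, length(ws))
  sum(ws * preds) / sum(ws)
}

# both LSA estimates for every missing cell of `mask`, using `values`
lsa_estimates <- function(values, mask, n_genes) {
  complete_rows <- which(rowSums(mask) == 0)
  colreg <- lsa_column_regressions(values, mask)
  cells <- which(mask, arr.ind = TRUE)
  gene_est <- rep(NA_real_, nrow(cells))
  array_est <- rep(NA_real_, nrow(cells))
  rstar <- rep(NA_real_, nrow(cells))
  for (g in unique(cells[, 1])) {
    sel <- which(cells[, 1] == g)
    ge <- lsa_gene_estimate(values, mask, g, complete_rows, n_genes)
    gene_est[sel] <- ge$pred
    rstar[sel] <- ge$rstar
    for (j in sel)
      array_est[j] <- lsa_array_estimate(values, mask, g, cells[j, 2], colreg)
  }
  tibble::tibble(row = cells[, 1], col = cells[, 2],
                 gene = gene_est, array = array_est, rstar = rstar)
}

#' Least squares adaptive imputation
#'
#' Combines a gene-based estimate (weighted univariate regressions on the
#' most-correlated complete rows, weights `(r^2/(1-r^2))^2`) with an
#' array-based estimate (weighted univariate regressions of the target
#' column on the other columns). The mixing weight `p` in
#' `p * gene + (1 - p) * array` is calibrated adaptively: an additional
#' probe set of observed cells (fraction `lsa_probe_fraction`, seeded) is
#' hidden, both estimates are computed there against known truth, probes
#' are binned by the strength of their best gene correlation `r*`
#' (quartile bins), and each bin's `p` minimizes the squared error in
#' closed form, clipped to `[0, 1]`.
#'
#' @inheritParams impute_row_average
#' @param cfg A [method_config()] with `method = "LSA"` (fields used:
#'   `lsa_n_genes`, `lsa_probe_fraction`, `seed`).
#' @return An `imputed_matrix`.
#' @export
impute_lsa <- function(m, cfg = method_config("LSA")) {
  m <- as_masked_matrix(m)
  out <- m$values
  if (!any(m$mask)) return(new_imputed(out, m, "LSA"))
  est <- lsa_estimates(m$values, m$mask, cfg$lsa_n_genes)

  # calibrate the adaptive weight on a hidden probe set of observed cells
  obs_cells <- which(!m$mask)
  n_probe <- max(4, round(cfg$lsa_probe_fraction * length(obs_cells)))
  n_probe <- min(n_probe, length(obs_cells) - 1)
  probe_cells <- withr::with_seed(cfg$seed,
                                  sample(obs_cells, n_probe))
  probe_values <- m$values
  probe_values[probe_cells] <- NA
  probe_mask <- is.na(probe_values)
  pest <- lsa_estimates(probe_values, probe_mask, cfg$lsa_n_genes)
  pest$truth <- m$values[cbind(pest$row, pest$col)]
  # keep only the probe cells (originally observed), not the real missing cells
  pest <- pest[!m$mask[cbind(pest$row, pest$col)], ]
  pest <- pest[is.finite(pest$truth), ]

  # quartile bins of the gene-correlation strength
  br <- stats::quantile(pest$rstar, probs = c(0.25, 0.5, 0.75), na.rm = TRUE)
  bin_of <- function(r) {
    b <- findInterval(r, unique(br)) + 1L
    b[!is.finite(r)] <- NA_integer_
    b
  }
  pest$bin <- bin_of(pest$rstar)
  p_bin <- rep(0.5, length(unique(br)) + 1L)
  for (b in seq_along(p_bin)) {
    sel <- pest$bin == b & is.finite(pest$gene) & is.finite(pest$array)
    sel[is.na(sel)] <- FALSE
    if (any(sel))
      p_bin[b] <- optimal_mix_weight(pest$gene[sel], pest$array[sel],
                                     pest$truth[sel])
  }

  est$bin <- bin_of(est$rstar)
  rm_fallback <- row_means_observed(m$values, m$mask)
  fill <- numeric(nrow(est))
  for (j in seq_len(nrow(est))) {
    ge <- est$gene[j]; ae <- est$array[j]
    if (is.finite(ge) && is.finite(ae)) {
      p <- if (is.na(est$bin[j])) 0.5 else p_bin[est$bin[j]]
      fill[j] <- p * ge + (1 - p) * ae
    } else if (is.finite(ge)) {
      fill[j] <- ge
    } else if (is.finite(ae)) {
      fill[j] <- ae
    } else {
      fill[j] <- rm_fallback[est$row[j]]
    }
  }
  out[cbind(est$row, est$col)] <- fill
  new_imputed(out, m, "LSA")
}

#' Bayesian PCA imputation
#'
#' Fits the probabilistic PCA model `y = W x + mu + eps` (isotropic Gaussian
#' noise) by an EM/variational scheme with an automatic-relevance-
#' determination prior on the columns of W, so superfluous components are
#' shrunk away and the effective dimensionality is selected by the data.
#' Missing entries are replaced each iteration by their posterior mean under
#' the current model. Initialization is the SVD of the row-average-filled
#' matrix plus seeded jitter, so runs are deterministic given `seed`.
#'
#' @inheritParams impute_row_average
#' @param n_components Latent dimensionality (default `ncol - 1`).
#' @param max_iter Iteration cap.
#' @param tol Convergence threshold on the maximum absolute change of the
#'   imputed values, relative to the observed value scale.
#' @param seed Seed for the initialization jitter.
#' @return An `imputed_matrix` (with `converged` flag).
#' @export
impute_bpca <- function(m, n_components = NULL, max_iter = 200, tol = 1e-4,
                        seed = 1L) {
  m <- as_masked_matrix(m)
  if (!any(m$mask)) return(new_imputed(m$values, m, "BPCA"))
  D <- ncol(m$values)
  N <- nrow(m$values)
  q <- n_components %||% (D - 1L)
  if (q < 1 || q > D - 1)
    stop("BPCA requires 1 <= n_components <= ncol - 1", call. = FALSE)
  scale_obs <- mean(abs(m$values[!m$mask]))
  filled <- impute_row_average(m)$values
  mu <- colMeans(filled)
  sv <- svd(sweep(filled, 2, mu), nu = 0, nv = q)
  w <- sv$v %*% diag(sv$d[seq_len(q)] / sqrt(N), q, q)
  w <- w + withr::with_seed(seed,
                            matrix(stats::rnorm(D * q, sd = 1e-3 * scale_obs),
                                   D, q))
  # the noise floor keeps the ARD regularization active even on noiseless
  # low-rank data, so superfluous components are shrunk rather than left
  # free to chase the imputed cells
  sigma2_floor <- 1e-6 * scale_obs^2
  sigma2 <- max(stats::var(as.vector(filled)) * 0.05, sigma2_floor)
  alpha <- rep(1 / scale_obs^2, q)
  incomplete <- which(rowSums(m$mask) > 0)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    yc <- sweep(filled, 2, mu)
    mq <- crossprod(w) + sigma2 * diag(q)
    minv <- solve(mq)
    x <- yc %*% w %*% minv                          # N x q posterior means
    # incomplete rows: the latent posterior conditions on the observed
    # coordinates only, so the masked cells never feed back into the fit
    for (i in incomplete) {
      o <- which(!m$mask[i, ])
      if (length(o) == 0) next
      wo <- w[o, , drop = FALSE]
      x[i, ] <- solve(crossprod(wo) + sigma2 * diag(q),
                      crossprod(wo, yc[i, o]))
    }
    sxx <- crossprod(x) + N * sigma2 * minv
    w <- crossprod(yc, x) %*% solve(sxx + sigma2 * diag(alpha, q, q))
    alpha <- D / (colSums(w^2) + 1e-10 * scale_obs^2)
    recon <- x %*% t(w)
    resid <- (yc - recon)[!m$mask]
    sigma2 <- max(mean(resid^2), sigma2_floor)
    old <- filled[m$mask]
    filled[m$mask] <- (recon + rep(mu, each = N))[m$mask]
    mu <- colMeans(filled)
    if (max(abs(filled[m$mask] - old)) < tol * scale_obs) {
      converged <- TRUE
      break
    }
  }
  new_imputed(filled, m, "BPCA", iterations = iter, converged = converged)
}

#' NIPALS imputation
#'
#' Nonlinear iterative partial least squares PCA that simply skips missing
#' cells in every inner product: per component, score and loading vectors
#' are alternately regressed over the available entries until the loading
#' stabilizes, the component is deflated from the observed cells, and after
#' `n_components` components the missing entries are reconstructed as
#' `sum_a t_a p_a'` (plus the observed-entry column means when centering is
#' on; off by default, which preserves the low-rank structure of positive
#' expression data).
#'
#' @inheritParams impute_row_average
#' @param n_components Number of components (default 2).
#' @param max_iter Inner-iteration cap per component.
#' @param tol Relative change threshold on the loading vector.
#' @param center Subtract observed-entry column means first (default FALSE).
#' @return An `imputed_matrix` (with `converged` flag).
#' @export
impute_nipals <- function(m, n_components = 2, max_iter = 500, tol = 1e-9,
                          center = FALSE) {
  m <- as_masked_matrix(m)
  if (!any(m$mask)) return(new_imputed(m$values, m, "NIPALS"))
  if (n_components < 1 || n_components > min(dim(m$values)))
    stop("n_components must satisfy 1 <= n_components <= min(G, S)",
         call. = FALSE)
  vals <- m$values
  centers <- if (center) colMeans(vals, na.rm = TRUE) else
    rep(0, ncol(vals))
  r <- sweep(vals, 2, centers)
  obs <- !m$mask
  r0 <- r; r0[m$mask] <- 0
  recon <- matrix(0, nrow(r), ncol(r))
  all_converged <- TRUE
  total_iter <- 0L
  for (a in seq_len(n_components)) {
    col_var <- apply(r, 2, stats::var, na.rm = TRUE)
    col_var[!is.finite(col_var)] <- 0
    if (max(col_var) == 0 && sum(r0^2) == 0) break
    tvec <- r0[, which.max(col_var)]
    p_old <- rep(0, ncol(r))
    converged_a <- FALSE
    for (it in seq_len(max_iter)) {
      total_iter <- total_iter + 1L
      den_p <- crossprod(obs, tvec^2)
      p <- as.vector(crossprod(r0, tvec)) / pmax(as.vector(den_p), 1e-300)
      np <- sqrt(sum(p^2))
      if (np == 0) break
      p <- p / np
      tvec <- as.vector(r0 %*% p) / pmax(as.vector(obs %*% p^2), 1e-300)
      if (sqrt(sum((p - p_old)^2)) < tol) {
        converged_a <- TRUE
        break
      }
      p_old <- p
    }
    if (!converged_a) {
      warning("NIPALS component ", a, " did not fully converge; using current vectors")
      all_converged <- FALSE
    }
    comp <- tcrossprod(tvec, p)
    recon <- recon + comp
    r <- r - comp
    r[m$mask] <- NA
    r0 <- r; r0[m$mask] <- 0
  }
  filled <- vals
  filled[m$mask] <- (recon + rep(centers, each = nrow(r)))[m$mask]
  new_imputed(filled, m, "NIPALS", iterations = total_iter,
              converged = all_converged)
}

#' Impute a masked matrix with a configured method
#'
#' Dispatches to the method named in `cfg`. Every method guarantees that
#' observed entries are returned unchanged and that the output is complete.
#'
#' @inheritParams impute_row_average
#' @param cfg A [method_config()].
#' @return An `imputed_matrix`.
#' @export
impute <- function(m, cfg) {
  stopifnot(inherits(cfg, "method_config"))
  m <- as_masked_matrix(m)
  S <- ncol(m$values)
  res <- switch(
    cfg$method,
    ROW = impute_row_average(m),
    KNN = impute_knn(m, k = cfg$k, distance = cfg$distance),
    SVD = impute_svd(m, n_components = cfg$n_components %||% 2,
                     threshold = cfg$convergence_threshold %||% 0.01,
                     max_iter = cfg$max_iter),
    LLS = impute_lls(m, k = cfg$k),
    LSA = impute_lsa(m, cfg),
    BPCA = impute_bpca(m, n_components = cfg$n_components,
                       max_iter = cfg$max_iter,
                       tol = cfg$convergence_threshold %||% 1e-4,
                       seed = cfg$seed),
    NIPALS = impute_nipals(m, n_components = cfg$n_components %||% 2,
                           max_iter = cfg$max_iter),
    stop("unknown imputation method: ", cfg$method, call. = FALSE)
  )
  res$method <- cfg$label
  res$config <- cfg
  res
}
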