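# Standard scRNA-seq preprocessing producing the log-normalized, scaled
# matrix the panel-design model consumes. Stage order is fixed:
#   filter -> normalize+log -> HVG -> regress-out -> scale+clip -> per-type cap
# Matrices are cells x genes throughout.

#' Preprocessing configuration
#'
#' @param min_genes_per_cell Drop cells detecting fewer genes (default 200).
#' @param min_cells_per_gene Drop genes detected in fewer cells (default 3).
#' @param target_sum Per-cell total after count normalization (default 1e4).
#' @param hvg Logical: run highly-variable-gene selection (default TRUE).
#' @param min_mean,max_mean,min_disp HVG thresholds on the log1p mean and the
#'   within-bin z-scored dispersion (defaults 0.0125, 3, 0.5).
#' @param regress Logical: regress out total counts (and percent
#'   mitochondrial counts when mito genes are present) per gene.
#' @param mito_prefix Gene-id prefixes marking mitochondrial genes.
#' @param scale Logical: scale genes to unit variance and clip.
#' @param clip_sd Upper clip after scaling (default 10; one-sided).
#' @param max_cells_per_type Per-class cell cap (default 1000).
#' @param seed Seed for the per-type subsampling.
#' @return List of class \code{preprocess_config}.
#' @export
preprocess_config <- function(min_genes_per_cell = 200L, min_cells_per_gene = 3L,
                              target_sum = 1e4, hvg = TRUE,
                              min_mean = 0.0125, max_mean = 3, min_disp = 0.5,
                              regress = TRUE, mito_prefix = c("MT-", "mt-"),
                              scale = TRUE, clip_sd = 10,
                              max_cells_per_type = 1000L, seed = 0L) {
  stopifnot(min_genes_per_cell >= 0, min_cells_per_gene >= 0, target_sum > 0,
            clip_sd >= 0, max_cells_per_type >= 1)
  structure(as.list(environment()), class = "preprocess_config")
}

#' Basic cell and gene filtering
#'
#' Removes cells detecting fewer than \code{min_genes} genes, then genes
#' detected in fewer than \code{min_cells} of the remaining cells (single
#' pass, cell filter first).
#'
#' @param counts Cells x genes non-negative count matrix.
#' @param min_genes,min_cells Detection thresholds.
#' @return List with the filtered \code{counts} and logical index vectors
#'   \code{cells_kept}, \code{genes_kept} into the input.
#' @export
filter_cells_and_genes <- function(counts, min_genes = 200L, min_cells = 3L) {
  counts <- .as_dense_counts(counts)
  cells_kept <- rowSums(counts > 0) >= min_genes
  sub <- counts[cells_kept, , drop = FALSE]
  genes_kept <- colSums(sub > 0) >= min_cells
  sub <- sub[, genes_kept, drop = FALSE]
  if (nrow(sub) == 0L || ncol(sub) == 0L)
    stop("filtering removed every cell or gene; relax min_genes/min_cells")
  list(counts = sub, cells_kept = cells_kept, genes_kept = genes_kept)
}

#' Total-count normalization and log1p transform
#'
#' Scales every cell to the same total count, then applies
#' \code{log(1 + x)} elementwise.
#'
#' @param counts Cells x genes count matrix with positive row sums.
#' @param target_sum Per-cell total after normalization.
#' @return Matrix of log-normalized expression.
#' @export
normalize_and_log <- function(counts, target_sum = 1e4) {
  counts <- .as_dense_counts(counts)
  tot <- rowSums(counts)
  if (any(tot <= 0)) stop("cells with zero total count; filter first")
  log1p(counts * (target_sum / tot))
}

#' Dispersion-based highly variable gene selection
#'
#' Per gene, the mean and the dispersion (variance/mean) are computed on the
#' de-logged (\code{expm1}) normalized scale; genes are cut into
#' equal-frequency bins by mean and dispersions are z-scored within each
#' bin. A gene is kept when its log1p mean lies in
#' \[\code{min_mean}, \code{max_mean}\] and its normalized dispersion is at
#' least \code{min_disp}.
#'
#' @param logmat Cells x genes log-normalized matrix (>= 2 cells).
#' @param min_mean,max_mean,min_disp Selection thresholds.
#' @param n_bins Number of mean bins (default 20).
#' @return Logical vector over genes (TRUE = highly variable).
#' @export
select_highly_variable <- function(logmat, min_mean = 0.0125, max_mean = 3,
                                   min_disp = 0.5, n_bins = 20L) {
  stopifnot(nrow(logmat) >= 2L)
  X <- expm1(logmat)
  mu <- colMeans(X)
  v <- apply(X, 2L, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  n_bins <- max(1L, min(n_bins, ncol(logmat)))
  br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1L)))
  bins <- if (length(br) > 2L) cut(mu, breaks = br, include.lowest = TRUE)
          else factor(rep(1L, length(mu)))
  zdisp <- disp
  g_m <- mean(disp); g_s <- stats::sd(disp)
  for (b in levels(bins)) {
    i <- which(bins == b)
    m <- mean(disp[i]); s <- stats::sd(disp[i])
    if (is.na(s) || s == 0) {
      # degenerate bin (single gene, or identical dispersions): fall back to
      # a z-score against all genes so lone high-dispersion genes survive
      zdisp[i] <- if (is.na(g_s) || g_s == 0) 0 else (disp[i] - g_m) / g_s
    } else {
      zdisp[i] <- (disp[i] - m) / s
    }
  }
  lmu <- log1p(mu)
  keep <- lmu >= min_mean & lmu <= max_mean & zdisp >= min_disp
  if (!any(keep))
    stop("no gene passes the HVG thresholds; relax min_disp or the mean window")
  keep
}

#' Regress out per-cell covariates
#'
#' Fits, per gene, an ordinary least-squares model of expression on the
#' given covariates (with intercept) and returns the residuals. Constant
#' covariates are dropped with a warning. When \code{pct_mito} is
#' \code{NULL}, only total counts are regressed and a notice is emitted.
#'
#' @param logmat Cells x genes matrix.
#' @param total_counts Per-cell total raw counts.
#' @param pct_mito Per-cell percent mitochondrial counts, or \code{NULL}.
#' @return Residual matrix of the same shape.
#' @export
regress_out_covariates <- function(logmat, total_counts, pct_mito = NULL) {
  stopifnot(length(total_counts) == nrow(logmat), all(is.finite(total_counts)))
  covs <- list(total_counts = total_counts)
  if (is.null(pct_mito)) {
    message("no mitochondrial annotation; regressing on total counts only")
  } else {
    stopifnot(length(pct_mito) == nrow(logmat), all(is.finite(pct_mito)))
    covs$pct_mito <- pct_mito
  }
  keep <- vapply(covs, function(v) stats::sd(v) > 0, TRUE)
  if (any(!keep)) {
    warning("constant covariate(s) dropped: ",
            paste(names(covs)[!keep], collapse = ", "))
    covs <- covs[keep]
  }
  D <- cbind(1, do.call(cbind, covs))
  res <- qr.resid(qr(D), logmat)
  dimnames(res) <- dimnames(logmat)
  res
}

#' Scale genes to unit variance with one-sided clipping
#'
#' Centers each gene to mean 0, divides by its standard deviation and clamps
#' values above \code{clip_sd} to \code{clip_sd} (the lower tail is not
#' clamped). Zero-variance genes map to all zeros.
#'
#' @param mat Cells x genes matrix (>= 2 cells).
#' @param clip_sd Upper clip in standard-deviation units (default 10).
#' @return Scaled matrix.
#' @export
scale_and_clip <- function(mat, clip_sd = 10) {
  stopifnot(nrow(mat) >= 2L)
  mu <- colMeans(mat)
  s <- apply(mat, 2L, stats::sd)
  out <- sweep(mat, 2L, mu, "-")
  nz <- s > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, s[nz], "/")
  out[, !nz] <- 0
  pmin(out, clip_sd)
}

#' Cap the number of cells per cell type
#'
#' For every class with more than \code{max_n} cells, retains a seeded
#' uniform random subset of \code{max_n}; smaller classes are untouched.
#' The relative order of retained cells is preserved.
#'
#' @param mat Cells x genes matrix.
#' @param labels Per-cell labels aligned with rows.
#' @param max_n Cap (default 1000).
#' @param seed Integer seed.
#' @return List with subsampled \code{mat}, \code{labels} and the retained
#'   row indices \code{idx}.
#' @export
cap_cells_per_type <- function(mat, labels, max_n = 1000L, seed = 0L) {
  stopifnot(nrow(mat) == length(labels), max_n >= 1)
  labels <- as.character(labels)
  keep <- logical(length(labels))
  .with_seed(seed, {
    for (cl in unique(labels)) {
      i <- which(labels == cl)
      if (length(i) > max_n) i <- sort(sample(i, max_n))
      keep[i] <- TRUE
    }
  })
  idx <- which(keep)
  list(mat = mat[idx, , drop = FALSE], labels = labels[idx], idx = idx)
}

#' Full preprocessing pipeline
#'
#' Applies, in order: basic filtering, total-count normalization + log1p,
#' highly variable gene selection, covariate regression, unit-variance
#' scaling with clipping, and the per-type cell cap. Each stage's input and
#' output dimensions are recorded in a provenance log.
#'
#' @param counts Cells x genes raw count matrix (row names = cell ids,
#'   column names = gene ids).
#' @param labels Per-cell labels aligned with rows.
#' @param config A \code{\link{preprocess_config}}.
#' @return List with the processed \code{x} (matrix the model consumes),
#'   \code{labels}, and \code{log} (data frame: stage, cells, genes).
#' @export
preprocess_pipeline <- function(counts, labels, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  counts <- .as_dense_counts(counts)
  if (nrow(counts) != length(labels)) stop("labels must align with cells")
  labels <- as.character(labels)
  stage_log <- list(data.frame(stage = "input", cells = nrow(counts),
                               genes = ncol(counts)))
  note <- function(stage, m) stage_log[[length(stage_log) + 1L]] <<-
    data.frame(stage = stage, cells = nrow(m), genes = ncol(m))

  f <- filter_cells_and_genes(counts, config$min_genes_per_cell,
                              config$min_cells_per_gene)
  labels <- labels[f$cells_kept]
  counts <- f$counts
  note("filter", counts)

  total_counts <- rowSums(counts)
  mito <- rep(FALSE, ncol(counts))
  if (!is.null(colnames(counts)))
    for (pref in config$mito_prefix)
      mito <- mito | startsWith(colnames(counts), pref)
  pct_mito <- if (any(mito))
    100 * rowSums(counts[, mito, drop = FALSE]) / total_counts else NULL

  x <- normalize_and_log(counts, config$target_sum)
  note("normalize_log", x)

  if (isTRUE(config$hvg)) {
    keep <- select_highly_variable(x, config$min_mean, config$max_mean,
                                   config$min_disp)
    x <- x[, keep, drop = FALSE]
    note("hvg", x)
  }
  if (isTRUE(config$regress)) {
    x <- regress_out_covariates(x, total_counts, pct_mito)
    note("regress", x)
  }
  if (isTRUE(config$scale)) {
    x <- scale_and_clip(x, config$clip_sd)
    note("scale_clip", x)
  }
  cap <- cap_cells_per_type(x, labels, config$max_cells_per_type, config$seed)
  x <- cap$mat
  labels <- cap$labels
  note("cap_per_type", x)

  list(x = x, labels = labels, log = do.call(rbind, stage_log))
}

.as_dense_counts <- function(counts) {
  if (inherits(counts, "Matrix")) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix (cells x genes)")
  if (any(counts < 0) || !all(is.finite(counts)))
    stop("counts must be finite and non-negative")
  counts
}
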