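# Negative-binomial synthetic scRNA-seq generator with planted structure:
# per-type exclusive marker genes, co-expressed gene modules (shared
# log-normal latent factor per module per cell), co-expressed gene pairs
# standing in for protein complexes, and background noise genes. Counts get
# per-cell library-size scaling and independent dropout thinning, so the
# output exercises the full preprocessing path.

#' Specification of a synthetic dataset
#'
#' Defaults follow the package's reference simulation: 5 cell types of 200
#' cells, 3 exclusive markers per type at a 6-fold effect, 200 noise genes,
#' no modules or complex pairs.
#'
#' @param n_types Number of cell types (>= 2).
#' @param cells_per_type Cells per type.
#' @param n_markers_per_type Exclusive marker genes per type.
#' @param n_modules,n_module_genes Number of co-expression modules and genes
#'   per module.
#' @param n_complex_pairs Number of planted co-expressed gene pairs
#'   (complex stand-ins).
#' @param n_noise_genes Background genes without planted structure.
#' @param marker_effect Fold-change of a marker's mean in its own type
#'   (>= 1; 1 plants no signal, the null case).
#' @param complex_effect Fold-change of a pair's mean in the types where it
#'   is active.
#' @param dispersion Negative-binomial overdispersion (NB size = 1 /
#'   dispersion).
#' @param library_size_mean Mean per-cell total count.
#' @param library_size_sd Log-scale SD of the per-cell library size.
#' @param dropout_rate Probability an observed count is zeroed (in \[0, 1)).
#' @param module_sd Log-scale SD of the shared module factor.
#' @param seed Integer seed.
#' @return List of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_types = 5L, cells_per_type = 200L,
                           n_markers_per_type = 3L, n_modules = 0L,
                           n_module_genes = 4L, n_complex_pairs = 0L,
                           n_noise_genes = 200L, marker_effect = 6,
                           complex_effect = 3, dispersion = 0.3,
                           library_size_mean = 20000, library_size_sd = 0.2,
                           dropout_rate = 0.05, module_sd = 0.5, seed = 0L) {
  stopifnot(n_types >= 2, cells_per_type >= 1, n_markers_per_type >= 0,
            n_modules >= 0, n_module_genes >= 2 || n_modules == 0,
            n_complex_pairs >= 0, n_noise_genes >= 0,
            marker_effect >= 1, complex_effect >= 1, dispersion > 0,
            library_size_mean > 0, library_size_sd >= 0,
            dropout_rate >= 0, dropout_rate < 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a synthetic count dataset with known ground truth
#'
#' Per-gene base means are Gamma draws; marker genes get
#' \code{marker_effect} times their base mean in their own type; module
#' genes share a log-normal latent factor per module per cell (inducing
#' positive within-module correlation); each complex pair is elevated in a
#' random subset of types and shares its own per-cell factor. Expected
#' per-cell totals are scaled to a log-normal library size, counts drawn
#' negative-binomially and thinned by independent dropout. Fully
#' deterministic given the spec's seed.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @return List with \code{counts} (cells x genes integer matrix, named),
#'   \code{labels} (character vector of cell types) and \code{truth}
#'   (class \code{synthetic_truth}): \code{markers} (list per type),
#'   \code{marker_gene_ids}, \code{modules}, \code{complex_pairs}
#'   (two-column id matrix), \code{base_means}, \code{active_types} per
#'   pair.
#' @export
simulate_panel_data <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  tn <- paste0("type", seq_len(spec$n_types))
  markers <- lapply(seq_len(spec$n_types), function(t)
    sprintf("MK%d_%d", t, seq_len(spec$n_markers_per_type)))
  names(markers) <- tn
  modules <- lapply(seq_len(spec$n_modules), function(m)
    sprintf("MOD%d_%d", m, seq_len(spec$n_module_genes)))
  pair_ids <- if (spec$n_complex_pairs > 0)
    cbind(sprintf("CPX%d_A", seq_len(spec$n_complex_pairs)),
          sprintf("CPX%d_B", seq_len(spec$n_complex_pairs)))
  else matrix(character(0), ncol = 2L)
  noise <- if (spec$n_noise_genes > 0) sprintf("NOISE%d", seq_len(spec$n_noise_genes))
           else character(0)
  gene_ids <- c(unlist(markers, use.names = FALSE),
                unlist(modules, use.names = FALSE),
                as.vector(t(pair_ids)), noise)
  n <- length(gene_ids)
  if (n == 0L) stop("spec yields zero genes")
  N <- spec$n_types * spec$cells_per_type
  labels <- rep(tn, each = spec$cells_per_type)

  .with_seed(spec$seed, {
    base <- stats::rgamma(n, shape = 2, rate = 2) + 0.05
    names(base) <- gene_ids
    # type x gene fold-change matrix
    E <- matrix(1, spec$n_types, n, dimnames = list(tn, gene_ids))
    for (t in seq_len(spec$n_types)) E[t, markers[[t]]] <- spec$marker_effect
    active_types <- list()
    if (spec$n_complex_pairs > 0) {
      for (pidx in seq_len(spec$n_complex_pairs)) {
        act <- sort(sample.int(spec$n_types, size = max(1L, spec$n_types %/% 2L)))
        E[act, pair_ids[pidx, ]] <- spec$complex_effect
        active_types[[pidx]] <- tn[act]
      }
    }
    ty <- match(labels, tn)
    mu <- E[ty, , drop = FALSE] * rep(base, each = N)
    # shared latent factors: modules and complex pairs
    for (m in seq_along(modules)) {
      f <- stats::rlnorm(N, 0, spec$module_sd)
      mu[, modules[[m]]] <- mu[, modules[[m]]] * f
    }
    if (spec$n_complex_pairs > 0) {
      for (pidx in seq_len(spec$n_complex_pairs)) {
        f <- stats::rlnorm(N, 0, spec$module_sd)
        mu[, pair_ids[pidx, ]] <- mu[, pair_ids[pidx, ]] * f
      }
    }
    lib <- stats::rlnorm(N, log(spec$library_size_mean), spec$library_size_sd)
    mu <- mu * (lib / rowSums(mu))
    counts <- matrix(stats::rnbinom(N * n, mu = as.vector(mu),
                                    size = 1 / spec$dispersion), N, n)
    if (spec$dropout_rate > 0) {
      drop <- matrix(stats::runif(N * n) < spec$dropout_rate, N, n)
      counts[drop] <- 0L
    }
  })
  dimnames(counts) <- list(sprintf("cell%d", seq_len(N)), gene_ids)
  truth <- structure(list(markers = markers,
                          marker_gene_ids = unlist(markers, use.names = FALSE),
                          modules = modules, complex_pairs = pair_ids,
                          base_means = base, active_types = active_types),
                     class = "synthetic_truth")
  list(counts = counts, labels = labels, truth = truth)
}

#' Fraction of planted markers recovered by a panel
#'
#' @param panel A \code{gene_panel} or character vector of gene ids.
#' @param truth A \code{synthetic_truth}.
#' @return Overall recovered fraction, with a per-type breakdown in
#'   attribute \code{"per_type"}.
#' @export
truth_recovery_score <- function(panel, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  genes <- if (is.data.frame(panel)) panel$gene_id else as.character(panel)
  per_type <- vapply(truth$markers, function(m) mean(m %in% genes), 1.0)
  all_m <- truth$marker_gene_ids
  score <- if (length(all_m)) mean(all_m %in% genes) else NA_real_
  attr(score, "per_type") <- per_type
  score
}
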