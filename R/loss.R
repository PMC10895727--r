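#' Sparsity penalty of the feature-selection weights
#'
#' Computes \eqn{\sum_i |w_i| \, |w_i - 1|}, the term that drives each
#' feature-selection weight towards 0 (gene excluded) or 1 (gene included).
#' It is zero exactly when every weight is 0 or 1.
#'
#' @param w Numeric vector of feature-selection weights (finite).
#' @return A single non-negative number.
#' @export
#' @examples
#' sparsity_penalty(c(0, 1, 0, 1)) # 0
#' sparsity_penalty(0.5)           # 0.25
sparsity_penalty <- function(w) {
  .check_weights(w)
  sum(abs(w) * abs(w - 1))
}

#' Panel-size penalty
#'
#' Computes \eqn{\alpha\,|\;\|w\|_1 - d\;|}: since the sparsity penalty keeps
#' the weights near 0/1, the L1 norm of \code{w} counts the genes effectively
#' selected, and this term steers that count towards the target panel size
#' \code{d}. With \code{exceed_only = TRUE} only an over-budget panel is
#' penalized: \eqn{\alpha \max(\|w\|_1 - d, 0)}.
#'
#' @param w Numeric vector of feature-selection weights.
#' @param d Target panel size (positive integer).
#' @param alpha Penalty coefficient (default 1.5).
#' @param exceed_only If \code{TRUE}, penalize only when the weight sum
#'   exceeds \code{d}.
#' @return A single non-negative number.
#' @export
size_penalty <- function(w, d, alpha = 1.5, exceed_only = FALSE) {
  .check_weights(w)
  stopifnot(length(d) == 1L, d >= 1, length(alpha) == 1L, alpha >= 0)
  excess <- sum(abs(w)) - d
  if (exceed_only) alpha * max(excess, 0) else alpha * abs(excess)
}

#' Gene-priority penalty
#'
#' Computes \eqn{\beta \sum_i p_i (1 - \min(|w_i|, 1))}. A gene carrying a
#' priority score \eqn{p_i > 0} incurs a penalty proportional to how far its
#' weight falls short of 1, i.e. to how much it is excluded from the panel.
#' The clamp \eqn{\min(|w_i|, 1)} means weights beyond 1 earn no bonus.
#'
#' @param w Numeric vector of feature-selection weights.
#' @param priorities Numeric vector of priority scores in \[0, 1\], one per
#'   gene (0 for genes without a user priority). Recycled scalars are not
#'   accepted; length must equal \code{length(w)}.
#' @param beta Penalty coefficient (default 0.2).
#' @return A single non-negative number.
#' @export
priority_penalty <- function(w, priorities, beta = 0.2) {
  .check_weights(w)
  stopifnot(is.numeric(priorities), length(priorities) == length(w),
            all(is.finite(priorities)), length(beta) == 1L, beta >= 0)
  beta * sum(priorities * (1 - pmin(abs(w), 1)))
}

#' Complex-pairing penalty
#'
#' Computes \eqn{\gamma \sum_{(i,j)} |\,|w_i| - |w_j|\,|} over gene pairs
#' derived from protein complexes (e.g. receptor--ligand pairs). Panels that
#' include only part of a complex pay for the weight mismatch; the term is
#' zero when paired genes carry equal absolute weights (both in or both out).
#'
#' @param w Numeric vector of feature-selection weights.
#' @param pairs Two-column integer matrix of gene indices, one row per
#'   unordered pair; may have zero rows.
#' @param gamma Penalty coefficient (default 0.5).
#' @return A single non-negative number.
#' @export
complex_penalty <- function(w, pairs, gamma = 0.5) {
  .check_weights(w)
  stopifnot(length(gamma) == 1L, gamma >= 0)
  pairs <- .check_pairs(pairs, length(w))
  if (nrow(pairs) == 0L) return(0)
  gamma * sum(abs(abs(w[pairs[, 1L]]) - abs(w[pairs[, 2L]])))
}

#' Full regularizer with per-term breakdown
#'
#' Assembles the four-term regularizer
#' \deqn{R = \sum_i |w_i||w_i - 1| + \alpha|\|w\|_1 - d|
#'       + \beta\sum_{i \in G} p_i(1 - \min(|w_i|,1))
#'       + \gamma\sum_{(i,j) \in C} ||w_i| - |w_j||}
#' for a weight vector under a \code{\link{panel_config}} already resolved
#' against a gene universe (see \code{\link{resolve_config}}).
#'
#' @param w Numeric vector of feature-selection weights, length equal to the
#'   number of genes the config was resolved against.
#' @param config A resolved \code{panel_config}.
#' @return A list of class \code{loss_breakdown} with elements
#'   \code{sparsity_term}, \code{size_term}, \code{priority_term},
#'   \code{complex_term} and their sum \code{r_total}.
#' @export
regularizer <- function(w, config) {
  config <- .assert_resolved(config, n = length(w))
  out <- list(
    sparsity_term = sparsity_penalty(w),
    size_term     = size_penalty(w, config$d, config$alpha, config$exceed_only),
    priority_term = priority_penalty(w, config$p, config$beta),
    complex_term  = complex_penalty(w, config$pairs, config$gamma)
  )
  out$r_total <- out$sparsity_term + out$size_term +
    out$priority_term + out$complex_term
  class(out) <- "loss_breakdown"
  out
}

#' Loss and panel hyperparameter configuration
#'
#' Bundles every hyperparameter of the panel-design loss together with the
#' optional gene-priority and complex specifications. Priorities and
#' complexes are given at the gene-identifier level and resolved to indices
#' against an expression matrix by \code{\link{resolve_config}} (done
#' automatically inside \code{\link{train_model}}).
#'
#' @param d Target panel size (number of genes the assay will probe).
#' @param alpha Size-penalty coefficient (default 1.5).
#' @param beta Priority coefficient (default 0.2).
#' @param gamma Complex-pairing coefficient (default 0.5).
#' @param lambda0 Weight of the regularizer R in the total loss (default 1).
#' @param lambda1 Coefficient of the dense-layer L2 term (default 0.01).
#' @param exceed_only If \code{TRUE}, the size penalty fires only when the
#'   weight sum exceeds \code{d}.
#' @param priorities Named numeric vector, gene id -> priority score in
#'   \[0, 1\]. Scores outside \[0, 1\] are clamped with a warning.
#' @param complexes List of character vectors, each a complex of >= 2 gene
#'   ids; expanded to all gene pairs at resolution time.
#' @param pairs Optional pre-built two-column character matrix of gene-id
#'   pairs (as produced by \code{\link{encode_complexes}}); used in addition
#'   to pairs derived from \code{complexes}.
#' @return An object of class \code{panel_config}.
#' @export
panel_config <- function(d, alpha = 1.5, beta = 0.2, gamma = 0.5,
                         lambda0 = 1, lambda1 = 0.01, exceed_only = FALSE,
                         priorities = NULL, complexes = NULL, pairs = NULL) {
  stopifnot(length(d) == 1L, is.finite(d), d >= 1, d == as.integer(d))
  for (nm in c("alpha", "beta", "gamma", "lambda0", "lambda1")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("'%s' must be a single non-negative number", nm))
  }
  if (!is.null(priorities)) {
    if (is.null(names(priorities)) || !is.numeric(priorities))
      stop("'priorities' must be a named numeric vector (gene id -> score)")
    if (any(priorities < 0 | priorities > 1)) {
      warning("priority scores outside [0, 1] clamped")
      priorities <- pmin(pmax(priorities, 0), 1)
    }
  }
  if (!is.null(complexes)) {
    stopifnot(is.list(complexes))
    if (any(vapply(complexes, length, 1L) < 2L))
      stop("every complex needs at least 2 gene ids")
  }
  structure(list(d = as.integer(d), alpha = alpha, beta = beta, gamma = gamma,
                 lambda0 = lambda0, lambda1 = lambda1,
                 exceed_only = isTRUE(exceed_only),
                 priorities = priorities, complexes = complexes,
                 id_pairs = pairs, resolved = FALSE),
            class = "panel_config")
}

#' Resolve a config against a gene universe
#'
#' Maps gene-id priorities and complexes onto column indices of an expression
#' matrix. Unknown gene ids are reported and dropped; complexes left with
#' fewer than two resolvable members are skipped with a warning. Complexes
#' are expanded to all 2-subsets, de-duplicated.
#'
#' @param config A \code{\link{panel_config}}.
#' @param gene_ids Character vector of unique gene identifiers (the columns
#'   of the training matrix).
#' @return The config with index-level fields filled in: \code{p} (length-n
#'   priority vector), \code{pairs} (two-column index matrix) and
#'   \code{complex_of} (named integer vector mapping member gene ids to a
#'   1-based complex number, \code{NA}-free).
#' @export
resolve_config <- function(config, gene_ids) {
  stopifnot(inherits(config, "panel_config"), is.character(gene_ids),
            !anyDuplicated(gene_ids))
  n <- length(gene_ids)
  if (config$d > n)
    stop("panel size d (", config$d, ") exceeds the number of genes (", n, ")")
  p <- numeric(n)
  if (!is.null(config$priorities)) {
    idx <- match(names(config$priorities), gene_ids)
    if (anyNA(idx)) {
      warning("dropping priorities for unknown gene ids: ",
              paste(names(config$priorities)[is.na(idx)], collapse = ", "))
    }
    keep <- !is.na(idx)
    p[idx[keep]] <- config$priorities[keep]
  }
  pair_rows <- list()
  complex_of <- integer(0)
  if (!is.null(config$complexes)) {
    for (ci in seq_along(config$complexes)) {
      members <- match(config$complexes[[ci]], gene_ids)
      if (anyNA(members))
        warning("complex ", ci, ": unknown gene ids dropped")
      members <- unique(members[!is.na(members)])
      if (length(members) < 2L) {
        warning("complex ", ci, " has fewer than 2 resolvable genes; skipped")
        next
      }
      pair_rows[[length(pair_rows) + 1L]] <- t(utils::combn(sort(members), 2L))
      cm <- setNames(rep(ci, length(members)), gene_ids[members])
      complex_of <- c(complex_of, cm[setdiff(names(cm), names(complex_of))])
    }
  }
  if (!is.null(config$id_pairs)) {
    m <- config$id_pairs
    stopifnot(is.matrix(m), ncol(m) == 2L)
    i <- match(m[, 1L], gene_ids); j <- match(m[, 2L], gene_ids)
    ok <- !is.na(i) & !is.na(j) & i != j
    if (any(!ok)) warning("dropping pairs with unknown or identical gene ids")
    if (any(ok)) {
      ij <- cbind(pmin(i[ok], j[ok]), pmax(i[ok], j[ok]))
      pair_rows[[length(pair_rows) + 1L]] <- ij
      for (r in which(ok)) {
        for (g in m[r, ]) if (!(g %in% names(complex_of))) {
          complex_of <- c(complex_of,
                          setNames(length(unique(complex_of)) + 1L, g))
        }
      }
    }
  }
  pairs <- if (length(pair_rows)) unique(do.call(rbind, pair_rows))
           else matrix(integer(0), ncol = 2L)
  config$p <- p
  config$pairs <- pairs
  config$complex_of <- complex_of
  config$n <- n
  config$gene_ids <- gene_ids
  config$resolved <- TRUE
  config
}

#' Expand complexes into gene pairs with default priorities
#'
#' A complex of m genes is encoded as all \eqn{\binom{m}{2}} unordered gene
#' pairs. For every pair in which neither member already carries a
#' user-provided priority, one member (chosen by the seeded generator) is
#' assigned priority score 1, so that the pairing penalty has an anchor gene
#' to pull its partner towards. User-provided priorities are never
#' overwritten.
#'
#' @param complexes List of character vectors of gene ids (length >= 2 each).
#' @param priorities Optional named numeric vector of user priorities.
#' @param seed Integer seed for the random within-pair priority assignment.
#' @return List with \code{pairs} (two-column character matrix),
#'   \code{priorities} (input priorities plus the random anchors) and
#'   \code{complex_of} (named integer: member gene id -> complex number).
#' @export
encode_complexes <- function(complexes, priorities = NULL, seed = 0L) {
  stopifnot(is.list(complexes))
  pr <- if (is.null(priorities)) setNames(numeric(0), character(0)) else priorities
  stopifnot(is.numeric(pr))
  pairs <- list()
  complex_of <- integer(0)
  .with_seed(seed, {
    for (ci in seq_along(complexes)) {
      genes <- unique(as.character(complexes[[ci]]))
      if (length(genes) < 2L) {
        warning("complex ", ci, " has fewer than 2 genes; skipped")
        next
      }
      pm <- t(utils::combn(genes, 2L))
      pairs[[length(pairs) + 1L]] <- pm
      for (r in seq_len(nrow(pm))) {
        g <- pm[r, ]
        if (!any(g %in% names(pr))) {
          anchor <- g[sample.int(2L, 1L)]
          pr[anchor] <- 1
        }
      }
      new <- setdiff(genes, names(complex_of))
      complex_of <- c(complex_of, setNames(rep(ci, length(new)), new))
    }
  })
  list(pairs = if (length(pairs)) do.call(rbind, pairs)
               else matrix(character(0), ncol = 2L),
       priorities = pr, complex_of = complex_of)
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat("Loss breakdown:\n")
  for (nm in names(x)) cat(sprintf("  %-14s %g\n", nm, x[[nm]]))
  invisible(x)
}

# ---- internal helpers -------------------------------------------------------

.check_weights <- function(w) {
  if (!is.numeric(w) || length(w) < 1L || !all(is.finite(w)))
    stop("weights must be a non-empty finite numeric vector")
  invisible(w)
}

.check_pairs <- function(pairs, n) {
  if (is.null(pairs)) return(matrix(integer(0), ncol = 2L))
  if (!is.matrix(pairs) || ncol(pairs) != 2L)
    stop("'pairs' must be a two-column matrix of gene indices")
  storage.mode(pairs) <- "integer"
  if (nrow(pairs) > 0L) {
    if (any(pairs < 1L | pairs > n)) stop("pair index out of range")
    if (any(pairs[, 1L] == pairs[, 2L])) stop("self-pairs are not allowed")
  }
  pairs
}

.assert_resolved <- function(config, n) {
  stopifnot(inherits(config, "panel_config"))
  if (!isTRUE(config$resolved))
    stop("config must be resolved against gene ids first (see resolve_config)")
  if (config$n != n)
    stop("weight vector length (", n, ") does not match config (", config$n, ")")
  config
}

# Evaluate expr with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}
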