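# Feature-selecting classifier: input (n genes) -> one-to-one selection layer
# (diagonal weights w) -> dense 32 (ReLU) -> dense 16 (ReLU) -> softmax (c).
# Trained by minimizing
#   J = mean cross-entropy + lambda0 * R(w) + lambda1 * sum_k ||W(k)||_2
# with analytic gradients and Adam. The regularizer R carries the panel-size
# constraint, so training performs embedded feature selection: after fitting,
# the d genes with the largest |w| form the panel.

#' Initialize model parameters
#'
#' Every selection weight starts at 0.5, the midpoint between the two
#' attractors of the sparsity penalty (0 and 1): both remain reachable and,
#' with an equal start, which genes rise is decided by the data rather than
#' by an initialization lottery. Dense layers use Glorot (fan-based) uniform
#' initialization and zero biases.
#'
#' @param n Number of genes (input features).
#' @param n_classes Number of cell types (>= 2).
#' @param seed Integer seed.
#' @return List of class \code{panel_params} with elements \code{w},
#'   \code{W1}, \code{b1}, \code{W2}, \code{b2}, \code{W3}, \code{b3}.
#' @export
init_params <- function(n, n_classes, seed = 0L) {
  stopifnot(n >= 1, n_classes >= 2)
  glorot <- function(fin, fout) {
    lim <- sqrt(6 / (fin + fout))
    matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
  }
  .with_seed(seed, {
    p <- list(
      w  = rep(0.5, n),
      W1 = glorot(n, 32L),  b1 = numeric(32L),
      W2 = glorot(32L, 16L), b2 = numeric(16L),
      W3 = glorot(16L, n_classes), b3 = numeric(n_classes)
    )
  })
  structure(p, class = "panel_params")
}

#' Forward pass: class probabilities
#'
#' Multiplies each gene's expression by its selection weight (\code{w * x}
#' elementwise), feeds the result through the two ReLU layers and returns
#' softmax class probabilities. A gene with \code{w = 0} is invisible to the
#' classifier.
#'
#' @param params A \code{panel_params} object.
#' @param x Numeric vector (one cell) or matrix (cells x genes).
#' @return Matrix of class probabilities, one row per cell; rows sum to 1.
#' @export
forward <- function(params, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(params$w))
    stop("x has ", ncol(x), " features; model expects ", length(params$w))
  if (!all(is.finite(x))) stop("x must be finite")
  .forward_full(params, x)$P
}

.forward_full <- function(params, X) {
  Z0 <- sweep(X, 2L, params$w, "*")
  A1 <- sweep(Z0 %*% params$W1, 2L, params$b1, "+")
  H1 <- pmax(A1, 0)
  A2 <- sweep(H1 %*% params$W2, 2L, params$b2, "+")
  H2 <- pmax(A2, 0)
  A3 <- sweep(H2 %*% params$W3, 2L, params$b3, "+")
  list(Z0 = Z0, A1 = A1, H1 = H1, A2 = A2, H2 = H2, P = .softmax_rows(A3))
}

.softmax_rows <- function(A) {
  A <- A - apply(A, 1L, max)
  E <- exp(A)
  E / rowSums(E)
}

.l2sq <- function(M) sum(M * M)

#' Total loss with breakdown
#'
#' Evaluates \eqn{J(\theta)} on a batch: the mean categorical cross-entropy
#' of the forward outputs against the true labels, plus \code{lambda0} times
#' the four-term regularizer on \code{w}, plus \code{lambda1} times the L2
#' (squared-norm) penalty summed over the three dense weight matrices --
#' the standard weight decay that keeps subsequent layers from amplifying
#' small selection weights.
#'
#' @param params A \code{panel_params} object.
#' @param x Cells x genes matrix.
#' @param y Integer class labels in \code{1..c}.
#' @param config A resolved \code{\link{panel_config}}.
#' @return A \code{loss_breakdown} list with \code{nll}, the four R terms,
#'   \code{r_total}, \code{l2_term} and \code{total}.
#' @export
total_loss <- function(params, x, y, config) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  stopifnot(nrow(x) == length(y), nrow(x) >= 1L)
  n_classes <- length(params$b3)
  y <- as.integer(y)
  if (any(y < 1L | y > n_classes)) stop("label out of range 1..", n_classes)
  config <- .assert_resolved(config, n = length(params$w))
  P <- forward(params, x)
  nll <- -mean(log(pmax(P[cbind(seq_len(nrow(x)), y)], 1e-12)))
  reg <- regularizer(params$w, config)
  l2 <- .l2sq(params$W1) + .l2sq(params$W2) + .l2sq(params$W3)
  out <- c(list(nll = nll), unclass(reg),
           list(l2_term = l2,
                total = nll + config$lambda0 * reg$r_total + config$lambda1 * l2))
  class(out) <- "loss_breakdown"
  out
}

# Subgradient of R with respect to w (see regularizer()).
.reg_grad_w <- function(w, config) {
  aw <- abs(w); sw <- sign(w)
  g <- sw * abs(w - 1) + aw * sign(w - 1)                    # sparsity
  excess <- sum(aw) - config$d
  if (config$exceed_only) {
    if (excess > 0) g <- g + config$alpha * sw
  } else {
    g <- g + config$alpha * sign(excess) * sw
  }
  g <- g - config$beta * config$p * sw * (aw < 1)            # priority
  if (nrow(config$pairs) > 0L) {
    i <- config$pairs[, 1L]; j <- config$pairs[, 2L]
    s <- sign(aw[i] - aw[j])
    gc <- numeric(length(w))
    inc_i <- config$gamma * s * sw[i]
    inc_j <- -config$gamma * s * sw[j]
    for (r in seq_along(i)) {
      gc[i[r]] <- gc[i[r]] + inc_i[r]
      gc[j[r]] <- gc[j[r]] + inc_j[r]
    }
    g <- g + gc
  }
  g
}

# One backprop pass on a batch; returns gradients for all parameters.
.gradients <- function(params, X, Y1hot, config) {
  B <- nrow(X)
  f <- .forward_full(params, X)
  dA3 <- (f$P - Y1hot) / B
  gW3 <- crossprod(f$H2, dA3)
  gb3 <- colSums(dA3)
  dA2 <- (dA3 %*% t(params$W3)) * (f$A2 > 0)
  gW2 <- crossprod(f$H1, dA2)
  gb2 <- colSums(dA2)
  dA1 <- (dA2 %*% t(params$W2)) * (f$A1 > 0)
  gW1 <- crossprod(f$Z0, dA1)
  gb1 <- colSums(dA1)
  dZ0 <- dA1 %*% t(params$W1)
  gw <- colSums(dZ0 * X)
  out <- list(
    w  = gw + config$lambda0 * .reg_grad_w(params$w, config),
    W1 = gW1 + 2 * config$lambda1 * params$W1, b1 = gb1,
    W2 = gW2 + 2 * config$lambda1 * params$W2, b2 = gb2,
    W3 = gW3 + 2 * config$lambda1 * params$W3, b3 = gb3
  )
  lapply(out, function(g) { dimnames(g) <- NULL; names(g) <- NULL; g })
}

#' Train the panel-design model
#'
#' Minimizes the regularized classification loss with Adam (adaptive-moment
#' gradient descent). The run is fully reproducible given \code{seed}, which
#' controls initialization and the per-epoch batch order.
#'
#' @param x Cells x genes numeric matrix of log-normalized (typically also
#'   scaled) expression; column names are the gene ids.
#' @param labels Cell-type labels, one per row of \code{x} (factor or
#'   vector); at least two classes. Classes are encoded in first-appearance
#'   order.
#' @param config A \code{\link{panel_config}} (resolved automatically).
#' @param epochs Number of passes over the data (default 100).
#' @param batch_size Minibatch size (default 64).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed Integer seed for initialization and batch shuffling.
#' @param verbose Print the loss every 10 epochs.
#' @return Object of class \code{panel_model}: \code{params},
#'   \code{history} (one \code{loss_breakdown} row per epoch, as a data
#'   frame), \code{config} (resolved), \code{gene_ids}, \code{class_names}.
#' @export
train_model <- function(x, labels, config, epochs = 100L, batch_size = 64L,
                        learning_rate = 1e-3, seed = 0L, verbose = FALSE) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (!all(is.finite(x))) stop("expression matrix must be finite")
  if (nrow(x) != length(labels)) stop("labels must align with rows of x")
  stopifnot(epochs >= 0, batch_size >= 1)
  gene_ids <- colnames(x)
  if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(ncol(x)))
  labels <- as.character(labels)
  class_names <- unique(labels)
  if (length(class_names) < 2L)
    stop("at least 2 cell types are required")
  y <- match(labels, class_names)
  if (min(table(y)) < 1L) stop("every class must appear at least once")
  config <- resolve_config(config, gene_ids)

  N <- nrow(x); n <- ncol(x); cc <- length(class_names)
  params <- init_params(n, cc, seed = seed)
  Y1hot <- matrix(0, N, cc); Y1hot[cbind(seq_len(N), y)] <- 1

  # Adam state
  mom <- lapply(params, function(p) p * 0)
  vel <- lapply(params, function(p) p * 0)
  b1m <- 0.9; b2m <- 0.999; eps <- 1e-8; t <- 0L
  history <- vector("list", epochs)

  .with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      for (start in seq(1L, N, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, N)]
        g <- .gradients(params,
                        x[idx, , drop = FALSE],
                        Y1hot[idx, , drop = FALSE], config)
        t <- t + 1L
        for (nm in names(params)) {
          mom[[nm]] <- b1m * mom[[nm]] + (1 - b1m) * g[[nm]]
          vel[[nm]] <- b2m * vel[[nm]] + (1 - b2m) * g[[nm]]^2
          mhat <- mom[[nm]] / (1 - b1m^t)
          vhat <- vel[[nm]] / (1 - b2m^t)
          params[[nm]] <- params[[nm]] - learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
      lb <- total_loss(params, x, y, config)
      history[[ep]] <- as.data.frame(unclass(lb))
      if (verbose && ep %% 10L == 0L)
        message(sprintf("epoch %3d  total %.4f  nll %.4f  |w|_1 %.1f",
                        ep, lb$total, lb$nll, sum(abs(params$w))))
    }
  })

  structure(list(params = params,
                 history = if (epochs > 0) do.call(rbind, history)
                           else data.frame(),
                 config = config, gene_ids = gene_ids,
                 class_names = class_names, seed = seed),
            class = "panel_model")
}

#' Extract the gene panel from a trained model
#'
#' Selects the \code{d} genes with the largest absolute selection weights;
#' ties at the panel boundary are broken by ascending gene index, so the
#' result is deterministic.
#'
#' @param object A \code{panel_model}, or a \code{panel_params} list (then
#'   \code{gene_ids} and \code{config} must be given).
#' @param d Panel size; defaults to the config's \code{d}.
#' @param gene_ids Gene identifiers (taken from the model if absent).
#' @param config Resolved \code{\link{panel_config}} used to fill the
#'   provenance flags (taken from the model if absent).
#' @return Data frame of class \code{gene_panel} with columns \code{rank},
#'   \code{gene_id}, \code{weight} (the absolute selection weight,
#'   non-increasing), \code{prioritized} (logical) and \code{complex_id}
#'   (integer or \code{NA}).
#' @export
select_panel <- function(object, d = NULL, gene_ids = NULL, config = NULL) {
  if (inherits(object, "panel_model")) {
    params <- object$params
    if (is.null(gene_ids)) gene_ids <- object$gene_ids
    if (is.null(config)) config <- object$config
  } else {
    params <- object
  }
  w <- params$w
  if (is.null(gene_ids)) gene_ids <- paste0("G", seq_along(w))
  stopifnot(length(gene_ids) == length(w))
  if (is.null(d)) {
    if (is.null(config)) stop("either d or a config with d is required")
    d <- config$d
  }
  if (d > length(w)) stop("d (", d, ") exceeds the number of genes")
  aw <- abs(w)
  ord <- order(-aw, seq_along(aw))[seq_len(d)]
  prioritized <- rep(FALSE, d)
  complex_id <- rep(NA_integer_, d)
  if (!is.null(config) && isTRUE(config$resolved)) {
    prioritized <- config$p[ord] > 0
    if (length(config$complex_of))
      complex_id <- unname(config$complex_of[match(gene_ids[ord],
                                                   names(config$complex_of))])
  }
  structure(data.frame(rank = seq_len(d), gene_id = gene_ids[ord],
                       weight = aw[ord], prioritized = prioritized,
                       complex_id = complex_id,
                       stringsAsFactors = FALSE),
            class = c("gene_panel", "data.frame"))
}

#' @export
print.panel_model <- function(x, ...) {
  cat("Panel-design model:", length(x$gene_ids), "genes,",
      length(x$class_names), "cell types\n")
  cat("  target panel size d =", x$config$d,
      " |w|_1 =", round(sum(abs(x$params$w)), 2), "\n")
  if (nrow(x$history))
    cat("  final loss:", round(utils::tail(x$history$total, 1), 4),
        "after", nrow(x$history), "epochs\n")
  invisible(x)
}
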