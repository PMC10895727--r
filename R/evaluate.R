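# Panel evaluation protocol: restrict the matrix to the panel genes, split
# 75:25, fit a k-nearest-neighbour classifier on the training part and
# report accuracy, macro F1, per-class F1 and the confusion matrix on the
# held-out part. All tie-breaks are deterministic so the report is a pure
# function of (panel, x, labels, k, seed).

#' Train/test split
#'
#' Seeded, disjoint and exhaustive split. Stratified by class by default so
#' every class appears in both sets; per-class test counts are
#' \code{round(n_class * (1 - ratio))} (at least one cell stays in train). A
#' single-cell class goes to the training set with a warning.
#'
#' @param labels Per-cell class labels.
#' @param ratio Training fraction in (0, 1); default 0.75.
#' @param stratified Stratify by class (default TRUE).
#' @param seed Integer seed.
#' @return List with integer index vectors \code{train} and \code{test}.
#' @export
split_train_test <- function(labels, ratio = 0.75, stratified = TRUE,
                             seed = 0L) {
  stopifnot(ratio > 0, ratio < 1)
  labels <- as.character(labels)
  N <- length(labels)
  test <- integer(0)
  .with_seed(seed, {
    if (stratified) {
      classes <- unique(labels)
      sizes <- vapply(classes, function(cl) sum(labels == cl), 1L)
      single <- sizes < 2L
      if (any(single))
        warning("class(es) with a single cell assigned to train: ",
                paste(classes[single], collapse = ", "))
      # largest-remainder allocation: per-class floor, then distribute the
      # shortfall against the exact overall test size
      exact <- sizes * (1 - ratio)
      n_test <- floor(exact)
      n_test[single] <- 0L
      n_test <- pmin(n_test, sizes - 1L)
      shortfall <- round(N * (1 - ratio)) - sum(n_test)
      if (shortfall > 0) {
        room <- !single & n_test < sizes - 1L
        ord <- order(-(exact - floor(exact)), -sizes)
        ord <- ord[room[ord]]
        for (ix in utils::head(ord, shortfall))
          n_test[ix] <- n_test[ix] + 1L
      }
      for (ci in seq_along(classes)) {
        i <- which(labels == classes[ci])
        if (n_test[ci] > 0L) test <- c(test, sample(i, n_test[ci]))
      }
    } else {
      n_train <- round(N * ratio)
      test <- sample.int(N, N - n_train)
    }
  })
  test <- sort(test)
  list(train = setdiff(seq_len(N), test), test = test)
}

#' Confusion matrix
#'
#' Entry (i, j) counts cells of true class i predicted as class j.
#'
#' @param y_true,y_pred Integer labels in \code{1..n_classes}.
#' @param n_classes Number of classes.
#' @param normalize Row-normalize for display (rows sum to 1; empty rows 0).
#' @return \code{n_classes x n_classes} matrix.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes, normalize = FALSE) {
  stopifnot(length(y_true) == length(y_pred),
            all(y_true >= 1 & y_true <= n_classes),
            all(y_pred >= 1 & y_pred <= n_classes))
  cm <- unclass(table(factor(y_true, levels = seq_len(n_classes)),
                      factor(y_pred, levels = seq_len(n_classes))))
  dimnames(cm) <- NULL
  if (normalize) {
    rs <- rowSums(cm)
    cm <- cm / ifelse(rs > 0, rs, 1)
  }
  cm
}

#' Macro F1 score
#'
#' Per class, one-vs-rest F1 = 2PR/(P+R); a class with no true and no
#' predicted positives contributes F1 = 0 (penalizing missed rare classes).
#' Macro F1 is the unweighted mean over all classes.
#'
#' @param y_true,y_pred Integer labels in \code{1..n_classes}.
#' @param n_classes Number of classes; defaults to the largest label seen.
#' @return List with \code{macro_f1} and \code{per_class_f1}.
#' @export
macro_f1 <- function(y_true, y_pred, n_classes = max(y_true, y_pred)) {
  cm <- confusion_matrix(y_true, y_pred, n_classes)
  tp <- diag(cm)
  f1 <- ifelse(2 * tp + (rowSums(cm) - tp) + (colSums(cm) - tp) > 0,
               2 * tp / (2 * tp + (rowSums(cm) - tp) + (colSums(cm) - tp)),
               0)
  list(macro_f1 = mean(f1), per_class_f1 = unname(f1))
}

# Deterministic k-NN: Euclidean distance, first-k neighbours with distance
# ties broken by smaller train index, majority vote with ties broken by
# lowest class index.
.knn_predict <- function(train_x, train_y, test_x, k, n_classes) {
  if (k > nrow(train_x))
    stop("k (", k, ") exceeds the training-set size (", nrow(train_x), ")")
  d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") -
    2 * tcrossprod(test_x, train_x)
  apply(d2, 1L, function(row) {
    nb <- train_y[order(row, seq_along(row))[seq_len(k)]]
    which.max(tabulate(nb, nbins = n_classes))
  })
}

#' Evaluate a gene panel with a k-NN classifier
#'
#' Restricts the expression matrix to the panel genes, splits the cells into
#' train and test sets, fits a k-nearest-neighbour classifier on the
#' training part and computes accuracy, macro F1, per-class F1 and the
#' confusion matrix on the test part.
#'
#' @param panel A \code{gene_panel} (from \code{\link{select_panel}}) or a
#'   character vector of gene ids.
#' @param x Cells x genes matrix with gene ids as column names.
#' @param labels Per-cell class labels.
#' @param k Number of neighbours (default 5).
#' @param ratio Training fraction (default 0.75).
#' @param stratified Stratify the split by class (default TRUE).
#' @param seed Split seed.
#' @return Object of class \code{evaluation_report}: \code{accuracy},
#'   \code{macro_f1}, \code{per_class_f1}, \code{confusion} (rows = true),
#'   \code{class_names}, \code{panel_size}, \code{k}, \code{seed},
#'   \code{n_test}.
#' @export
knn_evaluate <- function(panel, x, labels, k = 5L, ratio = 0.75,
                         stratified = TRUE, seed = 0L) {
  genes <- if (inherits(panel, "gene_panel") || is.data.frame(panel))
    panel$gene_id else as.character(panel)
  stopifnot(k >= 1)
  missing_genes <- setdiff(genes, colnames(x))
  if (length(missing_genes))
    stop("panel genes absent from the matrix: ",
         paste(missing_genes, collapse = ", "))
  labels <- as.character(labels)
  class_names <- unique(labels)
  y <- match(labels, class_names)
  Xp <- x[, genes, drop = FALSE]
  sp <- split_train_test(labels, ratio = ratio, stratified = stratified,
                         seed = seed)
  pred <- .knn_predict(Xp[sp$train, , drop = FALSE], y[sp$train],
                       Xp[sp$test, , drop = FALSE], k,
                       n_classes = length(class_names))
  truth <- y[sp$test]
  cm <- confusion_matrix(truth, pred, length(class_names))
  f1 <- macro_f1(truth, pred, length(class_names))
  structure(list(accuracy = sum(diag(cm)) / sum(cm),
                 macro_f1 = f1$macro_f1, per_class_f1 = f1$per_class_f1,
                 confusion = cm, class_names = class_names,
                 panel_size = length(genes), k = k, seed = seed,
                 n_test = length(sp$test)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("k-NN evaluation (k = %d, panel size = %d, %d test cells)\n",
              x$k, x$panel_size, x$n_test))
  cat(sprintf("  accuracy: %.4f   macro F1: %.4f\n", x$accuracy, x$macro_f1))
  invisible(x)
}
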