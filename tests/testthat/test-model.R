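test_that("forward produces valid class distributions and masks w = 0 genes", {
  set.seed(3)
  p <- init_params(6, 3, seed = 2)
  p$w <- runif(6)
  X <- matrix(rnorm(30, sd = 4), 5, 6)
  P <- forward(p, X)
  expect_equal(dim(P), c(5L, 3L))
  expect_true(all(P >= 0))
  expect_equal(rowSums(P), rep(1, 5), tolerance = 1e-6)

  # all-zero w: output independent of the input
  p0 <- p; p0$w <- rep(0, 6)
  expect_equal(forward(p0, X), forward(p0, -3 * X))

  # a single masked gene: doubling its expression changes nothing
  pm <- p; pm$w[4] <- 0
  X2 <- X; X2[, 4] <- 2 * X2[, 4]
  expect_equal(forward(pm, X), forward(pm, X2))

  # extreme inputs still give finite, normalized distributions
  Pe <- forward(p, matrix(c(1e6, -1e6, 500, 0, 3, -7), 1, 6))
  expect_true(all(is.finite(Pe)))
  expect_equal(sum(Pe), 1, tolerance = 1e-6)

  expect_error(forward(p, matrix(0, 2, 5)), "features")
})

test_that("total loss decomposes into nll, regularizer and L2 terms", {
  ids <- paste0("G", 1:4)
  cfg <- resolve_config(panel_config(d = 2, lambda0 = 0, lambda1 = 0), ids)
  # a model that assigns probability ~1 to the true class via huge logits
  p <- init_params(4, 2, seed = 1)
  p$w <- rep(1, 4)
  p$W1 <- matrix(0, 4, 32); p$W1[1, 1] <- 1
  p$W2 <- matrix(0, 32, 16); p$W2[1, 1] <- 1
  p$W3 <- matrix(0, 16, 2); p$W3[1, 1] <- 50; p$W3[1, 2] <- -50
  p$b3 <- c(0, 0)
  x <- matrix(c(10, 0, 0, 0), 1, 4)
  expect_equal(total_loss(p, x, 1L, cfg)$total, 0, tolerance = 1e-8)

  # uniform output: nll = log(number of classes)
  cfg4 <- resolve_config(panel_config(d = 2, lambda0 = 0, lambda1 = 0), ids)
  pu <- init_params(4, 4, seed = 1)
  pu$W3 <- matrix(0, 16, 4); pu$b3 <- rep(0, 4)
  xs <- matrix(rnorm(20), 5, 4)
  expect_equal(total_loss(pu, xs, c(1L, 2L, 3L, 4L, 1L), cfg4)$total, log(4),
               tolerance = 1e-8)

  # lambda0 = 1, lambda1 = 0: total = nll + R with R from the regularizer
  cfgR <- resolve_config(panel_config(d = 2, lambda0 = 1, lambda1 = 0), ids)
  pr <- init_params(4, 2, seed = 3)
  pr$w <- c(0.3, -0.8, 1.2, 0)
  lb <- total_loss(pr, xs, c(1L, 2L, 1L, 2L, 1L), cfgR)
  expect_equal(lb$total, lb$nll + regularizer(pr$w, cfgR)$r_total,
               tolerance = 1e-10)
  # breakdown invariant with both multipliers active
  cfgB <- resolve_config(panel_config(d = 2), ids)
  lb2 <- total_loss(pr, xs, c(1L, 2L, 1L, 2L, 1L), cfgB)
  expect_equal(lb2$total, lb2$nll + cfgB$lambda0 * lb2$r_total +
                 cfgB$lambda1 * lb2$l2_term, tolerance = 1e-10)

  expect_error(total_loss(pr, xs, c(1L, 5L, 1L, 2L, 1L), cfgR),
               "out of range")
})

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  n <- 6; cc <- 3; N <- 8
  x <- matrix(rnorm(N * n), N, n)
  colnames(x) <- paste0("G", 1:n)
  y <- c(1:3, sample(1:cc, N - 3, replace = TRUE))
  cfg <- resolve_config(panel_config(d = 2, priorities = c(G2 = 0.7),
                                     complexes = list(c("G3", "G4"))),
                        colnames(x))
  p <- init_params(n, cc, seed = 7)
  # keep w away from the regularizer's kinks (0, 1, |w|1 = d)
  p$w <- c(0.31, -0.62, 1.24, 0.83, -0.17, 0.48)
  Y1 <- matrix(0, N, cc); Y1[cbind(1:N, y)] <- 1
  g <- scPanelDesign:::.gradients(p, x, Y1, cfg)
  J <- function(p) total_loss(p, x, y, cfg)$total
  eps <- 1e-6
  for (nm in names(p)) {
    num <- p[[nm]]
    for (i in seq_along(num)) {
      pp <- p; pm <- p
      pp[[nm]][i] <- pp[[nm]][i] + eps
      pm[[nm]][i] <- pm[[nm]][i] - eps
      num[i] <- (J(pp) - J(pm)) / (2 * eps)
    }
    expect_equal(g[[nm]], num, tolerance = 1e-5,
                 label = paste("gradient of", nm))
  }
})

test_that("training is reproducible and epochs = 0 returns the init", {
  sp <- small_processed()
  cfg <- panel_config(d = 6)
  m0 <- train_model(sp$x, sp$labels, cfg, epochs = 0L, seed = 3)
  expect_equal(m0$params$w, rep(0.5, ncol(sp$x)))
  expect_equal(nrow(m0$history), 0L)

  m1 <- train_model(sp$x, sp$labels, cfg, epochs = 8L, seed = 5)
  m2 <- train_model(sp$x, sp$labels, cfg, epochs = 8L, seed = 5)
  expect_identical(m1$params, m2$params)
  expect_identical(select_panel(m1)$gene_id, select_panel(m2)$gene_id)
  m3 <- train_model(sp$x, sp$labels, cfg, epochs = 8L, seed = 6)
  expect_false(identical(m1$params$W1, m3$params$W1))

  # loss history: trends downward over training
  m <- train_model(sp$x, sp$labels, cfg, epochs = 40L, seed = 1)
  expect_lt(utils::tail(m$history$total, 1), m$history$total[1])

  expect_error(train_model(sp$x, rep("a", nrow(sp$x)), cfg), "2 cell types")
  expect_error(train_model(sp$x, sp$labels, panel_config(d = 5000)),
               "exceeds")
})

test_that("training recovers planted exclusive markers", {
  sp <- small_processed()
  d <- length(sp$truth$marker_gene_ids)  # 6 markers for 3 types
  hits <- 0L
  for (s in 0:4) {
    m <- train_model(sp$x, sp$labels, panel_config(d = d), seed = s)
    panel <- select_panel(m)
    if (truth_recovery_score(panel, sp$truth) == 1) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("panel selection returns exactly d genes, sorted, ties by index", {
  p <- list(w = c(0.9, 0.1, 0.8, 0.2))
  panel <- select_panel(p, d = 2, gene_ids = paste0("G", 1:4))
  expect_equal(panel$gene_id, c("G1", "G3"))
  expect_equal(panel$rank, 1:2)

  tie <- select_panel(list(w = c(0.5, 0.5, 0.5)), d = 2,
                      gene_ids = paste0("G", 1:3))
  expect_equal(tie$gene_id, c("G1", "G2"))

  full <- select_panel(list(w = c(0.2, -0.7, 0.4)), d = 3,
                       gene_ids = paste0("G", 1:3))
  expect_equal(full$gene_id, c("G2", "G3", "G1"))  # by |w| descending
  expect_true(all(diff(full$weight) <= 0))

  # property: always exactly d unique genes
  set.seed(9)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    d <- sample.int(n, 1)
    pan <- select_panel(list(w = round(runif(n), 1)), d = d,
                        gene_ids = paste0("G", seq_len(n)))
    expect_equal(nrow(pan), d)
    expect_equal(anyDuplicated(pan$gene_id), 0L)
    expect_true(all(diff(pan$weight) <= 0))
  }

  expect_error(select_panel(p, d = 9, gene_ids = paste0("G", 1:4)),
               "exceeds")
})

test_that("panel provenance flags reflect priorities and complexes", {
  ids <- paste0("G", 1:5)
  cfg <- resolve_config(panel_config(d = 4, priorities = c(G2 = 0.8),
                                     complexes = list(c("G3", "G4"))), ids)
  panel <- select_panel(list(w = c(0.9, 0.8, 0.7, 0.6, 0.1)), d = 4,
                        gene_ids = ids, config = cfg)
  expect_equal(panel$prioritized, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(panel$complex_id, c(NA_integer_, NA_integer_, 1L, 1L))
})
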