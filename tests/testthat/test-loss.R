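test_that("sparsity penalty vanishes only on 0/1 weight vectors", {
  expect_equal(sparsity_penalty(c(0, 1, 0, 1)), 0)
  expect_equal(sparsity_penalty(0.5), 0.25)
  expect_equal(sparsity_penalty(2), 2)
  expect_gt(sparsity_penalty(c(0, 1, 0.3)), 0)
  expect_error(sparsity_penalty(c(1, NA)), "finite")
  expect_error(sparsity_penalty(c(1, Inf)), "finite")
})

test_that("size penalty measures distance of the weight budget from d", {
  expect_equal(size_penalty(rep(1, 5), d = 5, alpha = 1.5), 0)
  expect_equal(size_penalty(c(1, 1, 1), d = 2, alpha = 1.5), 1.5)
  expect_equal(size_penalty(1, d = 2, alpha = 1.5, exceed_only = TRUE), 0)
  expect_equal(size_penalty(c(1, 1, 1), d = 2, alpha = 1.5,
                            exceed_only = TRUE), 1.5)
  # negative weights count through |w|
  expect_equal(size_penalty(c(-1, -1), d = 2, alpha = 1.5), 0)
})

test_that("priority penalty rewards prioritized genes at full weight", {
  expect_equal(priority_penalty(c(1, 1), priorities = c(1, 1), beta = 0.2), 0)
  expect_equal(priority_penalty(0, priorities = 1, beta = 0.2), 0.2)
  expect_equal(priority_penalty(1.5, priorities = 1, beta = 0.2), 0)
  # scales with the score and the shortfall
  expect_equal(priority_penalty(0.5, priorities = 0.6, beta = 0.2),
               0.2 * 0.6 * 0.5)
})

test_that("complex penalty measures within-pair weight mismatch", {
  pair <- matrix(c(1L, 2L), ncol = 2)
  expect_equal(complex_penalty(c(0.7, 0.7), pair, gamma = 1), 0)
  expect_equal(complex_penalty(c(0.8, 0.3), pair, gamma = 1), 0.5)
  expect_equal(complex_penalty(c(-0.4, 0.4), pair, gamma = 1), 0)
  expect_equal(complex_penalty(c(0.8, 0.3), pair, gamma = 0.5), 0.25)
  expect_error(complex_penalty(c(1, 1), matrix(c(1L, 1L), ncol = 2)),
               "self-pairs")
  expect_error(complex_penalty(c(1, 1), matrix(c(1L, 3L), ncol = 2)),
               "out of range")
})

test_that("regularizer assembles the four terms and reports them", {
  cfg <- resolve_config(panel_config(d = 2), paste0("G", 1:3))
  rb <- regularizer(c(1, 1, 1), cfg)
  expect_equal(rb$sparsity_term, 0)
  expect_equal(rb$size_term, 1.5)
  expect_equal(rb$priority_term, 0)
  expect_equal(rb$complex_term, 0)
  expect_equal(rb$r_total, 1.5)

  cfg2 <- resolve_config(panel_config(d = 1, priorities = c(G1 = 1)), "G1")
  rb2 <- regularizer(0.5, cfg2)
  expect_equal(rb2$sparsity_term, 0.25)
  expect_equal(rb2$size_term, 1.5 * 0.5)
  expect_equal(rb2$priority_term, 0.2 * 0.5)
  expect_equal(rb2$r_total, 0.25 + 0.75 + 0.1)

  expect_error(regularizer(c(1, 1), cfg), "does not match")
})

test_that("regularizer matches a brute-force oracle on random vectors", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(3:20, 1)
    ids <- paste0("G", seq_len(n))
    w <- runif(n, -2, 3)
    d <- sample.int(n, 1)
    pr_n <- sample(0:n, 1)
    pr <- if (pr_n > 0) setNames(runif(pr_n), sample(ids, pr_n))
    cxs <- if (n >= 4 && runif(1) < 0.5)
      list(sample(ids, 2), sample(ids, min(3, n))) else NULL
    eo <- runif(1) < 0.3
    cfg <- resolve_config(
      panel_config(d = d, alpha = 1.5, beta = 0.2, gamma = 0.5,
                   exceed_only = eo, priorities = pr, complexes = cxs), ids)
    expect_equal(regularizer(w, cfg)$r_total,
                 oracle_regularizer(w, d, 1.5, 0.2, 0.5, cfg$p, cfg$pairs,
                                    exceed_only = eo),
                 tolerance = 1e-9)
  }
})

test_that("R is zero exactly on ideal panels", {
  ids <- paste0("G", 1:6)
  cfg <- resolve_config(
    panel_config(d = 3, priorities = c(G1 = 1),
                 complexes = list(c("G1", "G2"))), ids)
  w_ideal <- c(1, 1, 1, 0, 0, 0)
  expect_equal(regularizer(w_ideal, cfg)$r_total, 0)
  # each violated condition makes R positive
  expect_gt(regularizer(c(0.9, 1, 1, 0, 0, 0), cfg)$r_total, 0)  # not 0/1
  expect_gt(regularizer(c(1, 1, 1, 1, 0, 0), cfg)$r_total, 0)    # |w|1 != d
  expect_gt(regularizer(c(0, 1, 1, 1, 0, 0), cfg)$r_total, 0)    # G1 out
  expect_gt(regularizer(c(1, 0, 1, 1, 0, 0), cfg)$r_total, 0)    # pair broken
})

test_that("all penalty terms are invariant under consistent permutation", {
  set.seed(7)
  n <- 12
  ids <- paste0("G", 1:n)
  w <- runif(n, -1, 2)
  pr <- setNames(runif(4), sample(ids, 4))
  cfg <- resolve_config(panel_config(d = 5, priorities = pr,
                                     complexes = list(ids[1:3], ids[7:8])),
                        ids)
  perm <- sample.int(n)
  cfg_p <- resolve_config(panel_config(d = 5, priorities = pr,
                                       complexes = list(ids[1:3], ids[7:8])),
                          ids[perm])
  r1 <- regularizer(w, cfg)
  r2 <- regularizer(w[perm], cfg_p)
  for (nm in names(r1)) expect_equal(r1[[nm]], r2[[nm]], tolerance = 1e-12)
})

test_that("config validates and clamps inputs", {
  expect_error(panel_config(d = 0), "d")
  expect_error(panel_config(d = 5, alpha = -1), "alpha")
  expect_warning(cfg <- panel_config(d = 2, priorities = c(G1 = 1.7)),
                 "clamped")
  expect_equal(cfg$priorities[["G1"]], 1)
  expect_error(panel_config(d = 2, complexes = list("G1")), "at least 2")
  expect_error(resolve_config(panel_config(d = 5), paste0("G", 1:3)),
               "exceeds")
  expect_warning(
    rc <- resolve_config(panel_config(d = 1, priorities = c(BAD = 1)),
                         c("G1", "G2")),
    "unknown")
  expect_equal(rc$p, c(0, 0))
})

test_that("complex encoding enumerates all pairs and anchors one gene", {
  ids3 <- c("A", "B", "C")
  enc3 <- encode_complexes(list(ids3), seed = 1)
  expect_equal(nrow(enc3$pairs), 3L)
  expect_equal(nrow(encode_complexes(list(c("A", "B")), seed = 1)$pairs), 1L)
  expect_equal(nrow(encode_complexes(list(LETTERS[1:5]), seed = 1)$pairs), 10L)
  # every anchored gene gets priority 1; anchors are members
  expect_true(all(enc3$priorities == 1))
  expect_true(all(names(enc3$priorities) %in% ids3))
  # user priorities never overwritten, and respected as pair anchors
  encu <- encode_complexes(list(c("A", "B")), priorities = c(A = 0.3),
                           seed = 1)
  expect_equal(encu$priorities[["A"]], 0.3)
  expect_false("B" %in% names(encu$priorities))
  # deterministic given the seed
  expect_identical(encode_complexes(list(ids3), seed = 5),
                   encode_complexes(list(ids3), seed = 5))
  expect_warning(enc1 <- encode_complexes(list("A", c("B", "C")), seed = 1),
                 "skipped")
  expect_equal(nrow(enc1$pairs), 1L)
})
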