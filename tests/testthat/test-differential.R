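test_that("pooled t-test handles degenerate and separated groups", {
  same <- t_test_pooled(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)
  shifted <- t_test_pooled(c(1, 2, 3), c(101, 102, 103))
  expect_lt(shifted$p_value, 0.05)
  expect_error(t_test_pooled(1, c(1, 2)), "at least two")
})

test_that("pooled t-test matches the reference implementation", {
  withr::with_seed(31, {
    for (i in 1:50) {
      x <- rnorm(sample(3:10, 1), sd = runif(1, 0.5, 3))
      y <- rnorm(sample(3:10, 1), mean = runif(1, -1, 1))
      ours <- t_test_pooled(x, y)
      ref <- stats::t.test(x, y, var.equal = TRUE)
      expect_equal(ours$t_stat, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
      # invariance under a common positive affine transform
      tr <- t_test_pooled(3 * x + 7, 3 * y + 7)
      expect_equal(tr$t_stat, ours$t_stat, tolerance = 1e-10)
    }
  })
})

test_that("fold change is a ratio >= 1 with a separate direction", {
  expect_equal(fold_change(100, 270), list(fold_change = 2.7, direction = "up"))
  expect_equal(fold_change(530, 100), list(fold_change = 5.3, direction = "down"))
  tie <- fold_change(100, 100)
  expect_equal(tie$fold_change, 1)
  expect_identical(tie$direction, "none")
  # symmetry with flipped direction
  ab <- fold_change(120, 300)
  ba <- fold_change(300, 120)
  expect_equal(ab$fold_change, ba$fold_change)
  expect_identical(c(ab$direction, ba$direction), c("up", "down"))
  expect_error(fold_change(0, 10), "positive")
})

test_that("planted differential features are recovered on a null background", {
  fc <- c(F001 = 2.5, F002 = 2.5, F003 = 2.5)
  b <- generate_batch(
    n_features = 23, class_counts = c(steady = 23),
    fold_changes = fc, noise_cv = 0.10, seed = 41
  )
  res <- differential_table(b$features, b$schedule)
  expect_true(all(res$significant[match(names(fc), res$feature_id)]))
  expect_identical(res$direction[match(names(fc), res$feature_id)], rep("up", 3))
  # false positives no worse than a generous binomial bound at alpha = 0.05
  fp <- sum(res$significant[!res$feature_id %in% names(fc)])
  expect_lte(fp, qbinom(0.999, 20, 0.05))
  # alpha = 0 switches everything off
  res0 <- differential_table(b$features, b$schedule, alpha = 0)
  expect_false(any(res0$significant))
  # BH adjustment adds a p_adj column and only shrinks the significant set
  resbh <- differential_table(b$features, b$schedule, adjust = "BH")
  expect_true(all(resbh$p_adj >= resbh$p_value))
  expect_lte(sum(resbh$significant), sum(res$significant))
})

test_that("hierarchical clustering of significant features recovers planted blocks", {
  b <- generate_batch(
    n_features = 12, class_counts = c(steady = 12),
    fold_changes = stats::setNames(
      rep(c(3, 1 / 3), each = 6), sprintf("F%03d", 1:12)
    ),
    noise_cv = 0.05, seed = 51
  )
  res <- differential_table(b$features, b$schedule)
  hc <- hcluster_features(res, b$features, b$schedule)
  expect_identical(length(hc$hclust$order), sum(res$significant))
  blocks <- stats::cutree(hc$hclust, k = 2)
  truth <- ifelse(as.integer(sub("F", "", names(blocks))) <= 6, 1, 2)
  expect_true(all(blocks == blocks[1] | truth != truth[1]))
  expect_equal(length(unique(paste(blocks, truth))), 2L)

  # identical rows merge first at height 0
  feats <- b$features
  run_cols <- b$schedule$run_id
  feats[2, run_cols] <- feats[1, run_cols] * 2 # identical after z-scoring
  res2 <- res
  hc2 <- hcluster_features(res2, feats, b$schedule)
  expect_equal(min(hc2$hclust$height), 0)

  # fewer than two significant features: skipped with a message
  none <- res
  none$significant <- FALSE
  expect_message(expect_null(hcluster_features(none, feats, b$schedule)), "skipped")
})

test_that("LRWC is the printed formula with guarded inputs", {
  expect_equal(lrwc(2.0, 1.0), 50)
  expect_equal(lrwc(1.5, 1.5), 0)
  expect_equal(lrwc(1.0, 0.0), 100)
  expect_error(lrwc(0, 0), "positive")
  expect_error(lrwc(1, 2), "exceed")
})
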