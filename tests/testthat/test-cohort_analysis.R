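test_that("regression tree reproduces constants and simple step functions", {
  # constant target: root node, predicts the mean everywhere
  fit <- rtree_fit(matrix(1:6, ncol = 1), rep(0.2, 6))
  expect_equal(unname(predict(fit, matrix(c(0, 10), ncol = 1))), c(0.2, 0.2))
  # clean step function: recovered exactly
  x <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1)
  y <- c(0.1, 0.1, 0.1, 0.8, 0.8, 0.8)
  fit2 <- rtree_fit(x, y)
  expect_equal(unname(predict(fit2, matrix(c(2, 11), ncol = 1))), c(0.1, 0.8))
  # pure interpolation on distinct values (grown to purity)
  x3 <- matrix(c(1, 2, 3, 4), ncol = 1)
  y3 <- c(0.1, 0.3, 0.5, 0.9)
  expect_equal(unname(predict(rtree_fit(x3, y3), x3)), y3)
})

test_that("imputation fills only missing cells, deterministically", {
  m0 <- matrix(runif(40), 5, 8,
               dimnames = list(paste0("s", 1:5), paste0("x", 1:8)))
  cond <- rep(c("a", "b"), each = 4)
  # no missing values: identity
  expect_identical(impute_missing(m0, cond), m0)
  # one missing cell where the site is constant elsewhere in the condition
  m1 <- m0
  m1[2, cond == "a"] <- 0.2
  m1[2, 1] <- NA
  out <- impute_missing(m1, cond)
  expect_equal(out[2, 1], 0.2)
  obs <- !is.na(m1)
  expect_identical(out[obs], m1[obs])
  # bitwise determinism
  set.seed(1); a <- impute_missing(m1, cond, seed = 9)
  set.seed(2); b <- impute_missing(m1, cond, seed = 9)
  expect_identical(a, b)
  # site missing in a whole condition: global mean, with a warning
  m2 <- m0
  m2[3, cond == "a"] <- NA
  expect_warning(out2 <- impute_missing(m2, cond), "global mean")
  expect_equal(unname(out2[3, 1]), mean(m0[3, cond == "b"]))
  # values stay in [0, 1]
  expect_true(all(out >= 0 & out <= 1))
})

test_that("rank-sum test matches exact enumeration and wilcox.test", {
  # spec fixture: {0 x5} vs shifted values; exhaustive-permutation oracle
  x <- rep(0, 5); y <- c(0.5, 0.6, 0.5, 0.7, 0.6)
  rs <- ranksum_test(x, y)
  r <- rank(c(x, y)); mu <- 5 * 11 / 2
  ws <- combn(10, 5, function(i) sum(r[i]))
  oracle <- mean(abs(ws - mu) >= abs(rs$statistic - mu) - 1e-9)
  expect_equal(rs$p_value, oracle)
  expect_equal(rs$p_value, 2 / 252)
  expect_true(rs$exact)
  # identical groups: p = 1
  expect_equal(ranksum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # tie-free data: agrees with wilcox.test exact p
  set.seed(3)
  for (i in 1:5) {
    a <- rnorm(6); b <- rnorm(7) + 0.5
    expect_equal(ranksum_test(a, b)$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value)
  }
  # large groups: normal approximation close to wilcox.test
  a <- rnorm(30); b <- rnorm(30) + 0.3
  expect_equal(ranksum_test(a, b)$p_value,
               wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-6)
  expect_error(ranksum_test(1, c(1, 2)), "at least 2")
})

test_that("site selection keeps sites with any p < 0.1 against reference", {
  m <- rbind(
    flat = rep(0.3, 10),
    hit = c(rep(0, 5), rep(0.9, 5)),
    na_site = c(NA, NA, NA, NA, NA, 0.1, 0.2, 0.1, 0.2, 0.1))
  cond <- rep(c("healthy", "cancer"), each = 5)
  sel <- suppressWarnings(select_sites(m, cond, "healthy"))
  expect_false(sel$selected[sel$site_id == "flat"])   # identical: p = 1
  expect_true(sel$selected[sel$site_id == "hit"])     # p = 2/252 < 0.1
  expect_false(sel$selected[sel$site_id == "na_site"])
  expect_error(select_sites(m, cond, "absent"), "not present")
  # no non-reference condition: nothing selected
  sel0 <- select_sites(m[1:2, 1:5], rep("healthy", 5), "healthy")
  expect_true(all(!sel0$selected))
  # invariant to sample order
  o <- c(3, 1, 5, 2, 4, 8, 6, 10, 7, 9)
  sel_o <- suppressWarnings(select_sites(m[, o], cond[o], "healthy"))
  expect_equal(sel_o$selected, sel$selected)
})

test_that("PCA centers, fixes signs, and separates a rank-1 structure", {
  # two point clouds differing on one site only
  m <- rbind(sep = c(0, 0, 0, 0, 1, 1, 1, 1) + 1e-3 * (1:8),
             noise = rep(0.2, 8) + 1e-3 * c(8:1))
  colnames(m) <- paste0("s", 1:8); rownames(m) <- c("sep", "noise")
  pca <- run_pca(m)
  expect_gt(pca$var_explained[1], 0.99)
  expect_true(all(pca$scores[1:4, 1] < 0) || all(pca$scores[1:4, 1] > 0))
  expect_true(max(pca$scores[1:4, 1]) < min(pca$scores[5:8, 1]) ||
              min(pca$scores[1:4, 1]) > max(pca$scores[5:8, 1]))
  # sign convention: dominant loading positive
  expect_gt(pca$loadings[which.max(abs(pca$loadings[, 1])), 1], 0)
  # duplicate samples: identical scores
  expect_equal(pca$scores["s1", ] + c(pca$scores["s2", ] - pca$scores["s1", ]),
               pca$scores["s2", ])
  m2 <- cbind(m, s9 = m[, "s1"])
  p2 <- run_pca(m2)
  expect_equal(p2$scores["s9", ], p2$scores["s1", ])
  # orthogonal scores
  cv <- cov(pca$scores)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  expect_error(run_pca(matrix(0.5, 3, 4, dimnames = list(paste0("c", 1:3),
                                                         paste0("s", 1:4)))),
               "zero variance")
  # reconstruction error decreases with retained components
  set.seed(8)
  m3 <- matrix(runif(60), 6, 10,
               dimnames = list(paste0("t", 1:6), paste0("s", 1:10)))
  p3 <- run_pca(m3)
  x <- scale(t(m3), center = TRUE, scale = FALSE)
  errs <- vapply(1:5, function(k) {
    rec <- p3$scores[, 1:k, drop = FALSE] %*% t(p3$loadings[, 1:k, drop = FALSE])
    sum((x - rec)^2)
  }, numeric(1))
  expect_true(all(diff(errs) < 1e-10))
})

test_that("group comparison assigns direction and significance tiers", {
  m <- rbind(s1 = c(rep(0, 5), 0.5, 0.6, 0.5, 0.7, 0.6),
             s2 = rep(0.4, 10),
             s3 = c(0.5, 0.6, 0.5, 0.7, 0.6, rep(0, 5)))
  cond <- rep(c("healthy", "crc"), each = 5)
  g1 <- compare_groups(m, "s1", cond, "healthy", "crc")
  expect_equal(g1$p_value, 2 / 252)
  expect_equal(g1$significance_tier, "**")
  expect_equal(g1$direction, "up")
  g2 <- compare_groups(m, "s2", cond, "healthy", "crc")
  expect_equal(g2$significance_tier, "none")
  g3 <- compare_groups(m, "s3", cond, "healthy", "crc")
  expect_equal(g3$direction, "down")
  m_na <- m; m_na["s1", 6:10] <- NA
  expect_error(compare_groups(m_na, "s1", cond, "healthy", "crc"),
               "no observed values")
})

test_that("editing matrix holds levels with NA for uncovered sites", {
  calls <- data.frame(
    sample_id = c("a", "a", "b"), site_id = c("s1", "s2", "s1"),
    coverage = 10, edited_count = 2, level = c(0.2, 0.4, 0.1),
    p_value = 0.01, q_value = 0.02, passes = TRUE)
  m <- build_editing_matrix(calls)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["s1", "a"], 0.2)
  expect_true(is.na(m["s2", "b"]))
})
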