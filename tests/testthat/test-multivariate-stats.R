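test_that("Euclidean distances match the brute-force double loop", {
  expect_equal(euclidean_dm(rbind(c(0, 0), c(3, 4)))$d[1, 2], 5)
  x <- matrix(c(1, 1, 1, 1, 1, 1), 2, 3, byrow = TRUE)
  expect_true(all(euclidean_dm(x)$d == 0))
  set.seed(12)
  y <- matrix(rnorm(24), 6, 4)
  dm <- euclidean_dm(y)
  brute <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) brute[i, j] <- sqrt(sum((y[i, ] - y[j, ])^2))
  expect_equal(unname(dm$d), brute, tolerance = 1e-12)
  y[2, 1] <- NA
  expect_error(euclidean_dm(y), "missing")
})

test_that("PERMANOVA pseudo-F equals the classical ANOVA F on univariate
          Euclidean data, and the exhaustive permutation p is reproduced", {
  x <- c(1, 2, 3, 7, 8, 9)
  g <- factor(rep(c("a", "b"), each = 3))
  pm <- permanova(euclidean_dm(matrix(x)), g, n_perm = 999, seed = 3)
  expect_equal(pm$pseudo_f, 54, tolerance = 1e-12)
  expect_equal(pm$pseudo_f, anova(lm(x ~ g))[1, "F value"], tolerance = 1e-12)
  # complete enumeration of the 20 label arrangements: only the observed
  # split and its mirror reach F = 54, so the exact p is 2/20 = 0.1
  splits <- combn(6, 3)
  f_all <- apply(splits, 2, function(i) {
    gg <- factor(ifelse(seq_len(6) %in% i, "a", "b"))
    permanova(euclidean_dm(matrix(x)), gg, n_perm = 1, seed = 1)$pseudo_f
  })
  expect_equal(mean(f_all >= pm$pseudo_f), 0.1)
  expect_gte(pm$p_value, 1 / 1000)
  expect_lt(abs(pm$p_value - 0.1), 0.04)
  # seed-reproducible p-values
  expect_identical(pm$p_value,
                   permanova(euclidean_dm(matrix(x)), g, 999, seed = 3)$p_value)
  expect_error(permanova(euclidean_dm(matrix(x)), factor(rep("a", 6))),
               "groups")
})

test_that("PERMANOVA agrees with an independent implementation on
          multivariate data", {
  skip_if_not_installed("vegan")
  set.seed(21)
  for (i in 1:5) {
    x <- matrix(rnorm(48), 12, 4)
    g <- factor(rep(1:3, each = 4))
    ours <- permanova(euclidean_dm(x), g, n_perm = 99, seed = 1)
    ref <- vegan::adonis2(dist(x) ~ g, permutations = 99)
    expect_equal(ours$pseudo_f, ref$F[1], tolerance = 1e-10)
  }
})

test_that("PERMANOVA pseudo-F matches ANOVA on 50 random univariate
          instances at machine precision", {
  set.seed(77)
  for (i in 1:50) {
    n_per <- sample(2:5, 3, replace = TRUE)
    g <- factor(rep(seq_along(n_per), n_per))
    x <- rnorm(length(g), mean = as.integer(g) * runif(1, 0, 2))
    pm <- permanova(euclidean_dm(matrix(x)), g, n_perm = 1, seed = 1)
    expect_equal(pm$pseudo_f, anova(lm(x ~ g))[1, "F value"],
                 tolerance = 1e-10)
  }
})

test_that("CAP separates well-separated groups perfectly and keeps its
          bookkeeping invariants", {
  set.seed(9)
  x <- rbind(matrix(rnorm(50, 0, 1), 5), matrix(rnorm(50, 100, 1), 5),
             matrix(rnorm(50, -100, 1), 5))
  g <- factor(rep(1:3, each = 5))
  cap <- cap_fit(euclidean_dm(x), g, n_perm = 99, seed = 2)
  expect_equal(cap$loo_accuracy, 100)
  expect_equal(unname(rowSums(cap$confusion)), as.integer(table(g)))
  expect_lte(cap$p_value, 0.05)
  expect_gt(cap$g_prop, 0)
  expect_lte(cap$g_prop, 100)
  expect_lte(cap$trc_stat, nlevels(g) - 1 + 1e-9)
  # user-fixed m honoured; over-parameterized m rejected
  cap8 <- cap_fit(euclidean_dm(x), g, m = 8, n_perm = 19, seed = 2)
  expect_equal(cap8$m, 8)
  expect_error(cap_fit(euclidean_dm(x), g, m = 14), "N - 1")
  # confusion row sums equal group sizes on noisy, overlapping data too
  y <- matrix(rnorm(45), 15, 3)
  capy <- cap_fit(euclidean_dm(y), g, n_perm = 19, seed = 2)
  expect_equal(unname(rowSums(capy$confusion)), as.integer(table(g)))
})

test_that("CAP's discriminant agrees with linear discriminant analysis on
          clearly separated PCoA scores", {
  skip_if_not_installed("MASS")
  set.seed(14)
  shift3 <- matrix(rep(c(0, 30, 0, 30), each = 5), 5, 4)
  x <- rbind(matrix(rnorm(20, 0), 5), matrix(rnorm(20, 30), 5),
             matrix(rnorm(20), 5) + shift3)
  g <- factor(rep(1:3, each = 5))
  cap <- cap_fit(euclidean_dm(x), g, m = 4, n_perm = 19, seed = 1)
  scores <- cmdscale(dist(x), k = 4)
  lda_cv <- MASS::lda(scores, g, CV = TRUE)$class
  # both classifiers resolve the separable structure
  expect_gte(cap$loo_accuracy, 90)
  expect_gte(100 * mean(lda_cv == g), 90)
})

test_that("proportional chance criterion reproduces the printed chance rates
          and its symmetry properties", {
  expect_equal(round(pcc_test(c(4, 3, 3, 4))$chance_accuracy, 1), 25.5)
  expect_equal(pcc_test(c(4, 3, 3, 4))$chance_accuracy, 100 * 50 / 196)
  expect_equal(pcc_test(c(5, 4, 4, 5))$chance_accuracy, 100 * 82 / 324)
  for (k in 2:6) {
    expect_equal(pcc_test(rep(7, k))$chance_accuracy, 100 / k)
  }
  # invariant to group order; maximal when one group holds everything
  expect_equal(pcc_test(c(2, 5, 9))$chance_accuracy,
               pcc_test(c(9, 2, 5))$chance_accuracy)
  expect_equal(pcc_test(16)$chance_accuracy, 100)
  # exact binomial tail
  res <- pcc_test(c(4, 3, 3, 4), observed_correct = 12)
  expect_equal(res$p_value, pbinom(11, 14, 50 / 196, lower.tail = FALSE))
  expect_equal(res$observed_accuracy, 100 * 12 / 14)
})
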