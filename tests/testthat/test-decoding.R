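test_that("balanced splits put half of every class in train and test", {
  labels <- rep(c("A", "B"), each = 70)
  sp <- split_balanced(labels, n_splits = 5, seed = 1)
  for (s in sp) {
    expect_length(s$train, 70)
    expect_length(s$test, 70)
    expect_equal(sum(labels[s$train] == "A"), 35)
    expect_equal(sum(labels[s$test] == "B"), 35)
    expect_length(intersect(s$train, s$test), 0)
  }
  # 2+2 trials -> 1/1 per class; odd sizes floor and drop the remainder
  sp2 <- split_balanced(rep(c("A", "B"), each = 2), 3, seed = 2)
  expect_length(sp2[[1]]$train, 2)
  sp3 <- split_balanced(c(rep("A", 5), rep("B", 4)), 2, seed = 3)
  expect_equal(sum(sp3[[1]]$train %in% 1:5), 2)
  expect_identical(split_balanced(labels, 4, seed = 9),
                   split_balanced(labels, 4, seed = 9))
  expect_error(split_balanced(c("A", "B"), 1, seed = 1), "2 trials")
})

test_that("SVD projection truncates to rank and captures stated variance", {
  set.seed(4)
  base <- matrix(rnorm(20 * 2), 20, 2)
  x <- base %*% matrix(rnorm(2 * 30), 2, 30)     # rank 2 in 30 channels
  pr <- fit_svd_projection(x, k = 40)
  expect_equal(ncol(pr$rotation), 2)
  proj <- project_svd(pr, x)
  # zero reconstruction error at full rank
  xc <- sweep(x, 2, colMeans(x))
  expect_equal(proj %*% t(pr$rotation), xc, tolerance = 1e-10)

  # variance captured equals top-k squared singular values / total (oracle)
  y <- matrix(rnorm(50 * 10), 50, 10)
  d2 <- svd(sweep(y, 2, colMeans(y)))$d^2
  pr3 <- fit_svd_projection(y, k = 3)
  expect_equal(pr3$var_captured, sum(d2[1:3]) / sum(d2), tolerance = 1e-12)

  # k = channels preserves pairwise distances (orthogonality)
  prf <- fit_svd_projection(y, k = 10)
  expect_equal(as.matrix(dist(project_svd(prf, y))), as.matrix(dist(y)),
               tolerance = 1e-10)
})

test_that("LDA is perfect on separated clouds and matches MASS on a fixture", {
  set.seed(5)
  xa <- matrix(rnorm(40 * 3), 40, 3) + 10
  xb <- matrix(rnorm(40 * 3), 40, 3) - 10
  x <- rbind(xa, xb); y <- rep(c("a", "b"), each = 40)
  expect_equal(lda_accuracy(x, y, x, y), 1.0)

  x2 <- rbind(matrix(rnorm(60 * 4), 60, 4) + 0.8,
              matrix(rnorm(60 * 4), 60, 4))
  y2 <- rep(c("a", "b"), each = 60)
  xt <- rbind(matrix(rnorm(50 * 4), 50, 4) + 0.8,
              matrix(rnorm(50 * 4), 50, 4))
  yt <- rep(c("a", "b"), each = 50)
  acc <- lda_accuracy(x2, y2, xt, yt)
  fit <- MASS::lda(x2, grouping = y2)
  acc_mass <- mean(predict(fit, xt)$class == yt)
  expect_equal(acc, acc_mass, tolerance = 0.021)  # shrinkage 1e-6 vs none
})

test_that("LDA accuracy approaches the closed-form Bayes rate", {
  # unit-variance Gaussians separated by d = 2 along one axis -> Phi(1)
  set.seed(6)
  accs <- replicate(60, {
    x <- rbind(matrix(rnorm(70 * 4), 70, 4), matrix(rnorm(70 * 4), 70, 4))
    x[1:70, 1] <- x[1:70, 1] + 2
    y <- rep(c("a", "b"), each = 70)
    sp <- split_balanced(y, 1, seed = sample.int(1e6, 1))[[1]]
    lda_accuracy(x[sp$train, ], y[sp$train], x[sp$test, ], y[sp$test])
  })
  expect_lt(abs(mean(accs) - pnorm(1)), 0.03)
})

test_that("accuracy is invariant to class swap and channel-space rotation", {
  set.seed(7)
  x <- rbind(matrix(rnorm(30 * 5), 30, 5) + 1, matrix(rnorm(30 * 5), 30, 5))
  y <- rep(c("a", "b"), each = 30)
  sp <- split_balanced(y, 1, seed = 4)[[1]]
  a1 <- decode_split_helper(x, y, sp, n_dims = 5)
  y_sw <- ifelse(y == "a", "b", "a")
  a2 <- decode_split_helper(x, y_sw, sp, n_dims = 5)
  expect_equal(a1, a2)
  Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  a3 <- decode_split_helper(x %*% Q, y, sp, n_dims = 5)
  expect_equal(a1, a3, tolerance = 1e-8)
})

test_that("significance tiers follow CI overlap at 95/97.5/99%", {
  expect_equal(significance_tier(rep(1, 500), rnorm(500, 0.5, 0.02)), "***")
  x <- rnorm(500, 0.5, 0.05)
  expect_equal(significance_tier(x, x), "ns")
  # engineered borderline: 95% CIs separate, 97.5% CIs still overlap
  null <- seq(0, 1, length.out = 1001)           # quantile q = value q
  res <- null + 0.96
  expect_equal(significance_tier(res, null), "*")
  expect_equal(significance_tier(null + 1.2, null), "***")
})

test_that("pairwise decoding flags planted signal in the first post-onset bin", {
  d <- tiny_design(conditions = c("FPa", "VrFPa"), runs = 7, trials = 10)
  gain <- cbind(FPa = c(rep(2.5, 8), rep(1, 8)), VrFPa = 1)
  tr <- make_ground_truth(d, n_channels = 16, gain = gain)
  b <- quick_bundle(d, tr, seed = 31)
  dec <- run_pairwise(b, span = c(-0.5, 0.5), n_splits = 60, seed = 5)
  pre <- dec[dec$bin_start == -0.5, ]
  post <- dec[dec$bin_start == 0, ]
  expect_equal(pre$tier, "ns")
  expect_true(post$tier %in% c("*", "**", "***"))
  expect_gt(post$mean_acc, 0.8)
  expect_error(run_pairwise(b, pairs = rbind(c("FPa", "nope"))),
               "unknown condition")
})

test_that("noiseless separable data decodes at 1.0 regardless of split count", {
  d <- tiny_design(conditions = c("FPa", "BLa"), runs = 2, trials = 4)
  gain <- cbind(FPa = rep(3, 4), BLa = rep(1, 4))
  tr <- make_ground_truth(d, n_channels = 4, gain = gain,
                          noise_cov = matrix(0, 4, 4))
  b <- quick_bundle(d, tr, seed = 1)
  d1 <- run_pairwise(b, span = c(0, 0.5), n_splits = 1, seed = 1)
  d100 <- run_pairwise(b, span = c(0, 0.5), n_splits = 30, seed = 2)
  expect_equal(d1$mean_acc, 1.0)
  expect_equal(d100$mean_acc, 1.0)
})

test_that("generalization transfers a shared code and fails an orthogonal one", {
  d <- make_task_design(conditions = c("FPa", "FPf", "BLa", "BLf"),
                        runs_per_condition = 4, trials_per_run = 8)
  # shared location code: arm channels respond in both touch types
  gain_shared <- cbind(FPa = c(rep(2.5, 6), rep(1, 12)),
                       FPf = c(rep(1, 6), rep(2.5, 6), rep(1, 6)),
                       BLa = c(rep(2.5, 6), rep(1, 12)),
                       BLf = c(rep(1, 6), rep(2.5, 6), rep(1, 6)))
  tr <- make_ground_truth(d, n_channels = 18, gain = gain_shared)
  b <- quick_bundle(d, tr, seed = 41)
  g <- run_generalization(b, "BLa", "BLf", "FPa", "FPf",
                          span = c(0, 0.5), n_splits = 40, seed = 6)
  expect_gt(g$mean_acc, 0.85)
  expect_true(g$tier != "ns")

  # orthogonal location code: disjoint channel sets per touch type
  gain_orth <- cbind(FPa = c(rep(2.5, 5), rep(1, 13)),
                     FPf = c(rep(1, 5), rep(2.5, 4), rep(1, 9)),
                     BLa = c(rep(1, 9), rep(2.5, 4), rep(1, 5)),
                     BLf = c(rep(1, 13), rep(2.5, 5)))
  tro <- make_ground_truth(d, n_channels = 18, gain = gain_orth)
  bo <- quick_bundle(d, tro, seed = 42)
  go <- run_generalization(bo, "BLa", "BLf", "FPa", "FPf",
                           span = c(0, 0.5), n_splits = 40, seed = 7)
  ci <- percentile_ci(go$accuracies[[1]], 0.95)
  expect_true(ci[1] <= 0.5 && ci[2] >= 0.5)
  expect_error(run_generalization(b, "FPa", "FPf", "FPa", "BLf"),
               "disjoint")
})

test_that("generalization to a held-out half matches pairwise decoding", {
  d <- tiny_design(conditions = c("FPa", "FPf", "TPa", "TPf"), runs = 4,
                   trials = 8)
  gain <- cbind(FPa = c(rep(2, 5), rep(1, 7)), FPf = c(rep(1, 5), rep(2, 4), rep(1, 3)),
                TPa = c(rep(2, 5), rep(1, 7)), TPf = c(rep(1, 5), rep(2, 4), rep(1, 3)))
  tr <- make_ground_truth(d, n_channels = 12, gain = gain)
  b <- quick_bundle(d, tr, seed = 8)
  pw <- run_pairwise(b, pairs = rbind(c("FPa", "FPf")), span = c(0, 0.5),
                     n_splits = 40, seed = 9)
  gen <- run_generalization(b, "TPa", "TPf", "FPa", "FPf",
                            span = c(0, 0.5), n_splits = 40, seed = 9)
  ci <- percentile_ci(pw$accuracies[[1]], 0.95)
  expect_gt(gen$mean_acc, ci[1] - 0.1)
})
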