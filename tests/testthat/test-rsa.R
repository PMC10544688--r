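test_that("noise estimation recovers independent unit channels and shrinks as asked", {
  d <- make_task_design(conditions = c("A", "B"), runs_per_condition = 5,
                        trials_per_run = 40, catch_per_run = 0)
  tr <- make_ground_truth(d, n_channels = 4, baseline_rate = 20,
                          noise_sd = 1, noise_rho = 0)
  b <- quick_bundle(d, tr, seed = 51)
  nm <- estimate_noise(b, window = c(0, 0.5), shrinkage = 0)
  # normalized rates: unit Hz noise / baseline 20, averaged over 10 bins
  expected_var <- (1 / 20)^2 / 10
  expect_lt(max(abs(nm$cov - expected_var * diag(4))), expected_var * 0.35)

  nm1 <- estimate_noise(b, window = c(0, 0.5), shrinkage = 1)
  off <- nm1$cov_reg; diag(off) <- 0
  expect_true(all(off == 0))

  # duplicated channel: singular without shrinkage, invertible with the rule
  b2 <- b
  b2$rates <- b$rates[c(1, 1, 2, 3), , ]
  nm2 <- estimate_noise(b2, window = c(0, 0.5))
  expect_true(all(is.finite(nm2$inv)))
})

test_that("crossnobis matches the hand-computed two-fold example", {
  # 1 channel, 2 folds, fold means a: (1,1), b: (0,0), unit noise -> d = 1
  d <- make_task_design(conditions = c("a", "b"), runs_per_condition = 2,
                        trials_per_run = 2, catch_per_run = 0)
  b <- manual_bundle(d, 1, function(ch, cond, mids) {
    if (cond == "a") rep(1, length(mids)) else rep(0, length(mids))
  }, normalized = TRUE)
  nm <- structure(list(cov = matrix(1), shrinkage = 0, cov_reg = matrix(1),
                       inv = matrix(1), df = 2, channels = 1L),
                  class = "noise_model")
  rdm <- crossnobis_rdm(b, window = c(0, 0.5), noise = nm)
  expect_equal(rdm["a", "b"], 1)
  expect_true(is.na(rdm["a", "a"]))
})

test_that("identical condition patterns at zero noise give exactly zero distance", {
  d <- make_task_design(conditions = c("a", "b"), runs_per_condition = 3,
                        trials_per_run = 2, catch_per_run = 0)
  b <- manual_bundle(d, 3, function(ch, cond, mids) rep(ch, length(mids)),
                     normalized = TRUE)
  nm <- structure(list(cov = diag(3), shrinkage = 0, cov_reg = diag(3),
                       inv = diag(3), df = 3, channels = 1:3),
                  class = "noise_model")
  rdm <- crossnobis_rdm(b, window = c(0, 0.5), noise = nm)
  expect_equal(rdm["a", "b"], 0)
})

test_that("crossnobis agrees with brute-force fold-pair summation", {
  set.seed(52)
  for (rep_i in 1:5) {
    C <- sample(2:3, 1); F_ <- sample(2:3, 1); P <- sample(1:3, 1)
    d <- make_task_design(conditions = LETTERS[1:C], runs_per_condition = F_,
                          trials_per_run = 3, catch_per_run = 0)
    tr <- make_ground_truth(d, n_channels = P, baseline_rate = 10,
                            gain = matrix(runif(P * C, 1, 3), P, C),
                            noise_sd = 1.5, noise_rho = 0.2)
    b <- quick_bundle(d, tr, seed = 52 + rep_i)
    nm <- estimate_noise(b, window = c(0, 0.5), shrinkage = 0.3)
    rdm <- crossnobis_rdm(b, window = c(0, 0.5), noise = nm)
    feats <- window_features(b, c(0, 0.5))
    fm <- lapply(d$conditions, function(cc) {
      m <- matrix(NA_real_, F_, P)
      for (f in seq_len(F_)) {
        m[f, ] <- colMeans(feats[b$trials$condition == cc &
                                   b$trials$run == f, , drop = FALSE])
      }
      m
    })
    names(fm) <- d$conditions
    brute <- crossnobis_brute(fm, nm$inv)
    expect_equal(unclass(rdm)[lower.tri(rdm)], brute[lower.tri(brute)] / 1,
                 tolerance = 1e-10)
  }
})

test_that("RDMs are symmetric and invariant to fold relabelling", {
  d <- make_task_design(conditions = c("A", "B", "C"), runs_per_condition = 4,
                        trials_per_run = 5, catch_per_run = 0)
  tr <- make_ground_truth(d, n_channels = 6,
                          gain = matrix(runif(18, 1, 2), 6, 3))
  b <- quick_bundle(d, tr, seed = 53)
  nm <- estimate_noise(b, window = c(0, 0.5))
  rdm <- crossnobis_rdm(b, window = c(0, 0.5), noise = nm)
  expect_equal(unclass(rdm), t(unclass(rdm)))
  # permute fold labels
  b2 <- b
  b2$trials$run <- c(3, 4, 1, 2)[b$trials$run]
  rdm2 <- crossnobis_rdm(b2, window = c(0, 0.5), noise = nm)
  expect_lt(max(abs(rdm - rdm2), na.rm = TRUE), 1e-12)
})

test_that("isotropic noise reduces crossnobis to scaled cross-validated Euclidean", {
  d <- make_task_design(conditions = c("A", "B"), runs_per_condition = 3,
                        trials_per_run = 4, catch_per_run = 0)
  tr <- make_ground_truth(d, n_channels = 4,
                          gain = cbind(A = c(2, 2, 1, 1), B = 1))
  b <- quick_bundle(d, tr, seed = 54)
  s2 <- 0.37
  nm <- structure(list(cov = s2 * diag(4), shrinkage = 0,
                       cov_reg = s2 * diag(4), inv = diag(4) / s2, df = 10,
                       channels = 1:4), class = "noise_model")
  rdm <- crossnobis_rdm(b, window = c(0, 0.5), noise = nm)
  feats <- window_features(b, c(0, 0.5))
  fm <- lapply(c("A", "B"), function(cc) {
    t(vapply(1:3, function(f) colMeans(
      feats[b$trials$condition == cc & b$trials$run == f, , drop = FALSE]),
      numeric(4)))
  })
  D <- fm[[1]] - fm[[2]]
  G <- D %*% t(D)
  d_euc <- (sum(G) - sum(diag(G))) / (3 * 2)
  expect_equal(rdm["A", "B"], d_euc / (s2 * 4), tolerance = 1e-12)
})

test_that("crossnobis is unbiased under identical condition distributions", {
  d <- make_task_design(conditions = c("A", "B"), runs_per_condition = 4,
                        trials_per_run = 5, catch_per_run = 0)
  tr <- make_ground_truth(d, n_channels = 8)
  ds <- replicate(150, NA_real_)
  for (i in seq_along(ds)) {
    b <- quick_bundle(d, tr, seed = 1000 + i)
    rdm <- crossnobis_rdm(b, window = c(0, 0.5),
                          noise = estimate_noise(b, c(0, 0.5)))
    ds[i] <- rdm["A", "B"]
  }
  se <- sd(ds) / sqrt(length(ds))
  expect_lt(abs(mean(ds)), 3.5 * se)
})

test_that("RDM correlations behave as Pearson on the lower triangle", {
  set.seed(55)
  r1 <- matrix(runif(36), 6, 6); r1 <- (r1 + t(r1)) / 2; diag(r1) <- NA
  dimnames(r1) <- list(LETTERS[1:6], LETTERS[1:6])
  expect_equal(rdm_correlation(r1, r1)$r, 1)
  expect_equal(rdm_correlation(r1, -r1 + 3)$r, -1)
  r2 <- matrix(runif(36), 6, 6); r2 <- (r2 + t(r2)) / 2; diag(r2) <- NA
  dimnames(r2) <- dimnames(r1)
  out <- rdm_correlation(r1, r2, n_comparisons = 4)
  oracle <- cor.test(r1[lower.tri(r1)], r2[lower.tri(r2)])
  expect_equal(out$r, unname(oracle$estimate))
  expect_equal(out$p_corrected, min(1, oracle$p.value * 4))
  const <- matrix(1, 6, 6); diag(const) <- NA
  dimnames(const) <- dimnames(r1)
  expect_true(rdm_correlation(r1, const)$degenerate)
  expect_error(rdm_correlation(r1, r1[1:5, 1:5]), "condition set")
})

test_that("MDS embeds realizable geometries with near-zero stress", {
  # triangle with valid side lengths
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  em <- mds_embed(D3, seed = 1)
  expect_lt(em$stress, 1e-6)
  expect_equal(as.matrix(dist(em$coords))["a", "b"], 3, tolerance = 1e-4)

  # 4 equidistant points cannot be planar
  D4 <- matrix(1, 4, 4); diag(D4) <- 0
  em4 <- mds_embed(D4, seed = 2)
  expect_gt(em4$stress, 0.01)

  # distances from random planar points are recovered up to rotation
  set.seed(56)
  X <- matrix(rnorm(10), 5, 2)
  D5 <- as.matrix(dist(X))
  em5 <- mds_embed(D5, seed = 3)
  expect_lt(em5$stress, 1e-6)
  expect_equal(as.matrix(dist(em5$coords)), D5, tolerance = 1e-4)
  expect_error(mds_embed(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("Procrustes alignment removes rotation between successive embeddings", {
  set.seed(57)
  X <- matrix(rnorm(12), 6, 2)
  D <- as.matrix(dist(X))
  dimnames(D) <- list(letters[1:6], letters[1:6])
  e1 <- mds_embed(D, seed = 4)
  e2 <- mds_embed(D, seed = 99, align_to = e1)
  expect_lt(max(abs(e2$coords - e1$coords)), 1e-3)
})

test_that("run_rsa produces one symmetric RDM per bin with tidy output", {
  d <- tiny_design(conditions = c("FPa", "BLa", "VrFPa"), runs = 3, trials = 4)
  tr <- make_ground_truth(d, n_channels = 6,
                          gain = cbind(FPa = c(2, 2, 1, 1, 1, 1), BLa = 1,
                                       VrFPa = 1))
  b <- quick_bundle(d, tr, seed = 58)
  rs <- run_rsa(b, span = c(0, 1))
  expect_equal(nrow(rs), 2)
  td <- tidy(rs)
  expect_equal(nrow(td), 2 * 3)
  expect_true(all(c("bin_start", "cond_a", "cond_b", "d") %in% names(td)))
})
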