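test_that("closed-form tuning regression matches an explicit lm oracle", {
  d <- tiny_design(conditions = c("FPa", "BLa"), runs = 2, trials = 5)
  tr <- make_ground_truth(d, n_channels = 3,
                          gain = cbind(FPa = c(2, 1, 1.5), BLa = 1))
  b <- quick_bundle(d, tr, seed = 61)
  fit <- fit_channel_tuning(b, window = c(0, 0.5))
  feats <- window_features(b, c(0, 0.5))
  base <- colMeans(window_features(b, d$baseline_window))
  n_base <- d$runs_per_condition * d$trials_per_run
  for (ch in 1:3) {
    F_vec <- c(feats[, ch], rep(base[ch], n_base))
    X <- rbind(stats::model.matrix(~ 0 + condition, data = b$trials),
               matrix(0, n_base, 2))
    colnames(X) <- c("BLa", "FPa")
    lmfit <- summary(lm(F_vec ~ X))
    co <- lmfit$coefficients
    for (cc in c("FPa", "BLa")) {
      row <- fit[fit$channel == ch & fit$condition == cc, ]
      expect_equal(row$beta, co[paste0("X", cc), "Estimate"], tolerance = 1e-10)
      expect_equal(row$t, co[paste0("X", cc), "t value"], tolerance = 1e-8)
      expect_equal(row$p, co[paste0("X", cc), "Pr(>|t|)"], tolerance = 1e-8)
    }
  }
})

test_that("coefficients detect planted modulation and ignore its absence", {
  d <- tiny_design(conditions = c("FPa", "BLa"), runs = 7, trials = 10)
  tr <- make_ground_truth(d, n_channels = 4,
                          gain = cbind(FPa = c(3, 1, 1, 1), BLa = 1))
  b <- quick_bundle(d, tr, seed = 62)
  fit <- fit_channel_tuning(b, window = c(0, 0.5))
  strong <- fit[fit$channel == 1 & fit$condition == "FPa", ]
  expect_equal(strong$beta, 2, tolerance = 0.25)   # 3x baseline, normalized
  expect_lt(strong$p, 1e-6)
  flat <- fit[fit$channel == 2 & fit$condition == "FPa", ]
  expect_gt(flat$p, 0.01)
})

test_that("per-condition false-positive rate is near alpha without correction", {
  d <- tiny_design(conditions = c("FPa", "BLa"), runs = 7, trials = 10)
  tr <- make_ground_truth(d, n_channels = 24)
  ps <- unlist(lapply(1:6, function(i) {
    b <- quick_bundle(d, tr, seed = 700 + i)
    fit_channel_tuning(b, window = c(0, 0.5))$p
  }))
  rate <- mean(ps < 0.05)
  n <- length(ps)
  expect_lt(abs(rate - 0.05), 0.05 / 2 + 3 * sqrt(0.05 * 0.95 / n))
})

test_that("Holm step-down matches hand enumeration and p.adjust", {
  expect_equal(holm_correct(0.04, alpha = 0.05), TRUE)
  expect_equal(holm_correct(c(0.01, 0.02, 0.9)), c(TRUE, TRUE, FALSE))
  expect_equal(holm_correct(rep(1, 5)), rep(FALSE, 5))
  # 0.02 <= 0.05/2 passes only after 0.01 <= 0.05/3 opens the gate
  expect_equal(holm_correct(c(0.02, 0.018, 0.9)), c(FALSE, FALSE, FALSE))
  set.seed(63)
  for (i in 1:25) {
    p <- runif(sample(1:8, 1))^2
    expect_equal(holm_correct(p, 0.05), p.adjust(p, "holm") <= 0.05)
  }
})

test_that("Holm equals the closed-testing oracle and dominates Bonferroni", {
  grid <- c(0.001, 0.009, 0.013, 0.02, 0.05, 0.3, 1)
  set.seed(64)
  for (i in 1:40) {
    m <- sample(1:4, 1)
    p <- sample(grid, m, replace = TRUE)
    expect_equal(holm_correct(p, 0.05), holm_closed_testing(p, 0.05))
    bonf <- p <= 0.05 / m
    expect_true(all(holm_correct(p, 0.05) >= bonf))
  }
})

test_that("run_tuning recovers the planted tuned set with Holm control", {
  d <- tiny_design(conditions = c("FPa", "BLa", "VrFPa"), runs = 7, trials = 10)
  gain <- cbind(FPa = c(rep(2, 6), rep(1, 6)), BLa = 1, VrFPa = 1)
  tr <- make_ground_truth(d, n_channels = 12, gain = gain)
  b <- quick_bundle(d, tr, seed = 65)
  tt <- run_tuning(b)
  counts <- tuning_counts(tt)
  expect_equal(counts$n_tuned[counts$condition == "FPa"], 6)
  expect_lte(counts$n_tuned[counts$condition == "VrFPa"], 1)
  tuned_fpa <- unique(tt$channel[tt$condition == "FPa" & tt$tuned])
  expect_setequal(tuned_fpa, 1:6)
})

test_that("bootstrap counts report the observed count and separate planted tiers", {
  # 30 channels planted to one condition, 5 to the other, strong gain
  d <- tiny_design(conditions = c("FPa", "BLa"), runs = 7, trials = 10)
  gain <- cbind(FPa = c(rep(3, 30), rep(1, 66)),
                BLa = c(rep(3, 5), rep(1, 91)))
  tr <- make_ground_truth(d, n_channels = 96, gain = gain)
  b <- quick_bundle(d, tr, seed = 66)
  bc <- bootstrap_tuned_counts(b, n_iter = 60, seed = 3)
  full <- tuning_counts(run_tuning(b))
  expect_equal(bc$counts$n_tuned,
               full$n_tuned[match(bc$counts$condition, full$condition)])
  a <- bc$counts[bc$counts$condition == "FPa", ]
  bb <- bc$counts[bc$counts$condition == "BLa", ]
  expect_gt(a$ci_lo, bb$ci_hi)
  expect_true(bc$pairs$tier[1] != "ns")
})

test_that("overlap sets classify membership and conserve channel counts", {
  d <- tiny_design(conditions = c("FPa", "FPf", "BLa", "BLf"), runs = 7,
                   trials = 10)
  gain <- cbind(FPa = c(rep(2.5, 4), rep(1, 6)),
                FPf = c(1, 1, 2.5, 2.5, 2.5, rep(1, 5)),
                BLa = c(2.5, rep(1, 9)), BLf = 1)
  tr <- make_ground_truth(d, n_channels = 10, gain = gain)
  b <- quick_bundle(d, tr, seed = 67)
  tt <- run_tuning(b, alpha = 0.01)     # strict alpha: unambiguous recovery
  ov <- overlap_sets(tt, grid = c(1, 5))
  memb <- ov$membership
  expect_equal(memb$class_all[memb$channel == 1], "arm_only")
  expect_equal(memb$class_all[memb$channel == 3], "both")
  expect_equal(memb$class_all[memb$channel == 5], "finger_only")
  cnt <- ov$counts[ov$counts$scope == "all", ]
  total_tuned <- sum(vapply(memb$conditions, length, integer(1)) > 0)
  expect_equal(sum(cnt$n_channels[cnt$class != "none"]), total_tuned)
  expect_equal(nrow(ov$array_map), 10)
})

test_that("onset follows the bin-midpoint convention on a noiseless step", {
  d <- make_task_design(conditions = "FPa", runs_per_condition = 2,
                        trials_per_run = 5, catch_per_run = 0)
  b <- manual_bundle(d, 2, function(ch, cond, mids) {
    1 + (mids > 0.10) * 1.0      # step from 1 to 2 at t = 0.10 s
  }, normalized = TRUE)
  on <- detect_onset_offset(b, 1:2, "FPa", n_boot = 50, seed = 1)
  expect_equal(on$onset_ms, 125)
  expect_equal(on$onset_lo, 125)
  expect_equal(on$onset_hi, 125)
})

test_that("flat traces have undefined onsets", {
  d <- make_task_design(conditions = "FPa", runs_per_condition = 1,
                        trials_per_run = 4, catch_per_run = 0)
  b <- manual_bundle(d, 1, function(ch, cond, mids) rep(1, length(mids)),
                     normalized = TRUE)
  on <- detect_onset_offset(b, 1, "FPa", n_boot = 20, seed = 1)
  expect_true(is.na(on$onset_ms))
})

test_that("onset shifts by exactly k bins when the response shifts", {
  d <- make_task_design(conditions = "FPa", runs_per_condition = 1,
                        trials_per_run = 6, catch_per_run = 0)
  mk <- function(shift_bins) {
    manual_bundle(d, 1, function(ch, cond, mids) {
      1 + (mids > 0.05 * shift_bins) * 1.0
    }, normalized = TRUE)
  }
  on0 <- detect_onset_offset(mk(0), 1, "FPa", n_boot = 10, seed = 1)
  on3 <- detect_onset_offset(mk(3), 1, "FPa", n_boot = 10, seed = 1)
  expect_equal(on3$onset_ms - on0$onset_ms, 3 * 50)
})

test_that("offset search starts at the peak by default", {
  d <- make_task_design(conditions = "FPa", runs_per_condition = 1,
                        trials_per_run = 4, catch_per_run = 0)
  # dips briefly below threshold between onset and peak
  b <- manual_bundle(d, 1, function(ch, cond, mids) {
    v <- rep(1, length(mids))
    v[mids > 0 & mids < 0.2] <- 2
    v[mids > 0.2 & mids < 0.3] <- 0.5  # transient dip below threshold
    v[mids > 0.3 & mids < 0.8] <- 3    # peak afterwards
    v[mids > 0.8 & mids < 1.2] <- 0.5  # post-peak return below threshold
    v
  }, normalized = TRUE)
  on_peak <- detect_onset_offset(b, 1, "FPa", n_boot = 10, seed = 1)
  on_onset <- detect_onset_offset(b, 1, "FPa", n_boot = 10, seed = 1,
                                  offset_from = "onset")
  expect_gt(on_peak$offset_ms, 800)
  expect_lt(on_onset$offset_ms, 300)
})
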