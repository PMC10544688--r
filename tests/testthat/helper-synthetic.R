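# Small fixtures and independent oracles used across the suite.

# internal helpers exercised directly in a few tests
kernel_bin_average <- touchdecode:::kernel_bin_average
percentile_ci <- touchdecode:::percentile_ci
decode_split_helper <- touchdecode:::decode_split

# A compact two-array-style design: fewer conditions/runs, full bin grid.
tiny_design <- function(conditions = c("FPa", "BLa"), runs = 3, trials = 6,
                        ...) {
  make_task_design(conditions = conditions, runs_per_condition = runs,
                   trials_per_run = trials, ...)
}

# Simulated, catch-stripped, normalized bundle.
quick_bundle <- function(design, truth, seed = 1, ...) {
  s <- simulate_session(design, truth, seed = seed, ...)
  normalize_by_baseline(drop_catch_trials(s$bundle))
}

# Build a session bundle directly from a deterministic rate function
# rate_fun(channel, condition, bin_mid) -> Hz; one run per `runs`.
manual_bundle <- function(design, n_channels, rate_fun, normalized = FALSE) {
  conds <- design$conditions
  trials_per_cond <- design$runs_per_condition * design$trials_per_run
  trials <- tibble::tibble(
    trial_id = seq_len(length(conds) * trials_per_cond),
    condition = rep(conds, each = trials_per_cond),
    run_condition = rep(conds, each = trials_per_cond),
    run = rep(rep(seq_len(design$runs_per_condition),
                  each = design$trials_per_run), times = length(conds)),
    run_id = as.integer(interaction(
      rep(conds, each = trials_per_cond),
      rep(rep(seq_len(design$runs_per_condition),
              each = design$trials_per_run), times = length(conds)),
      drop = TRUE)),
    set = 1L, is_catch = FALSE, onset_time = 0
  )
  mids <- bin_midpoints(design)
  rates <- array(0, dim = c(n_channels, nrow(trials), design$n_bins))
  for (ch in seq_len(n_channels)) {
    for (tr in seq_len(nrow(trials))) {
      rates[ch, tr, ] <- rate_fun(ch, trials$condition[tr], mids)
    }
  }
  new_session_bundle(rates, design, trials, normalized = normalized)
}

# Independent crossnobis oracle: direct summation over ordered fold pairs.
# fold_means: list (per condition) of fold x channel matrices.
crossnobis_brute <- function(fold_means, sigma_inv) {
  conds <- names(fold_means)
  F_ <- nrow(fold_means[[1]])
  P <- ncol(fold_means[[1]])
  rdm <- matrix(NA_real_, length(conds), length(conds),
                dimnames = list(conds, conds))
  for (i in seq_along(conds)) for (j in seq_along(conds)) {
    if (i == j) next
    acc <- 0
    for (m in seq_len(F_)) for (n in seq_len(F_)) {
      if (m == n) next
      dm <- fold_means[[i]][m, ] - fold_means[[j]][m, ]
      dn <- fold_means[[i]][n, ] - fold_means[[j]][n, ]
      acc <- acc + drop(t(dm) %*% sigma_inv %*% dn)
    }
    rdm[i, j] <- acc / (F_ * (F_ - 1)) / P
  }
  rdm
}

# Closed-testing oracle for Holm: reject H_i iff every subset containing i
# passes its local Bonferroni test min_j p_j <= alpha / |S|.
holm_closed_testing <- function(p, alpha = 0.05) {
  m <- length(p)
  reject <- rep(TRUE, m)
  for (mask in seq_len(2^m - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    if (min(p[S]) > alpha / length(S)) reject[S] <- FALSE
  }
  reject
}
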