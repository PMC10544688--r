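#' Balanced train/test splits
#'
#' Each split assigns exactly half of every class's trials to train and half
#' to test (70 trials per condition gives 35/35); odd class sizes are floored
#' to equal halves and the remainder dropped from that split. Splits are
#' drawn independently per iteration, ignoring run and session membership.
#'
#' @param labels Vector of class labels, one per trial.
#' @param n_splits Number of independent splits.
#' @param seed Integer seed; the same seed yields the identical sequence.
#' @return List of `n_splits` lists with integer `train` and `test` indices.
#' @export
split_balanced <- function(labels, n_splits = 1000, seed = 1) {
  classes <- unique(labels)
  idx_by_class <- lapply(classes, function(cl) which(labels == cl))
  if (any(lengths(idx_by_class) < 2)) {
    stop("every class needs at least 2 trials", call. = FALSE)
  }
  with_local_seed(seed, {
    lapply(seq_len(n_splits), function(s) {
      tr <- te <- integer(0)
      for (ix in idx_by_class) {
        h <- length(ix) %/% 2L
        perm <- sample(ix)
        tr <- c(tr, perm[seq_len(h)])
        te <- c(te, perm[h + seq_len(h)])
      }
      list(train = tr, test = te)
    })
  })
}

#' Fit an SVD projection onto the top variance directions of training data
#'
#' Centers the training matrix by its column means and returns the operator
#' projecting onto the top `min(k, rank)` right-singular directions. Test
#' data must be projected with the same operator (same centering, same
#' directions), which is how the decoders avoid train/test leakage.
#'
#' @param train_matrix trials x channels numeric matrix.
#' @param k Number of dimensions to keep (study default 40).
#' @return A `svd_projection`: list with `center`, `rotation`
#'   (channels x k_eff), `d` (singular values) and `var_captured`.
#' @export
fit_svd_projection <- function(train_matrix, k = 40) {
  stopifnot(nrow(train_matrix) > 0, k >= 1)
  mu <- colMeans(train_matrix)
  xc <- sweep(train_matrix, 2, mu)
  sv <- svd(xc)
  tol <- max(dim(xc)) * max(sv$d, 0) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  k_eff <- max(1L, min(as.integer(k), rank))
  structure(list(
    center = mu,
    rotation = sv$v[, seq_len(k_eff), drop = FALSE],
    d = sv$d,
    var_captured = sum(sv$d[seq_len(k_eff)]^2) / max(sum(sv$d^2), .Machine$double.xmin)
  ), class = "svd_projection")
}

#' Apply an SVD projection
#' @param projection A `svd_projection`.
#' @param x trials x channels matrix.
#' @return trials x k_eff matrix.
#' @export
project_svd <- function(projection, x) {
  sweep(x, 2, projection$center) %*% projection$rotation
}

#' Linear discriminant accuracy on held-out data
#'
#' Two-class LDA with a pooled within-class covariance, shrunk toward a
#' scaled identity by `lambda` (raised automatically by factors of 10 if the
#' pooled covariance is singular). Discriminant-score ties are broken toward
#' the first class deterministically.
#'
#' @param train_x,train_y Training matrix (trials x dims) and labels.
#' @param test_x,test_y Held-out matrix and labels.
#' @param lambda Shrinkage weight toward `mean(diag(S)) * I` (default 1e-6).
#' @return Fraction of test rows classified correctly.
#' @export
lda_accuracy <- function(train_x, train_y, test_x, test_y, lambda = 1e-6) {
  classes <- unique(train_y)
  if (length(classes) != 2) stop("exactly two classes required", call. = FALSE)
  a <- classes[1]
  ia <- train_y == a
  if (!any(ia) || all(ia)) stop("both classes must appear in train", call. = FALSE)
  mu_a <- colMeans(train_x[ia, , drop = FALSE])
  mu_b <- colMeans(train_x[!ia, , drop = FALSE])
  xa <- sweep(train_x[ia, , drop = FALSE], 2, mu_a)
  xb <- sweep(train_x[!ia, , drop = FALSE], 2, mu_b)
  n <- nrow(train_x)
  S <- (crossprod(xa) + crossprod(xb)) / max(n - 2, 1)
  sc <- mean(diag(S))
  if (sc == 0) sc <- 1
  p <- ncol(S)
  w <- NULL
  lam <- lambda
  repeat {
    Sreg <- (1 - lam) * S + lam * sc * diag(p)
    w <- tryCatch(solve(Sreg, mu_a - mu_b), error = function(e) NULL)
    if (!is.null(w) || lam >= 1) break
    lam <- min(1, lam * 10)
  }
  if (is.null(w)) stop("pooled covariance irreparably singular", call. = FALSE)
  thr <- sum(w * (mu_a + mu_b)) / 2
  pred <- ifelse(drop(test_x %*% w) >= thr, a, classes[2])
  mean(pred == test_y)
}

# One split -> SVD -> LDA accuracy for a feature matrix and binary labels.
decode_split <- function(x, y, split, n_dims, lambda = 1e-6) {
  pr <- fit_svd_projection(x[split$train, , drop = FALSE], k = n_dims)
  lda_accuracy(project_svd(pr, x[split$train, , drop = FALSE]), y[split$train],
               project_svd(pr, x[split$test, , drop = FALSE]), y[split$test],
               lambda = lambda)
}

# Accuracy distribution over balanced splits, plus a matched shuffled-label
# null built with the identical machinery (labels shuffled once per
# iteration, before splitting).
decode_distribution <- function(x, y, n_splits, n_dims, seed, lambda = 1e-6) {
  splits <- split_balanced(y, n_splits, seed = seed)
  acc <- vapply(splits, function(sp) decode_split(x, y, sp, n_dims, lambda),
                numeric(1))
  null_acc <- with_local_seed(derive_seed(seed, "null"), {
    vapply(seq_len(n_splits), function(s) {
      ys <- sample(y)
      sp <- split_balanced(ys, 1, seed = sample.int(.Machine$integer.max, 1))[[1]]
      decode_split(x, ys, sp, n_dims, lambda)
    }, numeric(1))
  })
  list(accuracies = acc, null_accuracies = null_acc)
}

#' Significance tier from accuracy and null distributions
#'
#' The tier is the most stringent confidence level among 95, 97.5 and 99%
#' at which the percentile intervals of the two distributions do not
#' overlap: `"*"` (95%), `"**"` (97.5%), `"***"` (99%), or `"ns"`.
#'
#' @param accuracies Accuracy distribution across splits.
#' @param null_accuracies Matched shuffled-label distribution.
#' @return One of `"ns"`, `"*"`, `"**"`, `"***"`.
#' @export
significance_tier <- function(accuracies, null_accuracies) {
  stopifnot(length(accuracies) > 0, length(null_accuracies) > 0)
  tiers <- c("***" = 0.99, "**" = 0.975, "*" = 0.95)
  for (i in seq_along(tiers)) {
    ca <- percentile_ci(accuracies, tiers[i])
    cn <- percentile_ci(null_accuracies, tiers[i])
    if (ca[1] > cn[2] || ca[2] < cn[1]) return(names(tiers)[i])
  }
  "ns"
}

# 0.5 s (or other width) decoding windows inside a span, aligned to t = 0.
decoding_windows <- function(span, width) {
  starts <- seq(span[1], span[2] - width + 1e-9, by = width)
  lapply(starts, function(s) c(s, s + width))
}

#' Pairwise condition-identity decoding
#'
#' For every condition pair and every decoding window: balanced 35/35 splits,
#' SVD to the top `n_dims` directions of the training half, LDA on the
#' projected data, accuracy on the held-out half, averaged over `n_splits`
#' iterations; a shuffled-label null built with the identical machinery; and
#' a CI-overlap significance tier.
#'
#' @param bundle A normalized `session_bundle`.
#' @param pairs Optional 2-column matrix or list of condition pairs
#'   (default: all pairs present).
#' @param window_width Decoding bin width in seconds (default 0.5; use 0.1
#'   for the fine-timescale variant).
#' @param span Time span covered by the decoding windows (default the
#'   design's analysis window).
#' @param n_splits Balanced splits per decoder (study value 1000).
#' @param n_dims SVD dimensions (study value 40).
#' @param seed Integer seed.
#' @return A `decode_table` tibble: `class_a`, `class_b`, `bin_start`,
#'   `bin_end`, `mean_acc`, `ci_lo`, `ci_hi`, `null_mean`, `tier`, plus
#'   list-columns `accuracies` and `null_accuracies`.
#' @export
run_pairwise <- function(bundle, pairs = NULL, window_width = 0.5,
                         span = NULL, n_splits = 1000, n_dims = 40,
                         seed = 1) {
  if (!bundle$normalized) stop("bundle must be normalized first", call. = FALSE)
  bundle <- drop_catch_trials(bundle)
  conds <- sort(unique(bundle$trials$condition))
  if (is.null(pairs)) {
    pairs <- t(utils::combn(conds, 2))
  } else if (is.list(pairs)) {
    pairs <- do.call(rbind, pairs)
  }
  bad <- setdiff(unique(as.vector(pairs)), conds)
  if (length(bad)) stop("unknown condition code(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  span <- span %||% bundle$design$analysis_window
  windows <- decoding_windows(span, window_width)

  out <- list()
  for (wi in seq_along(windows)) {
    feats <- window_features(bundle, windows[[wi]])
    for (pi in seq_len(nrow(pairs))) {
      a <- pairs[pi, 1]; b <- pairs[pi, 2]
      sel <- bundle$trials$condition %in% c(a, b)
      x <- feats[sel, , drop = FALSE]
      keep_ch <- colSums(is.na(x)) == 0
      x <- x[, keep_ch, drop = FALSE]
      y <- bundle$trials$condition[sel]
      dd <- decode_distribution(x, y, n_splits, n_dims,
                                seed = derive_seed(seed, paste(a, b, wi)))
      ci <- percentile_ci(dd$accuracies, 0.95)
      out[[length(out) + 1]] <- tibble::tibble(
        class_a = a, class_b = b,
        bin_start = windows[[wi]][1], bin_end = windows[[wi]][2],
        mean_acc = mean(dd$accuracies),
        ci_lo = ci[1], ci_hi = ci[2],
        null_mean = mean(dd$null_accuracies),
        tier = significance_tier(dd$accuracies, dd$null_accuracies),
        accuracies = list(dd$accuracies),
        null_accuracies = list(dd$null_accuracies)
      )
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("decode_table", class(res))
  res
}

#' Cross-condition generalization decoding
#'
#' Trains a classifier to separate two trial groups (e.g. arm vs finger
#' within one touch type) and tests it on a label-disjoint pair of groups
#' (the same contrast within another touch type). Per iteration the training
#' groups are subsampled to equal size, the SVD + LDA machinery is fit on
#' the training trials only, and accuracy is measured on all test trials;
#' the null shuffles the training group labels.
#'
#' @param bundle A normalized `session_bundle`.
#' @param train_a,train_b Condition codes forming the two training groups.
#' @param test_a,test_b Condition codes forming the two test groups (class
#'   `a` in test corresponds to class `a` in train).
#' @param window_width,span,n_splits,n_dims,seed As in [run_pairwise()].
#' @return A `decode_table` tibble as in [run_pairwise()], with `class_a` /
#'   `class_b` describing the train -> test contrast.
#' @export
run_generalization <- function(bundle, train_a, train_b, test_a, test_b,
                               window_width = 0.5, span = NULL,
                               n_splits = 1000, n_dims = 40, seed = 1) {
  if (!bundle$normalized) stop("bundle must be normalized first", call. = FALSE)
  bundle <- drop_catch_trials(bundle)
  if (length(intersect(c(train_a, train_b), c(test_a, test_b)))) {
    stop("train and test selectors must be label-disjoint", call. = FALSE)
  }
  grp <- function(conds) which(bundle$trials$condition %in% conds)
  ia_tr <- grp(train_a); ib_tr <- grp(train_b)
  ia_te <- grp(test_a); ib_te <- grp(test_b)
  if (!length(ia_tr) || !length(ib_tr) || !length(ia_te) || !length(ib_te)) {
    stop("empty selector", call. = FALSE)
  }
  span <- span %||% bundle$design$analysis_window
  windows <- decoding_windows(span, window_width)
  n_bal <- min(length(ia_tr), length(ib_tr))
  y_test <- c(rep("a", length(ia_te)), rep("b", length(ib_te)))

  out <- list()
  for (wi in seq_along(windows)) {
    feats <- window_features(bundle, windows[[wi]])
    keep_ch <- colSums(is.na(feats)) == 0
    feats <- feats[, keep_ch, drop = FALSE]
    one_pass <- function(shuffle) {
      function(s) {
        sa <- sample(ia_tr, n_bal); sb <- sample(ib_tr, n_bal)
        xtr <- feats[c(sa, sb), , drop = FALSE]
        ytr <- c(rep("a", n_bal), rep("b", n_bal))
        if (shuffle) ytr <- sample(ytr)
        pr <- fit_svd_projection(xtr, k = n_dims)
        lda_accuracy(project_svd(pr, xtr), ytr,
                     project_svd(pr, feats[c(ia_te, ib_te), , drop = FALSE]),
                     y_test)
      }
    }
    acc <- with_local_seed(derive_seed(seed, paste("gen", wi)),
                           vapply(seq_len(n_splits), one_pass(FALSE), numeric(1)))
    null_acc <- with_local_seed(derive_seed(seed, paste("gen-null", wi)),
                                vapply(seq_len(n_splits), one_pass(TRUE), numeric(1)))
    ci <- percentile_ci(acc, 0.95)
    out[[length(out) + 1]] <- tibble::tibble(
      class_a = paste(train_a, collapse = "+"),
      class_b = paste(train_b, collapse = "+"),
      bin_start = windows[[wi]][1], bin_end = windows[[wi]][2],
      mean_acc = mean(acc), ci_lo = ci[1], ci_hi = ci[2],
      null_mean = mean(null_acc),
      tier = significance_tier(acc, null_acc),
      accuracies = list(acc), null_accuracies = list(null_acc)
    )
  }
  res <- dplyr::bind_rows(out)
  attr(res, "test_groups") <- list(a = test_a, b = test_b)
  class(res) <- c("decode_table", class(res))
  res
}

#' @export
glance.decode_table <- function(x, ...) {
  tibble::tibble(
    n_decoders = nrow(x),
    n_significant = sum(x$tier != "ns"),
    best_acc = max(x$mean_acc),
    mean_null = mean(x$null_mean)
  )
}

#' @export
tidy.decode_table <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), -dplyr::any_of(c("accuracies",
                                                       "null_accuracies")))
}

#' Heatmap of pairwise decoding accuracies per time bin
#'
#' @param object A `decode_table` from [run_pairwise()].
#' @param ... Unused.
#' @return A ggplot faceted by decoding bin; tiles show mean accuracy,
#'   asterisks the significance tier.
#' @export
autoplot.decode_table <- function(object, ...) {
  df <- tidy(object)
  df$bin <- sprintf("[%g, %g) s", df$bin_start, df$bin_end)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class_b, y = .data$class_a,
                                   fill = .data$mean_acc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$tier == "ns", "", .data$tier)), size = 3) +
    ggplot2::facet_wrap(~bin) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0.4, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "accuracy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
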