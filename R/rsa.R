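#' Estimate the channel noise covariance for multivariate noise normalization
#'
#' Pools within-condition, within-fold residuals (trial minus its
#' condition-by-fold mean) across conditions and folds, and shrinks the
#' resulting covariance toward its diagonal,
#' \deqn{\Sigma_\lambda = (1-\lambda)\hat\Sigma + \lambda\,\mathrm{diag}(\hat\Sigma),}
#' so the whitening operator is always invertible. The shrinkage weight is
#' chosen by the analytic optimal-shrinkage rule (Schafer-Strimmer, diagonal
#' target) with a configurable floor; `shrinkage = 1` gives an exactly
#' diagonal model.
#'
#' @param bundle A normalized `session_bundle`.
#' @param window Time window (s) whose bin-averaged rates supply the
#'   residuals.
#' @param shrinkage Fixed shrinkage weight in \[0, 1\], or `NULL` (default)
#'   for the analytic rule.
#' @param shrinkage_floor Minimum shrinkage when the analytic rule is used
#'   (default 0.01).
#' @return A `noise_model`: list with `cov` (raw pooled covariance),
#'   `shrinkage`, `cov_reg`, `inv` (cached whitening operator) and `df`.
#' @export
estimate_noise <- function(bundle, window, shrinkage = NULL,
                           shrinkage_floor = 0.01) {
  bundle <- drop_catch_trials(bundle)
  x <- window_features(bundle, window)            # trials x channels
  keep <- colSums(is.na(x)) == 0
  x <- x[, keep, drop = FALSE]
  grp <- interaction(bundle$trials$condition, bundle$trials$run, drop = TRUE)
  if (any(table(grp) < 2)) {
    stop("need >= 2 trials per condition per fold for residuals", call. = FALSE)
  }
  centers <- rowsum(x, grp) / as.vector(table(grp))
  res <- x - centers[as.integer(grp), , drop = FALSE]
  n <- nrow(res)
  g <- nlevels(grp)
  df <- n - g
  S <- crossprod(res) / df

  if (is.null(shrinkage)) {
    # analytic shrinkage toward the diagonal target
    Sb <- crossprod(res) / n
    M2 <- crossprod(res^2)
    var_s <- n / (n - 1)^3 * (M2 - (crossprod(res))^2 / n)
    off <- !diag(ncol(S))
    denom <- sum(Sb[off]^2)
    lambda <- if (denom > 0) sum(var_s[off]) / denom else 1
    shrinkage <- min(1, max(shrinkage_floor, lambda))
  }
  stopifnot(shrinkage >= 0, shrinkage <= 1)
  cov_reg <- (1 - shrinkage) * S + shrinkage * diag(diag(S), ncol(S))
  inv <- tryCatch(solve(cov_reg), error = function(e) NULL)
  while (is.null(inv) && shrinkage < 1) {
    shrinkage <- min(1, shrinkage + 0.1)
    cov_reg <- (1 - shrinkage) * S + shrinkage * diag(diag(S), ncol(S))
    inv <- tryCatch(solve(cov_reg), error = function(e) NULL)
  }
  if (is.null(inv)) stop("noise covariance irreparably singular", call. = FALSE)
  structure(list(cov = S, shrinkage = shrinkage, cov_reg = cov_reg,
                 inv = inv, df = df, channels = which(keep)),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model> %d channels, shrinkage %.3f, df %d\n",
              ncol(x$cov), x$shrinkage, x$df))
  invisible(x)
}

#' Cross-validated Mahalanobis (crossnobis) dissimilarity matrix
#'
#' For conditions a, b with fold-wise pattern means \eqn{\bar x_a^{(m)}},
#' \deqn{d(a,b) = \frac{1}{F(F-1)\,P} \sum_{m \ne n}
#'   (\bar x_a^{(m)} - \bar x_b^{(m)})^\top \Sigma_\lambda^{-1}
#'   (\bar x_a^{(n)} - \bar x_b^{(n)}),}
#' averaged over ordered fold pairs and normalized by the channel count P so
#' values are comparable across population sizes. Folds are the 10-trial
#' runs (7 per condition in the study design). The estimator is unbiased:
#' identical condition distributions give distances scattered around zero,
#' and slightly negative values are legitimate. The diagonal is meaningless
#' and stored as `NA`.
#'
#' @param bundle A normalized `session_bundle`.
#' @param window Time window (s); bin-averaged rates are the patterns.
#' @param noise A `noise_model` from [estimate_noise()] (default: estimated
#'   from the same window).
#' @param conditions Condition subset/order (default: all, sorted).
#' @return A condition x condition `rdm` matrix with `NA` diagonal and
#'   attributes `window`, `n_channels`, `n_folds`.
#' @export
crossnobis_rdm <- function(bundle, window, noise = NULL, conditions = NULL) {
  bundle <- drop_catch_trials(bundle)
  noise <- noise %||% estimate_noise(bundle, window)
  x <- window_features(bundle, window)[, noise$channels, drop = FALSE]
  conds <- conditions %||% sort(unique(bundle$trials$condition))
  folds <- sort(unique(bundle$trials$run))
  F_ <- length(folds)
  P <- ncol(x)
  if (F_ < 2) stop("need >= 2 folds", call. = FALSE)

  # fold x channel mean matrix per condition
  fold_means <- lapply(conds, function(cond) {
    m <- matrix(NA_real_, F_, P)
    for (fi in seq_along(folds)) {
      idx <- which(bundle$trials$condition == cond & bundle$trials$run == folds[fi])
      if (!length(idx)) stop("condition ", cond, " missing in fold ",
                             folds[fi], call. = FALSE)
      m[fi, ] <- colMeans(x[idx, , drop = FALSE])
    }
    m
  })
  names(fold_means) <- conds

  C <- length(conds)
  rdm <- matrix(NA_real_, C, C, dimnames = list(conds, conds))
  for (i in seq_len(C - 1)) {
    for (j in (i + 1):C) {
      D <- fold_means[[i]] - fold_means[[j]]      # F x P deltas
      G <- D %*% noise$inv %*% t(D)
      d <- (sum(G) - sum(diag(G))) / (F_ * (F_ - 1)) / P
      rdm[i, j] <- rdm[j, i] <- d
    }
  }
  structure(rdm, class = c("rdm", "matrix"),
            window = window, n_channels = P, n_folds = F_)
}

#' Crossnobis RDM time series
#'
#' Computes one RDM per decoding window (default 0.5 s bins across the
#' analysis window), each with its own per-bin noise model.
#'
#' @param bundle A normalized `session_bundle`.
#' @param window_width RDM bin width in seconds (default 0.5).
#' @param span Time span (default the design's analysis window).
#' @param shrinkage Passed to [estimate_noise()].
#' @return An `rdm_series` tibble: `bin_start`, `bin_end`, list-columns
#'   `rdm` and `noise`.
#' @export
run_rsa <- function(bundle, window_width = 0.5, span = NULL, shrinkage = NULL) {
  if (!bundle$normalized) stop("bundle must be normalized first", call. = FALSE)
  span <- span %||% bundle$design$analysis_window
  windows <- decoding_windows(span, window_width)
  rows <- purrr::map(windows, function(w) {
    nm <- estimate_noise(bundle, w, shrinkage = shrinkage)
    tibble::tibble(bin_start = w[1], bin_end = w[2],
                   rdm = list(crossnobis_rdm(bundle, w, noise = nm)),
                   noise = list(nm))
  })
  res <- dplyr::bind_rows(rows)
  class(res) <- c("rdm_series", class(res))
  res
}

# Lower-triangle vectorization excluding the (meaningless) diagonal.
rdm_lower <- function(rdm) rdm[lower.tri(rdm)]

#' Pearson correlation between two RDMs
#'
#' Correlates the vectorized lower off-diagonal triangles and applies a
#' Bonferroni correction for the stated number of comparisons. A constant
#' RDM has no defined correlation; `r` is returned as `NA` with
#' `degenerate = TRUE`.
#'
#' @param rdm_a,rdm_b Square symmetric RDMs over the same conditions in the
#'   same order.
#' @param n_comparisons Bonferroni family size (default 1).
#' @return One-row tibble: `r`, `p_raw`, `p_corrected`, `n_pairs`,
#'   `degenerate`.
#' @export
rdm_correlation <- function(rdm_a, rdm_b, n_comparisons = 1) {
  if (!all(dim(rdm_a) == dim(rdm_b))) {
    stop("RDMs must share the same condition set", call. = FALSE)
  }
  if (!is.null(dimnames(rdm_a)) && !is.null(dimnames(rdm_b)) &&
      !identical(rownames(rdm_a), rownames(rdm_b))) {
    stop("RDMs must share condition ordering", call. = FALSE)
  }
  a <- rdm_lower(rdm_a)
  b <- rdm_lower(rdm_b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(tibble::tibble(r = NA_real_, p_raw = NA_real_,
                          p_corrected = NA_real_, n_pairs = length(a),
                          degenerate = TRUE))
  }
  ct <- stats::cor.test(a, b, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_raw = ct$p.value,
                 p_corrected = min(1, ct$p.value * n_comparisons),
                 n_pairs = length(a), degenerate = FALSE)
}

#' Metric-stress MDS embedding of an RDM
#'
#' Embeds conditions in `dims` dimensions by minimizing the metric stress
#' \deqn{\sqrt{\sum_{i<j} (\hat d_{ij} - d_{ij})^2 / \sum_{i<j} d_{ij}^2}}
#' over configurations, from a classical-scaling start plus seeded random
#' restarts. Negative crossnobis entries are clipped to 0 for the embedding
#' (dissimilarities must be nonnegative); the diagonal is ignored. Axes can
#' be aligned to a previous embedding by orthogonal Procrustes rotation for
#' consistency across time bins.
#'
#' @param rdm A symmetric `rdm` (or plain matrix).
#' @param dims Embedding dimensionality (default 2).
#' @param seed Integer seed for the random restarts.
#' @param n_starts Number of random restarts beyond the classical start.
#' @param align_to Optional `mds_embedding` (or coordinate matrix) to align
#'   axes to.
#' @return An `mds_embedding`: list with `coords` (condition x dims),
#'   `stress`, and `pair_residuals` (tibble of per-pair embedded vs target
#'   distances, the basis of "rubber band" distortion displays).
#' @export
mds_embed <- function(rdm, dims = 2, seed = 1, n_starts = 8, align_to = NULL) {
  D <- unclass(rdm)
  if (!isSymmetric(unname(D), tol = 1e-8)) {
    stop("RDM must be symmetric", call. = FALSE)
  }
  diag(D) <- 0
  D[D < 0] <- 0
  n <- nrow(D)
  denom <- sum(D[lower.tri(D)]^2)
  if (denom == 0) denom <- 1
  stress_of <- function(v) {
    X <- matrix(v, n, dims)
    E <- as.matrix(stats::dist(X))
    sqrt(sum((E[lower.tri(E)] - D[lower.tri(D)])^2) / denom)
  }
  inits <- with_local_seed(seed, {
    cm <- suppressWarnings(stats::cmdscale(D, k = dims))
    if (ncol(cm) < dims) {
      cm <- cbind(cm, matrix(0, n, dims - ncol(cm)))
    }
    c(list(cm),
      lapply(seq_len(n_starts), function(i)
        matrix(stats::rnorm(n * dims, sd = max(stats::sd(D), 0.1)), n, dims)))
  })
  best <- NULL
  for (x0 in inits) {
    fit <- stats::optim(as.vector(x0), stress_of, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  X <- matrix(best$par, n, dims)
  X <- sweep(X, 2, colMeans(X))
  if (!is.null(align_to)) {
    ref <- if (inherits(align_to, "mds_embedding")) align_to$coords else align_to
    X <- procrustes_rotate(X, ref)
  }
  rownames(X) <- rownames(D)
  E <- as.matrix(stats::dist(X))
  lw <- which(lower.tri(D), arr.ind = TRUE)
  pair_residuals <- tibble::tibble(
    cond_a = rownames(D)[lw[, 1]] %||% as.character(lw[, 1]),
    cond_b = rownames(D)[lw[, 2]] %||% as.character(lw[, 2]),
    target = D[lw], embedded = E[lw],
    residual = E[lw] - D[lw]
  )
  structure(list(coords = X, stress = best$value,
                 pair_residuals = pair_residuals),
            class = "mds_embedding")
}

# Orthogonal Procrustes: rotate/reflect centered X to best match ref.
procrustes_rotate <- function(X, ref) {
  Xc <- sweep(X, 2, colMeans(X))
  Rc <- sweep(ref, 2, colMeans(ref))
  sv <- svd(crossprod(Xc, Rc))
  Xc %*% (sv$u %*% t(sv$v))
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("<mds_embedding> %d conditions in %d dims, stress %.4g\n",
              nrow(x$coords), ncol(x$coords), x$stress))
  invisible(x)
}

#' @export
tidy.mds_embedding <- function(x, ...) {
  coords <- x$coords
  stress <- x$stress
  tibble::tibble(condition = rownames(coords) %||%
                   as.character(seq_len(nrow(coords))),
                 x = coords[, 1], y = coords[, 2],
                 stress = stress)
}

#' @export
autoplot.mds_embedding <- function(object, ...) {
  df <- tidy(object)
  seg <- object$pair_residuals
  seg <- dplyr::left_join(seg, df[, c("condition", "x", "y")],
                          by = c(cond_a = "condition"))
  seg <- dplyr::left_join(seg, df[, c("condition", "x", "y")],
                          by = c(cond_b = "condition"),
                          suffix = c("", "_b"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$x_b, yend = .data$y_b,
                                       linewidth = -abs(.data$residual)),
                          colour = "grey70", show.legend = FALSE) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$condition),
                       vjust = -0.8, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "MDS 1", y = "MDS 2") +
    ggplot2::theme_minimal()
}

#' Tidy an RDM or RDM series into long format
#'
#' @param x An `rdm` matrix or `rdm_series` tibble.
#' @param ... Unused.
#' @return Long tibble: (`bin_start`,) `cond_a`, `cond_b`, `d` for the lower
#'   triangle.
#' @export
tidy.rdm <- function(x, ...) {
  lw <- which(lower.tri(x), arr.ind = TRUE)
  tibble::tibble(cond_a = rownames(x)[lw[, 1]], cond_b = colnames(x)[lw[, 2]],
                 d = unclass(x)[lw])
}

#' @export
tidy.rdm_series <- function(x, ...) {
  purrr::map2_dfr(x$bin_start, x$rdm, function(b, r) {
    out <- tidy(r)
    out$bin_start <- b
    out[, c("bin_start", "cond_a", "cond_b", "d")]
  })
}

#' @export
autoplot.rdm_series <- function(object, ...) {
  df <- tidy(object)
  df$bin <- sprintf("%g s", df$bin_start)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cond_b, y = .data$cond_a,
                                   fill = .data$d)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~bin) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "crossnobis d") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
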