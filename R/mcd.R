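#' Minimum covariance determinant estimator
#'
#' Location and scatter of the size-`h` observation subset whose classical
#' covariance has minimal determinant. When the number of candidate subsets
#' `C(n, h)` is at most `10^5` the search is exhaustive; otherwise the
#' FAST-MCD algorithm is used (random elemental starts followed by
#' concentration steps). The raw subset covariance is multiplied by the
#' standard consistency factor `alpha / P(chisq_{p+2} <= q_alpha)` with
#' `alpha = h/n` and `q_alpha` the `alpha` quantile of `chisq_p`, making it
#' consistent at the normal model; the returned estimate then applies the
#' standard one-step reweighting (points within the 0.975 chi-squared
#' quantile of the corrected robust distance, with its own truncation
#' consistency factor), which removes most of the raw MCD's finite-sample
#' inefficiency while keeping its breakdown point. With `h = n` no trimming
#' or reweighting occurs and the result is exactly the classical sample
#' covariance.
#'
#' @param X n x p numeric matrix, `n > p`.
#' @param h Subset size; defaults to `ceiling((n + p + 1) / 2)`.
#' @param support_fraction Alternative to `h`: `h = max(h_min, floor(f * n))`.
#' @param n_starts Number of random elemental starts for FAST-MCD (default
#'   500).
#' @param seed Integer seed controlling the random starts.
#' @param exhaustive_limit Largest `C(n, h)` for which the subset search is
#'   exhaustive (default `1e5`).
#' @param reweight Apply the one-step reweighting (default TRUE; ignored when
#'   `h = n`).
#' @return List with `center` and `cov` (the reweighted, consistency-corrected
#'   estimate), `raw_cov` (uncorrected covariance of the optimal subset),
#'   `raw_cov_corrected`, `support` (indices of the optimal subset),
#'   `weights` (0/1 reweighting mask), `h`, and `correction`.
#' @export
mcd_covariance <- function(X, h = NULL, support_fraction = NULL,
                           n_starts = 500L, seed = 1L,
                           exhaustive_limit = 1e5, reweight = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("n <= p: use fewer tasks or more subjects")
  h_min <- ceiling((n + p + 1) / 2)
  if (is.null(h)) {
    h <- if (is.null(support_fraction)) h_min
         else max(h_min, floor(support_fraction * n))
  }
  h <- as.integer(h)
  if (h < h_min || h > n)
    stop(sprintf("h must satisfy %d <= h <= %d", h_min, n))

  subset_stats <- function(idx) {
    xs <- X[idx, , drop = FALSE]
    mu <- colMeans(xs)
    S <- stats::cov(xs)
    list(mu = mu, S = S, det = det(S))
  }
  cstep <- function(mu, S) {
    d2 <- stats::mahalanobis(X, mu, S)
    sort(order(d2)[seq_len(h)])
  }

  best <- NULL
  if (h == n) {
    best <- c(subset_stats(seq_len(n)), list(support = seq_len(n)))
  } else if (choose(n, h) <= exhaustive_limit) {
    combs <- utils::combn(n, h)
    for (k in seq_len(ncol(combs))) {
      st <- subset_stats(combs[, k])
      if (is.null(best) || st$det < best$det)
        best <- c(st, list(support = combs[, k]))
    }
  } else {
    set.seed(as.integer(seed))
    for (s in seq_len(n_starts)) {
      idx <- sample.int(n, p + 1L)
      st <- tryCatch(subset_stats(idx), error = function(e) NULL)
      if (is.null(st) || !is.finite(st$det) || st$det <= 0) {
        # degenerate elemental set: grow it until the covariance is regular
        repeat {
          idx <- c(idx, sample(setdiff(seq_len(n), idx), 1L))
          st <- subset_stats(idx)
          if (is.finite(st$det) && st$det > 0) break
        }
      }
      idx <- cstep(st$mu, st$S)
      for (it in seq_len(100L)) {
        st <- subset_stats(idx)
        new_idx <- cstep(st$mu, st$S)
        if (identical(new_idx, idx)) break
        idx <- new_idx
      }
      st <- subset_stats(idx)
      if (is.null(best) || st$det < best$det) best <- c(st, list(support = idx))
    }
  }
  alpha <- h / n
  corr <- if (h == n) 1
          else alpha / stats::pchisq(stats::qchisq(alpha, p), p + 2)
  cov0 <- best$S * corr
  center <- best$mu
  covf <- cov0
  w <- rep(TRUE, n)
  if (reweight && h < n) {
    d2 <- stats::mahalanobis(X, best$mu, cov0)
    w <- d2 <= stats::qchisq(0.975, p)
    cw <- 0.975 / stats::pchisq(stats::qchisq(0.975, p), p + 2)
    center <- colMeans(X[w, , drop = FALSE])
    covf <- stats::cov(X[w, , drop = FALSE]) * cw
  }
  list(center = center, cov = covf, raw_cov = best$S,
       raw_cov_corrected = cov0, support = best$support,
       weights = as.integer(w), h = h, correction = corr)
}

#' Robust principal components of decline slopes
#'
#' Eigendecomposition of the minimum-covariance-determinant covariance of a
#' corrected, IQR-normalized slope panel. Two fit variants are intended:
#' controls plus carriers (for visualizing group trajectories) and carriers
#' only (for stratifying within the disease group). Eigenvector signs are
#' fixed so each component's largest-magnitude loading is positive, making
#' projections reproducible.
#'
#' @param slopes Subject x task matrix (age/sex-corrected, IQR-normalized);
#'   rows with missing values are dropped from the fit.
#' @param n_components Components to retain (default 5).
#' @param h,support_fraction,n_starts,seed Passed to [mcd_covariance()];
#'   `support_fraction = 1` gives classical PCA.
#' @return A `pc_model`: `cov`, `center`, `loadings` (task x component),
#'   `eigenvalues`, `variance_fraction`, `n_components`, `fit_rows`.
#' @export
robust_pca <- function(slopes, n_components = 5L, h = NULL,
                       support_fraction = NULL, n_starts = 500L, seed = 1L) {
  X <- as.matrix(slopes)
  fit_rows <- which(apply(X, 1, function(z) all(is.finite(z))))
  mcd <- mcd_covariance(X[fit_rows, , drop = FALSE], h = h,
                        support_fraction = support_fraction,
                        n_starts = n_starts, seed = seed)
  if (!all(is.finite(mcd$cov))) stop("non-finite robust covariance")
  eig <- eigen(mcd$cov, symmetric = TRUE)
  vecs <- eig$vectors
  for (j in seq_len(ncol(vecs))) {
    k <- which.max(abs(vecs[, j]))
    if (vecs[k, j] < 0) vecs[, j] <- -vecs[, j]
  }
  rownames(vecs) <- colnames(X)
  n_components <- min(n_components, ncol(X))
  structure(list(cov = mcd$cov, center = mcd$center,
                 loadings = vecs, eigenvalues = eig$values,
                 variance_fraction = eig$values / sum(eig$values),
                 n_components = as.integer(n_components),
                 fit_rows = fit_rows, mcd = mcd),
            class = "pc_model")
}

#' Project slopes onto fitted principal components
#'
#' @param object A `pc_model`.
#' @param newdata Subject x task matrix on the same tasks.
#' @param ... Unused.
#' @return Subject x component score matrix (`PC1`, `PC2`, ...).
#' @export
predict.pc_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  sc <- sweep(X, 2, object$center) %*%
    object$loadings[, seq_len(object$n_components), drop = FALSE]
  colnames(sc) <- paste0("PC", seq_len(object$n_components))
  sc
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf("<pc_model> %d tasks, %d retained components (MCD h = %d)\n",
              nrow(x$loadings), x$n_components, x$mcd$h))
  vf <- round(100 * x$variance_fraction[seq_len(x$n_components)], 1)
  cat("  variance explained (%):", paste(vf, collapse = ", "), "\n")
  invisible(x)
}
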