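# small cohort configuration used across tests: 4 sites, desk-scale imaging
small_config <- function(seed = 1, n_controls = 24, n_prehd = 40, ...) {
  cohort_config(n_controls = n_controls, n_prehd = n_prehd, n_sites = 4,
                n_voxels = 300, grid_dim = c(8L, 8L, 5L),
                seed = seed, ...)
}

# voxel x frame matrix whose first `k` voxels share one latent time course
# with loading `a` (plus unit noise); remaining voxels are independent noise
shared_latent_series <- function(n_voxels, n_frames, k, a, seed = 1) {
  set.seed(seed)
  lat <- rnorm(n_frames)
  X <- matrix(rnorm(n_voxels * n_frames), n_voxels, n_frames)
  X[seq_len(k), ] <- X[seq_len(k), ] + a * rep(1, k) %o% lat
  X
}

# brute-force O(V^2) FCD oracle: explicit double loop over voxel pairs
fcd_bruteforce <- function(data, threshold = 0.7) {
  V <- nrow(data)
  degree <- integer(V)
  for (i in seq_len(V - 1)) for (j in (i + 1):V) {
    r <- suppressWarnings(cor(data[i, ], data[j, ]))
    if (is.finite(r) && r > threshold) {
      degree[i] <- degree[i] + 1L
      degree[j] <- degree[j] + 1L
    }
  }
  lg <- log(degree + 1)
  lg / quantile(lg, 0.5, type = 1, names = FALSE)
}

# brute-force AUC by concordant-pair counting
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# exhaustive MCD oracle: minimal-determinant h-subset over all combinations,
# followed by the same consistency correction and one-step reweighting
mcd_bruteforce <- function(X, h) {
  n <- nrow(X); p <- ncol(X)
  combs <- combn(n, h)
  best <- NULL
  for (k in seq_len(ncol(combs))) {
    S <- cov(X[combs[, k], , drop = FALSE])
    d <- det(S)
    if (is.null(best) || d < best$det)
      best <- list(det = d, cov = S, center = colMeans(X[combs[, k], , drop = FALSE]),
                   support = combs[, k])
  }
  alpha <- h / n
  best$cov0 <- best$cov *
    if (h == n) 1 else alpha / pchisq(qchisq(alpha, p), p + 2)
  if (h < n) {
    d2 <- mahalanobis(X, best$center, best$cov0)
    w <- d2 <= qchisq(0.975, p)
    best$corrected <- cov(X[w, , drop = FALSE]) *
      0.975 / pchisq(qchisq(0.975, p), p + 2)
  } else best$corrected <- best$cov0
  best
}

# two sites separated by a constant additive offset on every feature
two_site_offset_fixture <- function(n_per_site = 60, p = 30, offset = 2,
                                    seed = 41) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per_site * p), 2 * n_per_site, p)
  sites <- rep(c("A", "B"), each = n_per_site)
  X[sites == "B", ] <- X[sites == "B", ] + offset   # pure additive site offset
  list(X = X, sites = sites)
}

# labelled decision-value fixture spread over sites (for metric tests)
site_fixture <- function(n_per_site = 20, n_sites = 4, effect = 1, seed = 1) {
  set.seed(seed)
  n <- n_per_site * n_sites
  sites <- rep(paste0("site", seq_len(n_sites)), each = n_per_site)
  y <- rbinom(n, 1, 0.5)
  list(scores = effect * y + rnorm(n), labels = y, sites = sites)
}
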