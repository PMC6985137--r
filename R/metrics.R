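#' Area under the ROC curve by rank statistic
#'
#' Mann-Whitney formulation: the fraction of (positive, negative) pairs in
#' which the positive scores higher, counting ties as 1/2.
#'
#' @param scores Numeric decision values.
#' @param labels Binary labels (logical, 0/1, or two-level factor; the larger
#'   level / `TRUE` / 1 is the positive class).
#' @return AUC in `[0, 1]`; `NA` if a class is absent.
#' @export
auc_rank <- function(scores, labels) {
  y <- .as_binary(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.as_binary <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) return(as.integer(labels == levels(labels)[2]))
  if (is.character(labels)) {
    lv <- sort(unique(labels))
    if (length(lv) > 2) stop("more than two label levels")
    return(as.integer(labels == lv[length(lv)]))
  }
  as.integer(labels != 0)
}

#' Site-averaged AUC with bootstrap-median replicate
#'
#' Computes the AUC within each test site and averages across sites that
#' contain both classes; sites lacking a class are excluded with a warning.
#' For robustness to outliers the computation is repeated under bootstrap
#' resampling of subjects within each site and the median resampled average is
#' reported alongside.
#'
#' @param decision_values Continuous classifier outputs.
#' @param labels Binary labels (see [auc_rank()]).
#' @param sites Site assignment per subject.
#' @param n_boot Number of bootstrap resamples (default 1000; increase to 1e5
#'   for final reporting).
#' @param seed Integer seed for the resampling.
#' @return List with `per_site` (named AUC vector), `mean_auc`,
#'   `bootstrap_median_auc`, and `n_per_site`.
#' @export
site_avg_auc <- function(decision_values, labels, sites, n_boot = 1000L,
                         seed = 1L) {
  y <- .as_binary(labels)
  sites <- as.character(sites)
  usable <- vapply(split(y, sites), function(z) length(unique(z)) == 2,
                   logical(1))
  if (!all(usable))
    warning(sprintf("site(s) lacking both classes excluded from AUC: %s",
                    paste(names(usable)[!usable], collapse = ", ")))
  use_sites <- names(usable)[usable]
  if (!length(use_sites)) {
    warning("no site contains both classes: AUC undefined")
    return(list(per_site = numeric(0), mean_auc = NA_real_,
                bootstrap_median_auc = NA_real_, n_per_site = table(sites)))
  }
  per_site <- vapply(use_sites, function(s) {
    sel <- sites == s
    auc_rank(decision_values[sel], y[sel])
  }, numeric(1))
  set.seed(as.integer(seed))
  boot <- vapply(seq_len(n_boot), function(b) {
    a <- vapply(use_sites, function(s) {
      sel <- which(sites == s)
      idx <- sel[sample.int(length(sel), replace = TRUE)]
      auc_rank(decision_values[idx], y[idx])
    }, numeric(1))
    mean(a, na.rm = TRUE)
  }, numeric(1))
  list(per_site = per_site, mean_auc = mean(per_site),
       bootstrap_median_auc = stats::median(boot),
       n_per_site = table(sites[sites %in% use_sites]))
}

#' Fisher-z pooled Spearman correlation across sites
#'
#' Per-site Spearman rank correlations are Fisher z-transformed, averaged,
#' and transformed back. Sites with fewer than 3 subjects are excluded with a
#' warning. Perfect correlations are clamped at |rho| = 1 - 1e-12 before the
#' transform.
#'
#' @param decision_values Continuous classifier outputs.
#' @param decline_values Continuous decline measure per subject.
#' @param sites Site assignment per subject.
#' @return List with `per_site` (named rho vector) and `rho_pooled`.
#' @export
pooled_spearman <- function(decision_values, decline_values, sites) {
  sites <- as.character(sites)
  tab <- table(sites)
  small <- names(tab)[tab < 3]
  if (length(small))
    warning(sprintf("site(s) with < 3 subjects excluded: %s",
                    paste(small, collapse = ", ")))
  use <- setdiff(names(tab), small)
  if (!length(use)) stop("no site with >= 3 subjects")
  per_site <- vapply(use, function(s) {
    sel <- sites == s
    suppressWarnings(stats::cor(decision_values[sel], decline_values[sel],
                                method = "spearman"))
  }, numeric(1))
  z <- atanh(pmin(1 - 1e-12, pmax(-1 + 1e-12, per_site)))
  list(per_site = per_site, rho_pooled = tanh(mean(z, na.rm = TRUE)))
}

#' Within-site permutation p-value
#'
#' Permutes labels independently within each site, recomputes the statistic,
#' and reports the add-one upper-tail p-value
#' `(1 + #(null >= observed)) / (1 + n_perm)`, which can never be zero.
#'
#' @param observed_stat The observed statistic.
#' @param stat_fn Function `(labels) -> statistic` evaluated on permuted
#'   labels.
#' @param labels Label vector to permute.
#' @param sites Site assignment; permutations are within site.
#' @param n_perm Number of permutations (default 1000; 1e5 for final
#'   reporting).
#' @param seed Integer seed.
#' @return List with `p`, `null` (the permutation distribution), `n_perm`.
#' @export
permutation_pvalue <- function(observed_stat, stat_fn, labels, sites,
                               n_perm = 1000L, seed = 1L) {
  sites <- as.character(sites)
  if (length(unique(labels)) < 2) {
    warning("degenerate labels: p = 1")
    return(list(p = 1, null = rep(NA_real_, 0), n_perm = n_perm))
  }
  set.seed(as.integer(seed))
  idx_by_site <- split(seq_along(labels), sites)
  null <- vapply(seq_len(n_perm), function(b) {
    perm <- labels
    for (ix in idx_by_site) perm[ix] <- perm[sample(ix, length(ix))]
    stat_fn(perm)
  }, numeric(1))
  list(p = (1 + sum(null >= observed_stat, na.rm = TRUE)) / (1 + n_perm),
       null = null, n_perm = n_perm)
}
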