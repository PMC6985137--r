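#' Connectome fingerprinting across visits
#'
#' For each subject, the baseline FCD map is correlated (Pearson, across
#' voxels) with every subject's follow-up map; the correlations are ranked in
#' descending order and the rank of the subject's own follow-up is recorded
#' (1 = identified). Correlation ties are broken against the self-match
#' (worst rank), a conservative convention.
#'
#' @param baseline_maps,followup_maps Subject x voxel matrices with identical
#'   row (subject) and column (voxel) order; rownames are compared when
#'   present.
#' @return A `fingerprint_result`: `ranks` (per subject), `identification_rate`
#'   (fraction with rank 1), `chance_level` (`1/N`), `n`.
#' @export
fingerprint <- function(baseline_maps, followup_maps) {
  B <- as.matrix(baseline_maps); F1 <- as.matrix(followup_maps)
  if (!all(dim(B) == dim(F1))) stop("mismatched map dimensions between visits")
  if (!is.null(rownames(B)) && !is.null(rownames(F1)) &&
      !identical(rownames(B), rownames(F1)))
    stop("mismatched subject sets between visits")
  n <- nrow(B)
  R <- suppressWarnings(stats::cor(t(B), t(F1)))   # R[i, j] = cor(base i, follow j)
  R[!is.finite(R)] <- -Inf
  ranks <- vapply(seq_len(n), function(i) sum(R[i, ] >= R[i, i]), integer(1))
  structure(list(ranks = ranks, identification_rate = mean(ranks == 1L),
                 chance_level = 1 / n, n = n),
            class = "fingerprint_result")
}

#' @export
print.fingerprint_result <- function(x, ...) {
  cat(sprintf(
    "<fingerprint_result> N = %d: identification rate %.1f%% (chance %.2f%%), median self-rank %g\n",
    x$n, 100 * x$identification_rate, 100 * x$chance_level,
    stats::median(x$ranks)))
  invisible(x)
}

#' Classification outcome labels
#'
#' Standard confusion outcomes: controls can be TN (predicted control) or FP
#' (predicted carrier); carriers can be FN or TP.
#'
#' @param predictions Predicted class per subject: binary (`TRUE`/1 =
#'   predicted carrier) or decision values thresholded at `threshold`.
#' @param truth True group per subject (`"control"` / `"preHD"`, or binary
#'   with 1 = carrier).
#' @param threshold Decision threshold applied to numeric `predictions`
#'   (default 0, i.e. probability 0.5 on the affine score).
#' @return Factor with levels TN, FP, FN, TP.
#' @export
outcome_labels <- function(predictions, truth, threshold = 0) {
  if (is.numeric(predictions) && any(predictions != round(predictions)))
    predictions <- predictions > threshold
  pred1 <- .as_binary(predictions)
  true1 <- if (is.character(truth) || is.factor(truth))
    as.integer(as.character(truth) == "preHD") else .as_binary(truth)
  out <- ifelse(true1 == 1, ifelse(pred1 == 1, "TP", "FN"),
                ifelse(pred1 == 1, "FP", "TN"))
  factor(out, levels = c("TN", "FP", "FN", "TP"))
}

#' Test-retest transition matrix of classification outcomes
#'
#' Empirical conditional probabilities `P(follow-up outcome | baseline
#' outcome)`. By construction controls occupy only the TN/FP block and
#' carriers only the FN/TP block.
#'
#' @param baseline_outcomes,followup_outcomes Factors from [outcome_labels()],
#'   same subjects in the same order.
#' @return A `transition_matrix`: `P` (4 x 4 row-conditional matrix; rows with
#'   no baseline occupancy are NA), `counts`, `n`.
#' @export
transition_matrix <- function(baseline_outcomes, followup_outcomes) {
  lv <- c("TN", "FP", "FN", "TP")
  b <- factor(baseline_outcomes, lv); f <- factor(followup_outcomes, lv)
  if (length(b) != length(f)) stop("visits must cover the same subjects")
  counts <- table(baseline = b, followup = f)
  P <- matrix(NA_real_, 4, 4, dimnames = dimnames(counts))
  occ <- rowSums(counts) > 0
  P[occ, ] <- counts[occ, , drop = FALSE] / rowSums(counts)[occ]
  structure(list(P = P, counts = counts, n = length(b)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix> P(follow-up | baseline):\n")
  print(round(x$P, 3))
  invisible(x)
}

#' Group-preserving permutation null for the transition matrix
#'
#' Follow-up outcomes are permuted among subjects of the same group, which
#' preserves each group's outcome proportions per visit while destroying the
#' within-subject correspondence. The chance matrix is the mean permuted
#' transition matrix; each diagonal (consistency) cell gets a two-sided
#' add-one permutation p-value.
#'
#' @param baseline_outcomes,followup_outcomes Factors from [outcome_labels()].
#' @param groups Group per subject (`"control"`/`"preHD"`).
#' @param n_perm Number of permutations (default 1000; 1e5 for final
#'   reporting).
#' @param seed Integer seed.
#' @return List with `observed` ([transition_matrix()]), `chance` (mean
#'   permuted P), `p_diagonal` (two-sided p per diagonal cell), `n_perm`, and
#'   `fixed_groups` (groups with a single subject, whose follow-up cannot
#'   move).
#' @export
transition_null <- function(baseline_outcomes, followup_outcomes, groups,
                            n_perm = 1000L, seed = 1L) {
  lv <- c("TN", "FP", "FN", "TP")
  b <- factor(baseline_outcomes, lv); f <- factor(followup_outcomes, lv)
  groups <- as.character(groups)
  obs <- transition_matrix(b, f)
  idx_by_group <- split(seq_along(f), groups)
  fixed <- names(idx_by_group)[lengths(idx_by_group) == 1]
  set.seed(as.integer(seed))
  acc <- matrix(0, 4, 4, dimnames = dimnames(obs$P))
  occ <- rowSums(obs$counts) > 0
  null_diag <- matrix(NA_real_, n_perm, 4,
                      dimnames = list(NULL, lv))
  for (k in seq_len(n_perm)) {
    fp <- f
    for (ix in idx_by_group)
      if (length(ix) > 1) fp[ix] <- fp[sample(ix, length(ix))]
    tp <- transition_matrix(b, fp)
    Pk <- tp$P; Pk[!occ, ] <- 0
    acc <- acc + Pk
    null_diag[k, ] <- diag(tp$P)
  }
  chance <- acc / n_perm
  chance[!occ, ] <- NA_real_
  obs_diag <- diag(obs$P)
  p_diag <- vapply(seq_len(4), function(j) {
    if (!occ[j]) return(NA_real_)
    hi <- (1 + sum(null_diag[, j] >= obs_diag[j], na.rm = TRUE)) / (1 + n_perm)
    lo <- (1 + sum(null_diag[, j] <= obs_diag[j], na.rm = TRUE)) / (1 + n_perm)
    min(1, 2 * min(hi, lo))
  }, numeric(1))
  names(p_diag) <- lv
  list(observed = obs, chance = chance, p_diagonal = p_diag,
       n_perm = n_perm, fixed_groups = fixed)
}
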