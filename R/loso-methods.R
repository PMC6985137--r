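#' @export
print.loso_strat <- function(x, ...) {
  r <- x$report
  cat(sprintf("<loso_strat> %s model, %d sites, %d subjects (%d trainable)\n",
              if (x$is_stratification) "stratification" else "group",
              length(x$models), length(x$labels), r$n_trainable))
  cat(sprintf("  site-averaged AUC: %.3f (bootstrap median %.3f, p = %.4g)\n",
              r$mean_auc, r$bootstrap_median_auc, r$auc_p))
  if (!is.null(r$pooled_spearman))
    cat(sprintf("  pooled Spearman rho: %.3f (p = %.4g)\n",
                r$pooled_spearman, r$spearman_p))
  invisible(x)
}

#' @export
summary.loso_strat <- function(object, ...) {
  r <- object$report
  cat("Leave-one-site-out stratification model\n")
  cat("---------------------------------------\n")
  cat(sprintf("Positive class: %s\n", r$positive))
  cat("\nPer-site AUC (fast vs slow subjects of the held-out site):\n")
  print(round(r$per_site_auc, 3))
  cat(sprintf("\nSite-averaged AUC: %.3f\nBootstrap-median AUC: %.3f\nPermutation p (AUC): %.4g\n",
              r$mean_auc, r$bootstrap_median_auc, r$auc_p))
  if (!is.null(r$pooled_spearman)) {
    cat("\nPer-site Spearman rho (decision value vs decline, all subjects):\n")
    print(round(r$per_site_spearman, 3))
    cat(sprintf("Fisher-z pooled rho: %.3f\nPermutation p (rho): %.4g\n",
                r$pooled_spearman, r$spearman_p))
  }
  cat("\nSubjects per site:\n")
  print(r$n_per_site)
  invisible(r)
}

#' Mean weight map across the per-site models
#'
#' @param object A `loso_strat` fit.
#' @param ... Unused.
#' @return Named list with `weights` (feature-wise mean across site models)
#'   and `intercept`.
#' @export
coef.loso_strat <- function(object, ...) {
  fitted <- Filter(Negate(is.null), object$models)
  W <- vapply(fitted, function(m) m$weights,
              numeric(length(fitted[[1]]$weights)))
  list(weights = rowMeans(W),
       intercept = mean(vapply(fitted, function(m) m$intercept, numeric(1))))
}

#' Score new subjects with a LOSO-trained stratifier
#'
#' Subjects from a site seen during fitting are scored by the model for which
#' their site was held out (so the score is always out-of-sample); subjects
#' from unseen sites are scored by the average weight map.
#'
#' @param object A `loso_strat` fit.
#' @param newdata Feature matrix with the training feature count (raw
#'   features; the per-site model's stored preprocessing is applied).
#' @param sites Site label per row of `newdata` (`NULL` uses the average
#'   model).
#' @param ... Unused.
#' @return Numeric decision values.
#' @export
predict.loso_strat <- function(object, newdata, sites = NULL, ...) {
  newdata <- as.matrix(newdata)
  avg <- coef(object)
  score_avg <- function(rows)
    as.numeric(newdata[rows, , drop = FALSE] %*% avg$weights + avg$intercept)
  if (is.null(sites)) return(score_avg(seq_len(nrow(newdata))))
  sites <- as.character(sites)
  out <- rep(NA_real_, nrow(newdata))
  for (s in unique(sites)) {
    rows <- which(sites == s)
    m <- object$models[[s]]
    out[rows] <- if (is.null(m)) score_avg(rows)
                 else predict(m, newdata[rows, , drop = FALSE])
  }
  out
}

#' Plot a LOSO stratification fit
#'
#' Decision values against the continuous decline measure (when present),
#' colored by discrete label, with the pooled Spearman correlation in the
#' title; otherwise a per-class strip chart of decision values.
#'
#' @param x A `loso_strat` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.loso_strat <- function(x, ...) {
  lab <- factor(x$labels)
  cols <- c(fast = "#d7301f", intermediate = "#888888", slow = "#2b8cbe")
  if (!is.null(x$decline_values)) {
    col <- if (all(levels(lab) %in% names(cols))) cols[as.character(lab)]
           else as.integer(lab) + 1L
    graphics::plot(x$decline_values, x$decision_values, col = col, pch = 19,
                   xlab = "decline measure (negative = faster decline)",
                   ylab = "decision value (w.x + b)",
                   main = sprintf("pooled Spearman rho = %.2f",
                                  x$report$pooled_spearman), ...)
    graphics::legend("topleft", legend = levels(lab), bty = "n",
                     col = if (all(levels(lab) %in% names(cols)))
                       cols[levels(lab)] else seq_along(levels(lab)) + 1L,
                     pch = 19)
  } else {
    graphics::stripchart(x$decision_values ~ lab, vertical = TRUE,
                         method = "jitter", pch = 19,
                         ylab = "decision value", ...)
  }
  invisible(x)
}

#' Residuals of the binary decision rule
#'
#' Difference between the 0/1 class indicator and the logistic probability
#' implied by the decision value, for the subjects with extreme labels.
#'
#' @param object A `loso_strat` fit.
#' @param ... Unused.
#' @return Named numeric vector (NA for intermediate / unscored subjects).
#' @export
residuals.loso_strat <- function(object, ...) {
  y <- as.integer(object$labels == object$report$positive)
  y[object$is_stratification &
      !(object$labels %in% c("fast", "slow"))] <- NA_integer_
  y - stats::plogis(object$decision_values)
}
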