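#' Ordinary least-squares slope of one longitudinal trace
#'
#' All available visits are used. With fewer than two distinct time points the
#' slope is undefined and `NA` is returned.
#'
#' @param times Visit times in years.
#' @param scores Task scores at those visits.
#' @return The OLS slope (units/yr), or `NA_real_`.
#' @export
fit_slope <- function(times, scores) {
  ok <- is.finite(times) & is.finite(scores)
  times <- times[ok]; scores <- scores[ok]
  if (length(times) < 2 || stats::sd(times) == 0) return(NA_real_)
  sum((times - mean(times)) * (scores - mean(scores))) /
    sum((times - mean(times))^2)
}

#' Per-subject per-task decline slopes
#'
#' @param panel Long-format task panel with columns `subject_id`, `task`,
#'   `time_years`, `score` (as produced by [generate_task_scores()] or
#'   [read_cognitive_table()]).
#' @return A `slope_panel`: subject x task matrix of slopes with attributes
#'   `stage = "raw"` and `visit_counts` (subject x task matrix). Subjects with
#'   undefined slopes are flagged in attribute `flagged`.
#' @export
fit_slopes <- function(panel) {
  subs <- unique(panel$subject_id)
  tasks <- unique(panel$task)
  slopes <- matrix(NA_real_, length(subs), length(tasks),
                   dimnames = list(subs, tasks))
  counts <- matrix(0L, length(subs), length(tasks),
                   dimnames = list(subs, tasks))
  key <- split(seq_len(nrow(panel)),
               list(factor(panel$subject_id, subs), factor(panel$task, tasks)))
  for (i in seq_along(subs)) for (j in seq_along(tasks)) {
    rows <- key[[paste(subs[i], tasks[j], sep = ".")]]
    if (!length(rows)) next
    counts[i, j] <- length(rows)
    slopes[i, j] <- fit_slope(panel$time_years[rows], panel$score[rows])
  }
  flagged <- subs[apply(slopes, 1, function(z) any(!is.finite(z)))]
  structure(slopes, stage = "raw", visit_counts = counts, flagged = flagged,
            class = c("slope_panel", "matrix", "array"))
}

.as_sex01 <- function(sex) {
  if (is.numeric(sex)) return(as.numeric(sex))
  as.numeric(sex %in% c("F", "female", "Female", "f"))
}

#' Remove healthy age and sex expectations from slopes
#'
#' Per task, a linear model `slope ~ age + sex` is fitted on controls only and
#' its prediction (including the intercept) is subtracted from every subject's
#' slope, so corrected control slopes are centered at the healthy expectation.
#'
#' @param slopes Subject x task slope matrix ([fit_slopes()] output).
#' @param age Age in years at the first functional image, per subject (named
#'   or in row order).
#' @param sex Sex per subject (`"F"`/`"M"` or 0/1 indicator; females coded 1).
#' @param control_ids Subject ids (rownames) of the healthy controls used to
#'   estimate the covariate effects.
#' @return The corrected `slope_panel` (stage `"age_sex_corrected"`), with the
#'   fitted per-task coefficients in attribute `coefficients`.
#' @export
residualize_on_controls <- function(slopes, age, sex, control_ids) {
  sex <- .as_sex01(sex)
  ctrl <- rownames(slopes) %in% control_ids
  if (sum(ctrl) < 3) stop("need at least 3 controls to estimate age/sex effects")
  Xc <- cbind(1, age = age[ctrl], sex = sex[ctrl])
  if (qr(Xc)$rank < 3) {
    bad <- if (stats::sd(age[ctrl]) == 0) "age" else "sex"
    stop(sprintf("singular design among controls: covariate '%s' is degenerate", bad))
  }
  Xall <- cbind(1, age = age, sex = sex)
  coefs <- matrix(NA_real_, 3, ncol(slopes),
                  dimnames = list(c("(Intercept)", "age", "sex"),
                                  colnames(slopes)))
  out <- slopes
  for (j in seq_len(ncol(slopes))) {
    y <- slopes[ctrl, j]
    ok <- is.finite(y)
    b <- stats::lm.fit(Xc[ok, , drop = FALSE], y[ok])$coefficients
    coefs[, j] <- b
    out[, j] <- slopes[, j] - as.numeric(Xall %*% b)
  }
  attr(out, "stage") <- "age_sex_corrected"
  attr(out, "coefficients") <- coefs
  out
}

#' Interquartile-range normalization of slopes
#'
#' Each task's slopes are divided by that task's interquartile range
#' (linear-interpolation quantiles, R type 7), making tasks with different
#' units commensurate.
#'
#' @param slopes Subject x task slope matrix.
#' @return The normalized `slope_panel` (stage `"iqr_normalized"`), with the
#'   per-task IQRs in attribute `iqr`.
#' @export
iqr_normalize <- function(slopes) {
  iqrs <- apply(slopes, 2, stats::IQR, na.rm = TRUE, type = 7)
  if (any(iqrs == 0))
    stop(sprintf("zero IQR for task(s): %s",
                 paste(colnames(slopes)[iqrs == 0], collapse = ", ")))
  out <- sweep(slopes, 2, iqrs, "/")
  attr(out, "stage") <- "iqr_normalized"
  attr(out, "iqr") <- iqrs
  out
}
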