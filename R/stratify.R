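#' Robust standard deviation from the interquartile range
#'
#' The standard deviation of the normal distribution whose interquartile range
#' equals the observed one: `IQR / (2 * qnorm(0.75))`, i.e. `IQR / 1.34898`.
#' Insensitive to outliers.
#'
#' @param values Numeric vector (>= 4 values).
#' @return The robust SD; 0 with a warning when the IQR is zero.
#' @export
robust_sd <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4) stop("robust_sd needs at least 4 values")
  iqr <- stats::IQR(values, type = 7)
  if (iqr == 0) {
    warning("zero IQR: robust SD is 0 (all values will be labelled intermediate)")
    return(0)
  }
  iqr / (2 * stats::qnorm(0.75))
}

#' Discretize a decline measure into fast / intermediate / slow
#'
#' Subjects more than half a robust SD below the median are `fast` decliners,
#' more than half a robust SD above are `slow` (stable), and the rest --
#' including exact boundary ties -- are `intermediate`. For a normal
#' distribution the cutpoints at median +/- 0.337 SD split the population into
#' approximate terciles (36.8 / 26.4 / 36.8%).
#'
#' @param values Decline measure per subject (oriented so that more negative
#'   = faster decline).
#' @param measure Name of the measure (for reporting).
#' @return A `decline_labels` data frame with columns `value` and `label`
#'   (factor fast/intermediate/slow), and attributes `median`, `robust_sd`,
#'   `measure`.
#' @export
discretize_decline <- function(values, measure = "decline") {
  med <- stats::median(values, na.rm = TRUE)
  rsd <- robust_sd(values[is.finite(values)])
  label <- rep("intermediate", length(values))
  label[values < med - rsd / 2] <- "fast"
  label[values > med + rsd / 2] <- "slow"
  label[!is.finite(values)] <- NA
  out <- data.frame(value = values,
                    label = factor(label, c("fast", "intermediate", "slow")))
  if (!is.null(names(values))) rownames(out) <- names(values)
  attr(out, "median") <- med
  attr(out, "robust_sd") <- rsd
  attr(out, "measure") <- measure
  class(out) <- c("decline_labels", "data.frame")
  out
}

#' Elastic-net logistic classifier with nested hyperparameter selection
#'
#' Minimizes the penalized logistic loss
#' `logloss + lambda * (alpha * ||w||_1 + (1 - alpha)/2 * ||w||_2^2)`.
#' The penalty pair `(lambda, alpha)` is chosen by stratified internal
#' 5-fold cross-validation maximizing AUC, then the model is refitted on the
#' full training set with the winners.
#'
#' @param X n x p feature matrix.
#' @param y Binary labels (see [auc_rank()] for coding).
#' @param lambda_grid Penalty strengths (default 8 log-spaced values in
#'   `10^-3 .. 10^2`).
#' @param alpha_grid L1 mixing fractions (default 0.1, 0.5, 0.9).
#' @param inner_folds Number of internal CV folds (default 5).
#' @param seed Integer seed fixing the fold assignment.
#' @return A `stratifier_model`: `weights`, `intercept`, `lambda`, `alpha`,
#'   `cv_auc` (inner-CV AUC grid), `standardize`.
#' @export
fit_elasticnet_logistic <- function(X, y,
                                    lambda_grid = 10^seq(2, -3, length.out = 8),
                                    alpha_grid = c(0.1, 0.5, 0.9),
                                    inner_folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- .as_binary(y)
  if (length(unique(y)) < 2) stop("single-class input: need both classes to train")
  if (min(table(y)) < 2)
    stop("need at least 2 observations in each class")
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  set.seed(as.integer(seed))
  # cap the fold count at the minor class size so every inner training set
  # keeps both classes
  inner_folds <- max(2L, min(as.integer(inner_folds), min(table(y))))
  folds <- integer(length(y))      # stratified fold assignment
  for (cl in unique(y)) {
    ix <- which(y == cl)
    folds[ix] <- sample(rep_len(seq_len(inner_folds), length(ix)))
  }
  # small extreme subgroups are routine here; glmnet's small-class advisory
  # would otherwise swamp the logs
  quiet_glmnet <- function(...) withCallingHandlers(
    glmnet::glmnet(...),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  cv_auc <- matrix(NA_real_, length(alpha_grid), length(lambda_grid),
                   dimnames = list(paste0("alpha", alpha_grid), NULL))
  for (a in seq_along(alpha_grid)) {
    preds <- matrix(NA_real_, length(y), length(lambda_grid))
    for (f in seq_len(inner_folds)) {
      tr <- folds != f
      if (length(table(y[tr])) < 2 || min(table(y[tr])) < 2) next
      fit <- quiet_glmnet(X[tr, , drop = FALSE], y[tr], family = "binomial",
                          alpha = alpha_grid[a], lambda = lambda_grid,
                          standardize = TRUE)
      preds[!tr, ] <- stats::predict(fit, X[!tr, , drop = FALSE],
                                     s = lambda_grid)
    }
    cv_auc[a, ] <- apply(preds, 2, function(p) {
      ok <- is.finite(p)
      if (length(unique(y[ok])) < 2) NA_real_ else auc_rank(p[ok], y[ok])
    })
  }
  if (all(is.na(cv_auc))) {
    # inner CV impossible at this sample size: fall back to mid-grid penalty
    alpha <- alpha_grid[ceiling(length(alpha_grid) / 2)]
    lambda <- lambda_grid[ceiling(length(lambda_grid) / 2)]
  } else {
    best <- which(cv_auc == max(cv_auc, na.rm = TRUE), arr.ind = TRUE)[1, ]
    alpha <- alpha_grid[best[1]]
    lambda <- lambda_grid[best[2]]
  }
  fit <- quiet_glmnet(X, y, family = "binomial", alpha = alpha,
                      lambda = lambda_grid, standardize = TRUE)
  beta <- stats::coef(fit, s = lambda)
  structure(list(weights = as.numeric(beta[-1]), intercept = beta[1],
                 lambda = lambda, alpha = alpha, cv_auc = cv_auc,
                 lambda_grid = lambda_grid, alpha_grid = alpha_grid),
            class = "stratifier_model")
}

#' Decision values of a fitted stratifier
#'
#' The raw affine score `w . x + b` (the signed distance to the decision
#' hyperplane up to the norm of `w`, to which rank-based validation metrics
#' are invariant).
#'
#' @param object A `stratifier_model`.
#' @param newdata Feature matrix.
#' @param ... Unused.
#' @return Numeric decision values.
#' @export
predict.stratifier_model <- function(object, newdata, ...) {
  as.numeric(as.matrix(newdata) %*% object$weights + object$intercept)
}

#' @export
print.stratifier_model <- function(x, ...) {
  cat(sprintf(
    "<stratifier_model> %d features, %d nonzero weights; lambda = %.4g, alpha = %.2g\n",
    length(x$weights), sum(x$weights != 0), x$lambda, x$alpha))
  invisible(x)
}

#' Learn and remove healthy age/sex expectations from features
#'
#' Per feature, a linear model `feature ~ age + sex` is fitted on the training
#' controls only; its prediction is subtracted from every row (training and
#' test) using those training weights, so no test-row information enters the
#' fit. Used for carrier-vs-control classification.
#'
#' @param X n x p feature matrix (all rows to be corrected).
#' @param age,sex Covariates for all rows (females coded 1).
#' @param control_rows Integer indices of training-control rows used to
#'   estimate the weights.
#' @return List with `X` (corrected matrix) and `coefficients` (3 x p), which
#'   can be reapplied via [apply_age_sex_correction()].
#' @export
correct_features_age_sex <- function(X, age, sex, control_rows) {
  X <- as.matrix(X)
  sex <- .as_sex01(sex)
  if (!length(control_rows)) stop("no controls in training set")
  # a covariate that is constant among the training controls carries no
  # estimable weight; drop it (its effect is absorbed by the intercept)
  use_age <- stats::sd(age[control_rows]) > 0
  use_sex <- stats::sd(sex[control_rows]) > 0
  if (!use_age) warning("age constant among training controls: age term dropped")
  if (!use_sex) warning("single-sex training controls: sex term dropped")
  keep <- c(TRUE, use_age, use_sex)
  Xc <- cbind(1, age[control_rows], sex[control_rows])[, keep, drop = FALSE]
  if (qr(Xc)$rank < ncol(Xc)) stop("degenerate age/sex design among controls")
  B <- matrix(0, 3, ncol(X), dimnames = list(c("(Intercept)", "age", "sex"),
                                             colnames(X)))
  B[keep, ] <- solve(crossprod(Xc), crossprod(Xc, X[control_rows, , drop = FALSE]))
  list(X = X - cbind(1, age, sex) %*% B, coefficients = B)
}

#' Apply previously learned age/sex correction weights
#'
#' @param X Feature matrix.
#' @param age,sex Covariates for the rows of `X`.
#' @param coefficients 3 x p matrix from [correct_features_age_sex()].
#' @return Corrected feature matrix.
#' @export
apply_age_sex_correction <- function(X, age, sex, coefficients) {
  as.matrix(X) - cbind(1, age, .as_sex01(sex)) %*% coefficients
}

#' Append a standardized CAG-repeat feature
#'
#' Standardization (mean/SD) is fitted on the training rows only and applied
#' to all rows.
#'
#' @param X n x p feature matrix.
#' @param cag CAG repeat count per row; must be complete.
#' @param training_rows Rows used to fit the standardization (default all).
#' @return n x (p + 1) matrix with the standardized CAG column appended.
#' @export
add_genetic_feature <- function(X, cag, training_rows = seq_len(nrow(X))) {
  if (any(!is.finite(cag))) stop("missing CAG value(s)")
  mu <- mean(cag[training_rows])
  sdv <- stats::sd(cag[training_rows])
  z <- if (is.na(sdv) || sdv == 0) rep(0, length(cag)) else (cag - mu) / sdv
  cbind(as.matrix(X), cag = z)
}

#' Site-robust FCD stratifier with leave-one-site-out cross-validation
#'
#' The central model fit: for each imaging site, an elastic-net logistic
#' classifier is trained on the extreme decline subgroups (fast vs slow;
#' intermediates are excluded from training) of all *other* sites, then every
#' held-out subject -- including intermediates -- is scored by the affine
#' decision value. All preprocessing that involves estimation (age/sex
#' weights, ComBat harmonization, motion detrending, atrophy residualization,
#' CAG standardization) is fitted on training-site rows only and applied to
#' the held-out site with the training parameters.
#'
#' @param X n x p feature matrix (unsmoothed FCD maps, one row per subject).
#' @param labels Class label per subject. For stratification models pass the
#'   `label` column of [discretize_decline()] (levels fast/intermediate/slow);
#'   for carrier-vs-control models pass a binary group label.
#' @param sites Site assignment per subject.
#' @param decline_values Optional continuous decline measure used for the
#'   Spearman validation (all scored subjects of each test site).
#' @param positive Level treated as the positive class (default `"fast"` when
#'   present).
#' @param covariates Optional data frame with columns `age`, `sex` (and `cag`,
#'   `fd_mean` when the corresponding options are enabled); `group` column
#'   with level `"control"` marks the rows usable for control-learned fits.
#' @param correct_age_sex Learn age/sex weights from training controls and
#'   subtract them from all rows (carrier-vs-control models).
#' @param harmonize_sites `FALSE` (default), `TRUE` (fit ComBat on the
#'   training sites inside each fold; a held-out site has no estimated
#'   parameters and passes through unadjusted), or `"global"` (fit once on
#'   all rows before cross-validation, mirroring a pooled harmonization).
#' @param detrend_motion Learn per-feature motion weights from healthy
#'   controls and remove the motion term from every row (needs
#'   `covariates$fd_mean` for the modeled rows). For stratification models,
#'   whose rows are all carriers, supply the controls via `motion_ref`;
#'   otherwise the training-control rows of `X` are used.
#' @param motion_ref Optional reference controls for motion detrending: list
#'   with `X` (control feature matrix), `fd_mean`, `sites`. Only reference
#'   rows from training sites are used within each fold.
#' @param gmc Optional subject x voxel grey-matter-concentration matrix; when
#'   supplied, per-voxel atrophy effects are residualized out (fitted on
#'   training rows).
#' @param add_cag Append a standardized CAG feature (needs `covariates$cag`).
#' @param lambda_grid,alpha_grid,inner_folds Hyperparameter search; see
#'   [fit_elasticnet_logistic()].
#' @param n_boot,n_perm Resampling sizes for the evaluation report (defaults
#'   1000; the reference analysis uses 1e5).
#' @param seed Integer seed for folds, bootstrap and permutations.
#' @return A `loso_strat` object: per-site `models`, per-subject
#'   `decision_values`, `labels`, `sites`, and `report` (per-site and averaged
#'   AUC, bootstrap-median AUC, permutation p, per-site and pooled Spearman
#'   with permutation p, group sizes).
#' @export
loso_stratify <- function(X, labels, sites, decline_values = NULL,
                          positive = NULL, covariates = NULL,
                          correct_age_sex = FALSE, harmonize_sites = FALSE,
                          detrend_motion = FALSE, motion_ref = NULL,
                          gmc = NULL, add_cag = FALSE,
                          lambda_grid = 10^seq(2, -3, length.out = 8),
                          alpha_grid = c(0.1, 0.5, 0.9), inner_folds = 5L,
                          n_boot = 1000L, n_perm = 1000L, seed = 1L) {
  X <- as.matrix(X)
  sites <- as.character(sites)
  site_levels <- sort(unique(sites))
  if (length(site_levels) < 2) stop("need at least 2 sites for LOSO-CV")
  labels <- as.character(labels)
  is_strat <- all(stats::na.omit(labels) %in% c("fast", "intermediate", "slow"))
  if (is.null(positive)) positive <- if (is_strat) "fast" else
    sort(unique(stats::na.omit(labels)))[length(unique(stats::na.omit(labels)))]
  trainable <- if (is_strat) labels %in% c("fast", "slow") else
    !is.na(labels)
  ybin <- as.integer(labels == positive)

  needs_cov <- correct_age_sex || detrend_motion || add_cag
  if (needs_cov && is.null(covariates))
    stop("covariates data frame required for the requested corrections")

  if (identical(harmonize_sites, "global")) {
    hm_global <- combat_fit(X, sites)
    X <- combat_apply(hm_global, X, sites)
    harmonize_sites <- FALSE
  }

  decisions <- rep(NA_real_, nrow(X))
  models <- stats::setNames(vector("list", length(site_levels)), site_levels)
  for (s in site_levels) {
    te <- which(sites == s)
    tr <- which(sites != s & trainable)
    if (length(unique(ybin[tr])) < 2 || min(table(ybin[tr])) < 2) {
      warning(sprintf("training set for held-out site %s lacks both classes; skipped", s))
      next
    }
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[te, , drop = FALSE]
    prep <- list()

    if (!is.null(gmc)) {
      gfit <- gmc_residualize(Xtr, gmc[tr, , drop = FALSE])
      Xtr <- gfit$residuals
      Xte <- apply_gmc_residualization(Xte, gmc[te, , drop = FALSE], gfit)
      prep$gmc <- gfit[c("intercept", "slope")]
    }
    if (harmonize_sites) {
      hm <- combat_fit(Xtr, sites[tr])
      Xtr <- combat_apply(hm, Xtr, sites[tr])
      Xte <- combat_apply(hm, Xte, rep(NA_character_, length(te)))
      prep$combat <- hm
    }
    if (correct_age_sex) {
      ctrl_tr <- which(covariates$group[tr] == "control")
      cf <- correct_features_age_sex(Xtr, covariates$age[tr],
                                     covariates$sex[tr], ctrl_tr)
      Xtr <- cf$X
      Xte <- apply_age_sex_correction(Xte, covariates$age[te],
                                      covariates$sex[te], cf$coefficients)
      prep$age_sex <- cf$coefficients
    }
    if (detrend_motion) {
      if (!is.null(motion_ref)) {
        ref <- which(as.character(motion_ref$sites) != s)
        md <- motion_detrend(motion_ref$X[ref, , drop = FALSE],
                             motion_ref$fd_mean[ref],
                             seq_along(ref))
      } else {
        ctrl_tr <- which(covariates$group[tr] == "control")
        md <- motion_detrend(Xtr, covariates$fd_mean[tr], ctrl_tr)
      }
      Xtr <- apply_motion_detrend(Xtr, covariates$fd_mean[tr], md)
      Xte <- apply_motion_detrend(Xte, covariates$fd_mean[te], md)
      prep$motion <- md[c("weights", "fd_ref")]
    }
    if (add_cag) {
      mu <- mean(covariates$cag[tr]); sdv <- stats::sd(covariates$cag[tr])
      Xtr <- add_genetic_feature(Xtr, covariates$cag[tr], seq_along(tr))
      zte <- if (is.na(sdv) || sdv == 0) rep(0, length(te))
             else (covariates$cag[te] - mu) / sdv
      Xte <- cbind(Xte, cag = zte)
      prep$cag <- c(mean = mu, sd = sdv)
    }

    mod <- fit_elasticnet_logistic(Xtr, ybin[tr], lambda_grid = lambda_grid,
                                   alpha_grid = alpha_grid,
                                   inner_folds = inner_folds, seed = seed)
    mod$preprocessing <- prep
    mod$held_out_site <- s
    models[[s]] <- mod
    decisions[te] <- predict(mod, Xte)
  }

  eval_rows <- which(trainable & !is.na(decisions))
  auc <- site_avg_auc(decisions[eval_rows], ybin[eval_rows], sites[eval_rows],
                      n_boot = n_boot, seed = seed)
  perm_auc <- if (is.na(auc$mean_auc)) list(p = NA_real_) else
    permutation_pvalue(
      auc$mean_auc,
      function(lab) site_avg_auc_stat(decisions[eval_rows], lab,
                                      sites[eval_rows]),
      ybin[eval_rows], sites[eval_rows], n_perm = n_perm, seed = seed)

  sp <- NULL; perm_sp <- NULL
  if (!is.null(decline_values)) {
    # orient the continuous score along the decline measure: when the
    # positive class is the low-value extreme ("fast" decliners have the most
    # negative decline values) a well-performing decision value is
    # anti-correlated with the measure, so its sign is flipped before the
    # Spearman validation
    sgn <- if (is_strat && positive == "fast") -1 else 1
    sc_rows <- which(!is.na(decisions) & is.finite(decline_values))
    sp <- pooled_spearman(sgn * decisions[sc_rows], decline_values[sc_rows],
                          sites[sc_rows])
    perm_sp <- permutation_pvalue(
      sp$rho_pooled,
      function(dv) pooled_spearman(sgn * decisions[sc_rows], dv,
                                   sites[sc_rows])$rho_pooled,
      decline_values[sc_rows], sites[sc_rows], n_perm = n_perm, seed = seed)
  }

  report <- list(per_site_auc = auc$per_site, mean_auc = auc$mean_auc,
                 bootstrap_median_auc = auc$bootstrap_median_auc,
                 auc_p = perm_auc$p,
                 per_site_spearman = if (!is.null(sp)) sp$per_site,
                 pooled_spearman = if (!is.null(sp)) sp$rho_pooled,
                 spearman_p = if (!is.null(perm_sp)) perm_sp$p,
                 n_per_site = table(sites),
                 n_trainable = sum(trainable),
                 positive = positive)
  structure(list(models = models, decision_values = decisions,
                 labels = labels, sites = sites,
                 decline_values = decline_values, report = report,
                 is_stratification = is_strat, seed = seed),
            class = "loso_strat")
}

# silent site-averaged AUC (no bootstrap) used inside permutation nulls
site_avg_auc_stat <- function(decision_values, labels, sites) {
  y <- .as_binary(labels)
  per <- vapply(split(seq_along(y), as.character(sites)), function(ix) {
    if (length(unique(y[ix])) < 2) return(NA_real_)
    auc_rank(decision_values[ix], y[ix])
  }, numeric(1))
  mean(per, na.rm = TRUE)
}
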