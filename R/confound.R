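#' Fit a ComBat site-harmonization model
#'
#' Location-scale batch adjustment: per feature, a grand mean and pooled
#' scale are estimated, per-site location (gamma) and scale (delta)
#' parameters are estimated on the standardized data, and -- with `eb = TRUE`
#' -- shrunk across features by parametric empirical Bayes (normal prior on
#' gamma, inverse-gamma on delta^2). No biological covariates are modelled,
#' so no label information can leak into the harmonized features.
#'
#' @param features n x p matrix (subjects x features).
#' @param sites Site label per row; every site needs >= 2 subjects.
#' @param eb Apply empirical-Bayes shrinkage of the site parameters (default
#'   TRUE). `eb = FALSE` gives the plain location-scale adjustment, which
#'   exactly equalizes per-site means and variances and is exactly
#'   idempotent.
#' @return A `harmonization_model`: `alpha` (grand mean), `sigma` (pooled
#'   scale), `gamma_star`, `delta_star` (site x feature), `sites`,
#'   `n_per_site`, `eb`.
#' @export
combat_fit <- function(features, sites, eb = TRUE) {
  X <- as.matrix(features)
  sites <- as.character(sites)
  n <- nrow(X); p <- ncol(X)
  site_levels <- sort(unique(sites))
  ns <- table(factor(sites, site_levels))
  if (any(ns < 2))
    stop(sprintf("single-subject site(s): %s (site scale undefined)",
                 paste(names(ns)[ns < 2], collapse = ", ")))
  S <- length(site_levels)
  site_mean <- matrix(0, S, p, dimnames = list(site_levels, NULL))
  for (s in site_levels)
    site_mean[s, ] <- colMeans(X[sites == s, , drop = FALSE])
  alpha <- as.numeric(as.numeric(ns / n) %*% site_mean)
  resid <- X - site_mean[sites, , drop = FALSE]
  # residual-df pooling keeps the plain location-scale adjustment exactly
  # idempotent (pooled scale of adjusted data reproduces itself)
  sigma2 <- colSums(resid^2) / (n - S)
  sigma <- sqrt(pmax(sigma2, .Machine$double.eps))

  Z <- sweep(sweep(X, 2, alpha), 2, sigma, "/")
  gamma_hat <- matrix(0, S, p, dimnames = list(site_levels, NULL))
  delta2_hat <- matrix(1, S, p, dimnames = list(site_levels, NULL))
  for (s in site_levels) {
    zs <- Z[sites == s, , drop = FALSE]
    gamma_hat[s, ] <- colMeans(zs)
    delta2_hat[s, ] <- apply(zs, 2, stats::var)
  }

  gamma_star <- gamma_hat
  delta_star <- sqrt(pmax(delta2_hat, .Machine$double.eps))
  if (eb && p >= 2) {
    for (si in seq_len(S)) {
      s <- site_levels[si]
      g <- gamma_hat[s, ]; d2 <- delta2_hat[s, ]
      gbar <- mean(g); tau2 <- stats::var(g)
      m <- mean(d2); v <- stats::var(d2)
      if (tau2 <= 0 || v <= 0) next
      lambda <- (m^2 + 2 * v) / v          # inverse-gamma moment estimates
      theta <- (m^3 + m * v) / v
      zs <- Z[sites == s, , drop = FALSE]
      nsi <- nrow(zs)
      g_new <- g; d2_new <- d2
      for (it in seq_len(100L)) {
        g_old <- g_new; d2_old <- d2_new
        g_new <- (nsi * tau2 * g + d2_new * gbar) / (nsi * tau2 + d2_new)
        sse <- colSums((zs - matrix(g_new, nsi, p, byrow = TRUE))^2)
        d2_new <- (theta + 0.5 * sse) / (nsi / 2 + lambda - 1)
        if (max(abs(g_new - g_old), abs(d2_new - d2_old)) < 1e-8) break
      }
      gamma_star[s, ] <- g_new
      delta_star[s, ] <- sqrt(pmax(d2_new, .Machine$double.eps))
    }
  }
  structure(list(alpha = alpha, sigma = sigma, gamma_star = gamma_star,
                 delta_star = delta_star, sites = site_levels,
                 n_per_site = ns, eb = eb),
            class = "harmonization_model")
}

#' Apply a fitted ComBat model
#'
#' Rows whose site was seen during fitting are location-scale adjusted with
#' that site's (shrunk) parameters; rows from unseen sites (or `NA`) pass
#' through unadjusted, since no parameters exist for them.
#'
#' @param model A [combat_fit()] model.
#' @param features n x p matrix on the same features.
#' @param sites Site label per row.
#' @return The harmonized matrix.
#' @export
combat_apply <- function(model, features, sites) {
  stopifnot(inherits(model, "harmonization_model"))
  X <- as.matrix(features)
  sites <- as.character(sites)
  Z <- sweep(sweep(X, 2, model$alpha), 2, model$sigma, "/")
  out <- X
  for (s in intersect(unique(sites), model$sites)) {
    rows <- which(sites == s)
    zadj <- sweep(sweep(Z[rows, , drop = FALSE], 2, model$gamma_star[s, ]),
                  2, model$delta_star[s, ], "/")
    out[rows, ] <- sweep(sweep(zadj, 2, model$sigma, "*"), 2, model$alpha, "+")
  }
  out
}

#' @export
print.harmonization_model <- function(x, ...) {
  cat(sprintf("<harmonization_model> %d features, %d sites (%s)%s\n",
              length(x$alpha), length(x$sites),
              paste(x$sites, collapse = ", "),
              if (x$eb) ", empirical-Bayes shrinkage" else ""))
  invisible(x)
}

#' Remove local atrophy effects from FCD maps
#'
#' Per voxel, the linear effect of grey-matter concentration on FCD across
#' subjects is estimated and the expected FCD given local GMC is subtracted;
#' the residuals are local-atrophy-controlled FCD maps. Voxels with constant
#' GMC get an intercept-only fit (mean-centering) with a warning.
#'
#' @param fcd_maps,gmc_maps Subject x voxel matrices on the same grid and
#'   subjects.
#' @param fit_rows Rows used to estimate the voxelwise regression (training
#'   rows inside cross-validation; default all).
#' @return List with `residuals` (corrected maps for all rows, using the
#'   fit-row regression), `intercept`, `slope` (per voxel).
#' @export
gmc_residualize <- function(fcd_maps, gmc_maps, fit_rows = seq_len(nrow(fcd_maps))) {
  F1 <- as.matrix(fcd_maps); G <- as.matrix(gmc_maps)
  if (!all(dim(F1) == dim(G))) stop("FCD and GMC matrices must match")
  Gf <- G[fit_rows, , drop = FALSE]; Ff <- F1[fit_rows, , drop = FALSE]
  gm <- colMeans(Gf); fm <- colMeans(Ff)
  gv <- colSums(sweep(Gf, 2, gm)^2)
  const <- gv <= .Machine$double.eps * nrow(Gf)
  if (any(const))
    warning(sprintf("%d voxel(s) with constant GMC: intercept-only fit", sum(const)))
  slope <- ifelse(const, 0,
                  colSums(sweep(Gf, 2, gm) * sweep(Ff, 2, fm)) / pmax(gv, .Machine$double.eps))
  intercept <- fm - slope * gm
  fitted <- sweep(G * matrix(slope, nrow(G), ncol(G), byrow = TRUE), 2,
                  intercept, "+")
  list(residuals = F1 - fitted, intercept = intercept, slope = slope)
}

#' Apply previously fitted voxelwise atrophy residualization
#'
#' @param fcd_maps,gmc_maps Matrices for new rows.
#' @param fit A [gmc_residualize()] result (its `intercept` and `slope`).
#' @return Residualized FCD matrix.
#' @export
apply_gmc_residualization <- function(fcd_maps, gmc_maps, fit) {
  F1 <- as.matrix(fcd_maps); G <- as.matrix(gmc_maps)
  fitted <- sweep(G * matrix(fit$slope, nrow(G), ncol(G), byrow = TRUE), 2,
                  fit$intercept, "+")
  F1 - fitted
}

#' Remove motion associations learned from controls
#'
#' Per feature, the linear weight of mean framewise displacement is estimated
#' on healthy controls only and the slope term
#' `weight * (fd - mean control fd)` is subtracted from every row, so control
#' means are preserved and no group information is used.
#'
#' @param features n x p matrix.
#' @param fd_mean Mean framewise displacement per row (mm).
#' @param control_rows Indices of the control rows used for the fit (>= 3,
#'   with positive fd variance).
#' @return List with `X` (detrended features), `weights` (per feature),
#'   `fd_ref` (mean control fd).
#' @export
motion_detrend <- function(features, fd_mean, control_rows) {
  X <- as.matrix(features)
  if (length(control_rows) < 3) stop("need >= 3 controls to learn motion weights")
  fdc <- fd_mean[control_rows]
  if (stats::var(fdc) <= 0) stop("zero framewise-displacement variance in controls")
  fdc_c <- fdc - mean(fdc)
  w <- as.numeric(crossprod(fdc_c, X[control_rows, , drop = FALSE])) / sum(fdc_c^2)
  list(X = X - (fd_mean - mean(fdc)) %o% w, weights = w, fd_ref = mean(fdc))
}

#' Apply previously learned motion detrending
#'
#' @param features Matrix for new rows.
#' @param fd_mean Mean framewise displacement per new row.
#' @param fit A [motion_detrend()] result.
#' @return Detrended feature matrix.
#' @export
apply_motion_detrend <- function(features, fd_mean, fit) {
  as.matrix(features) - (fd_mean - fit$fd_ref) %o% fit$weights
}

#' LOSO classifier on grey-matter-concentration maps
#'
#' The identical leave-one-site-out machinery applied to GMC features,
#' producing a report with the same schema as the FCD models -- the
#' negative-control comparison for local atrophy.
#'
#' @inheritParams loso_stratify
#' @param gmc_maps Subject x voxel GMC matrix.
#' @return A `loso_strat` fit.
#' @export
gmc_only_classifier <- function(gmc_maps, labels, sites, decline_values = NULL,
                                ...) {
  loso_stratify(gmc_maps, labels, sites, decline_values = decline_values, ...)
}
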