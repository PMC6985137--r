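test_that("ComBat removes a pure additive site offset", {
  fx <- two_site_offset_fixture()
  # EB default: offset essentially gone (residual ~ shrunk sampling noise)
  hm <- combat_fit(fx$X, fx$sites)
  Xh <- combat_apply(hm, fx$X, fx$sites)
  mA <- colMeans(Xh[fx$sites == "A", ]); mB <- colMeans(Xh[fx$sites == "B", ])
  expect_lt(max(abs(mA - mB)) / 2, 0.15)
  # plain location-scale adjustment: per-site means exactly equal
  h0 <- combat_fit(fx$X, fx$sites, eb = FALSE)
  X0 <- combat_apply(h0, fx$X, fx$sites)
  m0 <- colMeans(X0[fx$sites == "A", ]) - colMeans(X0[fx$sites == "B", ])
  expect_lt(max(abs(m0)), 1e-10)
  # harmonization also equalizes scales approximately
  vA <- apply(Xh[fx$sites == "A", ], 2, var)
  vB <- apply(Xh[fx$sites == "B", ], 2, var)
  expect_lt(median(abs(vA - vB) / (vA + vB)), 0.15)
})

test_that("ComBat is the identity for a single site and near-identity under permuted labels", {
  set.seed(42)
  X <- matrix(rnorm(600), 30, 20)
  hm <- combat_fit(X, rep("only", 30))
  expect_equal(combat_apply(hm, X, rep("only", 30)), X, tolerance = 1e-10)
  # permuted site labels: estimated site effects shrink toward zero and the
  # adjustment is close to the identity
  fx <- two_site_offset_fixture(offset = 0, seed = 43)
  hm0 <- combat_fit(fx$X, sample(fx$sites))
  expect_lt(max(abs(hm0$gamma_star)), 0.25)
  Xh0 <- combat_apply(hm0, fx$X, fx$sites)
  expect_lt(mean(abs(Xh0 - fx$X)), 0.1)
})

test_that("the plain location-scale adjustment is exactly idempotent; EB nearly so", {
  fx <- two_site_offset_fixture(seed = 44)
  # eb = FALSE: per-site means/variances equalized exactly, so a second fit
  # finds nothing to remove
  h1 <- combat_fit(fx$X, fx$sites, eb = FALSE)
  X1 <- combat_apply(h1, fx$X, fx$sites)
  h2 <- combat_fit(X1, fx$sites, eb = FALSE)
  X2 <- combat_apply(h2, X1, fx$sites)
  expect_lt(max(abs(X2 - X1)), 1e-8)
  # empirical-Bayes shrinkage leaves a small residual site effect by design;
  # a second pass moves values only slightly
  e1 <- combat_fit(fx$X, fx$sites)
  Y1 <- combat_apply(e1, fx$X, fx$sites)
  e2 <- combat_fit(Y1, fx$sites)
  Y2 <- combat_apply(e2, Y1, fx$sites)
  expect_lt(max(abs(Y2 - Y1)), 0.05 * diff(range(Y1)))
})

test_that("ComBat agrees with the sva reference implementation", {
  skip_if_not_installed("sva")
  fx <- two_site_offset_fixture(n_per_site = 40, p = 25, seed = 45)
  hm <- combat_fit(fx$X, fx$sites)
  ours <- combat_apply(hm, fx$X, fx$sites)
  theirs <- t(suppressMessages(
    sva::ComBat(dat = t(fx$X), batch = fx$sites, mod = NULL,
                par.prior = TRUE, prior.plots = FALSE)))
  # identical model up to the pooled-scale denominator convention: sva pools
  # by 1/n, this package by 1/(n - n_sites); the EB-standardized adjustment is
  # scale-invariant, so outputs agree exactly after rescaling around the
  # grand mean
  n <- nrow(fx$X); S <- length(unique(fx$sites))
  ratio <- sqrt(n / (n - S))
  ours_sva_scale <- sweep(sweep(unname(ours), 2, hm$alpha) / ratio, 2,
                          hm$alpha, "+")
  expect_equal(ours_sva_scale, unname(theirs), tolerance = 1e-4)
})

test_that("ComBat contracts: small sites rejected, unseen sites pass through", {
  X <- matrix(rnorm(100), 10, 10)
  expect_error(combat_fit(X, c(rep("A", 9), "B")), "single-subject")
  fx <- two_site_offset_fixture(n_per_site = 20, p = 10, seed = 46)
  hm <- combat_fit(fx$X, fx$sites)
  Xnew <- matrix(rnorm(50), 5, 10)
  expect_equal(combat_apply(hm, Xnew, rep("C", 5)), Xnew)
  # corrections commute with voxel reordering
  perm <- sample(ncol(fx$X))
  hmp <- combat_fit(fx$X[, perm], fx$sites)
  expect_equal(combat_apply(hmp, fx$X[, perm], fx$sites),
               combat_apply(hm, fx$X, fx$sites)[, perm], tolerance = 1e-10)
})

test_that("GMC residualization removes planted atrophy coupling", {
  set.seed(47)
  n <- 80; p <- 20
  G <- matrix(runif(n * p, 0.2, 0.9), n, p)
  F1 <- 2 * G + matrix(rnorm(n * p, 0, 0.3), n, p)
  fit <- gmc_residualize(F1, G)
  for (j in sample(p, 5))
    expect_lt(abs(cor(fit$residuals[, j], G[, j])), 1e-10)
  expect_equal(unname(fit$slope), rep(2, p), tolerance = 0.15)
  # GMC independent of FCD: residuals are approximately mean-centered FCD
  F0 <- matrix(rnorm(n * p), n, p)
  fit0 <- gmc_residualize(F0, G)
  expect_equal(fit0$residuals, scale(F0, scale = FALSE),
               ignore_attr = TRUE, tolerance = 0.5)
  # adding a constant to all GMC values leaves residuals unchanged
  fitc <- gmc_residualize(F1, G + 5)
  expect_equal(fitc$residuals, fit$residuals, tolerance = 1e-10)
  # constant GMC voxel: intercept-only fit with warning
  G2 <- G; G2[, 1] <- 0.5
  expect_warning(fit2 <- gmc_residualize(F1, G2), "constant GMC")
  expect_equal(fit2$residuals[, 1], F1[, 1] - mean(F1[, 1]))
  # held-out application uses stored coefficients only
  newF <- 2 * G[1:10, ] + rnorm(10 * p, 0, 0.3)
  res_new <- apply_gmc_residualization(newF, G[1:10, ], fit)
  expect_lt(max(abs(colMeans(res_new))), 0.5)
})

test_that("motion detrending removes planted motion weight while preserving control means", {
  set.seed(48)
  n <- 90; p <- 15
  fd <- runif(n, 0.05, 0.5)
  X <- matrix(rnorm(n * p, 0, 0.1), n, p) + 3 * fd %o% rep(1, p)  # planted +3*fd
  ctrl <- 1:45
  md <- motion_detrend(X, fd, ctrl)
  expect_equal(unname(md$weights), rep(3, p), tolerance = 0.05)
  for (j in sample(p, 5))
    expect_lt(abs(cor(md$X[ctrl, j], fd[ctrl])), 0.05)
  # control means preserved (slope-only subtraction)
  expect_equal(colMeans(md$X[ctrl, ]), colMeans(X[ctrl, ]), tolerance = 1e-10)
  # identical fd everywhere: features unchanged up to a constant
  Xs <- matrix(rnorm(30), 10, 3)
  expect_error(motion_detrend(Xs, rep(0.2, 10), 1:5), "variance")
  md2 <- motion_detrend(Xs, c(0.1, 0.2, 0.3, 0.1, 0.2, rep(0.2, 5)), 1:5)
  expect_equal(dim(md2$X), dim(Xs))
  expect_error(motion_detrend(Xs, runif(10), 1:2), "3 controls")
})

test_that("a decline signal uncorrelated with motion survives detrending", {
  fx_seed <- 49
  set.seed(fx_seed)
  n <- 96
  sites <- rep(paste0("s", 1:4), each = 24)
  decline <- rnorm(n)
  fd <- runif(n, 0.05, 0.4)                  # independent of decline
  X <- matrix(rnorm(n * 30), n, 30)
  X[, 1:5] <- X[, 1:5] - 2 * decline
  X <- X + 3 * fd %o% c(rep(0, 10), rep(1, 20))
  labels <- as.character(discretize_decline(decline)$label)
  ref_fd <- runif(40, 0.05, 0.4)
  ref <- list(X = matrix(rnorm(40 * 30), 40, 30) +
                3 * ref_fd %o% c(rep(0, 10), rep(1, 20)),
              fd_mean = ref_fd,
              sites = rep(paste0("s", 1:4), each = 10))
  covars <- data.frame(age = runif(n, 20, 60), sex = rep(c("F", "M"), 48),
                       group = rep("preHD", n), fd_mean = fd,
                       cag = rep(42, n))
  plain <- suppressWarnings(loso_stratify(X, labels, sites,
    decline_values = decline, n_boot = 10, n_perm = 10, seed = 2))
  detr <- suppressWarnings(loso_stratify(X, labels, sites,
    decline_values = decline, covariates = covars, detrend_motion = TRUE,
    motion_ref = ref, n_boot = 10, n_perm = 10, seed = 2))
  expect_lt(abs(plain$report$mean_auc - detr$report$mean_auc), 0.05)
})

test_that("GMC-only classifier reuses the LOSO machinery and detects planted group effects", {
  cfg0 <- small_config(seed = 51, atrophy_effect_scale = 0)
  coh <- generate_cohort(cfg0)
  g0 <- generate_gmc(coh, cfg0)$gmc
  fit0 <- suppressWarnings(gmc_only_classifier(g0, coh$group, coh$site,
                                               n_boot = 20, n_perm = 20,
                                               seed = 1))
  expect_lt(abs(fit0$report$mean_auc - 0.5), 0.2)
  cfg2 <- small_config(seed = 51, atrophy_effect_scale = 4)
  g2 <- generate_gmc(coh, cfg2)$gmc
  fit2 <- suppressWarnings(gmc_only_classifier(g2, coh$group, coh$site,
                                               n_boot = 20, n_perm = 20,
                                               seed = 1))
  expect_gt(fit2$report$mean_auc, fit0$report$mean_auc)
  expect_gt(fit2$report$mean_auc, 0.5)
  # identical report schema to FCD models
  expect_setequal(names(fit2$report), names(fit0$report))
})
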