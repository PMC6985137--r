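test_that("robust SD matches the IQR-matched normal definition", {
  expect_equal(robust_sd(1:8), 3.5 / (2 * qnorm(0.75)))
  expect_equal(robust_sd(1:8), 3.5 / 1.34898, tolerance = 1e-5)
  set.seed(1)
  expect_equal(robust_sd(rnorm(2e5)), 1, tolerance = 0.02)
  expect_warning(rs <- robust_sd(rep(3, 10)), "zero IQR")
  expect_equal(rs, 0)
  expect_error(robust_sd(1:3), "at least 4")
})

test_that("discretization labels extremes and sends boundary ties to intermediate", {
  # explicit construction with known median and robust SD
  v <- 1:9                       # median 5, IQR 4, rsd = 4/1.349 = 2.965
  rsd <- robust_sd(v)
  dl <- discretize_decline(v)
  expect_equal(as.character(dl$label),
               ifelse(v < 5 - rsd / 2, "fast",
                      ifelse(v > 5 + rsd / 2, "slow", "intermediate")))
  # boundary ties go to intermediate: with a zero IQR the robust SD is 0 and
  # both cutpoints coincide with the median, so values equal to the median
  # sit exactly on the boundary and must be intermediate
  vals <- c(1, 2, 2, 2, 2, 2, 3)
  expect_warning(dl3 <- discretize_decline(vals), "zero IQR")
  expect_equal(as.character(dl3$label),
               c("fast", rep("intermediate", 5), "slow"))

  # large Gaussian sample: fractions follow the normal CDF at +/- rsd/2
  set.seed(2)
  g <- rnorm(2e5)
  fr <- table(discretize_decline(g)$label) / 2e5
  expect_equal(unname(fr[["fast"]]), pnorm(-0.5), tolerance = 0.01)
  expect_equal(unname(fr[["slow"]]), pnorm(-0.5), tolerance = 0.01)
  expect_true(all(fr > 0.25 & fr < 0.42))

  # well-separated bimodal population recovers planted membership
  set.seed(3)
  planted <- rep(c("fast", "slow"), each = 40)
  vb <- c(rnorm(40, -10, 0.5), rnorm(40, 10, 0.5))
  dlb <- discretize_decline(vb)
  expect_equal(as.character(dlb$label), planted)
})

test_that("elastic-net logistic behaves across the penalty path", {
  set.seed(4)
  # linearly separable two-feature toy set
  X <- rbind(matrix(rnorm(40, -3), 20, 2), matrix(rnorm(40, 3), 20, 2))
  y <- rep(0:1, each = 20)
  m <- fit_elasticnet_logistic(X, y, seed = 1)
  expect_equal(auc_rank(predict(m, X), y), 1)

  # huge penalty shrinks all weights to zero
  m0 <- fit_elasticnet_logistic(X, y, lambda_grid = c(1e6, 5e5), seed = 1)
  expect_true(all(m0$weights == 0))
  expect_equal(length(unique(predict(m0, X))), 1)

  # lasso with one informative feature among 50: sparse and on target
  set.seed(5)
  X2 <- matrix(rnorm(120 * 51), 120, 51)
  y2 <- as.integer(X2[, 7] + 0.3 * rnorm(120) > 0)
  m2 <- fit_elasticnet_logistic(X2, y2, alpha_grid = 1,
                                lambda_grid = c(0.2, 0.15, 0.1), seed = 2)
  expect_lte(sum(m2$weights != 0), 5)
  expect_true(m2$weights[7] != 0)
  expect_error(fit_elasticnet_logistic(X, rep(1, 40)), "single-class")
})

test_that("rank AUC equals brute-force concordant-pair counting", {
  # hand-worked 6-subject site
  sc <- c(0.9, 0.8, 0.7, 0.6, 0.75, 0.1)
  lb <- c(1, 1, 1, 0, 0, 0)
  expect_equal(auc_rank(sc, lb), 8 / 9)
  set.seed(6)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    s <- sample(round(rnorm(n), 1))        # include ties
    l <- rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2) next
    expect_equal(auc_rank(s, l), auc_bruteforce(s, l))
  }
})

test_that("rank AUC cross-checks against pROC", {
  skip_if_not_installed("pROC")
  set.seed(7)
  s <- rnorm(60); l <- rbinom(60, 1, 0.5)
  expect_equal(auc_rank(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE))))
})

test_that("site-averaged AUC handles degenerate sites and bootstraps stably", {
  fx <- site_fixture(effect = 50, seed = 8)    # near-perfect separation
  r <- site_avg_auc(fx$scores, fx$labels, fx$sites, n_boot = 50, seed = 1)
  expect_equal(r$mean_auc, 1)
  expect_equal(r$bootstrap_median_auc, 1)
  # label-independent scores: both near 0.5
  fx0 <- site_fixture(n_per_site = 250, effect = 0, seed = 9)
  r0 <- site_avg_auc(fx0$scores, fx0$labels, fx0$sites, n_boot = 50, seed = 1)
  expect_equal(r0$mean_auc, 0.5, tolerance = 0.06)
  # a site lacking one class is excluded with a warning
  lab <- fx$labels; lab[fx$sites == "site1"] <- 1
  expect_warning(r1 <- site_avg_auc(fx$scores, lab, fx$sites, n_boot = 10),
                 "site1")
  expect_equal(length(r1$per_site), 3)
})

test_that("Fisher-z pooling of per-site Spearman follows closed forms", {
  # fixed point: all sites at the same rho pool to that rho
  x <- 1:30
  s1 <- pooled_spearman(c(x, x), c(x, x), rep(c("a", "b"), each = 30))
  expect_equal(s1$rho_pooled, 1, tolerance = 1e-6)
  # symmetry: two sites with opposite correlation pool to zero
  s2 <- pooled_spearman(c(x, x), c(x, rev(x)), rep(c("a", "b"), each = 30))
  expect_equal(s2$rho_pooled, 0, tolerance = 1e-12)
  # closed-form Fisher average of rho = 0.5 and 0.8:
  # tanh((0.5493 + 1.0986) / 2) = 0.677
  expect_equal(tanh((atanh(0.5) + atanh(0.8)) / 2), 0.677, tolerance = 1e-3)
  # sites with < 3 subjects are dropped with a warning
  expect_warning(s3 <- pooled_spearman(c(x, 1, 2), c(x, 2, 1),
                                       c(rep("a", 30), "b", "b")), "b")
  expect_equal(unname(s3$per_site), 1, tolerance = 1e-6)
})

test_that("within-site permutation p-values obey the add-one rule and calibrate", {
  fx <- site_fixture(n_per_site = 15, effect = 3, seed = 10)
  obs <- fcdstrat:::site_avg_auc_stat(fx$scores, fx$labels, fx$sites)
  pr <- permutation_pvalue(obs, function(lab)
    fcdstrat:::site_avg_auc_stat(fx$scores, lab, fx$sites),
    fx$labels, fx$sites, n_perm = 199, seed = 1)
  expect_gte(pr$p, 1 / 200)
  expect_lte(pr$p, 1)
  expect_equal(pr$p, 1 / 200)    # strong effect: never exceeded

  # observed below the null median gives p > 0.5
  pr2 <- permutation_pvalue(0.1, function(lab)
    fcdstrat:::site_avg_auc_stat(fx$scores, lab, fx$sites),
    fx$labels, fx$sites, n_perm = 99, seed = 2)
  expect_gt(pr2$p, 0.5)

  expect_warning(pd <- permutation_pvalue(1, function(lab) 1,
                                          rep(1, 10), rep("a", 10)),
                 "degenerate")
  expect_equal(pd$p, 1)

  # null calibration: p uniform under label exchange (KS on replicates)
  set.seed(11)
  ps <- replicate(120, {
    sc <- rnorm(40); lb <- rbinom(40, 1, 0.5)
    st <- rep(c("a", "b"), each = 20)
    if (min(table(lb, st)) == 0) return(NA_real_)
    obs <- fcdstrat:::site_avg_auc_stat(sc, lb, st)
    permutation_pvalue(obs, function(l)
      fcdstrat:::site_avg_auc_stat(sc, l, st), lb, st,
      n_perm = 99, seed = sample.int(1e6, 1))$p
  })
  ks <- suppressWarnings(ks.test(na.omit(ps), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("feature-level age/sex correction learns only from training controls", {
  set.seed(12)
  n <- 80; p <- 6
  age <- runif(n, 20, 60); sex <- rep(c("F", "M"), 40)
  X <- matrix(rnorm(n * p), n, p)
  X <- X + outer(age, rep(0.05, p))               # planted linear age effect
  ctrl <- 1:40
  cf <- correct_features_age_sex(X, age, sex, ctrl)
  for (j in seq_len(p))
    expect_lt(abs(cor(cf$X[ctrl, j], age[ctrl])), 0.05)
  # zero planted effect: corrected control features are exactly centered
  # (the intercept is part of the fitted prediction)
  X0 <- matrix(rnorm(n * p), n, p)
  cf0 <- correct_features_age_sex(X0, age, sex, ctrl)
  expect_equal(colMeans(cf0$X[ctrl, ]), rep(0, p), tolerance = 1e-8)
  # weights are reusable and independent of non-control rows
  X2 <- X; X2[41:80, ] <- rnorm(40 * p) * 100
  cf2 <- correct_features_age_sex(X2, age, sex, ctrl)
  expect_identical(cf$coefficients, cf2$coefficients)
  expect_error(correct_features_age_sex(X, age, sex, integer(0)), "controls")
})

test_that("genetic augmentation appends one standardized training-scaled column", {
  set.seed(13)
  X <- matrix(rnorm(50), 10, 5)
  cag <- c(40:44, 40:44)
  Xa <- add_genetic_feature(X, cag, training_rows = 1:5)
  expect_equal(ncol(Xa), 6)
  expect_equal(Xa[1:5, 6], scale(cag[1:5])[, 1])
  # constant CAG contributes nothing
  Xc <- add_genetic_feature(X, rep(42, 10))
  expect_true(all(Xc[, 6] == 0))
  expect_error(add_genetic_feature(X, c(cag[-1], NA)), "CAG")
  # planted CAG-linked labels: augmented model beats uninformative features
  set.seed(14)
  n <- 120
  Xn <- matrix(rnorm(n * 20), n, 20)
  cag2 <- round(rnorm(n, 43, 2))
  y <- as.integer(cag2 + rnorm(n, 0, 0.5) > 43)
  m_fcd <- fit_elasticnet_logistic(Xn, y, seed = 1)
  m_aug <- fit_elasticnet_logistic(add_genetic_feature(Xn, cag2), y, seed = 1)
  expect_gt(auc_rank(predict(m_aug, add_genetic_feature(Xn, cag2)), y),
            auc_rank(predict(m_fcd, Xn), y))
})
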