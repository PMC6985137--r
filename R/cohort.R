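#' Disease-burden (CAP) score
#'
#' CAG-age product, normalized so that a score of ~100 corresponds to the
#' expected age of motor-based diagnosis: `CAP = 100 * age * (cag - 35.5) / 627`.
#'
#' @param age Age in years at the first functional image.
#' @param cag CAG repeat length in the HTT gene (integer-valued).
#' @return Numeric vector of CAP scores.
#' @export
#' @examples
#' cap_score(42, 43)
cap_score <- function(age, cag) {
  100 * age * (cag - 35.5) / 627
}

#' Specification of one longitudinal cognitive/motor task
#'
#' Tasks are generated already oriented so that a negative slope indicates
#' decline; `loading_on_latent` must therefore be negative (or zero) and
#' `decline_sign` records the orientation applied.
#'
#' @param name Task name.
#' @param baseline Mean score at the first visit (task units).
#' @param aging_slope_per_year Healthy-aging slope (units/yr), typically small
#'   and negative.
#' @param sex_offset Additive slope offset for females (units/yr).
#' @param loading_on_latent Slope change per unit of the latent decline factor
#'   (units/yr); negative so that decline lowers scores.
#' @param noise_sd SD of per-visit measurement noise (task units).
#' @param visit_count_range Integer range of available visits per subject,
#'   within `[2, 7]`.
#' @param decline_sign Orientation applied to the raw measure (+1 or -1).
#' @return A `task_spec` list.
#' @export
task_spec <- function(name, baseline = 50, aging_slope_per_year = -0.1,
                      sex_offset = 0.05, loading_on_latent = -0.4,
                      noise_sd = 0.35, visit_count_range = c(2L, 7L),
                      decline_sign = 1) {
  stopifnot(length(visit_count_range) == 2,
            visit_count_range[1] >= 2, visit_count_range[2] <= 7,
            visit_count_range[1] <= visit_count_range[2])
  if (loading_on_latent > 0)
    stop("loading_on_latent must be <= 0: tasks are oriented so decline is negative")
  structure(list(name = name, baseline = baseline,
                 aging_slope_per_year = aging_slope_per_year,
                 sex_offset = sex_offset,
                 loading_on_latent = loading_on_latent,
                 noise_sd = noise_sd,
                 visit_count_range = as.integer(visit_count_range),
                 decline_sign = decline_sign),
            class = "task_spec")
}

#' Default battery of 10 cognitive/motor tasks
#'
#' Mirrors a premanifest-HD test battery: symbol-digit substitution and
#' cancelation load most strongly on the shared decline factor, visuospatial
#' tasks least.
#'
#' @return List of 10 [task_spec()] objects.
#' @export
default_tasks <- function() {
  mk <- function(name, loading, aging = -0.10, sexo = 0.05, noise = 0.35)
    task_spec(name, baseline = 50, aging_slope_per_year = aging,
              sex_offset = sexo, loading_on_latent = loading, noise_sd = noise)
  list(
    mk("sdmt",                 -0.55, aging = -0.15),
    mk("cancelation",          -0.45),
    mk("paced_tap",            -0.40),
    mk("stroop",               -0.35, aging = -0.12),
    mk("grip_variability",     -0.25),
    mk("indirect_circle_trace", -0.20),
    mk("count_backwards",      -0.20),
    mk("spot_change",          -0.15),
    mk("mental_rotation",      -0.10, sexo = 0.15),
    mk("map_search",           -0.10)
  )
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the demographic structure of a four-site premanifest-HD
#' imaging study: 79 controls and 74 gene carriers, ages 49 +/- 11 and
#' 42 +/- 10 years, CAG repeats 43 +/- 2, two imaging visits, and 10
#' longitudinal tasks with 2-7 yearly scores each. Imaging geometry is a
#' desk-scale surrogate (1,000 voxels on a 10x10x10 grid, 160 retained frames
#' at TR = 3 s; generators emit 5 extra unsteady leading frames so trimming
#' is exercised).
#'
#' @param n_controls,n_prehd Group sizes.
#' @param n_sites Number of imaging sites.
#' @param seed Integer seed; all generators are pure functions of
#'   (config, seed).
#' @param age_mean,age_sd Named vectors with elements `control`, `prehd`.
#' @param female_prob Named vector of female proportions per group.
#' @param cag_mean,cag_sd CAG distribution for carriers (rounded, clipped to
#'   38-50).
#' @param latent_mean,latent_sd Latent decline factor distribution for
#'   carriers (controls are fixed at 0); dimensionless.
#' @param latent_cap_weight Correlation weight tying the latent factor to the
#'   standardized CAP score (weak by default, matching the weak genetic
#'   association seen in premanifest cohorts).
#' @param n_latent_factors Number of latent decline dimensions (>1 plants
#'   secondary decline components for PC analyses beyond PC 1).
#' @param fd_meanlog,fd_sdlog Log-normal parameters of per-visit mean
#'   framewise displacement (mm); identical across groups.
#' @param site_effect_scale,motion_effect_scale,atrophy_effect_scale,fingerprint_strength,group_effect_strength,decline_hub_strength
#'   Non-negative effect sizes of the planted signal components (see
#'   [generate_bold()]).
#' @param n_voxels,n_frames,tr_seconds BOLD geometry; `n_frames` counts
#'   retained frames after trimming.
#' @param grid_dim 3-D grid dimensions; `prod(grid_dim) >= n_voxels`.
#' @param tasks List of [task_spec()]s.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_controls = 79L, n_prehd = 74L, n_sites = 4L,
                          seed = 1L,
                          age_mean = c(control = 49, prehd = 42),
                          age_sd = c(control = 11, prehd = 10),
                          female_prob = c(control = 30 / 79, prehd = 34 / 74),
                          cag_mean = 43, cag_sd = 2,
                          latent_mean = 1, latent_sd = 0.6,
                          latent_cap_weight = 0.3,
                          n_latent_factors = 1L,
                          fd_meanlog = log(0.12), fd_sdlog = 0.4,
                          site_effect_scale = 0.6,
                          motion_effect_scale = 5,
                          atrophy_effect_scale = 0.5,
                          fingerprint_strength = 1.3,
                          group_effect_strength = 2,
                          decline_hub_strength = 1.5,
                          n_voxels = 1000L, n_frames = 160L, tr_seconds = 3,
                          grid_dim = c(10L, 10L, 10L),
                          tasks = default_tasks()) {
  cfg <- list(n_controls = as.integer(n_controls), n_prehd = as.integer(n_prehd),
              n_sites = as.integer(n_sites), seed = as.integer(seed),
              age_mean = age_mean, age_sd = age_sd, female_prob = female_prob,
              cag_mean = cag_mean, cag_sd = cag_sd,
              latent_mean = latent_mean, latent_sd = latent_sd,
              latent_cap_weight = latent_cap_weight,
              n_latent_factors = as.integer(n_latent_factors),
              fd_meanlog = fd_meanlog, fd_sdlog = fd_sdlog,
              site_effect_scale = site_effect_scale,
              motion_effect_scale = motion_effect_scale,
              atrophy_effect_scale = atrophy_effect_scale,
              fingerprint_strength = fingerprint_strength,
              group_effect_strength = group_effect_strength,
              decline_hub_strength = decline_hub_strength,
              n_voxels = as.integer(n_voxels), n_frames = as.integer(n_frames),
              tr_seconds = tr_seconds, grid_dim = as.integer(grid_dim),
              tasks = tasks)
  counts <- c(cfg$n_controls, cfg$n_prehd, cfg$n_sites, cfg$n_voxels,
              cfg$n_frames, cfg$n_latent_factors)
  if (any(counts <= 0)) stop("configuration error: all counts must be positive")
  scales <- c(site_effect_scale, motion_effect_scale, atrophy_effect_scale,
              fingerprint_strength, group_effect_strength, decline_hub_strength)
  if (any(scales < 0)) stop("configuration error: effect scales must be non-negative")
  if (any(age_sd <= 0) || cag_sd < 0 || latent_sd < 0)
    stop("configuration error: invalid distribution parameters")
  if (prod(cfg$grid_dim) < cfg$n_voxels)
    stop("configuration error: grid_dim too small for n_voxels")
  class(cfg) <- "cohort_config"
  cfg
}

# deterministic sub-seed for a named generation stream
.stream_seed <- function(seed, stream, index = 0L) {
  offs <- c(cohort = 101L, tasks = 211L, bold_struct = 307L,
            bold_series = 401L, gmc = 503L)
  (as.integer(seed) %% 1000000L) * 1000L + offs[[stream]] + as.integer(index)
}

#' Generate a synthetic multi-site cohort
#'
#' Draws demographics (site, group, sex, age, CAG), computes CAP by
#' `100 * age * (cag - 35.5) / 627`, and assigns each carrier a hidden latent
#' decline factor that downstream analysis stages never see (it is ground
#' truth for validation only). Mean framewise displacement is drawn per visit
#' from the same distribution in both groups.
#'
#' @param config A [cohort_config()].
#' @return A data frame with one row per subject: `subject_id`, `site`,
#'   `group`, `sex`, `age`, `cag`, `cap`, `latent_decline` (and
#'   `latent_decline_2`, ... if `n_latent_factors > 1`), `fd_mean_v1`,
#'   `fd_mean_v2`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(.stream_seed(config$seed, "cohort"))
  n <- config$n_controls + config$n_prehd
  group <- rep(c("control", "preHD"), c(config$n_controls, config$n_prehd))
  g <- ifelse(group == "control", "control", "prehd")
  site <- paste0("site", 1L + (seq_len(n) - 1L) %% config$n_sites)
  sex <- ifelse(stats::runif(n) < config$female_prob[g], "F", "M")
  age <- pmin(65, pmax(18, stats::rnorm(n, config$age_mean[g], config$age_sd[g])))
  cag <- rep(NA_integer_, n)
  pre <- group == "preHD"
  cag[pre] <- as.integer(pmin(50, pmax(38, round(
    stats::rnorm(sum(pre), config$cag_mean, config$cag_sd)))))
  cap <- rep(NA_real_, n)
  cap[pre] <- cap_score(age[pre], cag[pre])

  latent <- matrix(0, n, config$n_latent_factors)
  w <- config$latent_cap_weight
  capz <- if (sum(pre) > 1 && stats::sd(cap[pre]) > 0)
    as.numeric(scale(cap[pre])) else rep(0, sum(pre))
  for (k in seq_len(config$n_latent_factors)) {
    z <- sqrt(max(0, 1 - w^2)) * stats::rnorm(sum(pre)) +
      (if (k == 1) w * capz else 0)
    latent[pre, k] <- config$latent_mean + config$latent_sd * z
  }
  fd1 <- stats::rlnorm(n, config$fd_meanlog, config$fd_sdlog)
  fd2 <- stats::rlnorm(n, config$fd_meanlog, config$fd_sdlog)

  out <- data.frame(
    subject_id = sprintf("sub%03d", seq_len(n)),
    site = site, group = group, sex = sex, age = age,
    cag = cag, cap = cap,
    latent_decline = latent[, 1],
    fd_mean_v1 = fd1, fd_mean_v2 = fd2,
    stringsAsFactors = FALSE)
  if (config$n_latent_factors > 1)
    for (k in 2:config$n_latent_factors)
      out[[paste0("latent_decline_", k)]] <- latent[, k]
  out
}

#' Generate longitudinal task scores
#'
#' Per subject, task and visit:
#' `score = baseline + (aging + sex_offset * female + loading * latent) * t + noise`,
#' with visit count drawn uniformly from the task's `visit_count_range` and
#' yearly visit times. Controls have latent decline 0, so their expected slope
#' is the healthy aging + sex slope.
#'
#' @param cohort Output of [generate_cohort()].
#' @param config The [cohort_config()] used to build `cohort`.
#' @param seed Optional integer seed; defaults to `config$seed`.
#' @return Long-format data frame (`task_panel`): `subject_id`, `task`,
#'   `visit`, `time_years`, `visit_date`, `score`.
#' @export
generate_task_scores <- function(cohort, config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(.stream_seed(seed, "tasks"))
  n <- nrow(cohort)
  rows <- vector("list", n * length(config$tasks))
  r <- 0L
  origin <- as.Date("2009-06-01")
  for (i in seq_len(n)) {
    fem <- cohort$sex[i] == "F"
    lat <- cohort$latent_decline[i]
    for (ts in config$tasks) {
      k <- sample(ts$visit_count_range[1]:ts$visit_count_range[2], 1L)
      t_yr <- 0:(k - 1L)
      slope <- ts$aging_slope_per_year + ts$sex_offset * fem +
        ts$loading_on_latent * lat
      sc <- ts$baseline + slope * t_yr + stats::rnorm(k, 0, ts$noise_sd)
      r <- r + 1L
      rows[[r]] <- data.frame(subject_id = cohort$subject_id[i],
                              task = ts$name, visit = seq_len(k),
                              time_years = t_yr,
                              visit_date = origin + round(t_yr * 365.25),
                              score = sc, stringsAsFactors = FALSE)
    }
  }
  panel <- do.call(rbind, rows[seq_len(r)])
  rownames(panel) <- NULL
  structure(panel, class = c("task_panel", "data.frame"))
}

# population-level signal architecture shared by all subjects and visits
.bold_structure <- function(cohort, config, seed) {
  set.seed(.stream_seed(seed, "bold_struct"))
  V <- config$n_voxels
  # voxel budget: background networks give every map a stable degree median;
  # planted sets are disjoint from the networks so extra loadings never dilute
  # the background links
  n_hub <- max(4L, round(0.06 * V))
  n_grp <- max(4L, round(0.04 * V))
  n_fp  <- max(4L, round(0.12 * V))
  n_mot <- max(2L, round(0.05 * V))
  n_net <- V - n_hub - n_grp - n_fp - n_mot - max(0L, round(0.03 * V))
  perm <- sample.int(V)
  hub <- perm[seq_len(n_hub)]
  grp <- perm[n_hub + seq_len(n_grp)]
  fp  <- perm[n_hub + n_grp + seq_len(n_fp)]
  mot <- perm[n_hub + n_grp + n_fp + seq_len(n_mot)]
  net <- perm[n_hub + n_grp + n_fp + n_mot + seq_len(n_net)]
  free <- perm[seq.int(n_hub + n_grp + n_fp + n_mot + n_net + 1L, V)]
  n_networks <- max(2L, min(20L, n_net %/% 10L))
  net_id <- rep_len(seq_len(n_networks), n_net)

  n <- nrow(cohort)
  fingerprints <- matrix(stats::rnorm(n * n_fp, 0, config$fingerprint_strength),
                         n, n_fp)
  site_load <- matrix(stats::rnorm(config$n_sites * V, 0,
                                   config$site_effect_scale),
                      config$n_sites, V)
  list(hub = hub, hub_w = stats::runif(n_hub, 0.6, 1.2),
       grp = grp, grp_w = stats::runif(n_grp, 0.8, 1.2),
       fp = fp, fingerprints = fingerprints,
       mot = mot, mot_w = stats::runif(n_mot, 0.5, 1.5),
       site_load = site_load,
       net = net, net_id = net_id, n_networks = n_networks,
       drift_amp = stats::rnorm(V, 0, 0.3),
       # CSF/head-edge surrogate voxels live outside all planted neural sets,
       # so the tCompCor noise mask never captures planted structure
       physio = sort(sample(free, min(length(free),
                                      max(1L, round(0.025 * V))))))
}

.bold_one <- function(cohort, config, structure, i, visit, seed) {
  set.seed(.stream_seed(seed, "bold_series", i * 7L + visit))
  V <- config$n_voxels
  Tn <- config$n_frames + 5L   # 5 leading unsteady frames, to be discarded
  st <- structure
  lat <- cohort$latent_decline[i]
  fd <- if (visit == 1) cohort$fd_mean_v1[i] else cohort$fd_mean_v2[i]
  site_idx <- as.integer(sub("site", "", cohort$site[i]))

  X <- matrix(stats::rnorm(V * Tn), V, Tn)
  net_lat <- matrix(stats::rnorm(st$n_networks * Tn), st$n_networks, Tn)
  X[st$net, ] <- X[st$net, ] + 2 * net_lat[st$net_id, , drop = FALSE]
  hub_lat <- stats::rnorm(Tn)
  X[st$hub, ] <- X[st$hub, ] +
    (config$decline_hub_strength * lat * st$hub_w) %o% hub_lat
  if (cohort$group[i] == "preHD") {
    grp_lat <- stats::rnorm(Tn)
    X[st$grp, ] <- X[st$grp, ] +
      (config$group_effect_strength * st$grp_w) %o% grp_lat
  }
  fp_lat <- stats::rnorm(Tn)
  X[st$fp, ] <- X[st$fp, ] + st$fingerprints[i, ] %o% fp_lat
  site_lat <- stats::rnorm(Tn)
  X <- X + st$site_load[site_idx, ] %o% site_lat
  mot_lat <- stats::rnorm(Tn)
  X[st$mot, ] <- X[st$mot, ] +
    (config$motion_effect_scale * fd * st$mot_w) %o% mot_lat
  # artifacts removed by preprocessing: slow drift, a shared physiological
  # component confined to a small high-variance voxel set, and an unsteady
  # leading transient
  tt <- seq_len(Tn) / Tn
  X <- X + st$drift_amp %o% (tt - mean(tt)) * 2
  # physio voxels emulate CSF/head-edge signal: by far the highest-variance
  # voxel set, so tCompCor's variance ranking isolates them and not the
  # planted neural structure
  physio_lat <- stats::rnorm(Tn)
  X[st$physio, ] <- X[st$physio, ] + 12 * rep(1, length(st$physio)) %o% physio_lat
  X[, 1:5] <- X[, 1:5] + 4 * exp(-(0:4))[col(X[, 1:5, drop = FALSE])]
  X
}

#' Generate synthetic BOLD series
#'
#' Each voxel's series is a linear mixture of shared network latents,
#' subject-stable fingerprint loadings, a decline-linked hub latent whose
#' loading breadth grows with the hidden latent decline factor (raising
#' thresholded degree in the hub voxel set), a group-linked latent for
#' carriers, a per-site loading pattern, a motion-locked artifact scaled by
#' mean framewise displacement, white noise, and nuisance components (drift,
#' a physiological component on a small high-variance voxel set, and 5
#' unsteady leading frames) that the preprocessing chain removes.
#'
#' @param cohort Output of [generate_cohort()].
#' @param config The matching [cohort_config()].
#' @param seed Optional seed; defaults to `config$seed`.
#' @param subjects Integer indices of subjects to generate (default all).
#' @param visits Visits to generate (subset of 1:2).
#' @return List with `series` (named list of [bold_series()] objects, one per
#'   subject-visit, keyed `"<subject_id>_v<visit>"`) and `ground_truth`
#'   (planted voxel sets and fingerprint loadings).
#' @export
generate_bold <- function(cohort, config, seed = config$seed,
                          subjects = seq_len(nrow(cohort)), visits = 1:2) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_voxels < 10L || config$n_frames < 20L)
    stop("configuration error: n_voxels or n_frames too small")
  st <- .bold_structure(cohort, config, seed)
  mask <- .grid_mask(config)
  out <- list()
  for (i in subjects) for (v in visits) {
    key <- sprintf("%s_v%d", cohort$subject_id[i], v)
    out[[key]] <- bold_series(.bold_one(cohort, config, st, i, v, seed),
                              tr = config$tr_seconds, mask = mask,
                              subject_id = cohort$subject_id[i], visit = v)
  }
  list(series = out,
       ground_truth = list(hub_voxels = sort(st$hub),
                           group_voxels = sort(st$grp),
                           fingerprint_voxels = sort(st$fp),
                           motion_voxels = sort(st$mot),
                           physio_voxels = st$physio,
                           fingerprints = st$fingerprints,
                           network_voxels = st$net, network_id = st$net_id))
}

# voxel -> grid coordinate table for the configured geometry
.grid_mask <- function(config) {
  g <- config$grid_dim
  idx <- arrayInd(seq_len(config$n_voxels), g)
  data.frame(voxel = seq_len(config$n_voxels),
             x = idx[, 1], y = idx[, 2], z = idx[, 3])
}

#' Generate grey-matter-concentration maps
#'
#' One map per subject, values in `[0, 1]`: a shared smooth spatial profile,
#' subject noise, and (when `atrophy_effect_scale > 0`) a reduction on a
#' designated atrophy voxel set proportional to the latent decline factor.
#'
#' @inheritParams generate_bold
#' @return List with `gmc` (subject x voxel matrix, rows named by subject id)
#'   and `atrophy_voxels` (planted ground truth).
#' @export
generate_gmc <- function(cohort, config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(.stream_seed(seed, "gmc"))
  V <- config$n_voxels
  n <- nrow(cohort)
  base <- 0.55 + 0.15 * sin(seq_len(V) / V * 4 * pi)
  atrophy <- sort(sample(V, max(2L, round(0.1 * V))))
  aw <- stats::runif(length(atrophy), 0.5, 1.5)
  gmc <- matrix(stats::rnorm(n * V, 0, 0.05), n, V, byrow = FALSE)
  gmc <- sweep(gmc, 2, base, "+")
  gmc[, atrophy] <- gmc[, atrophy] -
    config$atrophy_effect_scale * 0.1 * cohort$latent_decline %o% aw
  gmc[gmc < 0] <- 0
  gmc[gmc > 1] <- 1
  rownames(gmc) <- cohort$subject_id
  list(gmc = gmc, atrophy_voxels = atrophy)
}
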