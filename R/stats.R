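#' Mann-Whitney U test
#'
#' Rank-sum test with tie correction. For pooled sample sizes above 20 a
#' normal approximation with continuity correction is used; otherwise the
#' exact null distribution of U is built by enumerating every assignment of
#' the pooled (possibly tied) values to the two groups. U is reported as
#' `min(U_x, U_y)` and the two-sided p doubles the smaller tail, capped at 1.
#'
#' @param x,y Numeric samples (non-empty).
#' @param exact_limit Pooled size at or below which enumeration is used
#'   (default 20).
#' @return List with `U`, `U_x`, `U_y`, `p`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 20L) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) stop("both samples must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  Ux <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  Uy <- nx * ny - Ux
  U <- min(Ux, Uy)
  n <- nx + ny
  if (n <= exact_limit) {
    combs <- utils::combn(n, nx)
    ux_null <- apply(combs, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
    p <- min(1, 2 * min(mean(ux_null <= Ux), mean(ux_null >= Ux)))
    method <- "exact enumeration"
  } else {
    ties <- table(pooled)
    mu <- nx * ny / 2
    sig2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) return(list(U = U, U_x = Ux, U_y = Uy, p = 1,
                               method = "degenerate"))
    z <- (U - mu + 0.5) / sqrt(sig2)    # continuity-corrected lower tail
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal approximation"
  }
  list(U = U, U_x = Ux, U_y = Uy, p = p, method = method)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted q-values (monotone-enforced) and the rejection mask at
#' level `q`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @param q FDR level (default 0.05).
#' @return List with `q_values`, `reject` (logical mask), `q`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  qv <- stats::p.adjust(p_values, method = "BH")
  list(q_values = qv, reject = !is.na(qv) & qv < q, q = q)
}

#' Spearman correlation with t-based significance
#'
#' Pearson correlation of the (average-tie) ranks, converted to
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` and a two-sided p-value from the
#' t distribution with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors, `n >= 3`.
#' @return List with `rho`, `t`, `p`, `n`; `rho` is `NA` for constant input.
#' @export
spearman_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("spearman_rho needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, t = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1)
    return(list(rho = rho, t = sign(rho) * Inf, p = 0, n = n))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, t = tt, p = 2 * stats::pt(-abs(tt), n - 2), n = n)
}

#' Voxelwise statistical map with FDR control
#'
#' Per voxel, either a two-sided Mann-Whitney U test between two groups
#' (`kind = "group_diff"`) or a Spearman correlation with a continuous target
#' (`kind = "spearman"`), Benjamini-Hochberg correction across in-mask
#' voxels, and a signed `-log10(q)` map for export (sign of the effect
#' direction). Univariate maps should be computed on smoothed inputs.
#'
#' @param maps Subject x voxel matrix.
#' @param target Group factor (two levels) or continuous vector, per subject.
#' @param kind `"group_diff"` or `"spearman"`.
#' @param q FDR level (default 0.05).
#' @param mask Logical voxel inclusion vector (default all).
#' @return A `voxel_stat_map`: data frame with per-voxel `stat` (U or rho),
#'   `t` (for spearman), `effect` (direction), `p`, `q_value`, `significant`,
#'   `signed_logq`; attribute `kind`.
#' @export
voxelwise_map <- function(maps, target, kind = c("group_diff", "spearman"),
                          q = 0.05, mask = NULL) {
  kind <- match.arg(kind)
  X <- as.matrix(maps)
  if (is.null(mask)) mask <- rep(TRUE, ncol(X))
  if (!any(mask)) stop("empty voxel mask")
  voxels <- which(mask)
  stat <- tvec <- eff <- pv <- rep(NA_real_, ncol(X))
  if (kind == "group_diff") {
    g <- factor(target)
    if (nlevels(g) != 2) stop("group_diff needs exactly two groups")
    i1 <- which(g == levels(g)[1]); i2 <- which(g == levels(g)[2])
    for (v in voxels) {
      mw <- mann_whitney_u(X[i1, v], X[i2, v])
      stat[v] <- mw$U
      eff[v] <- mean(X[i2, v]) - mean(X[i1, v])
      pv[v] <- mw$p
    }
  } else {
    for (v in voxels) {
      sp <- spearman_rho(X[, v], target)
      stat[v] <- sp$rho; tvec[v] <- sp$t
      eff[v] <- sp$rho
      pv[v] <- sp$p
    }
  }
  adj <- bh_fdr(pv[voxels], q = q)
  qv <- rep(NA_real_, ncol(X)); qv[voxels] <- adj$q_values
  sig <- rep(FALSE, ncol(X)); sig[voxels] <- adj$reject
  slq <- sign(eff) * -log10(pmax(qv, .Machine$double.xmin))
  out <- data.frame(voxel = seq_len(ncol(X)), stat = stat, t = tvec,
                    effect = eff, p = pv, q_value = qv, significant = sig,
                    signed_logq = slq)
  attr(out, "kind") <- kind
  attr(out, "q") <- q
  class(out) <- c("voxel_stat_map", "data.frame")
  out
}
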