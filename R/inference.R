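#' TFCE parameters
#'
#' @param E cluster-extent exponent (> 0).
#' @param H cluster-height exponent (> 0).
#' @param n_steps number of threshold steps between 0 and the map maximum
#'   (>= 10).
#' @param connectivity neighbourhood definition: 6, 18 or 26.
#' @return list of class `tfce_params`.
#' @export
tfce_params <- function(E = 0.5, H = 2, n_steps = 100, connectivity = 26) {
  if (E <= 0 || H <= 0) stop("E and H must be > 0")
  if (n_steps < 10) stop("n_steps must be >= 10")
  if (!connectivity %in% c(6, 18, 26)) stop("connectivity must be 6, 18 or 26")
  structure(list(E = E, H = H, n_steps = as.integer(n_steps),
                 connectivity = as.integer(connectivity)),
            class = "tfce_params")
}

#' Permutation-inference configuration
#'
#' @param n_perm number of permutations (>= 100); if it reaches the number
#'   of distinct group-label arrangements, the null is enumerated
#'   exhaustively instead (with a warning).
#' @param alpha family-wise error level for the significance mask.
#' @param bonferroni_m number of ROI tests in the Bonferroni family.
#' @param seed integer seed for the permutation draw.
#' @return list of class `stats_config`.
#' @export
stats_config <- function(n_perm = 5000, alpha = 0.05, bonferroni_m = 6,
                         seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(n_perm = as.integer(n_perm), alpha = alpha,
                 bonferroni_m = as.integer(bonferroni_m),
                 seed = as.integer(seed)),
            class = "stats_config")
}

#' Mean parameter estimates within ROIs
#'
#' Extracts, per subject, the arithmetic mean of the target component's
#' stage-2 dual-regression map within each atlas ROI.
#'
#' @param subject_maps list of `subject_maps` from [run_dual_regression()].
#' @param atlas named list of logical 3D ROI masks.
#' @param mask logical 3D analysis mask the stage-2 map rows refer to.
#' @param target index of the target component in the template.
#' @return subjects-by-ROIs numeric matrix with ROI names as columns.
#' @export
roi_mean_pe <- function(subject_maps, atlas, mask, target = 1L) {
  sel <- lapply(atlas, function(r) {
    idx <- which(r[mask])
    if (length(idx) == 0)
      stop("ROI has no voxels inside the analysis mask")
    idx
  })
  out <- t(vapply(subject_maps, function(sm) {
    m <- sm$stage2_maps[, target]
    vapply(sel, function(idx) mean(m[idx]), numeric(1))
  }, numeric(length(atlas))))
  colnames(out) <- names(atlas)
  out
}

#' Pooled-variance two-sample t-test
#'
#' Classical Student t (group A minus group B) with pooled variance and a
#' two-sided p-value on `n1 + n2 - 2` degrees of freedom.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @return list with `t`, `p`, `df`.
#' @export
t_two_sample <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 values")
  res <- t_from_summary(n1, mean(a), stats::sd(a), n2, mean(b), stats::sd(b))
  df <- n1 + n2 - 2
  list(t = res, p = 2 * stats::pt(-abs(res), df), df = df)
}

#' Pooled-variance t statistic from group summaries
#'
#' Computes `t = (mean1 - mean2) / sqrt(sp^2 (1/n1 + 1/n2))` with the
#' pooled variance `sp^2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2)`,
#' as used when re-deriving a published t-value from printed
#' `mean ± SD` cells. Set `welch = TRUE` for the unequal-variance
#' (Welch) statistic instead.
#'
#' @param n1,n2 group sizes (>= 2).
#' @param mean1,mean2 group means.
#' @param sd1,sd2 group standard deviations (not both zero).
#' @param welch use the Welch denominator `sqrt(sd1^2/n1 + sd2^2/n2)`.
#' @return scalar t statistic.
#' @export
t_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2, welch = FALSE) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0")
  if (sd1 == 0 && sd2 == 0) stop("zero variance in both groups")
  if (welch) return((mean1 - mean2) / sqrt(sd1^2 / n1 + sd2^2 / n2))
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Bonferroni significance flags
#'
#' Flags `p < alpha / m` for a family of `m` tests across structures.
#'
#' @param pvals numeric p-values.
#' @param m family size (defaults to 6, the bilateral caudate / pallidum /
#'   putamen family).
#' @param alpha nominal level.
#' @return logical vector of significance flags.
#' @export
bonferroni_flags <- function(pvals, m = 6, alpha = 0.05) {
  if (m < 1) stop("m must be >= 1")
  pvals < alpha / m
}

#' Threshold-free cluster enhancement of a statistic map
#'
#' Integrates `e(h)^E * h^H` over `n_steps` equal threshold steps from 0 to
#' the map maximum, where `e(h)` is the size of the connected
#' supra-threshold cluster containing each voxel. Only positive values are
#' enhanced; run the negated map through for the opposite contrast.
#'
#' @param stat_map 3D numeric array (use 0 outside the analysis mask).
#' @param params a [tfce_params()].
#' @return 3D array of TFCE scores.
#' @export
tfce <- function(stat_map, params = tfce_params()) {
  stopifnot(inherits(params, "tfce_params"))
  if (!all(is.finite(stat_map))) stop("statistic map must be finite")
  d <- dim(stat_map)
  if (length(d) != 3) stop("stat_map must be a 3D array")
  out <- .tfce_cpp(as.numeric(stat_map), as.integer(d), params$E, params$H,
                   params$n_steps, params$connectivity)
  array(out, d)
}

# orthonormal nuisance basis and residualizer for the Freedman-Lane scheme
# Y: n x V; returns Y residualized against [1, age, voxelwise gm]
.make_rz <- function(n, age, Q3) {
  q1 <- rep(1 / sqrt(n), n)
  q2 <- NULL
  if (!is.null(age)) {
    a <- age - mean(age)
    if (sum(a^2) > 0) q2 <- a / sqrt(sum(a^2))
  }
  function(Y) {
    Y <- Y - tcrossprod(q1, crossprod(Y, q1))
    if (!is.null(q2)) Y <- Y - tcrossprod(q2, crossprod(Y, q2))
    if (!is.null(Q3)) Y <- Y - Q3 * rep(colSums(Q3 * Y), each = nrow(Y))
    Y
  }
}

#' Voxel-wise group GLM with Freedman-Lane permutation and TFCE correction
#'
#' Tests a one-sided group contrast on subject-level maps, covarying for
#' age (global) and grey matter (voxel-wise), with family-wise error
#' control from the permutation distribution of the maximum TFCE score.
#' Nuisance effects are handled with the Freedman-Lane scheme: maps and the
#' group regressor are residualized against the nuisance design, the
#' residual rows are permuted, and the full model is refitted. The FWE
#' p-value is `(1 + #{null max >= observed}) / (n_perm + 1)`; if `n_perm`
#' reaches the number of distinct group-label arrangements the null is
#' enumerated exhaustively (with a warning) and `p = #{>=} / N`.
#'
#' @param Y subjects-by-voxels matrix of target-component maps, columns in
#'   the voxel order of `mask`.
#' @param group character/factor with two levels; the contrast `"A_gt_B"`
#'   tests first level > second level.
#' @param age optional numeric covariate.
#' @param gm optional voxels-by-subjects (or subjects-by-voxels) matrix of
#'   grey-matter values, same voxel order as `Y`.
#' @param mask logical 3D array giving the voxel order of `Y` columns.
#' @param analysis_mask optional logical 3D array restricting inference
#'   (e.g. from [gm_analysis_mask()]); defaults to `mask`.
#' @param contrast `"A_gt_B"` or `"B_gt_A"`.
#' @param params a [tfce_params()].
#' @param config a [stats_config()].
#' @return list of class `stat_result`: `tmap`, `tfce_map`, `fwe_pmap`
#'   (3D arrays; 0/1 outside the analysis mask as appropriate), `sig_mask`
#'   (logical 3D), `contrast`, `n_perm`, `exhaustive`, `max_null`
#'   (the null max-TFCE sample).
#' @export
permutation_glm <- function(Y, group, age = NULL, gm = NULL, mask,
                            analysis_mask = NULL,
                            contrast = c("A_gt_B", "B_gt_A"),
                            params = tfce_params(),
                            config = stats_config()) {
  contrast <- match.arg(contrast)
  stopifnot(inherits(config, "stats_config"))
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  n <- nrow(Y)
  if (length(group) != n) stop("group length must match rows of Y")
  if (is.null(analysis_mask)) analysis_mask <- mask
  if (!any(analysis_mask)) stop("analysis mask is empty")
  keep <- analysis_mask[mask]           # voxels of Y inside analysis mask
  Ya <- Y[, keep, drop = FALSE]
  V <- ncol(Ya)

  g <- as.numeric(group == levels(group)[1])
  if (contrast == "B_gt_A") g <- 1 - g

  Q3 <- NULL
  if (!is.null(gm)) {
    G <- as.matrix(gm)
    if (nrow(G) != n) G <- t(G)
    if (nrow(G) != n || ncol(G) != ncol(Y))
      stop("gm must be subjects-by-voxels matching Y")
    G <- G[, keep, drop = FALSE]
    rz0 <- .make_rz(n, age, NULL)
    G <- rz0(G)
    nrm <- sqrt(colSums(G^2))
    ok <- nrm > 1e-10 * max(nrm, 1)
    G[, ok] <- sweep(G[, ok, drop = FALSE], 2, nrm[ok], "/")
    G[, !ok] <- 0
    Q3 <- G
  }
  rz <- .make_rz(n, age, Q3)

  E <- rz(Ya)                            # n x V residualized maps
  Gp <- rz(matrix(g, n, V))              # residualized group regressor
  gnorm2 <- colSums(Gp^2)
  degen <- gnorm2 < 1e-12
  gnorm2[degen] <- 1
  p_cols <- 2L + (!is.null(age)) + (!is.null(Q3))
  df <- n - p_cols
  if (df < 1) stop("design has no residual degrees of freedom")

  t_of <- function(Yp) {
    Ep <- rz(Yp)
    num <- colSums(Gp * Ep)
    rss <- pmax(colSums(Ep^2) - num^2 / gnorm2, 0)
    tt <- num / sqrt(gnorm2) / sqrt(rss / df)
    tt[degen | !is.finite(tt)] <- 0
    tt
  }
  embed <- function(vals) {
    v <- array(0, dim(mask))
    v[analysis_mask] <- vals
    v
  }
  tfce_of <- function(tvals) tfce(embed(tvals), params)

  t_obs <- t_of(E)
  tfce_obs <- tfce_of(t_obs)
  obs_vals <- tfce_obs[analysis_mask]

  # permutation set: distinct group-label arrangements
  nA <- sum(g == 1)
  n_distinct <- choose(n, nA)
  set.seed(config$seed)
  if (config$n_perm >= n_distinct) {
    warning("n_perm (", config$n_perm, ") >= distinct arrangements (",
            n_distinct, "); enumerating exhaustively")
    subsets <- utils::combn(n, nA, simplify = FALSE)
    # representative permutation sends each subset's rows to the A slots
    slotsA <- which(g == 1)
    perms <- lapply(subsets, function(s) {
      p <- integer(n)
      p[slotsA] <- s
      p[setdiff(seq_len(n), slotsA)] <- setdiff(seq_len(n), s)
      p
    })
    exhaustive <- TRUE
  } else {
    perms <- replicate(config$n_perm, sample.int(n), simplify = FALSE)
    exhaustive <- FALSE
  }
  max_null <- vapply(perms, function(p) {
    tt <- t_of(E[p, , drop = FALSE])
    max(tfce_of(tt)[analysis_mask])
  }, numeric(1))

  if (exhaustive) {
    fwe <- vapply(obs_vals, function(v) mean(max_null >= v), numeric(1))
  } else {
    fwe <- vapply(obs_vals, function(v)
      (1 + sum(max_null >= v)) / (length(max_null) + 1), numeric(1))
  }
  sig <- array(FALSE, dim(mask))
  sig[analysis_mask] <- fwe < config$alpha
  structure(list(
    tmap = embed(t_obs), tfce_map = tfce_obs,
    fwe_pmap = { p <- array(1, dim(mask)); p[analysis_mask] <- fwe; p },
    sig_mask = sig, contrast = contrast,
    n_perm = length(perms), exhaustive = exhaustive, max_null = max_null),
    class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat("stat_result (", x$contrast, "): ", sum(x$sig_mask),
      " significant voxels, ", x$n_perm, " permutations",
      if (x$exhaustive) " (exhaustive)", "\n", sep = "")
  invisible(x)
}

#' Average grey-matter analysis mask
#'
#' Voxels whose grey-matter value, averaged across subjects, exceeds a
#' threshold; intersected with the brain mask.
#'
#' @param gm_maps voxels-by-subjects matrix of grey-matter values (rows in
#'   `mask` voxel order).
#' @param mask logical 3D brain mask.
#' @param threshold mean-GM cutoff (default 0.3).
#' @return logical 3D array.
#' @export
gm_analysis_mask <- function(gm_maps, mask, threshold = 0.3) {
  mean_gm <- rowMeans(as.matrix(gm_maps))
  out <- array(FALSE, dim(mask))
  out[mask] <- mean_gm > threshold
  out
}
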