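#' Pearson spatial correlation between two maps
#'
#' @param map1,map2 3D arrays on the same grid, or masked value vectors of
#'   equal length.
#' @param mask logical 3D array selecting the voxels to correlate (required
#'   for array input; at least 3 voxels).
#' @return correlation in `[-1, 1]`.
#' @export
spatial_correlation <- function(map1, map2, mask = NULL) {
  if (!is.null(mask)) {
    if (sum(mask) < 3) stop("mask must contain at least 3 voxels")
    map1 <- map1[mask]; map2 <- map2[mask]
  }
  if (length(map1) != length(map2)) stop("maps differ in length")
  if (stats::sd(map1) == 0 || stats::sd(map2) == 0)
    stop("zero variance in one of the maps")
  stats::cor(map1, map2)
}

#' Dice overlap index of two binary maps
#'
#' `2 |A intersect B| / (|A| + |B|)`. If both masks are empty the index is
#' defined as 0 with a warning.
#'
#' @param mask1,mask2 logical arrays/vectors on the same grid.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(mask1, mask2) {
  if (length(mask1) != length(mask2)) stop("masks differ in length")
  a <- as.logical(mask1); b <- as.logical(mask2)
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    warning("both masks are empty; Dice defined as 0")
    return(0)
  }
  2 * sum(a & b) / denom
}

# classify a template pair into the comparison classes:
#  A = same component subset (network_plus_noise), different cohort
#  B = same cohort, different subset
#  C = all components, different cohort
#  D = different cohort and different subset
#  same = identical cohort and subset
.pair_class <- function(t1, t2) {
  same_cohort <- identical(t1$provenance$cohort, t2$provenance$cohort)
  same_subset <- identical(t1$subset, t2$subset)
  if (same_cohort && same_subset) return("same")
  if (same_cohort) return("B")
  if (!same_subset) return("D")
  if (t1$subset == "network_plus_noise") "A" else "C"
}

#' Run one pipeline variant end to end
#'
#' Cleans every subject, dual-regresses against the variant's template, and
#' runs the voxel-wise permutation GLM on the target-component maps.
#'
#' @param cohort result of [generate_cohort()].
#' @param template a `template`.
#' @param cleaning a [cleaning_config()].
#' @param params a [tfce_params()].
#' @param config a [stats_config()].
#' @param analysis_mask optional logical 3D array; defaults to the
#'   grey-matter mask from the cohort's ground truth.
#' @param contrast passed to [permutation_glm()] (`"A_gt_B"` tests
#'   controls > patients given alphabetical level order).
#' @param use_age,use_gm include the covariates (default `TRUE`).
#' @return the `stat_result`, with the subject maps attached as attribute
#'   `subject_maps`.
#' @export
run_variant <- function(cohort, template, cleaning = cleaning_config(),
                        params = tfce_params(), config = stats_config(),
                        analysis_mask = NULL,
                        contrast = "A_gt_B", use_age = TRUE, use_gm = TRUE) {
  tr <- cohort$truth
  cleaned <- lapply(seq_along(cohort$images), function(i)
    clean_image(cohort$images[[i]], motion = tr$motion_params[[i]],
                comps = subject_components(cohort, i), config = cleaning))
  dr <- run_dual_regression(cleaned, template)
  tgt <- template$target_index %||% 1L
  Y <- t(vapply(dr, function(s) s$stage2_maps[, tgt],
                numeric(nrow(dr[[1]]$stage2_maps))))
  if (is.null(analysis_mask))
    analysis_mask <- gm_analysis_mask(tr$gm_maps, tr$mask)
  res <- permutation_glm(
    Y, group = cohort$cohort$group,
    age = if (use_age) cohort$cohort$age else NULL,
    gm = if (use_gm) t(tr$gm_maps) else NULL,
    mask = tr$mask, analysis_mask = analysis_mask,
    contrast = contrast, params = params, config = config)
  attr(res, "subject_maps") <- dr
  res
}

#' Compare pipeline variants pairwise
#'
#' Runs each named variant (a template plus a cleaning configuration) on
#' the same cohort and tabulates, for every variant pair, the spatial
#' correlation of the t-maps over the analysis mask and the Dice overlap of
#' the significant-cluster masks. Pairs are classified by how their
#' templates differ (classes A-D; see Details). A variant that fails is
#' recorded and its pairs skipped.
#'
#' @details Pair classes: A = templates from different cohorts, both
#'   restricted to the target network plus noise components; B = same
#'   cohort, different component subset; C = different cohorts, both using
#'   all components; D = different cohort and different subset.
#'
#' @param variants named list; each element is a list with elements
#'   `template` and optionally `cleaning` (default [cleaning_config()]).
#' @param cohort result of [generate_cohort()].
#' @param params,config,analysis_mask,contrast passed to [run_variant()].
#' @return list with `pairs` (data.frame: var1, var2, class, r, dice),
#'   `class_summary` (mean r and Dice per class), `results` (named list of
#'   `stat_result`), `failures` (named character of error messages).
#' @export
compare_variants <- function(variants, cohort, params = tfce_params(),
                             config = stats_config(), analysis_mask = NULL,
                             contrast = "A_gt_B") {
  if (is.null(analysis_mask))
    analysis_mask <- gm_analysis_mask(cohort$truth$gm_maps,
                                      cohort$truth$mask)
  results <- list(); failures <- character(0)
  for (nm in names(variants)) {
    v <- variants[[nm]]
    results[[nm]] <- tryCatch(
      run_variant(cohort, v$template,
                  cleaning = v$cleaning %||% cleaning_config(),
                  params = params, config = config,
                  analysis_mask = analysis_mask, contrast = contrast),
      error = function(e) { failures[[nm]] <<- conditionMessage(e); NULL })
  }
  ok <- names(results)[!vapply(results, is.null, logical(1))]
  pairs <- data.frame()
  if (length(ok) >= 2) {
    cmb <- utils::combn(ok, 2)
    pairs <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      a <- cmb[1, j]; b <- cmb[2, j]
      ra <- results[[a]]; rb <- results[[b]]
      empty_pair <- sum(ra$sig_mask) == 0 || sum(rb$sig_mask) == 0
      data.frame(
        var1 = a, var2 = b,
        class = .pair_class(variants[[a]]$template,
                            variants[[b]]$template),
        r = spatial_correlation(ra$tmap, rb$tmap, analysis_mask),
        dice = suppressWarnings(dice(ra$sig_mask, rb$sig_mask)),
        empty = empty_pair, stringsAsFactors = FALSE)
    }))
  }
  cls <- pairs[pairs$class %in% c("A", "B", "C", "D"), , drop = FALSE]
  class_summary <- if (nrow(cls)) {
    agg <- stats::aggregate(cbind(r, dice) ~ class, cls, mean)
    agg[order(agg$class), ]
  } else data.frame()
  list(pairs = pairs, class_summary = class_summary,
       results = results, failures = failures)
}

#' Split-half reproducibility of a pipeline
#'
#' Repeatedly splits the cohort into two disjoint, group-stratified halves,
#' runs the cleaning + dual-regression + permutation pipeline on each half
#' against the same template, and measures between-half reproducibility as
#' the Dice overlap of the significant-cluster masks and the spatial
#' correlation of the t-maps.
#'
#' @param cohort result of [generate_cohort()] (>= 4 subjects per group).
#' @param template a `template`.
#' @param n_splits number of random splits.
#' @param seed integer seed for the splits.
#' @param cleaning,params,config,analysis_mask passed to [run_variant()].
#' @param force_identical_halves degenerate test hook: analyse the same
#'   half twice (reproducibility must then be perfect).
#' @return list with `table` (data.frame: split, dice, r) and `summary`
#'   (mean and SD of each metric).
#' @export
split_half <- function(cohort, template, n_splits = 10, seed = 1,
                       cleaning = cleaning_config(),
                       params = tfce_params(), config = stats_config(),
                       analysis_mask = NULL,
                       force_identical_halves = FALSE) {
  grp <- cohort$cohort$group
  idx_c <- which(grp == "control"); idx_p <- which(grp == "patient")
  if (length(idx_c) < 4 || length(idx_p) < 4)
    stop("each group needs at least 4 subjects to split in half")
  if (is.null(analysis_mask))
    analysis_mask <- gm_analysis_mask(cohort$truth$gm_maps,
                                      cohort$truth$mask)
  set.seed(seed)
  take_subcohort <- function(idx) {
    list(images = cohort$images[idx],
         cohort = cohort$cohort[idx, , drop = FALSE],
         truth = within_truth(cohort$truth, idx))
  }
  within_truth <- function(tr, idx) {
    tr$subject_timecourses <- tr$subject_timecourses[idx]
    tr$subject_amplitudes <- tr$subject_amplitudes[idx, , drop = FALSE]
    tr$motion_params <- tr$motion_params[idx]
    tr$gm_maps <- tr$gm_maps[, idx, drop = FALSE]
    tr$ages <- tr$ages[idx]
    tr
  }
  rows <- lapply(seq_len(n_splits), function(s) {
    h1c <- sample(idx_c, length(idx_c) %/% 2)
    h1p <- sample(idx_p, length(idx_p) %/% 2)
    h1 <- sort(c(h1c, h1p))
    h2 <- if (force_identical_halves) h1
          else sort(c(setdiff(idx_c, h1c), setdiff(idx_p, h1p)))
    r1 <- run_variant(take_subcohort(h1), template, cleaning = cleaning,
                      params = params, config = config,
                      analysis_mask = analysis_mask)
    r2 <- run_variant(take_subcohort(h2), template, cleaning = cleaning,
                      params = params, config = config,
                      analysis_mask = analysis_mask)
    data.frame(split = s,
               dice = suppressWarnings(dice(r1$sig_mask, r2$sig_mask)),
               r = spatial_correlation(r1$tmap, r2$tmap, analysis_mask))
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       summary = data.frame(metric = c("dice", "r"),
                            mean = c(mean(tab$dice), mean(tab$r)),
                            sd = c(stats::sd(tab$dice), stats::sd(tab$r))))
}
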