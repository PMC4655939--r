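#' Simulation configuration for synthetic two-group rfMRI cohorts
#'
#' Defines the conditions under which a synthetic cohort is generated: grid
#' geometry, temporal scale, group sizes, number of spatial networks and
#' structured artefacts, the magnitude of the planted group deficit, and the
#' noise model. Defaults emulate a small clinical resting-state study at
#' desk scale: 180 volumes at TR 2 s (6 minutes of data), two matched groups
#' of 19 subjects, five networks of which the first is the basal-ganglia
#' analogue carrying a bilateral "putamen" amplitude deficit in patients.
#'
#' @param grid_shape integer length-3, voxels per axis (all >= 8).
#' @param n_timepoints number of volumes (>= 30).
#' @param tr repetition time, seconds.
#' @param n_controls,n_patients group sizes.
#' @param n_networks number of signal networks (the first is the target).
#' @param n_artefacts number of structured artefact components.
#' @param effect_size fraction in `[0, 1]`: relative amplitude reduction of
#'   the target network inside the deficit mask for patients.
#' @param noise_sd standard deviation of additive Gaussian voxel noise
#'   (arbitrary units, > 0).
#' @param noise_smooth_fwhm FWHM (mm) of optional spatial smoothing applied
#'   to the noise field; 0 (default) gives white noise.
#' @param motion_coupling fraction in `[0, 1]` of the motion-coupled
#'   artefact's time-course variance driven by the motion traces.
#' @param amp_mean,amp_sd mean and SD of subject component amplitudes.
#' @param baseline mean in-brain signal level added to every voxel series.
#' @param motion_severity_mean,motion_severity_sd distribution of per-subject
#'   mean relative displacement, mm (same for both groups).
#' @param age_mean,age_sd age distribution, years (same for both groups).
#' @param voxel_mm voxel size, mm.
#' @param seed integer seed; the same seed yields a byte-identical cohort.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(grid_shape = c(20, 20, 12), n_timepoints = 180,
                       tr = 2, n_controls = 19, n_patients = 19,
                       n_networks = 5, n_artefacts = 4,
                       effect_size = 0.4, noise_sd = 1,
                       noise_smooth_fwhm = 0, motion_coupling = 0.5,
                       amp_mean = 4, amp_sd = 0.5, baseline = 100,
                       motion_severity_mean = 0.13,
                       motion_severity_sd = 0.05,
                       age_mean = 63, age_sd = 9,
                       voxel_mm = c(3, 3, 3), seed = 1) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 8))
    stop("grid_shape must be 3 integers, all >= 8")
  if (n_timepoints < 30) stop("n_timepoints must be >= 30")
  if (effect_size < 0 || effect_size > 1)
    stop("effect_size must be in [0, 1]")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (motion_coupling < 0 || motion_coupling > 1)
    stop("motion_coupling must be in [0, 1]")
  if (n_controls < 1 || n_patients < 1) stop("need at least 1 subject per group")
  if (n_networks < 1) stop("need at least 1 network")
  structure(as.list(environment()), class = "sim_config")
}

# ---- spatial layout --------------------------------------------------------

# Ellipsoid in-brain mask inscribed in the grid.
.brain_mask <- function(d) {
  g <- .coord_grids(d)
  c0 <- (d + 1) / 2
  r <- d / 2 - 0.5
  ((g$x - c0[1]) / r[1])^2 + ((g$y - c0[2]) / r[2])^2 +
    ((g$z - c0[3]) / r[3])^2 <= 1
}

# Target-network layout: two bilateral clusters of three blobs each
# (caudate / putamen / pallidum analogues); blob cores define the ROI atlas
# and the putamen cores define the deficit mask.
.target_layout <- function(d) {
  xs <- round(d[1] * c(0.3, 0.7))
  ys <- round(d[2] * c(0.25, 0.5, 0.75))
  z <- round(d[3] * 0.5)
  rois <- list()
  centres <- list()
  nm <- c("caudate", "putamen", "pallidum")
  for (side in 1:2) for (k in 1:3) {
    cen <- c(xs[side], ys[k], z)
    centres[[length(centres) + 1L]] <- cen
    rois[[paste0(c("left_", "right_")[side], nm[k])]] <- .ball(d, cen, 1.5)
  }
  map <- Reduce(`+`, lapply(centres, function(cen) .blob(d, cen, 1.4)))
  map <- map / max(map)
  deficit <- rois$left_putamen | rois$right_putamen
  list(map = map, rois = rois, deficit = deficit, centres = centres)
}

# Centres for the remaining networks, away from the target clusters.
.other_network_centres <- function(d, n_other, target_centres) {
  cand <- expand.grid(x = round(d[1] * c(0.22, 0.5, 0.78)),
                      y = round(d[2] * c(0.25, 0.75)),
                      z = round(d[3] * c(0.25, 0.78)))
  sep <- apply(cand, 1, function(p)
    min(vapply(target_centres,
               function(tc) sqrt(sum((p - tc)^2)), numeric(1))))
  cand <- cand[sep >= 2.75, , drop = FALSE]
  sep <- sep[sep >= 2.75]
  if (nrow(cand) < n_other)
    stop("configuration error: grid too small to place ", n_other + 1,
         " non-overlapping networks (only ", nrow(cand),
         " candidate sites)")
  best <- order(sep, decreasing = TRUE)[seq_len(n_other)]
  lapply(best, function(i) as.numeric(cand[i, ]))
}

# Artefact spatial maps: drift gradient, global/patchy spikes, motion-coupled
# brain-edge shell, vessel-like inferior slab; extras are smooth random maps.
.artefact_maps <- function(d, mask, n_artefacts) {
  g <- .coord_grids(d)
  maps <- list(
    # drift loads on one end of the readout axis; the high ramp power keeps
    # the map spatially sparse (super-Gaussian), away from the brain edge
    drift = ((d[1] - g$x) / max(d[1] - 1, 1))^6 *
      array(as.numeric(.erode6(mask)), d),
    # scattered smooth bumps: smoothed noise thresholded at its upper tail
    spike = {
      r <- .gauss_smooth3d(array(stats::rnorm(prod(d)), d), 2)
      pmax(r - stats::quantile(r[mask], 0.92), 0)
    },
    motion = array(as.numeric(mask & !.erode6(mask)), d),
    vessel = {
      slab <- g$z <= ceiling(d[3] * 0.25)
      v <- slab & .erode6(mask)
      if (!any(v)) v <- slab & mask   # erosion can empty the slab on small grids
      array(as.numeric(v), d)
    }
  )
  while (length(maps) < n_artefacts) {
    r <- .gauss_smooth3d(array(stats::rnorm(prod(d)), d), 1.5)
    maps[[paste0("extra", length(maps) - 3L)]] <- (r - min(r)) /
      (max(r) - min(r))
  }
  maps <- maps[seq_len(n_artefacts)]
  lapply(maps, function(m) { m[!mask] <- 0; m / max(m) })
}

# ---- motion ----------------------------------------------------------------

#' Mean relative displacement of a motion trace
#'
#' Mean over time of the Euclidean norm of frame-to-frame differences of the
#' three translation columns, the usual summary of head motion.
#'
#' @param motion T-by-6 matrix (translations in columns 1-3, mm).
#' @return scalar displacement in mm.
#' @export
mean_rel_displacement <- function(motion) {
  stopifnot(ncol(motion) == 6)
  dd <- diff(motion[, 1:3, drop = FALSE])
  mean(sqrt(rowSums(dd^2)))
}

#' Generate rigid-body motion parameter traces
#'
#' Smooth random-walk traces for 3 translations (mm) and 3 rotations
#' (radians); the translation columns are scaled so the mean relative
#' displacement equals `severity`.
#'
#' @param n_timepoints number of volumes (>= 2).
#' @param severity target mean relative displacement, mm (>= 0).
#' @param seed integer seed.
#' @return T-by-6 numeric matrix.
#' @export
make_motion_params <- function(n_timepoints, severity, seed = 1) {
  if (n_timepoints < 2) stop("n_timepoints must be >= 2")
  if (severity < 0) stop("severity must be >= 0")
  set.seed(seed)
  raw <- apply(matrix(stats::rnorm(n_timepoints * 6), ncol = 6), 2,
               function(x) {
                 w <- cumsum(x)
                 as.numeric(stats::filter(w, rep(1 / 5, 5), sides = 2,
                                          circular = TRUE))
               })
  raw <- matrix(as.numeric(scale(raw)), n_timepoints, 6)
  if (severity == 0) return(matrix(0, n_timepoints, 6))
  mrd <- mean_rel_displacement(raw)
  out <- raw
  out[, 1:3] <- raw[, 1:3] * (severity / mrd)
  out[, 4:6] <- raw[, 4:6] * (severity / mrd) / 50  # radians, small angles
  out
}

# ---- component labels ------------------------------------------------------

#' Apply classifier-accuracy label noise to component labels
#'
#' Emulates an automated signal/noise component classifier with a given
#' operating point: each true signal label is kept as signal with
#' probability `tpr`, each true noise label kept as noise with probability
#' `tnr`; otherwise the label is flipped.
#'
#' @param labels character vector of `"signal"` / `"noise"`.
#' @param tpr true-positive ratio in `[0, 1]`.
#' @param tnr true-negative ratio in `[0, 1]`.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return character vector of corrupted labels, same length.
#' @export
corrupt_labels <- function(labels, tpr, tnr, seed = NULL) {
  stopifnot(all(labels %in% c("signal", "noise")))
  if (tpr < 0 || tpr > 1 || tnr < 0 || tnr > 1)
    stop("tpr and tnr must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(length(labels))
  out <- labels
  is_sig <- labels == "signal"
  out[is_sig & u > tpr] <- "noise"
  out[!is_sig & u > tnr] <- "signal"
  out
}

# ---- composition -----------------------------------------------------------

#' Compose a subject image from component maps and time courses
#'
#' Builds `baseline + sum_c amplitude_c * map_c * timecourse_c(t) + noise`.
#' Exposed so the generative model can be exercised algebraically in tests
#' and extended by users.
#'
#' @param maps voxels-by-components matrix of spatial maps (masked values).
#' @param timecourses T-by-components matrix.
#' @param amplitudes length-C numeric.
#' @param mask logical 3D array the map rows refer to.
#' @param tr repetition time, seconds.
#' @param baseline scalar added to every in-mask series.
#' @param noise_sd SD of additive Gaussian noise (0 for noise-free).
#' @param noise_smooth_sigma_vox if > 0, smooth each noise volume with this
#'   Gaussian sigma (voxels) before adding.
#' @param voxel_mm voxel size, mm.
#' @return an `image4d`.
#' @export
compose_image <- function(maps, timecourses, amplitudes, mask, tr = 2,
                          baseline = 0, noise_sd = 0,
                          noise_smooth_sigma_vox = 0,
                          voxel_mm = c(3, 3, 3)) {
  stopifnot(ncol(maps) == ncol(timecourses),
            ncol(maps) == length(amplitudes))
  dat <- maps %*% (t(timecourses) * amplitudes) + baseline
  if (noise_sd > 0) {
    if (noise_smooth_sigma_vox > 0) {
      noise <- vapply(seq_len(nrow(timecourses)), function(t) {
        v <- array(stats::rnorm(prod(dim(mask)), sd = noise_sd), dim(mask))
        .gauss_smooth3d(v, noise_smooth_sigma_vox)[mask]
      }, numeric(sum(mask)))
    } else {
      noise <- matrix(stats::rnorm(length(dat), sd = noise_sd), nrow(dat))
    }
    dat <- dat + noise
  }
  image4d(dat, mask, tr = tr, voxel_mm = voxel_mm)
}

# component time courses for one subject; columns ordered networks then
# artefacts [drift, spike, motion-coupled, vessel, extras...]
.subject_timecourses <- function(cfg, motion) {
  nt <- cfg$n_timepoints
  tcs <- matrix(0, nt, cfg$n_networks + cfg$n_artefacts)
  for (k in seq_len(cfg$n_networks)) tcs[, k] <- .ar1_series(nt)
  art <- list()
  tt <- seq_len(nt) / nt
  art$drift <- .standardize(tt + 0.5 * cos(pi * tt) + 0.1 * stats::rnorm(nt))
  sp <- numeric(nt)
  idx <- sample.int(nt, max(3L, nt %/% 30L))
  sp[idx] <- sample(c(-1, 1), length(idx), replace = TRUE) *
    stats::runif(length(idx), 2, 4)
  art$spike <- .standardize(sp)
  w <- motion %*% stats::rnorm(6)
  w <- if (stats::sd(w) == 0) stats::rnorm(nt) else w
  mc <- cfg$motion_coupling
  art$motion <- .standardize(sqrt(mc) * .standardize(w) +
                               sqrt(1 - mc) * stats::rnorm(nt))
  art$vessel <- .standardize(diff(c(0, stats::rnorm(nt))))
  while (length(art) < cfg$n_artefacts)
    art[[length(art) + 1L]] <- .standardize(stats::rnorm(nt))
  for (k in seq_len(cfg$n_artefacts))
    tcs[, cfg$n_networks + k] <- art[[k]]
  tcs
}

#' Generate a synthetic two-group cohort with full ground truth
#'
#' Builds a cohort of 4D images as mixtures of shared spatial networks and
#' structured artefact components with subject-specific amplitudes and time
#' courses, plus Gaussian noise. Patients have the amplitude of the target
#' network reduced by `effect_size` inside the deficit mask (bilateral
#' "putamen" cores of the target network). Both groups draw ages and motion
#' severity from the same distributions.
#'
#' @param config a [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{images}{list of `image4d`, controls first.}
#'     \item{cohort}{data.frame with `subject_id`, `group`, `age`, `path`.}
#'     \item{truth}{ground-truth list: `mask`, `network_maps` and
#'       `artefact_maps` (masked voxel matrices), `component_labels`,
#'       `target_network` (index 1), `deficit_mask`, `roi_atlas` (6 disjoint
#'       masks), `gm_maps`, `subject_timecourses`, `subject_amplitudes`,
#'       `motion_params`, `ages`, `effect_size`.}
#'   }
#' @export
generate_cohort <- function(config) {
  cfg <- config
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  d <- cfg$grid_shape
  mask <- .brain_mask(d)
  lay <- .target_layout(d)
  nets <- list(lay$map)
  if (cfg$n_networks > 1) {
    cen <- .other_network_centres(d, cfg$n_networks - 1, lay$centres)
    for (p in cen) nets[[length(nets) + 1L]] <- .blob(d, p, 1.8)
  }
  net_mat <- vapply(nets, function(m) { m[!mask] <- 0; m[mask] },
                    numeric(sum(mask)))
  arts <- .artefact_maps(d, mask, cfg$n_artefacts)
  art_mat <- vapply(arts, function(m) m[mask], numeric(sum(mask)))
  C <- cfg$n_networks + cfg$n_artefacts
  labels <- c(rep("signal", cfg$n_networks), rep("noise", cfg$n_artefacts))

  n <- cfg$n_controls + cfg$n_patients
  group <- c(rep("control", cfg$n_controls), rep("patient", cfg$n_patients))
  ages <- stats::rnorm(n, cfg$age_mean, cfg$age_sd)
  sev <- abs(stats::rnorm(n, cfg$motion_severity_mean,
                          cfg$motion_severity_sd))
  noise_sigma_vox <- if (cfg$noise_smooth_fwhm > 0)
    cfg$noise_smooth_fwhm / 2.3548 / cfg$voxel_mm[1] else 0

  # grey-matter base profile: smoothed interior of the mask
  gm_base <- .gauss_smooth3d(array(as.numeric(.erode6(mask)), d), 1.5)
  gm_base <- pmin(1, gm_base / max(gm_base))

  deficit_in_mask <- lay$deficit[mask]
  images <- vector("list", n)
  tcs_all <- vector("list", n)
  amps_all <- matrix(0, n, C)
  motion_all <- vector("list", n)
  gm_all <- matrix(0, sum(mask), n)
  for (i in seq_len(n)) {
    motion_all[[i]] <- make_motion_params(cfg$n_timepoints, sev[i],
                                          seed = sample.int(2^31 - 1, 1))
    tcs <- .subject_timecourses(cfg, motion_all[[i]])
    amps <- pmax(0.5, stats::rnorm(C, cfg$amp_mean, cfg$amp_sd))
    maps_i <- cbind(net_mat, art_mat)
    if (group[i] == "patient")
      maps_i[deficit_in_mask, 1] <-
        maps_i[deficit_in_mask, 1] * (1 - cfg$effect_size)
    images[[i]] <- compose_image(maps_i, tcs, amps, mask, tr = cfg$tr,
                                 baseline = cfg$baseline,
                                 noise_sd = cfg$noise_sd,
                                 noise_smooth_sigma_vox = noise_sigma_vox,
                                 voxel_mm = cfg$voxel_mm)
    gm_vol <- pmin(1, pmax(0, gm_base +
      .gauss_smooth3d(array(stats::rnorm(prod(d), sd = 0.15), d), 1.5)))
    gm_all[, i] <- gm_vol[mask]
    tcs_all[[i]] <- tcs
    amps_all[i, ] <- amps
  }
  cohort <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    group = group, age = ages, path = NA_character_,
    stringsAsFactors = FALSE)
  truth <- list(
    mask = mask, network_maps = net_mat, artefact_maps = art_mat,
    component_labels = labels, target_network = 1L,
    deficit_mask = lay$deficit, roi_atlas = lay$rois,
    gm_maps = gm_all, subject_timecourses = tcs_all,
    subject_amplitudes = amps_all, motion_params = motion_all,
    ages = ages, motion_severity = sev, effect_size = cfg$effect_size)
  list(images = images, cohort = cohort, truth = truth)
}

#' Ground-truth component set for one subject
#'
#' Reconstructs the subject's true mixing model (spatial maps, time courses,
#' labels) as a [component_set()], including the patient-specific deficit
#' scaling of the target network map.
#'
#' @param cohort result of [generate_cohort()].
#' @param i subject index.
#' @return a `component_set`.
#' @export
subject_components <- function(cohort, i) {
  tr <- cohort$truth
  maps <- cbind(tr$network_maps, tr$artefact_maps)
  if (cohort$cohort$group[i] == "patient") {
    dm <- tr$deficit_mask[tr$mask]
    maps[dm, tr$target_network] <-
      maps[dm, tr$target_network] * (1 - tr$effect_size)
  }
  component_set(maps, tr$subject_timecourses[[i]],
                tr$component_labels, mask = tr$mask,
                target_index = tr$target_network)
}

#' Write a synthetic cohort to disk in native formats
#'
#' One 4D NIfTI per subject, motion parameters as 6-column text, the cohort
#' table as TSV, and a ground-truth sidecar directory with the mask, ROI
#' atlas, deficit mask and per-subject grey-matter maps as NIfTI.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt_dir <- file.path(dir, "truth")
  dir.create(gt_dir, showWarnings = FALSE)
  tab <- cohort$cohort
  vx <- cohort$images[[1]]$voxel_mm
  for (i in seq_along(cohort$images)) {
    id <- tab$subject_id[i]
    p <- file.path(dir, paste0(id, "_bold.nii.gz"))
    write_image4d(cohort$images[[i]], p)
    write_motion(cohort$truth$motion_params[[i]],
                 file.path(dir, paste0(id, "_motion.par")))
    write_volume(as_volume(cohort$truth$gm_maps[, i], cohort$truth$mask),
                 file.path(gt_dir, paste0(id, "_gm.nii.gz")), vx)
    tab$path[i] <- p
  }
  utils::write.table(tab, file.path(dir, "cohort.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_volume(cohort$truth$mask, file.path(gt_dir, "mask.nii.gz"), vx)
  write_volume(cohort$truth$deficit_mask,
               file.path(gt_dir, "deficit_mask.nii.gz"), vx)
  for (nm in names(cohort$truth$roi_atlas))
    write_volume(cohort$truth$roi_atlas[[nm]],
                 file.path(gt_dir, paste0("roi_", nm, ".nii.gz")), vx)
  utils::write.table(
    data.frame(component = seq_along(cohort$truth$component_labels),
               label = cohort$truth$component_labels),
    file.path(gt_dir, "component_labels.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
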