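#' Component set: paired spatial maps and time courses
#'
#' Holds the output of a decomposition (or a ground-truth mixing model):
#' spatial maps over a mask, optional time courses, per-component
#' signal/noise labels, and optionally the index of the network of
#' interest.
#'
#' @param maps voxels-by-components matrix of masked spatial map values.
#' @param timecourses optional T-by-components matrix.
#' @param labels optional character vector of `"signal"` / `"noise"`.
#' @param mask logical 3D array the map rows refer to.
#' @param target_index optional index of the network of interest; must be
#'   labelled `"signal"` when labels are present.
#' @return list of class `component_set`.
#' @export
component_set <- function(maps, timecourses = NULL, labels = NULL,
                          mask = NULL, target_index = NULL) {
  maps <- as.matrix(maps)
  if (ncol(maps) < 1) stop("need at least one component")
  if (!is.null(labels)) {
    if (length(labels) != ncol(maps))
      stop("labels length must equal component count")
    if (!all(labels %in% c("signal", "noise")))
      stop("labels must be 'signal' or 'noise'")
  }
  if (!is.null(timecourses) && ncol(timecourses) != ncol(maps))
    stop("timecourses must have one column per component")
  if (!is.null(target_index)) {
    if (target_index < 1 || target_index > ncol(maps))
      stop("target_index out of range")
    if (!is.null(labels) && labels[target_index] != "signal")
      stop("target component must be labelled 'signal'")
  }
  structure(list(maps = maps, timecourses = timecourses, labels = labels,
                 mask = mask, target_index = target_index),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat("component_set: ", ncol(x$maps), " components, ",
      nrow(x$maps), " voxels",
      if (!is.null(x$labels))
        paste0(" (", sum(x$labels == "noise"), " noise)"),
      if (!is.null(x$target_index))
        paste0(", target #", x$target_index), "\n", sep = "")
  invisible(x)
}

#' Temporally concatenate and normalize subject data
#'
#' Demeans (and by default variance-normalizes) each subject's voxel series
#' and concatenates the subjects along time, the input arrangement for
#' group-ICA with temporal concatenation.
#'
#' @param subjects list of `image4d` on identical grids and masks.
#' @param var_norm divide each voxel series by its temporal SD (default
#'   `TRUE`; zero-SD series are left demeaned).
#' @return voxels-by-(sum of T) matrix.
#' @export
concat_normalize <- function(subjects, var_norm = TRUE) {
  stopifnot(length(subjects) >= 1)
  m0 <- subjects[[1]]$mask
  blocks <- lapply(subjects, function(s) {
    if (!identical(dim(s$mask), dim(m0)) || !all(s$mask == m0))
      stop("all subjects must share the same grid and mask")
    y <- s$data - rowMeans(s$data)
    if (var_norm) {
      sd_t <- sqrt(rowSums(y^2) / (ncol(y) - 1))
      sd_t[sd_t == 0] <- 1
      y <- y / sd_t
    }
    y
  })
  do.call(cbind, blocks)
}

#' Group spatial ICA on concatenated data
#'
#' Reduces the concatenated voxels-by-time matrix to `d` dimensions by SVD
#' and estimates `d` spatially independent sources (FastICA, maximizing
#' map non-Gaussianity). Maps are scaled to unit variance and signed so
#' their skewness is non-negative. The decomposition is deterministic for a
#' given seed; on non-convergence the rotation is restarted (up to
#' `restarts` times) from seeded random orthogonal initializations.
#'
#' @param concat voxels-by-time matrix (e.g. from [concat_normalize()]).
#' @param d number of components (2 <= d <= min(dim(concat))).
#' @param seed integer seed.
#' @param mask optional mask carried into the result.
#' @param restarts maximum number of restarts on non-convergence.
#' @param maxit FastICA iteration cap per attempt.
#' @return a `component_set` (maps only; no labels).
#' @export
group_ica <- function(concat, d, seed = 1, mask = NULL, restarts = 5,
                      maxit = 300) {
  if (d < 2) stop("d must be >= 2")
  if (d > min(dim(concat)))
    stop("d = ", d, " exceeds data dimensions ",
         paste(dim(concat), collapse = "x"))
  sv <- svd(concat, nu = d, nv = 0)
  red <- sv$u %*% diag(sv$d[seq_len(d)], d)    # voxels x d
  set.seed(seed)
  res <- NULL
  for (att in seq_len(restarts + 1)) {
    rot <- if (att == 1) diag(d) else qr.Q(qr(matrix(stats::rnorm(d * d), d)))
    fit <- ica::icafast(red, nc = d, maxit = maxit, Rmat = rot)
    if (isTRUE(fit$converged)) { res <- fit; break }
  }
  if (is.null(res))
    stop("group ICA failed to converge after ", restarts + 1,
         " attempts (d = ", d, ", maxit = ", maxit,
         "); last tolerance not reached")
  maps <- apply(res$S, 2, function(s) {
    s <- s / stats::sd(s)
    sk <- mean((s - mean(s))^3)
    if (sk < 0) -s else s
  })
  component_set(maps, mask = mask)
}

#' Find the component best matching a reference map
#'
#' Returns the index of the component whose spatial map has the largest
#' absolute Pearson correlation with `reference` over the in-mask voxels.
#' The matched correlation is attached as attribute `correlation`.
#'
#' @param comps a `component_set`.
#' @param reference masked reference map values (same voxel order as
#'   `comps$maps` rows) or a 3D array on the component grid.
#' @return integer index with attribute `correlation`.
#' @export
match_target <- function(comps, reference) {
  if (is.array(reference) && length(dim(reference)) == 3) {
    if (is.null(comps$mask)) stop("component set has no mask to apply")
    reference <- reference[comps$mask]
  }
  if (length(reference) != nrow(comps$maps))
    stop("reference map length does not match component maps")
  r <- as.numeric(stats::cor(reference, comps$maps))
  best <- order(abs(r), decreasing = TRUE)
  # a tie between near-zero correlations is not ambiguous, just a non-match
  if (ncol(comps$maps) > 1 && abs(r[best[1]]) >= 1e-8 &&
      abs(abs(r[best[1]]) - abs(r[best[2]])) < 1e-12)
    stop("ambiguous match: components ", best[1], " and ", best[2],
         " tie at |r| = ", format(abs(r[best[1]])))
  out <- best[1]
  attr(out, "correlation") <- r[best[1]]
  out
}

#' Assemble a dual-regression template from a component set
#'
#' Either keeps all components in their original order (`subset = "all"`)
#' or keeps the target network first followed by all noise-labelled
#' components (`subset = "network_plus_noise"`).
#'
#' @param comps a `component_set` with labels (and `target_index` for the
#'   subset option).
#' @param subset `"all"` or `"network_plus_noise"`.
#' @param provenance optional list recorded with the template (e.g. cohort
#'   identity); used by [compare_variants()] to classify template pairs.
#' @return list of class `template` with `maps`, `mask`, `target_index`,
#'   `labels`, `subset`, `provenance`.
#' @export
assemble_template <- function(comps, subset = c("all", "network_plus_noise"),
                              provenance = list()) {
  subset <- match.arg(subset)
  if (subset == "network_plus_noise") {
    if (is.null(comps$target_index))
      stop("network_plus_noise requires a target_index")
    if (is.null(comps$labels) || !any(comps$labels == "noise"))
      stop("network_plus_noise requires at least one noise-labelled component")
    keep <- c(comps$target_index, which(comps$labels == "noise"))
    maps <- comps$maps[, keep, drop = FALSE]
    labels <- c("signal", rep("noise", length(keep) - 1L))
    target <- 1L
  } else {
    maps <- comps$maps
    labels <- comps$labels
    target <- comps$target_index
  }
  structure(list(maps = maps, mask = comps$mask, target_index = target,
                 labels = labels, subset = subset, provenance = provenance),
            class = "template")
}

#' @export
print.template <- function(x, ...) {
  cat("template: ", ncol(x$maps), " maps (subset = ", x$subset,
      "), target #", x$target_index, "\n", sep = "")
  invisible(x)
}

#' Build a dual-regression template from a cohort in one call
#'
#' Convenience wrapper: concatenate the given subjects, run [group_ica()],
#' label components by matching against reference signal/noise maps (a
#' component is labelled `"signal"` if its best absolute-correlation match
#' among the references is a signal map), locate the target network with
#' [match_target()], and assemble the requested subset.
#'
#' @param subjects list of `image4d`.
#' @param d group-ICA dimensionality.
#' @param reference_map masked values of the target network's map.
#' @param noise_maps voxels-by-K matrix of reference artefact maps used for
#'   labelling (optional; without it all non-target components are labelled
#'   noise).
#' @param subset template subset, as in [assemble_template()].
#' @param seed ICA seed.
#' @param var_norm passed to [concat_normalize()].
#' @param provenance recorded in the template.
#' @return a `template`.
#' @export
build_template <- function(subjects, d, reference_map, noise_maps = NULL,
                           subset = "network_plus_noise", seed = 1,
                           var_norm = TRUE, provenance = list()) {
  concat <- concat_normalize(subjects, var_norm = var_norm)
  comps <- group_ica(concat, d, seed = seed, mask = subjects[[1]]$mask)
  tgt <- match_target(comps, reference_map)
  # orient the target component with its reference so downstream parameter
  # estimates carry the network's amplitude with a positive sign
  if (attr(tgt, "correlation") < 0)
    comps$maps[, tgt] <- -comps$maps[, tgt]
  if (!is.null(noise_maps)) {
    refs <- cbind(reference_map, noise_maps)
    is_noise_ref <- c(FALSE, rep(TRUE, ncol(as.matrix(noise_maps))))
    r <- abs(stats::cor(comps$maps, refs))
    labels <- ifelse(is_noise_ref[max.col(r)], "noise", "signal")
  } else {
    labels <- rep("noise", ncol(comps$maps))
  }
  labels[tgt] <- "signal"
  comps$labels <- labels
  comps$target_index <- as.integer(tgt)
  assemble_template(comps, subset = subset, provenance = provenance)
}

#' Write a template as 4D NIfTI plus a TSV manifest
#' @param tmpl a `template`.
#' @param dir output directory.
#' @param voxel_mm voxel size, mm.
#' @return `dir`, invisibly.
#' @export
write_template <- function(tmpl, dir, voxel_mm = c(3, 3, 3)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arr <- as_volume(tmpl$maps, tmpl$mask)
  nim <- RNifti::asNifti(arr)
  RNifti::pixdim(nim) <- c(voxel_mm, 1)
  RNifti::writeNifti(nim, file.path(dir, "template.nii.gz"))
  write_volume(tmpl$mask, file.path(dir, "mask.nii.gz"), voxel_mm)
  man <- data.frame(
    index = seq_len(ncol(tmpl$maps)),
    label = if (is.null(tmpl$labels)) NA else tmpl$labels,
    role = ifelse(seq_len(ncol(tmpl$maps)) ==
                    (tmpl$target_index %||% 0L), "target", "other"),
    subset = tmpl$subset)
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a template written by [write_template()]
#' @param dir template directory.
#' @return a `template`.
#' @export
read_template <- function(dir) {
  man <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  mask <- array(read_volume(file.path(dir, "mask.nii.gz")) != 0,
                dim(read_volume(file.path(dir, "mask.nii.gz"))))
  nim <- RNifti::readNifti(file.path(dir, "template.nii.gz"))
  arr <- array(as.numeric(nim), dim(nim))
  if (dim(arr)[4] != nrow(man))
    stop("manifest lists ", nrow(man), " components but template has ",
         dim(arr)[4], " volumes")
  maps <- matrix(arr[rep(mask, dim(arr)[4])], nrow = sum(mask))
  target <- which(man$role == "target")
  structure(list(maps = maps, mask = mask,
                 target_index = if (length(target)) target[1] else NULL,
                 labels = if (all(is.na(man$label))) NULL else man$label,
                 subset = man$subset[1], provenance = list(dir = dir)),
            class = "template")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
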