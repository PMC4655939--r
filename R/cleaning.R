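#' Cleaning configuration
#'
#' Bundles the preprocessing and nuisance-regression choices for
#' [clean_image()]: the cleaning mode, the spatial smoothing kernel, the
#' high-pass cutoff, and how component signal/noise labels are obtained in
#' the ICA-based modes.
#'
#' @param mode one of `"uncleaned"`, `"motion24"`, `"ica_soft"`,
#'   `"ica_aggressive"`.
#' @param fwhm_mm Gaussian smoothing kernel FWHM in mm (>= 0; 0 disables).
#' @param highpass_cutoff_s high-pass cutoff in seconds: fluctuations with
#'   period longer than this are removed. Must exceed twice the TR.
#' @param label_source `"truth"` to use the component set's own labels,
#'   `"corrupted"` to pass them through [corrupt_labels()] at the
#'   (`tpr`, `tnr`) operating point, or a character vector of labels.
#' @param tpr,tnr operating point used when `label_source = "corrupted"`.
#'   Defaults are a study-specific component classifier's leave-one-out
#'   accuracy (98.2% TPR, 65.8% TNR).
#' @param label_seed seed for the label corruption draw.
#' @return list of class `cleaning_config`.
#' @export
cleaning_config <- function(mode = c("uncleaned", "motion24", "ica_soft",
                                     "ica_aggressive"),
                            fwhm_mm = 6, highpass_cutoff_s = 150,
                            label_source = "truth",
                            tpr = 0.982, tnr = 0.658, label_seed = 1) {
  mode <- match.arg(mode)
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (highpass_cutoff_s <= 0) stop("highpass_cutoff_s must be > 0")
  structure(list(mode = mode, fwhm_mm = fwhm_mm,
                 highpass_cutoff_s = highpass_cutoff_s,
                 label_source = label_source, tpr = tpr, tnr = tnr,
                 label_seed = label_seed),
            class = "cleaning_config")
}

#' Expand 6 rigid-body motion parameters to the 24-regressor set
#'
#' Returns the six parameter time series, their backward-looking temporal
#' derivatives (first row zero), and the squares of those twelve regressors,
#' in that column order.
#'
#' @param motion T-by-6 matrix.
#' @return T-by-24 matrix.
#' @export
friston24 <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6)
    stop("motion matrix must have 6 columns, got ", ncol(motion))
  if (nrow(motion) < 2) stop("need at least 2 timepoints")
  deriv <- rbind(0, diff(motion))
  twelve <- cbind(motion, deriv)
  unname(cbind(twelve, twelve^2))
}

# low-frequency drift basis: sine/cosine pairs at k cycles per acquisition,
# k = 1..floor(window / cutoff), i.e. all pairs with period >= cutoff
.drift_basis <- function(n_timepoints, tr, cutoff_s) {
  K <- floor(n_timepoints * tr / cutoff_s)
  if (K < 1) return(NULL)
  ang <- 2 * pi * outer(seq_len(n_timepoints) - 0.5, seq_len(K)) /
    n_timepoints
  cbind(cos(ang), sin(ang))
}

#' High-pass filter an image by low-frequency projection
#'
#' Removes, per voxel, the temporal mean and the sine/cosine components
#' with period of `cutoff_s` or longer. Frequencies above `1/cutoff_s`
#' pass essentially unattenuated (gain >= 0.99 on resolved probe
#' sinusoids).
#'
#' @param img an `image4d`.
#' @param cutoff_s cutoff period in seconds (> 2 * TR).
#' @return filtered `image4d` (zero temporal mean).
#' @export
highpass <- function(img, cutoff_s) {
  if (cutoff_s <= 2 * img$tr)
    stop("cutoff_s must exceed twice the TR (", 2 * img$tr, " s)")
  y <- img$data - rowMeans(img$data)
  basis <- .drift_basis(ncol(y), img$tr, cutoff_s)
  if (!is.null(basis)) {
    q <- qr.Q(qr(scale(basis, scale = FALSE)))
    y <- y - (y %*% q) %*% t(q)
  }
  out <- img; out$data <- y
  out
}

#' Spatially smooth an image with a Gaussian kernel
#'
#' Volume-wise separable Gaussian convolution with sigma =
#' `fwhm_mm / 2.3548` per axis (in voxel units). Values outside the mask
#' are treated as missing: the smoothed volume is renormalized by the
#' smoothed mask, so a constant image stays constant.
#'
#' @param img an `image4d`.
#' @param fwhm_mm kernel full width at half maximum in mm (0 = identity).
#' @param voxel_mm voxel size override; defaults to the image's.
#' @return smoothed `image4d`.
#' @export
smooth_image <- function(img, fwhm_mm, voxel_mm = NULL) {
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(img)
  vx <- if (is.null(voxel_mm)) img$voxel_mm else rep_len(voxel_mm, 3)
  sigma_vox <- fwhm_mm / 2.3548 / vx
  mask_s <- .gauss_smooth3d(array(as.numeric(img$mask), img$dim), sigma_vox)
  norm <- mask_s[img$mask]
  out <- img
  vol <- array(0, img$dim)
  for (t in seq_len(ncol(img$data))) {
    vol[img$mask] <- img$data[, t]
    s <- .gauss_smooth3d(vol, sigma_vox)
    out$data[, t] <- s[img$mask] / norm
  }
  out
}

# drop constant columns; returns matrix (possibly 0-column)
.drop_constant <- function(x) {
  if (is.null(x) || ncol(x) == 0) return(matrix(0, nrow(x), 0))
  keep <- apply(x, 2, function(v) stats::sd(v) > 0)
  x[, keep, drop = FALSE]
}

#' Regress ICA components (and motion) out of an image
#'
#' Removes artefact-labelled component time courses, optionally together
#' with a 24-column motion design, using either the soft or the aggressive
#' scheme. In the soft scheme each voxel's series is fitted on signal and
#' noise time courses jointly and only the noise part of the fit (the
#' variance uniquely attributable to the artefacts) is subtracted; the
#' aggressive scheme subtracts the full projection onto the noise design.
#' The per-voxel temporal mean is preserved.
#'
#' @param img an `image4d`.
#' @param comps a [component_set()] with time courses and labels.
#' @param motion24 optional T-by-24 matrix appended to the noise design.
#' @param mode `"soft"` or `"aggressive"`.
#' @return cleaned `image4d`.
#' @export
regress_components <- function(img, comps, motion24 = NULL,
                               mode = c("soft", "aggressive")) {
  mode <- match.arg(mode)
  tcs <- comps$timecourses
  if (is.null(tcs)) stop("component set has no time courses")
  if (nrow(tcs) != ncol(img$data))
    stop("component time courses have ", nrow(tcs),
         " rows but image has ", ncol(img$data), " timepoints")
  if (is.null(comps$labels)) stop("component labels are required")
  S <- tcs[, comps$labels == "signal", drop = FALSE]
  N <- tcs[, comps$labels == "noise", drop = FALSE]
  if (!is.null(motion24)) N <- cbind(N, motion24)
  N <- .drop_constant(scale(N, scale = FALSE))
  S <- .drop_constant(scale(S, scale = FALSE))
  mu <- rowMeans(img$data)
  y <- t(img$data - mu)               # T x V, demeaned
  if (ncol(N) == 0) return(img)
  if (mode == "aggressive") {
    fitted <- qr.fitted(qr(N), y)
  } else {
    X <- cbind(S, N)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      bad <- setdiff(seq_len(ncol(X)), qx$pivot[seq_len(qx$rank)])
      stop("rank-deficient joint design; collinear columns: ",
           paste(bad, collapse = ", "),
           " (columns 1-", ncol(S), " are signal, the rest noise/motion)")
    }
    beta <- qr.coef(qx, y)
    idxN <- seq(ncol(S) + 1L, ncol(X))
    fitted <- N %*% beta[idxN, , drop = FALSE]
  }
  out <- img
  out$data <- t(y - fitted) + mu
  out
}

#' Run one of the cleaning pipeline variants
#'
#' Applies spatial smoothing and high-pass filtering, then the nuisance
#' regression prescribed by `config$mode`: nothing further (`uncleaned`),
#' the 24-parameter motion design (`motion24`), or motion plus ICA component
#' regression with soft or aggressive removal (`ica_soft`,
#' `ica_aggressive`). Component signal/noise labels come from
#' `config$label_source`. The per-voxel temporal mean of the smoothed data
#' is preserved so temporal-SNR remains well defined.
#'
#' @param img an `image4d`.
#' @param motion T-by-6 motion matrix (required for all modes but
#'   `uncleaned`).
#' @param comps a [component_set()] (required for the ICA modes).
#' @param config a [cleaning_config()].
#' @return cleaned `image4d`.
#' @export
clean_image <- function(img, motion = NULL, comps = NULL,
                        config = cleaning_config()) {
  stopifnot(inherits(config, "cleaning_config"))
  if (config$highpass_cutoff_s <= 2 * img$tr)
    stop("highpass_cutoff_s must exceed twice the TR")
  out <- smooth_image(img, config$fwhm_mm)
  mu <- rowMeans(out$data)
  out <- highpass(out, config$highpass_cutoff_s)
  if (config$mode != "uncleaned") {
    if (is.null(motion)) stop("mode ", config$mode, " requires motion")
    m24 <- .drop_constant(friston24(motion))
    if (ncol(m24) > 0) {
      m24 <- scale(m24, scale = FALSE)
      q <- qr.Q(qr(m24))[, seq_len(qr(m24)$rank), drop = FALSE]
      y <- t(out$data)
      out$data <- t(y - q %*% crossprod(q, y))
    }
  }
  if (config$mode %in% c("ica_soft", "ica_aggressive")) {
    if (is.null(comps))
      stop("ICA cleaning modes require a component set")
    use <- comps
    if (identical(config$label_source, "corrupted")) {
      use$labels <- corrupt_labels(comps$labels, config$tpr, config$tnr,
                                   seed = config$label_seed)
    } else if (!identical(config$label_source, "truth")) {
      use$labels <- config$label_source
    }
    out <- regress_components(
      out, use, motion24 = NULL,
      mode = if (config$mode == "ica_soft") "soft" else "aggressive")
  }
  out$data <- out$data - rowMeans(out$data) + mu
  out
}

#' Median temporal SNR over an eroded mask
#'
#' Forms the raw tSNR image as the temporal mean divided by the temporal
#' standard deviation per voxel, erodes the mask (6-connectivity) to avoid
#' brain-edge effects, and returns the median tSNR over the eroded mask.
#' Voxels with zero temporal SD are excluded; their count is attached as
#' attribute `n_zero_sd`.
#'
#' @param img an `image4d` with at least 3 timepoints.
#' @param erode number of one-voxel erosion passes (default 1).
#' @return scalar median tSNR with attribute `n_zero_sd`.
#' @export
tsnr_median <- function(img, erode = 1) {
  if (ncol(img$data) < 3) stop("need at least 3 timepoints")
  em <- img$mask
  for (i in seq_len(erode)) em <- .erode6(em)
  if (!any(em)) stop("eroded mask is empty")
  sel <- em[img$mask]
  mu <- rowMeans(img$data[sel, , drop = FALSE])
  sd_t <- apply(img$data[sel, , drop = FALSE], 1, stats::sd)
  zero <- sd_t == 0
  if (all(zero)) stop("all eroded-mask voxels have zero temporal SD")
  out <- stats::median(mu[!zero] / sd_t[!zero])
  attr(out, "n_zero_sd") <- sum(zero)
  out
}
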