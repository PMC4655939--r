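#' Dual regression, stage 1: subject time courses from template maps
#'
#' Regresses each time point's volume on all template maps simultaneously
#' (maps demeaned over the mask, intercept included), yielding one time
#' course per template component.
#'
#' @param img an `image4d` on the template grid.
#' @param template a `template` (or any object with a `maps` matrix whose
#'   rows match the image's in-mask voxels).
#' @return T-by-C matrix of component time courses.
#' @export
dr_stage1 <- function(img, template) {
  maps <- as.matrix(template$maps)
  if (nrow(maps) != nrow(img$data))
    stop("template maps (", nrow(maps), " voxels) do not match image (",
         nrow(img$data), " voxels)")
  X <- scale(maps, scale = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X) || kappa(crossprod(X)) > 1e16)
    stop("template maps are collinear over the mask")
  beta <- qr.coef(qx, sweep(img$data, 2, colMeans(img$data)))
  t(beta)
}

#' Dual regression, stage 2: subject spatial maps from time courses
#'
#' Regresses each voxel's series on all component time courses
#' simultaneously (time courses demeaned, intercept included), returning
#' per-component parameter-estimate (P.E.) maps. With `normalize = TRUE`
#' (the default) time courses are first scaled to unit variance, so the
#' P.E. carries the component's amplitude.
#'
#' @param img an `image4d`.
#' @param timecourses T-by-C matrix (e.g. from [dr_stage1()]).
#' @param normalize scale each time course to unit variance first.
#' @return voxels-by-C matrix of P.E. maps.
#' @export
dr_stage2 <- function(img, timecourses, normalize = TRUE) {
  tcs <- as.matrix(timecourses)
  if (nrow(tcs) != ncol(img$data))
    stop("timecourses have ", nrow(tcs), " rows but image has ",
         ncol(img$data), " timepoints")
  X <- scale(tcs, scale = FALSE)
  if (normalize) {
    sd_c <- apply(X, 2, stats::sd)
    if (any(sd_c == 0)) stop("constant time course cannot be normalized")
    X <- sweep(X, 2, sd_c, "/")
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("collinear time courses")
  beta <- qr.coef(qx, t(img$data - rowMeans(img$data)))
  t(beta)
}

#' Run two-stage dual regression over a cohort
#'
#' Applies [dr_stage1()] then [dr_stage2()] to every subject against a
#' common template.
#'
#' @param cohort list of `image4d` sharing the template grid.
#' @param template a `template`.
#' @param normalize stage-1 time-course variance normalization flag,
#'   passed to [dr_stage2()].
#' @return list of `subject_maps` objects, each with
#'   `stage1_timecourses` (T-by-C), `stage2_maps` (voxels-by-C),
#'   `normalized`, and `template_ref` (the template's provenance).
#' @export
run_dual_regression <- function(cohort, template, normalize = TRUE) {
  lapply(seq_along(cohort), function(i) {
    res <- tryCatch({
      tcs <- dr_stage1(cohort[[i]], template)
      maps <- dr_stage2(cohort[[i]], tcs, normalize = normalize)
      structure(list(stage1_timecourses = tcs, stage2_maps = maps,
                     normalized = normalize,
                     template_ref = template$provenance),
                class = "subject_maps")
    }, error = function(e)
      stop("dual regression failed for subject ", i, ": ",
           conditionMessage(e)))
    res
  })
}
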