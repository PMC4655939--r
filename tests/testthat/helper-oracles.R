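# Independent brute-force oracles and tiny fixtures used across the suite.
# These deliberately avoid the package's own computational paths.

# small default-physics cohort for pipeline tests
tiny_cohort <- function(seed = 3, n_per_group = 8, grid = c(14, 14, 10),
                        nt = 80, ...) {
  generate_cohort(sim_config(grid_shape = grid, n_timepoints = nt,
                             n_controls = n_per_group,
                             n_patients = n_per_group, seed = seed, ...))
}

# ground-truth template (all components) for a generated cohort
truth_template <- function(co, subset = "all", cohort_id = "truth") {
  comps <- component_set(cbind(co$truth$network_maps, co$truth$artefact_maps),
                         labels = co$truth$component_labels,
                         mask = co$truth$mask,
                         target_index = co$truth$target_network)
  assemble_template(comps, subset = subset,
                    provenance = list(cohort = cohort_id))
}

# connected-component labelling by breadth-first search, pure R
label_components_R <- function(supra, connectivity = 26) {
  d <- dim(supra)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  a <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- offs[a > 0 & a <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), ]
  lab <- array(0L, d)
  cur <- 0L
  idx <- which(supra, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p0 <- idx[r, ]
    if (lab[p0[1], p0[2], p0[3]] != 0L) next
    cur <- cur + 1L
    queue <- list(p0)
    lab[p0[1], p0[2], p0[3]] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        q <- p + c(offs$dx[k], offs$dy[k], offs$dz[k])
        if (any(q < 1) || any(q > d)) next
        if (supra[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- cur
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# brute-force TFCE: explicit per-threshold labelling
tfce_R <- function(stat_map, E = 0.5, H = 2, n_steps = 100,
                   connectivity = 26) {
  out <- array(0, dim(stat_map))
  hmax <- max(stat_map)
  if (hmax <= 0) return(out)
  dh <- hmax / n_steps
  for (s in seq_len(n_steps)) {
    h <- if (s == n_steps) hmax else s * dh
    supra <- stat_map >= h
    if (!any(supra)) next
    lab <- label_components_R(supra, connectivity)
    sizes <- tabulate(lab[lab > 0])
    out[supra] <- out[supra] + sizes[lab[supra]]^E * h^H * dh
  }
  out
}

# least-squares via explicit pseudoinverse (normal equations / svd)
pinv_fit <- function(X, Y) {
  sv <- svd(X)
  keep <- sv$d > max(sv$d) * 1e-12
  (sv$v[, keep, drop = FALSE] %*%
      diag(1 / sv$d[keep], sum(keep)) %*%
      t(sv$u[, keep, drop = FALSE])) %*% Y
}
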