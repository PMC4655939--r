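# Internal numeric helpers shared across modules.

# (x - mean) / sd, guarding sd = 0
.standardize <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

# sampled Gaussian kernel, truncated at 4 sigma, unit sum
.gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# separable 3D Gaussian convolution (zero-padded) of a full volume
.gauss_smooth3d <- function(vol, sigma_vox) {
  d <- dim(vol)
  sigma_vox <- rep_len(sigma_vox, 3)
  out <- vol
  for (ax in 1:3) {
    k <- .gauss_kernel(sigma_vox[ax])
    if (length(k) == 1) next
    r <- (length(k) - 1L) / 2L
    # fold the volume so the convolution axis is the first dimension
    perm <- switch(ax, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    a <- aperm(out, perm)
    m <- matrix(a, nrow = dim(a)[1])
    n <- nrow(m)
    acc <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      off <- j - r - 1L
      src <- seq_len(n) + off
      ok <- src >= 1L & src <= n
      acc[ok, ] <- acc[ok, ] + k[j] * m[src[ok], , drop = FALSE]
    }
    a <- array(acc, dim(a))
    out <- aperm(a, order(perm))
  }
  out
}

# erode a logical 3D mask by one voxel, 6-connectivity; grid border counts
# as outside
.erode6 <- function(mask) {
  d <- dim(mask)
  keep <- mask
  shift_ok <- function(ax, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    if (n == 1) return(out)   # no interior along a singleton axis
    if (by == 1) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
    else         { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    out <- do.call(`[<-`, c(list(out), idx_dst,
                            list(do.call(`[`, c(list(mask), idx_src)))))
    out
  }
  for (ax in 1:3) for (by in c(1, -1)) keep <- keep & shift_ok(ax, by)
  keep
}

# stationary AR(1) series, standardized
.ar1_series <- function(n, phi = 0.4) {
  .standardize(as.numeric(stats::filter(stats::rnorm(n), phi,
                                        method = "recursive")))
}

# voxel-centre coordinate grids for a 3D array
.coord_grids <- function(d) {
  list(x = array(rep(seq_len(d[1]), times = d[2] * d[3]), d),
       y = array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d),
       z = array(rep(seq_len(d[3]), each = d[1] * d[2]), d))
}

# isotropic 3D Gaussian blob (peak 1) centred at `centre`, sd `sigma` voxels
.blob <- function(d, centre, sigma) {
  g <- .coord_grids(d)
  r2 <- (g$x - centre[1])^2 + (g$y - centre[2])^2 + (g$z - centre[3])^2
  exp(-r2 / (2 * sigma^2))
}

# voxels within Euclidean distance `radius` of `centre`
.ball <- function(d, centre, radius) {
  g <- .coord_grids(d)
  r2 <- (g$x - centre[1])^2 + (g$y - centre[2])^2 + (g$z - centre[3])^2
  r2 <= radius^2
}
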