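make_img <- function(data, dims = NULL, tr = 2) {
  if (is.null(dims)) dims <- c(nrow(data), 1, 1)
  mask <- array(TRUE, dims)
  image4d(data, mask, tr = tr)
}

test_that("friston24 expands parameters, derivatives and squares", {
  expect_equal(friston24(matrix(0, 5, 6)), matrix(0, 5, 24))
  m <- cbind(c(0, 1, 3), matrix(0, 3, 5))
  f <- friston24(m)
  expect_equal(ncol(f), 24)
  expect_equal(f[, 1], c(0, 1, 3))
  expect_equal(f[, 7], c(0, 1, 2))    # backward difference, first row 0
  expect_equal(f[, 13], c(0, 1, 9))   # squared parameter
  expect_equal(f[, 19], c(0, 1, 4))   # squared derivative
  expect_error(friston24(matrix(0, 5, 5)), "6 columns")
  # random input still yields width 24
  expect_equal(ncol(friston24(matrix(rnorm(60), 10, 6))), 24)
})

test_that("high-pass filter removes slow and keeps fast oscillations", {
  # a 30-minute window resolves both probes with whole numbers of cycles
  tr <- 2; nt <- 900
  tt <- seq_len(nt) * tr
  probe <- function(period) sin(2 * pi * tt / period + 0.4)
  img <- make_img(rbind(probe(300), probe(50), rep(5, nt)), c(3, 1, 1),
                  tr = tr)
  out <- highpass(img, 150)
  amp <- function(x) sqrt(2 * mean(x^2))  # RMS amplitude of a sinusoid
  expect_lt(amp(out$data[1, ]) / amp(img$data[1, ]), 0.01)
  expect_gt(amp(out$data[2, ]) / amp(img$data[2, ]), 0.99)
  expect_equal(out$data[3, ], rep(0, nt))  # constant -> zero
  expect_error(highpass(img, 3), "cutoff")
})

test_that("spectral gain above the cutoff frequency stays near one", {
  tr <- 2; nt <- 900
  tt <- seq_len(nt) * tr
  for (period in c(100, 60, 30, 10)) {
    x <- sin(2 * pi * tt / period + 0.7)
    img <- make_img(matrix(x, 1), c(1, 1, 1), tr)
    y <- highpass(img, 150)$data[1, ]
    expect_gt(sqrt(mean(y^2)) / sqrt(mean((x - mean(x))^2)), 0.99)
  }
})

test_that("gaussian smoothing has the right width and preserves mass", {
  d <- c(21, 21, 13)
  mask <- array(TRUE, d)
  # identity at fwhm 0
  img <- image4d(matrix(rnorm(prod(d) * 2), ncol = 2), mask, tr = 2)
  expect_identical(smooth_image(img, 0), img)
  # impulse response width: delta at the centre
  vol <- array(0, d); vol[11, 11, 7] <- 1
  delta <- image4d(cbind(vol[mask], vol[mask]), mask, tr = 2,
                   voxel_mm = c(3, 3, 3))
  sm <- as_volume(smooth_image(delta, 6)$data[, 1], mask)
  prof <- sm[, 11, 7]
  half <- max(prof) / 2
  above <- which(prof >= half)
  # linear interpolation at the half-maximum crossings
  lo <- min(above); hi <- max(above)
  f_lo <- lo - 1 + (half - prof[lo - 1]) / (prof[lo] - prof[lo - 1])
  f_hi <- hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1])
  fwhm_vox <- f_hi - f_lo
  expect_equal(fwhm_vox * 3, 6, tolerance = 0.1 * 6)
  # constant image stays constant (all-ones mask)
  cimg <- image4d(matrix(7, prod(d), 2), mask, tr = 2)
  expect_equal(smooth_image(cimg, 6)$data, cimg$data, tolerance = 1e-10)
})

test_that("soft and aggressive component regression behave as specified", {
  set.seed(5)
  nt <- 60
  # zero-mean, mutually orthogonal signal and noise -> identical outputs
  q <- qr.Q(qr(cbind(1, matrix(rnorm(nt * 2), nt))))[, 2:3]
  s <- q[, 1]; n <- q[, 2]
  dat <- rbind(3 * s + 2 * n, s - n, 5 * n)
  img <- make_img(dat, c(3, 1, 1))
  cs <- component_set(matrix(rnorm(6), 3, 2), cbind(s, n),
                      labels = c("signal", "noise"))
  soft <- regress_components(img, cs, mode = "soft")
  aggr <- regress_components(img, cs, mode = "aggressive")
  expect_equal(soft$data, aggr$data, tolerance = 1e-10)
  # pure noise series is annihilated by the aggressive mode
  expect_lt(max(abs(aggr$data[3, ] - mean(dat[3, ]))), 1e-10)
  # correlated case: soft preserves more signal than aggressive
  n2 <- as.numeric(scale(0.5 * scale(s) + sqrt(0.75) * scale(q[, 2])))
  stopifnot(abs(cor(s, n2) - 0.5) < 1e-6)
  dat2 <- rbind(s + n2)
  img2 <- make_img(dat2, c(1, 1, 1))
  cs2 <- component_set(matrix(rnorm(2), 1, 2), cbind(s, n2),
                       labels = c("signal", "noise"))
  soft2 <- regress_components(img2, cs2, mode = "soft")
  aggr2 <- regress_components(img2, cs2, mode = "aggressive")
  expect_gt(cor(soft2$data[1, ], s), cor(aggr2$data[1, ], s))
  # oracle: soft residual equals data minus noise part of the joint fit
  X <- cbind(scale(s, scale = FALSE), scale(n2, scale = FALSE))
  beta <- pinv_fit(X, matrix(dat2[1, ] - mean(dat2[1, ])))
  expect_equal(soft2$data[1, ],
               dat2[1, ] - as.numeric(X[, 2] * beta[2]),
               tolerance = 1e-10)
})

test_that("component regression is idempotent and variance-ordered", {
  co <- tiny_cohort(seed = 6, n_per_group = 2, grid = c(10, 10, 8), nt = 50)
  img <- co$images[[1]]
  cs <- subject_components(co, 1)
  m24 <- friston24(co$truth$motion_params[[1]])
  for (mode in c("soft", "aggressive")) {
    once <- regress_components(img, cs, m24, mode = mode)
    twice <- regress_components(once, cs, m24, mode = mode)
    expect_equal(twice$data, once$data, tolerance = 1e-8)
  }
  v <- function(x) sum((x$data - rowMeans(x$data))^2)
  soft <- regress_components(img, cs, m24, mode = "soft")
  aggr <- regress_components(img, cs, m24, mode = "aggressive")
  expect_lte(v(img) - v(soft), v(img) - v(aggr))
  # aggressive residuals orthogonal to the noise design
  noise_tc <- cs$timecourses[, cs$labels == "noise"]
  r <- cor(t(aggr$data), cbind(noise_tc, m24[, apply(m24, 2, sd) > 0]))
  expect_lt(max(abs(r)), 1e-8)
})

test_that("clean_image modes honour their contracts", {
  co <- tiny_cohort(seed = 8, n_per_group = 2, grid = c(10, 10, 8), nt = 50)
  img <- co$images[[1]]
  cs <- subject_components(co, 1)
  mot <- co$truth$motion_params[[1]]
  # uncleaned output ignores motion entirely
  u1 <- clean_image(img, motion = mot, config = cleaning_config("uncleaned"))
  u2 <- clean_image(img, motion = -2 * mot,
                    config = cleaning_config("uncleaned"))
  expect_identical(u1$data, u2$data)
  # motion24 residuals orthogonal to all motion regressors
  m <- clean_image(img, mot, config = cleaning_config("motion24"))
  m24 <- friston24(mot)
  r <- cor(t(m$data), m24[, apply(m24, 2, sd) > 0])
  expect_lt(max(abs(r)), 1e-8)
  # perfect classifier equals truth labels
  a <- clean_image(img, mot, cs, cleaning_config("ica_soft",
                                                 label_source = "truth"))
  b <- clean_image(img, mot, cs,
                   cleaning_config("ica_soft", label_source = "corrupted",
                                   tpr = 1, tnr = 1))
  expect_equal(a$data, b$data)
  expect_error(clean_image(img, mot, NULL, cleaning_config("ica_soft")),
               "component set")
  # temporal mean is preserved by cleaning
  expect_equal(rowMeans(a$data), rowMeans(smooth_image(img, 6)$data),
               tolerance = 1e-8)
})

test_that("median tSNR follows its definition and erosion rule", {
  # erosion of a 3x3x3 cube leaves the centre voxel
  m <- array(TRUE, c(3, 3, 3))
  er <- rsfcrepro:::.erode6(m)
  expect_equal(sum(er), 1)
  expect_true(er[2, 2, 2])
  # constructed tSNR of exactly 10
  d <- c(5, 5, 5)
  mask <- array(TRUE, d)
  set.seed(1)
  nt <- 40
  dat <- t(vapply(seq_len(prod(d)), function(v) {
    x <- rnorm(nt)
    100 + 10 * (x - mean(x)) / sd(x)
  }, numeric(nt)))
  img <- image4d(dat, mask, tr = 2)
  expect_equal(as.numeric(tsnr_median(img)), 10, tolerance = 1e-10)
  expect_equal(attr(tsnr_median(img), "n_zero_sd"), 0)
  # ICA cleaning increases tSNR relative to uncleaned on synthetic data
  co <- tiny_cohort(seed = 12, n_per_group = 2, grid = c(12, 12, 8), nt = 60)
  img <- co$images[[1]]
  cs <- subject_components(co, 1)
  mot <- co$truth$motion_params[[1]]
  t_u <- tsnr_median(clean_image(img, config = cleaning_config("uncleaned")))
  t_i <- tsnr_median(clean_image(img, mot, cs,
                                 cleaning_config("ica_soft")))
  expect_gt(t_i, t_u)
  expect_error(tsnr_median(image4d(matrix(1, 1, 5), array(TRUE, c(1, 1, 1)),
                                   tr = 2)), "empty")
})
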