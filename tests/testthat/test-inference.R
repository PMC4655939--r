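test_that("ROI extraction averages the target map within each ROI", {
  co <- tiny_cohort(seed = 14, n_per_group = 2, grid = c(10, 10, 8), nt = 40)
  tr <- co$truth
  nv <- sum(tr$mask)
  const <- structure(list(stage2_maps = matrix(3.25, nv, 1)),
                     class = "subject_maps")
  pe <- roi_mean_pe(list(const), tr$roi_atlas, tr$mask, 1)
  expect_equal(unname(pe[1, ]), rep(3.25, 6))
  # single-voxel ROI returns that voxel's value
  vox <- which(tr$mask)[17]
  single <- array(FALSE, dim(tr$mask)); single[vox] <- TRUE
  vals <- structure(list(stage2_maps = matrix(seq_len(nv), nv, 1)),
                    class = "subject_maps")
  expect_equal(unname(roi_mean_pe(list(vals), list(roi = single),
                                  tr$mask, 1)[1, 1]), 17)
  empty <- array(FALSE, dim(tr$mask))
  expect_error(roi_mean_pe(list(vals), list(roi = empty), tr$mask), "ROI")
})

test_that("planted deficit lowers patient ROI means only in the deficit ROIs", {
  co <- tiny_cohort(seed = 15)
  dr <- run_dual_regression(co$images, truth_template(co, "all"))
  pe <- roi_mean_pe(dr, co$truth$roi_atlas, co$truth$mask, 1)
  # normalize out subject amplitude so only the spatial deficit remains
  rel <- pe / co$truth$subject_amplitudes[, 1]
  g <- co$cohort$group == "control"
  for (roi in colnames(pe)) {
    p <- t_two_sample(rel[g, roi], rel[!g, roi])$p
    if (grepl("putamen", roi)) expect_lt(p, 1e-6)
    else expect_gt(p, 0.01)
  }
})

test_that("two-sample t matches its summary form and a textbook oracle", {
  a <- c(4.1, 5.3, 6.0); b <- c(3.2, 2.8, 4.4)
  res <- t_two_sample(a, b)
  # independent oracle: base R pooled t-test
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  expect_equal(res$df, 4)
  # algebraic identity with the summary form
  expect_equal(res$t,
               t_from_summary(3, mean(a), sd(a), 3, mean(b), sd(b)),
               tolerance = 1e-12)
  # identical groups: zero difference
  same <- c(1, 2, 3)
  expect_equal(t_two_sample(same, same)$t, 0)
  expect_equal(t_two_sample(same, same)$p, 1)
  expect_error(t_two_sample(c(1, 1), c(1, 1)), "variance")
  expect_error(t_two_sample(1, c(1, 2)), "at least 2")
  # equal means give t = 0; Welch equals pooled for equal n and sd
  expect_equal(t_from_summary(10, 5, 2, 10, 5, 1), 0)
  expect_equal(t_from_summary(8, 4, 1.5, 8, 3, 1.5, welch = TRUE),
               t_from_summary(8, 4, 1.5, 8, 3, 1.5))
})

test_that("bonferroni flags follow the family-size rule", {
  expect_true(bonferroni_flags(0.001, m = 6))
  expect_false(bonferroni_flags(0.01, m = 6))   # 0.01 > 0.05/6
  expect_equal(bonferroni_flags(c(0.04, 0.06), m = 1), c(TRUE, FALSE))
})

test_that("TFCE matches the closed form on constant-height clusters", {
  d <- c(12, 12, 8)
  for (h0 in c(2, 4)) {
    m <- array(0, d)
    m[3:5, 3:5, 3:4] <- h0            # 18-voxel block
    k <- sum(m > 0)
    out <- tfce(m, tfce_params())
    expected <- sqrt(k) * h0^3 / 3    # integral of k^0.5 h^2 dh
    got <- unique(round(out[m > 0], 10))
    expect_length(got, 1)
    expect_equal(got, expected, tolerance = 0.02)
  }
  # doubling the height multiplies TFCE by 8 (H = 2 gives a cubic law)
  m1 <- array(0, d); m1[2:4, 2:4, 2:3] <- 1.5
  m2 <- m1 * 2
  expect_equal(tfce(m2), 8 * tfce(m1), tolerance = 1e-12)
  expect_equal(tfce(array(0, d)), array(0, d))
})

test_that("TFCE agrees with the brute-force per-threshold oracle", {
  set.seed(33)
  d <- c(9, 8, 6)
  m <- array(0, d)
  m[2:4, 2:4, 2:3] <- runif(18, 0.5, 2)    # cluster 1
  m[6:8, 5:7, 4:6] <- runif(27, 1, 3)      # disjoint cluster 2
  m[5, 1, 1] <- 2.5                        # isolated voxel
  for (conn in c(6, 26)) {
    p <- tfce_params(n_steps = 40, connectivity = conn)
    expect_equal(tfce(m, p),
                 tfce_R(m, E = 0.5, H = 2, n_steps = 40,
                        connectivity = conn),
                 tolerance = 1e-10)
  }
  # disjoint clusters do not interact
  m1 <- m; m1[6:8, 5:7, 4:6] <- 0; m1[5, 1, 1] <- 0
  full <- tfce(m, tfce_params(n_steps = 40))
  alone <- tfce(m1, tfce_params(n_steps = 40))
  # cluster 1 values computed in isolation match only up to the threshold
  # grid (hmax differs), so compare against the oracle instead
  expect_equal(alone, tfce_R(m1, n_steps = 40), tolerance = 1e-10)
  # monotonicity: raising the map never lowers TFCE anywhere
  bumped <- m + 0.3 * (m > 0)
  expect_true(all(tfce(bumped, tfce_params(n_steps = 40)) >= full - 1e-12))
})

test_that("permutation GLM matches exhaustive enumeration on a tiny instance", {
  set.seed(44)
  n <- 6
  d <- c(5, 4, 1)                      # 20 voxels
  mask <- array(TRUE, d)
  group <- rep(c("ctl", "pat"), each = 3)
  age <- c(60, 63, 66, 59, 64, 70)
  gm <- matrix(runif(n * 20, 0.3, 0.9), n)
  Y <- matrix(rnorm(n * 20), n)
  Y[1:3, 5:8] <- Y[1:3, 5:8] + 1.5     # effect in a few voxels
  prm <- tfce_params(n_steps = 20, connectivity = 6)
  expect_warning(
    res <- permutation_glm(Y, group, age, gm, mask, contrast = "A_gt_B",
                           params = prm,
                           config = stats_config(n_perm = 100, seed = 9)),
    "exhaustively")
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, choose(6, 3))

  # oracle: naive per-voxel Freedman-Lane over the same permutation set
  rz_res <- function(M) {           # residualize each column on [1,age,gm_v]
    sapply(seq_len(ncol(M)), function(v)
      residuals(lm(M[, v] ~ age + gm[, v])))
  }
  g <- as.numeric(group == "ctl")
  E <- rz_res(Y)
  tstat <- function(Yp) {
    sapply(seq_len(ncol(Yp)), function(v) {
      fit <- lm(Yp[, v] ~ g + age + gm[, v])
      summary(fit)$coefficients["g", "t value"]
    })
  }
  subsets <- combn(6, 3, simplify = FALSE)
  slotsA <- which(g == 1)
  maxes <- sapply(subsets, function(s) {
    p <- integer(6); p[slotsA] <- s
    p[setdiff(1:6, slotsA)] <- setdiff(1:6, s)
    tt <- tstat(E[p, , drop = FALSE])
    vol <- array(0, d); vol[mask] <- tt
    max(tfce_R(vol, n_steps = 20, connectivity = 6))
  })
  obs_t <- tstat(E)
  vol <- array(0, d); vol[mask] <- obs_t
  obs_tfce <- tfce_R(vol, n_steps = 20, connectivity = 6)
  # tolerance on ties: the oracle and the implementation compute TFCE by
  # different float paths, and exact equals occur (identity permutation)
  p_oracle <- sapply(obs_tfce[mask], function(v) mean(maxes >= v - 1e-8))
  expect_equal(res$fwe_pmap[mask], p_oracle, tolerance = 1e-10)
  expect_equal(res$tmap[mask], obs_t, tolerance = 1e-8)
})

test_that("FWE p-values are valid and the mask rules are honoured", {
  co <- tiny_cohort(seed = 16, n_per_group = 6, grid = c(10, 10, 8), nt = 50)
  dr <- run_dual_regression(co$images, truth_template(co, "all"))
  Y <- t(sapply(dr, function(s) s$stage2_maps[, 1]))
  am <- gm_analysis_mask(co$truth$gm_maps, co$truth$mask)
  expect_true(all(am[co$truth$mask] %in% c(TRUE, FALSE)))
  expect_true(all(!am[!co$truth$mask]))
  res <- permutation_glm(Y, co$cohort$group, co$cohort$age,
                         t(co$truth$gm_maps), co$truth$mask,
                         analysis_mask = am,
                         params = tfce_params(n_steps = 30),
                         config = stats_config(n_perm = 120, seed = 5))
  expect_true(all(res$fwe_pmap > 0 & res$fwe_pmap <= 1))
  expect_true(all(res$sig_mask[!am] == FALSE))
  expect_error(permutation_glm(Y, co$cohort$group, mask = co$truth$mask,
                               analysis_mask = array(FALSE, dim(am))),
               "empty")
})
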