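test_that("top-voxel selection ranks only the visual beta", {
  set.seed(1)
  n <- 200
  labels <- rep(1:2, each = n / 2)
  visual <- stats::runif(n)
  gb <- stats::rnorm(n); nf <- stats::rnorm(n)
  t1 <- top_visual_average(gb, nf, visual, labels)
  # permuting the GB/NF values leaves the selected voxel set unchanged,
  # so re-permuting identically permuted betas reproduces the means
  sel_region1 <- order(-visual[1:100])[1:10]
  expect_equal(t1$mean_gb[1], mean(gb[sel_region1]))
  expect_equal(t1$mean_nf[1], mean(nf[sel_region1]))
  t2 <- top_visual_average(gb + 100, nf - 50, visual, labels)
  expect_equal(t2$mean_gb, t1$mean_gb + 100)
  expect_equal(t2$mean_nf, t1$mean_nf - 50)
  # identical voxels: zero s.e.m., mean equals the common value
  t3 <- top_visual_average(rep(0.1, n), rep(0.2, n), visual, labels)
  expect_equal(t3$sem_gb, c(0, 0))
  expect_equal(t3$mean_nf, c(0.2, 0.2))
  # small regions fall back to all voxels with a warning
  expect_warning(
    t4 <- top_visual_average(gb[1:5], nf[1:5], visual[1:5], rep(1, 5)),
    "fewer than")
  expect_identical(t4$n_used, 5L)
})

test_that("planted effects surface in the per-region scatter", {
  tr <- small_truth()
  d <- make_design("GB", seed = 2)
  dn <- make_design("NF", seed = 3)
  run_gb <- simulate_task_run(d, tr, seed = 1, noise = FALSE)
  run_nf <- simulate_task_run(dn, tr, seed = 1, noise = FALSE)
  fit_gb <- fit_glm(run_gb, build_design_matrix(d, run_gb$nuisance, mion_irf()))
  fit_nf <- fit_glm(run_nf, build_design_matrix(dn, run_nf$nuisance, mion_irf()))
  fit_v <- fit_glm(run_gb, build_visual_design(d, run_gb$nuisance, mion_irf()))
  gb <- contrast_map(fit_gb, contrast_spec("GB"))$estimate
  nf <- contrast_map(fit_nf, contrast_spec("NF"))$estimate
  tab <- top_visual_average(gb, nf, fit_v$betas[, "probe"], tr$labels)
  # network 2 (region 2) carries GB = NF = 0.1
  expect_lt(abs(tab$mean_gb[tab$region == 2] - 0.1), 1e-6)
  expect_lt(abs(tab$mean_nf[tab$region == 2] - 0.1), 1e-6)
})

test_that("the joint null fit recovers moments and rejects degeneracy", {
  set.seed(2)
  n <- 1e5
  gb <- stats::rnorm(n); nf <- stats::rnorm(n)
  fit <- fit_joint_null(gb, nf)
  expect_lt(max(abs(fit$mean)), 0.02)
  expect_lt(max(abs(fit$cov - diag(2))), 0.02)
  expect_error(fit_joint_null(1:100, 2 * (1:100) + 3), "singular")
  expect_error(fit_joint_null(gb[1:5], nf[1:5]), "at least 10")
  # affine transformation leaves Mahalanobis distances unchanged
  d2a <- stats::mahalanobis(cbind(gb, nf)[1:50, ], fit$mean, fit$cov)
  gb2 <- 2 * gb + 1; nf2 <- -0.5 * nf + 3
  fit2 <- fit_joint_null(gb2, nf2)
  d2b <- stats::mahalanobis(cbind(gb2, nf2)[1:50, ], fit2$mean, fit2$cov)
  expect_equal(d2a, d2b, tolerance = 1e-9)
})

test_that("contour classification is calibrated and nested", {
  set.seed(3)
  n <- 1e4
  gb <- stats::rnorm(n, 0.05, 0.2)
  nf <- 0.5 * gb + stats::rnorm(n, 0, 0.1)
  null <- fit_joint_null(gb, nf)
  cls <- classify_outside_contour(gb, nf, null,
                                  network = sample(1:3, n, replace = TRUE))
  frac95 <- mean(cls$outside[, "level0.95"])
  expect_lt(abs(frac95 - 0.05), 1.96 * sqrt(0.05 * 0.95 / n) + 0.005)
  frac68 <- mean(cls$outside[, "level0.68"])
  expect_lt(abs(frac68 - 0.32), 1.96 * sqrt(0.32 * 0.68 / n) + 0.01)
  # nesting: every voxel outside 95% is outside 68%
  expect_true(all(cls$outside[cls$outside[, 2], 1]))
  # a voxel at the null mean is inside every level
  cls0 <- classify_outside_contour(null$mean[1], null$mean[2], null)
  expect_false(any(cls0$outside))
  expect_identical(nrow(cls$fractions), 6L)
  expect_error(classify_outside_contour(gb, nf, null, levels = c(0.9, 0.5)))
})

test_that("identical planted dynamics give unit NF/GB time-course correlation", {
  eff <- data.frame(network = 1:4, visual = c(0.5, 0.3, 0.3, 0),
                    gb = c(0, 0.1, 0.05, 0), nf = c(0, 0.1, 0.05, 0),
                    contra_bias = 0)
  tr <- small_truth(effects = eff)
  # order-matched scans: same design seed pairs good with novel slots, so
  # the canonicalized time courses coincide exactly
  nf_runs <- lapply(1:2, function(i) {
    simulate_task_run(make_design("NF", seed = i), tr, seed = i, noise = FALSE)
  })
  gb_runs <- lapply(1:2, function(i) {
    simulate_task_run(make_design("GB", seed = i), tr, seed = i,
                      noise = FALSE)
  })
  lab <- as.vector(tr$labels)
  net <- ifelse(lab > 0, tr$network_of_region[lab], NA)
  out <- nfgb_timecourse_correlation(nf_runs, gb_runs, net)
  # value and novelty responses share their dynamics exactly in networks 1-3
  expect_equal(out$by_network$mean_r[1:3], rep(1, 3), tolerance = 1e-9)
  expect_true(all(out$r >= -1 & out$r <= 1, na.rm = TRUE))
  expect_true(all(out$by_network$sem_r >= 0))
  # with independent probe orders the hemodynamic response carries over
  # block boundaries, so canonicalized alignment is close but not exact
  gb_runs2 <- lapply(1:2, function(i) {
    simulate_task_run(make_design("GB", seed = 10 + i), tr, seed = i,
                      noise = FALSE)
  })
  out2 <- nfgb_timecourse_correlation(nf_runs, gb_runs2, net)
  expect_gt(min(out2$by_network$mean_r[1:3]), 0.95)
})

test_that("shared-dynamics networks correlate above silent ones under noise", {
  eff <- data.frame(network = 1:4, visual = c(1, 0, 1, 0),
                    gb = c(0.3, 0, 0.3, 0), nf = c(0.3, 0, 0.3, 0),
                    contra_bias = 0)
  tr <- small_truth(effects = eff)
  nf_runs <- lapply(1:4, function(i) {
    simulate_task_run(make_design("NF", seed = i), tr, seed = 100 + i)
  })
  gb_runs <- lapply(1:4, function(i) {
    simulate_task_run(make_design("GB", seed = 10 + i), tr, seed = 200 + i)
  })
  lab <- as.vector(tr$labels)
  net <- ifelse(lab > 0, tr$network_of_region[lab], NA)
  out <- nfgb_timecourse_correlation(nf_runs, gb_runs, net)
  active <- out$by_network$mean_r[out$by_network$network %in% c(1, 3)]
  silent <- out$by_network$mean_r[out$by_network$network %in% c(2, 4)]
  expect_gt(min(active), max(silent))
  # silent networks hover near zero correlation
  expect_lt(max(abs(silent)), 0.2)
})
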