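test_that("percent-change conversion is exact and masks degenerate voxels", {
  Y <- rbind(rep(5, 4), c(90, 110, 90, 110), rep(0, 4))
  out <- to_percent_change(Y)
  expect_equal(out[1, ], rep(0, 4))
  expect_equal(out[2, ], c(-10, 10, -10, 10))
  expect_true(all(is.na(out[3, ])))
  expect_identical(sum(attr(out, "masked")), 1L)
})

test_that("the design matrix has the prescribed structure", {
  d <- make_design("GB", seed = 1)
  tr <- small_truth()
  run <- simulate_task_run(d, tr, seed = 1, noise = FALSE)
  X <- build_design_matrix(d, run$nuisance, mion_irf())
  expect_identical(X$task_cols,
                   c("good_left", "bad_left", "good_right", "bad_right"))
  expect_identical(nrow(X$X), 189L)  # 192 volumes minus 3 discarded
  expect_identical(ncol(X$X), 4L + 17L + 5L)
  # motion columns are raw traces; non-motion nuisance is MION-convolved
  expect_equal(X$X[, "motion1"], run$nuisance[X$rows, "motion1"],
               ignore_attr = TRUE)
  conv_reward <- mion_convolve(run$nuisance[, "reward"], mion_irf())
  expect_equal(X$X[, "reward"], conv_reward[X$rows], ignore_attr = TRUE)
  expect_error(
    build_design_matrix(d, cbind(run$nuisance[, -1], motion1 = 0), mion_irf()),
    "all-zero")
  ev <- design_events(d)
  ev$trial_type[2] <- "surprise_left"
  expect_error(
    build_design_matrix(ev, run$nuisance, mion_irf(), scan_type = "GB",
                        n_volumes = 192),
    "unknown trial_type")
})

test_that("censoring excluded blocks equals fitting the shortened series", {
  tr <- small_truth()
  d <- make_design("GB", seed = 4, exclude_rate = 0.3)
  expect_true(any(design_events(d)$excluded))
  run <- simulate_task_run(d, tr, seed = 2)
  X <- build_design_matrix(d, run$nuisance, mion_irf())
  fit <- fit_glm(run, X)
  # manual OLS on the physically shortened series for a few voxels
  pct <- to_percent_change(run)
  Ysub <- t(pct[1:5, X$rows])
  beta_manual <- qr.coef(qr(X$X), Ysub)
  expect_equal(unname(fit$betas[1:5, ]), unname(t(beta_manual)),
               tolerance = 1e-10)
  expect_lt(length(X$rows), 189)
})

test_that("residuals are orthogonal to the design and dof is rows minus rank", {
  tr <- small_truth()
  d <- make_design("NF", seed = 6)
  run <- simulate_task_run(d, tr, seed = 3)
  X <- build_design_matrix(d, run$nuisance, mion_irf())
  fit <- fit_glm(run, X)
  ip <- crossprod(X$X, t(fit$residuals[1:20, ]))
  scale <- outer(sqrt(colSums(X$X^2)),
                 sqrt(rowSums(fit$residuals[1:20, ]^2)))
  expect_lt(max(abs(ip) / scale), 1e-6)
  expect_identical(fit$dof, nrow(X$X) - ncol(X$X))
})

test_that("rank-deficient designs fail with the collinear columns named", {
  d <- make_design("GB", seed = 1)
  tr <- small_truth()
  run <- simulate_task_run(d, tr, seed = 1, noise = FALSE)
  nuis <- run$nuisance
  nuis[, "eye_v"] <- 2 * nuis[, "eye_h"]
  X <- build_design_matrix(d, nuis, mion_irf())
  expect_error(fit_glm(run, X), "collinear.*eye")
})

test_that("contrasts are antisymmetric, zero under equality, and linear", {
  tr <- small_truth()
  d <- make_design("GB", seed = 2)
  run <- simulate_task_run(d, tr, seed = 1, noise = FALSE)
  X <- build_design_matrix(d, run$nuisance, mion_irf())
  fit <- fit_glm(run, X)
  gb <- contrast_map(fit, contrast_spec("GB"))
  # swapping good/bad labels flips the sign exactly
  fit2 <- fit
  cn <- colnames(fit2$betas)
  swap <- cn
  swap[match(c("good_left", "good_right", "bad_left", "bad_right"), cn)] <-
    c("bad_left", "bad_right", "good_left", "good_right")
  colnames(fit2$betas) <- swap
  gb2 <- contrast_map(fit2, contrast_spec("GB"))
  expect_equal(gb2$estimate, -gb$estimate, tolerance = 1e-12)
  # network 1 has no differential value coding: contrast is zero there
  lab <- as.vector(tr$labels)
  expect_lt(max(abs(gb$estimate[which(lab == 1)])), 1e-10)
  # NF spec against a GB fit is rejected
  expect_error(contrast_map(fit, contrast_spec("NF")), "scan type")
})

test_that("beta estimates are unbiased over noise realizations", {
  tr <- small_truth(grid_dim = c(6, 6, 4))
  d <- make_design("GB", seed = 3)
  X <- build_design_matrix(d, simulate_task_run(d, tr, seed = 1,
                                                noise = FALSE)$nuisance,
                           mion_irf())
  lab <- as.vector(tr$labels)
  idx <- which(lab == 2)
  errs <- vapply(1:200, function(i) {
    run <- simulate_task_run(d, tr, seed = 100 + i)
    fit <- fit_glm(run, X)
    mean(contrast_map(fit, contrast_spec("GB"))$estimate[idx]) - 0.1
  }, numeric(1))
  # 99.7% Monte-Carlo CI of the mean error covers zero
  expect_lt(abs(mean(errs)), 3 * stats::sd(errs) / sqrt(length(errs)))
})

test_that("voxel permutation permutes betas identically", {
  tr <- small_truth(grid_dim = c(6, 6, 4))
  d <- make_design("GB", seed = 5)
  run <- simulate_task_run(d, tr, seed = 7)
  X <- build_design_matrix(d, run$nuisance, mion_irf())
  pct <- to_percent_change(run)
  perm <- sample(nrow(pct))
  pct_perm <- pct[perm, ]
  attr(pct_perm, "masked") <- attr(pct, "masked")[perm]
  f1 <- fit_glm(pct, X, percent = FALSE)
  f2 <- fit_glm(pct_perm, X, percent = FALSE)
  expect_equal(f2$betas, f1$betas[perm, ], ignore_attr = TRUE)
})

test_that("the probe-vs-base visual fit responds to any probe block", {
  tr <- small_truth()
  d <- make_design("NF", seed = 8)
  run <- simulate_task_run(d, tr, seed = 2, noise = FALSE)
  Xv <- build_visual_design(d, run$nuisance, mion_irf())
  expect_identical(Xv$task_cols, "probe")
  fit <- fit_glm(run, Xv)
  lab <- as.vector(tr$labels)
  # visual beta approximates the mean condition effect in each network
  expect_gt(mean(fit$betas[which(lab == 1), "probe"]), 0.4)
})
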