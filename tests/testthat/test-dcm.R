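test_that("the model grid enumerates nine architectures with the stated masks", {
  grid <- dcm_model_grid()
  expect_identical(length(grid), 9L)
  schemes <- t(vapply(grid, function(m) c(m$input_scheme, m$self_mod_scheme),
                      character(2)))
  expect_identical(nrow(unique(schemes)), 9L)
  # every model shares the same reciprocal within-hemisphere A structure
  for (m in grid) {
    expect_identical(which(m$A_mask),
                     which(dcm_model("temporal", "simple")$A_mask))
  }
  # temporal input: drive lands only on the contralateral temporal node
  mt <- dcm_model("temporal", "simple")
  expect_true(all(rowSums(mt$C_mask)[c("temporal_L", "temporal_R")] == 4))
  expect_true(all(rowSums(mt$C_mask)[c("prefrontal_L", "prefrontal_R")] == 0))
  expect_true(mt$C_mask["temporal_R", "good_L"])
  expect_false(mt$C_mask["temporal_L", "good_L"])
  # simple scheme: no B matrix touches a self-connection
  for (Bm in mt$B_masks) expect_false(any(diag(Bm)))
  # GN scheme: good/novel inputs modulate every self-connection
  mg <- dcm_model("temporal", "GN")
  expect_true(all(diag(mg$B_masks[["good_L"]])))
  expect_false(any(diag(mg$B_masks[["bad_L"]])))
  mgb <- dcm_model("double", "GBNF")
  expect_true(all(diag(mgb$B_masks[["familiar_R"]])))
  # good/novel modulate forward and backward connections in all models
  for (m in grid) {
    expect_true(m$B_masks[["novel_L"]]["prefrontal_R", "temporal_R"])
    expect_true(m$B_masks[["novel_L"]]["temporal_R", "prefrontal_R"])
  }
})

test_that("simulation is silent without drive and deterministic otherwise", {
  m <- dcm_model("temporal", "simple")
  U <- dcm_concat_inputs(1)
  theta <- dcm_reference_theta(m, seed = 1)
  # zero C: nothing ever moves
  theta0 <- theta
  theta0[m$par_table$block == "C"] <- 0
  y0 <- simulate_dcm(m, theta0, U)
  expect_identical(max(abs(y0)), 0)
  y1 <- simulate_dcm(m, theta, U, snr = 5, seed = 3)
  y2 <- simulate_dcm(m, theta, U, snr = 5, seed = 3)
  expect_identical(y1, y2)
})

test_that("unstable parameterizations are rejected with the eigenvalue named", {
  m <- dcm_model("temporal", "simple")
  U <- dcm_concat_inputs(1)
  theta <- dcm_reference_theta(m, seed = 1)
  bad <- theta
  # overwhelm the self-decay with a strong reciprocal loop
  bad[m$par_table$block == "A"] <- 3
  bad[m$par_table$block == "A_self"] <- -2
  expect_error(simulate_dcm(m, bad, U), "unstable.*eigenvalue")
})

test_that("halving the integration step barely changes the output", {
  m <- dcm_model("temporal", "simple")
  U <- dcm_concat_inputs(1)
  theta <- dcm_reference_theta(m, seed = 2)
  y16 <- simulate_dcm(m, theta, U, substeps = 16)
  y32 <- simulate_dcm(m, theta, U, substeps = 32)
  y64 <- simulate_dcm(m, theta, U, substeps = 64)
  expect_lt(max(abs(y16 - y32)) / max(abs(y32)), 1e-5)
  expect_lt(max(abs(y32 - y64)) / max(abs(y64)), 1e-6)
})

test_that("the integrator shows fourth-order convergence", {
  m <- dcm_model("temporal", "simple")
  U <- dcm_concat_inputs(1)
  theta <- dcm_reference_theta(m, seed = 3)
  ref <- simulate_dcm(m, theta, U, substeps = 128)
  # asymptotic regime: step sizes small against the fastest time constant
  errs <- vapply(c(8, 16, 32), function(s) {
    max(abs(simulate_dcm(m, theta, U, substeps = s) - ref))
  }, numeric(1))
  slopes <- log2(errs[-3] / errs[-1])
  expect_true(all(abs(slopes - 4) < 0.5))
})

test_that("noise-free self-inversion recovers the generating parameters", {
  m <- dcm_model("temporal", "simple")
  U <- dcm_concat_inputs(1)
  theta <- dcm_reference_theta(m, seed = 4)
  y <- simulate_dcm(m, theta, U)
  fit <- fit_dcm(y, m, U, n_starts = 1, maxiter = 100)
  expect_false(fit$flagged)
  expect_lt(max(abs(fit$theta - theta)), 1e-2)
  expect_true(is.finite(fit$log_evidence))
})

test_that("on pure noise the evidence penalizes the richer model", {
  m_simple <- dcm_model("temporal", "simple")
  m_rich <- dcm_model("temporal", "GBNF")
  U <- dcm_concat_inputs(1)
  diffs <- vapply(1:3, function(i) {
    set.seed(400 + i)
    noise <- matrix(stats::rnorm(4 * ncol(U), sd = 0.05), 4)
    fs <- fit_dcm(noise, m_simple, U, n_starts = 1, maxiter = 40)
    fr <- fit_dcm(noise, m_rich, U, n_starts = 1, maxiter = 40)
    fs$log_evidence - fr$log_evidence
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("model selection normalizes, excludes flags, and breaks ties simply", {
  mk_fit <- function(ev, nf, flagged = FALSE) {
    structure(list(log_evidence = ev, flagged = flagged,
                   model = list(n_free = nf)), class = "dcm_fit")
  }
  fits <- list(a = mk_fit(-10, 5), b = mk_fit(-40, 8))
  sel <- model_select(fits)
  expect_identical(sel$best, "a")
  expect_gt(sel$table$posterior[1], 0.999)
  expect_equal(sum(sel$table$posterior), 1)
  # exact ties resolve toward the fewest free parameters
  tie <- model_select(list(rich = mk_fit(-5, 9), lean = mk_fit(-5, 3)))
  expect_identical(tie$best, "lean")
  expect_equal(tie$table$posterior, c(0.5, 0.5))
  expect_warning(
    sel2 <- model_select(list(good = mk_fit(-3, 4),
                              bad = mk_fit(0, 4, flagged = TRUE))),
    "flagged")
  expect_identical(sel2$best, "good")
})

test_that("edge summaries collapse to A without modulation and respect symmetry", {
  m <- dcm_model("temporal", "simple")
  theta <- dcm_reference_theta(m, seed = 5)
  theta[grepl("^B", m$par_table$block)] <- 0
  fit <- structure(list(params = dcm_unpack(m, theta), model = m),
                   class = "dcm_fit")
  tab <- summarize_edges(fit)
  A <- fit$params$A
  # without modulation every condition reports plain A entries
  fwd <- tab$weight[tab$edge == "forward"]
  expect_true(all(abs(fwd - mean(c(A[2, 1], A[4, 3]))) < 1e-12 |
                    abs(fwd - A[2, 1]) < 1e-12 | abs(fwd - A[4, 3]) < 1e-12))
  # left/right symmetric parameters make contra/ipsi averaging lossless
  theta_sym <- theta
  pt <- m$par_table
  theta_sym[pt$name == "A_prefrontal_R<-temporal_R"] <-
    theta_sym[pt$name == "A_prefrontal_L<-temporal_L"]
  theta_sym[pt$name == "A_temporal_R<-prefrontal_R"] <-
    theta_sym[pt$name == "A_temporal_L<-prefrontal_L"]
  fit_sym <- structure(list(params = dcm_unpack(m, theta_sym), model = m),
                       class = "dcm_fit")
  tab_sym <- summarize_edges(fit_sym)
  Asym <- fit_sym$params$A
  expect_equal(tab_sym$weight[tab_sym$edge == "forward"],
               rep(Asym[2, 1], 4), tolerance = 1e-12)
  expect_equal(tab_sym$weight[tab_sym$edge == "backward"],
               rep(Asym[1, 2], 4), tolerance = 1e-12)
})

test_that("a planted negative prefrontal feedback is recovered in sign", {
  m <- dcm_model("temporal", "simple")
  U <- dcm_concat_inputs(2)
  theta <- dcm_reference_theta(m, seed = 6)
  pt <- m$par_table
  backward <- grepl("^A_temporal_[LR]<-prefrontal", pt$name)
  theta[backward] <- c(-0.35, -0.3)
  y <- simulate_dcm(m, theta, U, snr = 5, seed = 7)
  fit <- fit_dcm(y, m, U, n_starts = 1, maxiter = 80)
  tab <- summarize_edges(fit, conditions = "good")
  expect_true(all(tab$sign[tab$edge == "backward"] == -1))
})

test_that("fitting rejects data too short for the parameter count", {
  m <- dcm_model("double", "GBNF")
  U <- dcm_concat_inputs(1)[, 1:100]
  y <- matrix(0, 4, 100)
  expect_error(fit_dcm(y, m, U), "at least")
})
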