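#' Simulate a task run
#'
#' Generates a 4D raw-signal volume series for a block design: each voxel is
#' `baseline * (1 + sum_c boxcar_c (x) MION kernel * effect_c / 100)` plus
#' spatially autocorrelated Gaussian noise scaled so the empirical temporal
#' signal-to-noise ratio matches the ground-truth target (`sd = baseline /
#' tsnr`). Seventeen nuisance traces (six motion parameters and their
#' derivatives, reward delivery, blinks, horizontal/vertical eye position and
#' their interaction) are emitted alongside, with known (default zero)
#' percent-signal loadings onto labeled voxels.
#'
#' @param design A [make_design()] scan design.
#' @param truth A [ground_truth()] object.
#' @param seed Integer seed; identical seeds reproduce the run bit-identically.
#' @param kernel MION kernel; default [mion_irf()] at the design TR.
#' @param noise If `FALSE`, no noise is added (planted effects are then
#'   recovered exactly by the GLM).
#' @return Object of class `simulated_run`: `bold` (4D array), `events`,
#'   `nuisance` (volumes x 17), `condition_regressors` (convolved, percent
#'   scale 0/1 boxcars), `design`, `seed`.
#' @export
simulate_task_run <- function(design, truth, seed = 1,
                              kernel = mion_irf(dt_s = design$tr_s),
                              noise = TRUE) {
  stopifnot(inherits(design, "scan_design"), inherits(truth, "ground_truth"))
  if (!isTRUE(all.equal(kernel$dt_s, design$tr_s))) {
    stop("kernel dt_s must equal the design TR")
  }
  nt <- n_volumes(design)
  grid <- truth$grid_dim
  nvox <- prod(grid)
  labels <- as.vector(truth$labels)

  # condition boxcars at TR resolution, MION-convolved
  conds <- condition_labels(design$scan_type)
  box <- condition_boxcars(design, conds)
  conv <- apply(box, 2, mion_convolve, kernel = kernel)

  # per-region percent effect per condition -> region x time percent signal
  eff <- vapply(conds, function(cn) {
    parts <- strsplit(cn, "_")[[1]]
    region_condition_effect(truth, parts[1], parts[2])
  }, numeric(truth$n_regions))
  pct_region <- eff %*% t(conv)  # regions x time

  nuis <- with_seed(seed + 17L, make_nuisance_traces(nt))
  load <- truth$nuisance_loadings
  pct_nuis <- if (any(load != 0)) {
    conv_nuis <- nuis
    idx <- !grepl("^motion|^dmotion", colnames(nuis))
    conv_nuis[, idx] <- apply(nuis[, idx, drop = FALSE], 2,
                              mion_convolve, kernel = kernel)
    as.vector(conv_nuis %*% load)
  } else rep(0, nt)

  pct <- matrix(0, nvox, nt)
  lab_ok <- labels > 0
  pct[lab_ok, ] <- pct_region[labels[lab_ok], ]
  pct[lab_ok, ] <- sweep(pct[lab_ok, , drop = FALSE], 2, pct_nuis, `+`)
  # plant effects about the run mean so that the voxel temporal mean equals
  # the baseline and "percent change from the mean" recovers them exactly
  pct <- pct - rowMeans(pct)

  bold <- truth$baseline * (1 + pct / 100)
  if (noise) {
    sigma <- truth$baseline / truth$tsnr
    S <- acf_spectrum(truth$acf, grid)
    noise_mat <- with_seed(seed, {
      vapply(seq_len(nt), function(t) {
        w <- array(stats::rnorm(nvox), dim = grid)
        as.vector(noise_filter(w, S))
      }, numeric(nvox))
    })
    bold <- bold + sigma * noise_mat
  }
  dim(bold) <- c(grid, nt)

  structure(list(bold = bold, events = design_events(design),
                 nuisance = nuis, condition_regressors = conv,
                 design = design, truth = truth, seed = seed),
            class = "simulated_run")
}

condition_labels <- function(scan_type) {
  types <- if (scan_type == "GB") c("good", "bad") else c("novel", "familiar")
  as.vector(outer(types, c("left", "right"), paste, sep = "_"))
}

# 0/1 boxcar per condition at TR resolution (excluded blocks still stimulate;
# they are censored at regression time, not at acquisition time)
condition_boxcars <- function(design, conds = condition_labels(design$scan_type)) {
  nt <- n_volumes(design)
  vb <- volume_blocks(design)
  ev <- design_events(design)
  box <- matrix(0, nt, length(conds), dimnames = list(NULL, conds))
  for (cn in conds) {
    blocks <- ev$block[!is.na(ev$trial_type) & ev$trial_type == cn]
    box[vb %in% blocks, cn] <- 1
  }
  box
}

# 17 named nuisance traces; caller seeds the RNG.
make_nuisance_traces <- function(nt) {
  smooth_walk <- function(scale) {
    x <- cumsum(stats::rnorm(nt, sd = scale))
    x - mean(x)
  }
  motion <- vapply(1:6, function(i) smooth_walk(0.02), numeric(nt))
  dmotion <- rbind(0, diff(motion))
  reward <- as.numeric(stats::runif(nt) < 0.15)
  blink <- as.numeric(stats::runif(nt) < 0.1)
  eye_h <- smooth_walk(0.05)
  eye_v <- smooth_walk(0.05)
  out <- cbind(motion, dmotion, reward, blink, eye_h, eye_v,
               eye_hv = eye_h * eye_v)
  colnames(out) <- c(paste0("motion", 1:6), paste0("dmotion", 1:6),
                     "reward", "blink", "eye_h", "eye_v", "eye_hv")
  out
}

#' Simulate resting-state region time series
#'
#' Draws independent zero-mean Gaussian vectors with covariance equal to the
#' inverse of the ground-truth precision matrix, optionally adding shared
#' confound traces (white-matter / ventricle analogues) with known loadings.
#'
#' @param truth A [ground_truth()] object (or a precision matrix).
#' @param n_volumes Number of time points; must exceed the region count.
#' @param seed Integer seed.
#' @param confound_sd SD of two shared confound traces added to every
#'   region; 0 (default) disables them.
#' @param confound_loadings Optional regions x 2 loading matrix
#'   (default all 0.5 when `confound_sd > 0`).
#' @return List of class `rest_sim`: `x` (regions x time), `confounds`
#'   (2 x time or NULL), `precision`.
#' @export
simulate_rest <- function(truth, n_volumes, seed = 1, confound_sd = 0,
                          confound_loadings = NULL) {
  P <- if (inherits(truth, "ground_truth")) truth$rest_precision else truth
  p <- nrow(P)
  stopifnot(n_volumes > p)
  R <- tryCatch(chol(P), error = function(e) {
    stop("rest precision must be symmetric positive definite")
  })
  # X ~ N(0, P^{-1}): solve R X = Z with Z white, since P = R'R
  x <- with_seed(seed, {
    z <- matrix(stats::rnorm(p * n_volumes), p, n_volumes)
    xx <- backsolve(R, z)
    conf <- NULL
    if (confound_sd > 0) {
      conf <- matrix(stats::rnorm(2 * n_volumes, sd = confound_sd), 2)
      if (is.null(confound_loadings)) {
        confound_loadings <- matrix(0.5, p, 2)
      }
      xx <- xx + confound_loadings %*% conf
    }
    list(x = xx, confounds = conf)
  })
  rownames(x$x) <- paste0("region", seq_len(p))
  structure(list(x = x$x, confounds = x$confounds, precision = P),
            class = "rest_sim")
}
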