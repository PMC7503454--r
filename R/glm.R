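#' Convert raw signal to percent change from the voxel mean
#'
#' Each voxel series `y` becomes `100 * (y / mean(y) - 1)`, so output voxel
#' means are zero and GLM betas are in percent-signal units. Voxels with
#' nonpositive mean are masked out (set to `NA`) and flagged.
#'
#' @param x A `simulated_run`, 4D array, or voxels x time matrix.
#' @return Matrix (voxels x time) with attributes `masked` (logical vector)
#'   and `grid_dim` when the input carried one.
#' @export
to_percent_change <- function(x) {
  Y <- as_voxel_matrix(x)
  m <- rowMeans(Y)
  bad <- !is.finite(m) | m <= 0
  out <- 100 * (Y / m - 1)
  if (any(bad)) out[bad, ] <- NA_real_
  attr(out, "masked") <- bad
  attr(out, "grid_dim") <- attr(Y, "grid_dim")
  out
}

#' Build the GLM design matrix
#'
#' Task regressors are 0/1 block boxcars per condition and hemifield
#' (four per scan type), convolved with the MION kernel. The seventeen
#' nuisance regressors are appended, with all non-motion nuisance columns
#' MION-convolved and the twelve motion columns left unconvolved. Five
#' Legendre drift terms (orders 0-4) computed over the full run timeline
#' implement fourth-order detrending inside the regression. The first
#' `n_discard_trs` rows (magnetization transient) are dropped and rows
#' belonging to excluded blocks are censored.
#'
#' @param events Event table ([design_events()]) or a `scan_design`.
#' @param nuisance Volumes x 17 named nuisance trace matrix.
#' @param kernel MION kernel sampled at the TR.
#' @param scan_type `"GB"` or `"NF"`.
#' @param tr_s,block_s,n_volumes,n_discard_trs Timing; taken from the design
#'   when `events` is a `scan_design`.
#' @param drift_order Legendre detrending order (default 4).
#' @return Object of class `design_matrix`: `X`, kept row indices `rows`,
#'   and column-group names.
#' @export
build_design_matrix <- function(events, nuisance, kernel,
                                scan_type = NULL, tr_s = 2.5, block_s = 30,
                                n_volumes = NULL, n_discard_trs = 3,
                                drift_order = 4) {
  if (inherits(events, "scan_design")) {
    design <- events
    scan_type <- design$scan_type
    tr_s <- design$tr_s; block_s <- design$block_s
    n_volumes <- mionmap::n_volumes(design)
    n_discard_trs <- design$n_discard_trs
    events <- design_events(design)
  }
  stopifnot(!is.null(scan_type), !is.null(n_volumes),
            inherits(kernel, "mion_kernel"))
  if (nrow(nuisance) != n_volumes) {
    stop("nuisance traces must have one row per volume")
  }
  conds <- condition_labels(scan_type)
  known <- c("base", conds)
  if (!all(events$trial_type %in% known)) {
    stop("unknown trial_type for ", scan_type, " scan: ",
         paste(setdiff(events$trial_type, known), collapse = ", "))
  }

  vols_per_block <- as.integer(round(block_s / tr_s))
  vb <- rep(events$block, each = vols_per_block)[seq_len(n_volumes)]
  task <- matrix(0, n_volumes, length(conds), dimnames = list(NULL, conds))
  for (cn in conds) {
    blk <- events$block[events$trial_type == cn]
    task[vb %in% blk, cn] <- 1
  }
  task <- apply(task, 2, mion_convolve, kernel = kernel)

  if (any(apply(nuisance, 2, function(x) all(x == 0)))) {
    zc <- colnames(nuisance)[apply(nuisance, 2, function(x) all(x == 0))]
    stop("all-zero nuisance trace(s) rejected: ", paste(zc, collapse = ", "))
  }
  nuis <- nuisance
  no_conv <- grepl("^motion|^dmotion", colnames(nuis))
  nuis[, !no_conv] <- apply(nuisance[, !no_conv, drop = FALSE], 2,
                            mion_convolve, kernel = kernel)

  drift <- legendre_basis(n_volumes, drift_order)
  X <- cbind(task, nuis, drift)

  excl_blocks <- events$block[events$excluded]
  keep <- seq_len(n_volumes) > n_discard_trs & !(vb %in% excl_blocks)
  rows <- which(keep)
  X <- X[rows, , drop = FALSE]
  if (any(apply(X, 2, function(x) all(x == 0)))) {
    zc <- colnames(X)[apply(X, 2, function(x) all(x == 0))]
    stop("design column(s) identically zero after censoring: ",
         paste(zc, collapse = ", "))
  }
  structure(list(X = X, rows = rows, task_cols = conds,
                 nuisance_cols = colnames(nuisance),
                 drift_cols = colnames(drift),
                 scan_type = scan_type, tr_s = tr_s),
            class = "design_matrix")
}

#' Single-regressor probe-vs-base design
#'
#' Separate regression used for the visual-responsivity betas: one
#' MION-convolved probe-vs-base boxcar plus the same nuisance and drift
#' columns. By construction the visual beta is orthogonal to value,
#' novelty, and hemifield labels (relabeling conditions leaves the
#' regressor unchanged).
#'
#' @inheritParams build_design_matrix
#' @return A `design_matrix` whose single task column is `"probe"`.
#' @export
build_visual_design <- function(events, nuisance, kernel, scan_type = NULL,
                                tr_s = 2.5, block_s = 30, n_volumes = NULL,
                                n_discard_trs = 3, drift_order = 4) {
  if (inherits(events, "scan_design")) {
    design <- events
    tr_s <- design$tr_s; block_s <- design$block_s
    n_volumes <- mionmap::n_volumes(design)
    n_discard_trs <- design$n_discard_trs
    events <- design_events(design)
  }
  stopifnot(!is.null(n_volumes), inherits(kernel, "mion_kernel"))
  if (nrow(nuisance) != n_volumes) {
    stop("nuisance traces must have one row per volume")
  }
  vols_per_block <- as.integer(round(block_s / tr_s))
  vb <- rep(events$block, each = vols_per_block)[seq_len(n_volumes)]
  probe_blocks <- events$block[events$trial_type != "base"]
  probe <- as.numeric(vb %in% probe_blocks)
  probe <- mion_convolve(probe, kernel)

  nuis <- nuisance
  no_conv <- grepl("^motion|^dmotion", colnames(nuis))
  nuis[, !no_conv] <- apply(nuisance[, !no_conv, drop = FALSE], 2,
                            mion_convolve, kernel = kernel)
  drift <- legendre_basis(n_volumes, drift_order)
  X <- cbind(probe = probe, nuis, drift)

  excl_blocks <- events$block[events$excluded]
  keep <- seq_len(n_volumes) > n_discard_trs & !(vb %in% excl_blocks)
  rows <- which(keep)
  structure(list(X = X[rows, , drop = FALSE], rows = rows,
                 task_cols = "probe", nuisance_cols = colnames(nuisance),
                 drift_cols = colnames(drift),
                 scan_type = "visual", tr_s = tr_s),
            class = "design_matrix")
}

#' Fit the voxelwise GLM
#'
#' Ordinary least squares per voxel on the percent-change data, returning
#' betas (percent-signal units), t statistics, residual time series, and
#' residual degrees of freedom. Masked voxels propagate as `NA`.
#'
#' @param data Percent-change data: output of [to_percent_change()], a
#'   `simulated_run` or 4D array (converted automatically), or a voxels x
#'   time matrix already in percent units.
#' @param design A [build_design_matrix()] object.
#' @param percent If `TRUE` (default) convert `data` with
#'   [to_percent_change()] unless it already carries a `masked` attribute.
#' @return Object of class `glm_result`.
#' @export
fit_glm <- function(data, design, percent = TRUE) {
  stopifnot(inherits(design, "design_matrix"))
  if (is.null(attr(data, "masked")) && percent) {
    data <- to_percent_change(data)
  } else {
    data <- as_voxel_matrix(data)
  }
  masked <- attr(data, "masked")
  if (is.null(masked)) masked <- rep(FALSE, nrow(data))
  X <- design$X
  Y <- t(data[, design$rows, drop = FALSE])  # time x voxels

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  ok <- !masked
  beta <- matrix(NA_real_, ncol(X), ncol(Y), dimnames = list(colnames(X), NULL))
  resid <- matrix(NA_real_, nrow(X), ncol(Y))
  beta[, ok] <- qr.coef(qrX, Y[, ok, drop = FALSE])
  resid[, ok] <- qr.resid(qrX, Y[, ok, drop = FALSE])
  dof <- nrow(X) - qrX$rank
  sigma2 <- colSums(resid^2) / dof
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(outer(diag(XtXinv), sigma2))
  tstat <- beta / se

  structure(list(betas = t(beta), se = t(se), tstats = t(tstat),
                 residuals = t(resid), sigma2 = sigma2, dof = dof,
                 xtx_inv = XtXinv, design = design, masked = masked,
                 grid_dim = attr(data, "grid_dim")),
            class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("<glm_result> %d voxels x %d regressors, dof %d\n",
              nrow(x$betas), ncol(x$betas), x$dof))
  invisible(x)
}

#' Contrast specification over task regressors
#'
#' `GB` is mean(good left, good right) - mean(bad left, bad right); `NF` is
#' mean(novel) - mean(familiar). Weights sum to zero. The `visual` contrast
#' is not defined here: it comes from the separate probe-vs-base fit
#' ([build_visual_design()]).
#'
#' @param name `"GB"` or `"NF"`.
#' @return Object of class `contrast_spec` with named `weights`.
#' @export
contrast_spec <- function(name = c("GB", "NF")) {
  name <- match.arg(name)
  w <- if (name == "GB") {
    c(good_left = 0.5, good_right = 0.5, bad_left = -0.5, bad_right = -0.5)
  } else {
    c(novel_left = 0.5, novel_right = 0.5,
      familiar_left = -0.5, familiar_right = -0.5)
  }
  structure(list(name = name, weights = w), class = "contrast_spec")
}

#' Evaluate a contrast on a fitted GLM
#'
#' @param result A [fit_glm()] result.
#' @param spec A [contrast_spec()].
#' @return List of class `contrast_map`: per-voxel `estimate` (percent
#'   units), `se`, `tstat`, `dof`, `name`; carries `grid_dim` when known.
#' @export
contrast_map <- function(result, spec) {
  stopifnot(inherits(result, "glm_result"), inherits(spec, "contrast_spec"))
  cols <- names(spec$weights)
  if (!all(cols %in% colnames(result$betas))) {
    stop(sprintf("contrast %s does not match the fitted scan type (missing: %s)",
                 spec$name,
                 paste(setdiff(cols, colnames(result$betas)), collapse = ", ")))
  }
  w <- spec$weights
  est <- as.vector(result$betas[, cols, drop = FALSE] %*% w)
  idx <- match(cols, colnames(result$betas))
  var_w <- as.numeric(t(w) %*% result$xtx_inv[idx, idx] %*% w)
  se <- sqrt(var_w * result$sigma2)
  structure(list(estimate = est, se = se, tstat = est / se,
                 dof = result$dof, name = spec$name,
                 grid_dim = result$grid_dim),
            class = "contrast_map")
}
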