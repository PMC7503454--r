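#' Per-region averages over the most visually active voxels
#'
#' For each region, ranks voxels by the probe-vs-base visual beta only --
#' a selection orthogonal to value, novelty and hemifield coding -- takes
#' the top `n_top`, and returns the mean and s.e.m. of the GB and NF betas
#' over the selected voxels.
#'
#' @param gb_betas,nf_betas,visual_betas Per-voxel beta vectors (percent
#'   units), equal length.
#' @param labels Integer region labels per voxel (vector or 3D array).
#' @param n_top Voxels per region (default 10); regions with fewer voxels
#'   use all of them (with a warning naming them).
#' @return Data frame: `region`, `n_used`, `mean_gb`, `mean_nf`, `sem_gb`,
#'   `sem_nf`.
#' @export
top_visual_average <- function(gb_betas, nf_betas, visual_betas, labels,
                               n_top = 10) {
  lab <- as.vector(labels)
  stopifnot(length(gb_betas) == length(lab),
            length(nf_betas) == length(lab),
            length(visual_betas) == length(lab), n_top >= 1)
  regions <- sort(unique(lab[lab > 0]))
  short <- integer(0)
  rows <- lapply(regions, function(r) {
    idx <- which(lab == r & is.finite(visual_betas))
    if (length(idx) == 0) return(NULL)
    if (length(idx) < n_top) short <<- c(short, r)
    # ties broken by voxel index for a deterministic selection
    sel <- idx[order(-visual_betas[idx], idx)][seq_len(min(n_top, length(idx)))]
    data.frame(region = r, n_used = length(sel),
               mean_gb = mean(gb_betas[sel]), mean_nf = mean(nf_betas[sel]),
               sem_gb = sem(gb_betas[sel]), sem_nf = sem(nf_betas[sel]))
  })
  empty <- regions[vapply(rows, is.null, logical(1))]
  if (length(empty)) warning("skipping empty region(s): ",
                             paste(empty, collapse = ", "))
  if (length(short)) warning("region(s) with fewer than ", n_top,
                             " voxels use all voxels: ",
                             paste(short, collapse = ", "))
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Fit the joint NF/GB null distribution
#'
#' Bivariate Gaussian fitted to the (GB, NF) beta pairs of all gray-matter
#' voxels regardless of significance: sample mean and covariance.
#'
#' @param gb,nf Per-voxel beta vectors.
#' @param gray Optional logical vector restricting to gray-matter voxels.
#' @return Object of class `joint_null`: `mean` (length 2), `cov` (2 x 2),
#'   `n`.
#' @export
fit_joint_null <- function(gb, nf, gray = NULL) {
  X <- cbind(gb = gb, nf = nf)
  if (!is.null(gray)) X <- X[as.vector(gray), , drop = FALSE]
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 10) stop("need at least 10 gray-matter voxels")
  S <- stats::cov(X)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) {
    stop("singular null covariance (betas lie on a line)")
  }
  structure(list(mean = colMeans(X), cov = S, n = nrow(X)),
            class = "joint_null")
}

#' Classify voxels outside iso-probability contours of the joint null
#'
#' A voxel lies outside the level-`q` contour iff its squared Mahalanobis
#' distance from the null mean exceeds the chi-square (2 d.o.f.) quantile at
#' `q`; the contours are therefore nested (outside-68% contains
#' outside-95%).
#'
#' @param gb,nf Per-voxel beta vectors.
#' @param null A [fit_joint_null()] fit.
#' @param levels Probability masses, strictly increasing in (0, 1);
#'   default `c(0.68, 0.95)`.
#' @param network Optional per-voxel network id (NA = unassigned) for
#'   per-network summaries.
#' @param breaks Number of histogram bins for the marginal summaries.
#' @return List: `outside` (voxels x levels logical), `d2` (squared
#'   Mahalanobis distances), `fractions` (per-network outside fraction per
#'   level), `marginals` (GB and NF histograms of the null input).
#' @export
classify_outside_contour <- function(gb, nf, null, levels = c(0.68, 0.95),
                                     network = NULL, breaks = 30) {
  stopifnot(inherits(null, "joint_null"),
            all(diff(levels) > 0), all(levels > 0), all(levels < 1))
  X <- cbind(gb, nf)
  d2 <- stats::mahalanobis(X, null$mean, null$cov)
  thr <- stats::qchisq(levels, df = 2)
  outside <- outer(d2, thr, `>`)
  colnames(outside) <- paste0("level", levels)
  fractions <- NULL
  if (!is.null(network)) {
    nets <- sort(unique(network[!is.na(network)]))
    fractions <- do.call(rbind, lapply(nets, function(w) {
      idx <- which(network == w)
      data.frame(network = w, level = levels,
                 fraction = colMeans(outside[idx, , drop = FALSE]),
                 n = length(idx))
    }))
  }
  marginals <- list(gb = graphics::hist(gb, breaks = breaks, plot = FALSE),
                    nf = graphics::hist(nf, breaks = breaks, plot = FALSE))
  list(outside = outside, d2 = d2, fractions = fractions,
       marginals = marginals)
}

# Reorder a run's time course so probe blocks follow a canonical
# type order within each cycle (positive valence/novelty first, left before
# right); base blocks keep their positions. Returns voxels x time.
canonicalize_run <- function(run) {
  stopifnot(inherits(run, "simulated_run"))
  design <- run$design
  pct <- to_percent_change(run)
  vb <- volume_blocks(design)
  ev <- design_events(design)
  types <- if (design$scan_type == "GB") c("good", "bad") else
    c("novel", "familiar")
  canon <- as.vector(t(outer(types, c("left", "right"), paste, sep = "_")))
  probe_blocks <- ev$block[ev$block_type == "probe"]
  n_cycles <- length(probe_blocks) / 4
  order_map <- seq_len(design$n_blocks)
  for (cyc in seq_len(n_cycles)) {
    slots <- probe_blocks[(cyc - 1) * 4 + 1:4]
    have <- ev$trial_type[match(slots, ev$block)]
    order_map[slots] <- slots[match(canon, have)]
  }
  new_cols <- unlist(lapply(seq_len(design$n_blocks), function(b) {
    which(vb == order_map[b])
  }))
  pct[, new_cols, drop = FALSE]
}

#' Correlation between canonicalized NF and GB time courses
#'
#' Averages block-order-canonicalized percent-change time courses across NF
#' runs and across GB runs (probe blocks reordered within each cycle to a
#' fixed canonical type sequence, pairing good with novel and bad with
#' familiar), Pearson-correlates the two averages per voxel, and reports
#' per-network mean r with s.e.m. over voxels.
#'
#' @param nf_runs,gb_runs Lists of `simulated_run` objects of the
#'   respective scan types, sharing the voxel grid and run length.
#' @param network Per-voxel network id (vector or 3D array; NA =
#'   unassigned).
#' @return List: `r` (per-voxel correlations), `by_network` (data frame
#'   `network`, `mean_r`, `sem_r`, `n_voxels`).
#' @export
nfgb_timecourse_correlation <- function(nf_runs, gb_runs, network) {
  stopifnot(length(nf_runs) >= 1, length(gb_runs) >= 1)
  avg_runs <- function(runs) {
    mats <- lapply(runs, canonicalize_run)
    nt <- unique(vapply(mats, ncol, integer(1)))
    nv <- unique(vapply(mats, nrow, integer(1)))
    if (length(nt) != 1 || length(nv) != 1) {
      stop("runs have mismatched lengths or voxel grids")
    }
    Reduce(`+`, mats) / length(mats)
  }
  nf_avg <- avg_runs(nf_runs)
  gb_avg <- avg_runs(gb_runs)
  if (!all(dim(nf_avg) == dim(gb_avg))) {
    stop("NF and GB runs have mismatched lengths or voxel grids")
  }
  nv <- nrow(nf_avg)
  r <- vapply(seq_len(nv), function(v) {
    a <- nf_avg[v, ]; b <- gb_avg[v, ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0 || anyNA(a) || anyNA(b)) {
      return(NA_real_)
    }
    stats::cor(a, b)
  }, numeric(1))
  net <- as.vector(network)
  nets <- sort(unique(net[!is.na(net) & net > 0]))
  by_network <- do.call(rbind, lapply(nets, function(w) {
    idx <- which(net == w & is.finite(r))
    data.frame(network = w, mean_r = mean(r[idx]), sem_r = sem(r[idx]),
               n_voxels = length(idx))
  }))
  list(r = r, by_network = by_network)
}
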