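#' Monte-Carlo cluster-simulation configuration
#'
#' @param mask Logical 3D array defining the volume over which clusters are
#'   formed.
#' @param p_voxel Voxelwise two-sided threshold (default 0.001).
#' @param alpha_fwe Familywise error level (default 0.01).
#' @param connectivity Neighborhood: 1 = faces (6 neighbors), 2 = faces +
#'   edges (18), 3 = faces + edges + corners (26).
#' @param n_iter Monte-Carlo iterations (default 10000).
#' @param seed Integer seed.
#' @return Object of class `cluster_sim_config`.
#' @export
cluster_sim_config <- function(mask, p_voxel = 0.001, alpha_fwe = 0.01,
                               connectivity = 1, n_iter = 10000, seed = 1) {
  stopifnot(is.array(mask), length(dim(mask)) == 3, is.logical(mask),
            p_voxel > 0, p_voxel < 1, alpha_fwe > 0, alpha_fwe < 1,
            connectivity %in% 1:3, n_iter >= 1)
  if (!any(mask)) stop("mask must contain at least one voxel")
  structure(list(mask = mask, p_voxel = p_voxel, alpha_fwe = alpha_fwe,
                 connectivity = connectivity, n_iter = n_iter, seed = seed),
            class = "cluster_sim_config")
}

neighbor_offsets <- function(connectivity) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  d <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  lim <- c(1, 2, 3)[connectivity]
  as.matrix(g[d > 0 & d <= lim, ])
}

#' Label connected clusters of a logical volume
#'
#' Connected-component labeling of `TRUE` voxels under the given
#' neighborhood (NN = 1 uses face adjacency only, so diagonally touching
#' voxels form separate clusters).
#'
#' @param flag Logical 3D array.
#' @param connectivity 1, 2 or 3 (see [cluster_sim_config()]).
#' @return List: `labels` (integer array, 0 = background), `sizes`
#'   (voxel count per cluster, decreasing).
#' @export
label_clusters <- function(flag, connectivity = 1) {
  stopifnot(is.array(flag), length(dim(flag)) == 3)
  dims <- dim(flag)
  idx <- which(flag)
  labels <- array(0L, dims)
  if (length(idx) == 0) return(list(labels = labels, sizes = integer(0)))
  coords <- arrayInd(idx, dims)
  rank <- integer(prod(dims))
  rank[idx] <- seq_along(idx)
  off <- neighbor_offsets(connectivity)
  edges <- NULL
  for (k in seq_len(nrow(off))) {
    nb <- sweep(coords, 2, off[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * dims[1] +
      (nb[ok, 3] - 1L) * dims[1] * dims[2]
    j <- rank[lin]
    hit <- j > 0
    if (any(hit)) {
      edges <- rbind(edges, cbind(which(ok)[hit], j[hit]))
    }
  }
  m <- length(idx)
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  labels[idx] <- comp$membership
  sizes <- sort(tabulate(comp$membership), decreasing = TRUE)
  list(labels = labels, sizes = sizes)
}

#' Monte-Carlo cluster-extent threshold
#'
#' Repeatedly simulates null noise fields with the target spatial ACF,
#' applies the two-sided voxelwise threshold inside the mask, labels
#' suprathreshold clusters, and records the maximum cluster size. The
#' minimum cluster size controlling the familywise error at `alpha_fwe` is
#' the point where the empirical survival function of the max size crosses
#' `alpha_fwe`, linearly interpolated (hence possibly fractional); rounding
#' up happens at application time.
#'
#' @param cfg A [cluster_sim_config()].
#' @param params Spatial noise [acf_params()].
#' @return Object of class `cluster_threshold`: fractional `min_voxels`,
#'   integer `min_voxels_int`, the sampled `max_cluster_distribution`, and
#'   the inputs.
#' @export
cluster_extent_threshold <- function(cfg, params) {
  stopifnot(inherits(cfg, "cluster_sim_config"), inherits(params, "acf_params"))
  dims <- dim(cfg$mask)
  S <- acf_spectrum(params, dims)
  zcut <- stats::qnorm(1 - cfg$p_voxel / 2)
  maxsizes <- with_seed(cfg$seed, {
    vapply(seq_len(cfg$n_iter), function(i) {
      w <- array(stats::rnorm(prod(dims)), dim = dims)
      field <- noise_filter(w, S)
      flag <- abs(field) >= zcut & cfg$mask
      if (!any(flag)) return(0L)
      as.integer(label_clusters(flag, cfg$connectivity)$sizes[1])
    }, integer(1))
  })
  surv <- function(s) mean(maxsizes >= s)
  s_int <- 1L
  while (surv(s_int) > cfg$alpha_fwe) s_int <- s_int + 1L
  min_voxels <- if (s_int == 1L) 1 else {
    p0 <- surv(s_int - 1L); p1 <- surv(s_int)
    (s_int - 1L) + (p0 - cfg$alpha_fwe) / (p0 - p1)
  }
  structure(list(min_voxels = min_voxels, min_voxels_int = s_int,
                 max_cluster_distribution = maxsizes,
                 config = cfg, params = params),
            class = "cluster_threshold")
}

#' @export
print.cluster_threshold <- function(x, ...) {
  cat(sprintf(
    "<cluster_threshold> min cluster size %.2f (apply as %d) at p<%g, alpha<%g (%d iters)\n",
    x$min_voxels, x$min_voxels_int, x$config$p_voxel,
    x$config$alpha_fwe, x$config$n_iter))
  invisible(x)
}

#' Apply voxelwise + cluster-extent correction to a statistic map
#'
#' Thresholds `|t|` at the two-sided `p_voxel` quantile of the t
#' distribution with `dof` degrees of freedom, then keeps only voxels in
#' suprathreshold clusters of at least `ceiling(min_voxels)` voxels.
#'
#' @param stat 3D t-statistic array (or z when `dof = Inf`).
#' @param dof Degrees of freedom of the statistic.
#' @param p_voxel Two-sided voxelwise threshold.
#' @param min_voxels Minimum cluster size (possibly fractional; a
#'   `cluster_threshold` object is also accepted).
#' @param connectivity Neighborhood (1-3).
#' @param mask Optional logical array restricting the correction.
#' @return Logical array of surviving voxels.
#' @export
apply_cluster_correction <- function(stat, dof, p_voxel = 0.001, min_voxels,
                                     connectivity = 1, mask = NULL) {
  if (inherits(min_voxels, "cluster_threshold")) {
    min_voxels <- min_voxels$min_voxels
  }
  stopifnot(min_voxels >= 1, is.array(stat), length(dim(stat)) == 3)
  tcut <- if (is.finite(dof)) stats::qt(1 - p_voxel / 2, dof)
          else stats::qnorm(1 - p_voxel / 2)
  flag <- !is.na(stat) & abs(stat) >= tcut
  if (!is.null(mask)) flag <- flag & mask
  lab <- label_clusters(flag, connectivity)
  out <- array(FALSE, dim(stat))
  if (any(flag)) {
    sizes_by_label <- tabulate(lab$labels[lab$labels > 0])
    big <- which(sizes_by_label >= ceiling(min_voxels))
    out[lab$labels %in% big & lab$labels > 0] <- TRUE
  }
  out
}
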