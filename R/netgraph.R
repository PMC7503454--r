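#' Preprocess residual series for resting-state analysis
#'
#' Regresses shared confound traces (white-matter and ventricle means) out
#' of each row, then bandpasses by FFT bin zeroing: Fourier bins whose
#' frequency falls strictly outside `[band[1], band[2]]` Hz are set to zero
#' (the DC bin is always removed), and rows are re-centered.
#'
#' @param x Series x time matrix (regions or voxels), or a `rest_sim`.
#' @param confounds Optional confound traces, one per row (k x time), e.g.
#'   `rest$confounds`.
#' @param band Passband in Hz, `c(low, high)` with
#'   `0 < low < high <= Nyquist`.
#' @param tr_s Sampling interval in seconds.
#' @return Filtered matrix with attribute `tr_s`.
#' @export
preprocess_rest <- function(x, confounds = NULL, band = c(0.01, 0.1),
                            tr_s = 2.5) {
  if (inherits(x, "rest_sim")) {
    if (is.null(confounds)) confounds <- x$confounds
    x <- x$x
  }
  stopifnot(is.matrix(x), length(band) == 2, band[1] > 0, band[1] < band[2])
  nyq <- 1 / (2 * tr_s)
  if (band[2] > nyq + 1e-12) {
    stop(sprintf("band upper edge %.4g Hz exceeds Nyquist %.4g Hz",
                 band[2], nyq))
  }
  n <- ncol(x)
  if (!is.null(confounds)) {
    Z <- cbind(1, t(confounds))
    # row-wise residualization: X - X P' where P is the hat projector
    qz <- qr(Z)
    x <- x - t(qr.fitted(qz, t(x)))
  }
  freqs <- (seq_len(n) - 1) / (n * tr_s)
  freqs <- pmin(freqs, 1 / tr_s - freqs)  # fold to [0, Nyquist]
  keep <- freqs >= band[1] - 1e-12 & freqs <= band[2] + 1e-12
  F <- stats::mvfft(t(x))
  F[!keep, ] <- 0
  out <- t(Re(stats::mvfft(F, inverse = TRUE)) / n)
  out <- out - rowMeans(out)
  dimnames(out) <- dimnames(x)
  attr(out, "tr_s") <- tr_s
  out
}

#' Average voxel series into region series
#'
#' Region series are means over voxels in the intersection of the region
#' label and a significance mask; regions with fewer surviving voxels than
#' `min_voxels` are dropped (with a message listing them).
#'
#' @param x Voxels x time matrix or 4D array.
#' @param labels Integer 3D label array (0 = unlabeled).
#' @param mask Logical 3D array of significant voxels (default: all).
#' @param min_voxels Minimum surviving voxels per region (default 4).
#' @return List: `series` (kept regions x time, rownames `region<i>`),
#'   `kept`, `dropped`.
#' @export
extract_roi_series <- function(x, labels, mask = NULL, min_voxels = 4) {
  V <- as_voxel_matrix(x)
  lab <- as.vector(labels)
  stopifnot(length(lab) == nrow(V))
  m <- if (is.null(mask)) rep(TRUE, nrow(V)) else as.vector(mask)
  regions <- sort(unique(lab[lab > 0]))
  counts <- vapply(regions, function(r) sum(lab == r & m), integer(1))
  kept <- regions[counts >= min_voxels]
  dropped <- regions[counts < min_voxels]
  if (length(kept) == 0) stop("no region has enough significant voxels")
  if (length(dropped)) {
    message("dropping region(s) below ", min_voxels, " voxels: ",
            paste(dropped, collapse = ", "))
  }
  series <- t(vapply(kept, function(r) colMeans(V[lab == r & m, , drop = FALSE]),
                     numeric(ncol(V))))
  rownames(series) <- paste0("region", kept)
  list(series = series, kept = kept, dropped = dropped)
}

# Partial correlation of x1, x2 given columns S, from a correlation matrix.
partial_cor <- function(C, i, j, S) {
  sub <- c(i, j, S)
  Pi <- tryCatch(solve(C[sub, sub, drop = FALSE]),
                 error = function(e) MASS_ginv(C[sub, sub, drop = FALSE]))
  -Pi[1, 2] / sqrt(Pi[1, 1] * Pi[2, 2])
}

MASS_ginv <- function(X) {
  s <- svd(X)
  tol <- max(dim(X)) * max(s$d) * .Machine$double.eps
  pos <- s$d > tol
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# Fisher-z two-sided p for a partial correlation with |S| conditioning vars.
fisher_z_p <- function(r, n, ns) {
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  z <- sqrt(max(n - ns - 3, 1)) * atanh(r)
  2 * stats::pnorm(-abs(z))
}

#' PC-stable skeleton with net partial-correlation edge weights
#'
#' Order-independent constraint-based skeleton estimation: starting from the
#' complete graph, at each depth `l` the neighbor sets are frozen, and every
#' remaining edge (i, j) is tested against all conditioning subsets of size
#' `l` drawn from the frozen neighbors of either endpoint; the edge is
#' removed as soon as one Fisher-z partial-correlation test is
#' nonsignificant at `ci_alpha`. A surviving edge is weighted by the signed
#' partial correlation of smallest magnitude observed across all its tests
#' (its "net" correlation); since an edge is removed at its first
#' nonsignificant test, restricting to significant tests
#' (`weight_from = "significant"`) gives the same weights for survivors.
#'
#' @param x Regions x time matrix (rownames used as node names) or
#'   `rest_sim`.
#' @param ci_alpha Significance level of the conditional-independence tests.
#' @param weight_from `"all"` (default) or `"significant"`.
#' @param max_order Optional cap on conditioning-set size (default
#'   unlimited).
#' @return An [igraph][igraph::igraph-package] undirected graph with edge
#'   attributes `weight` (net partial correlation) and `p` (p-value of the
#'   weight-defining test), and graph attributes `ci_alpha` and `n`.
#' @export
pc_stable_skeleton <- function(x, ci_alpha = 0.01,
                               weight_from = c("all", "significant"),
                               max_order = Inf) {
  weight_from <- match.arg(weight_from)
  if (inherits(x, "rest_sim")) x <- x$x
  stopifnot(is.matrix(x), ci_alpha > 0, ci_alpha < 1)
  p <- nrow(x); n <- ncol(x)
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate (constant) node series: ",
         paste(rownames(x)[sds == 0], collapse = ", "))
  }
  nodes <- rownames(x)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(p))
  C <- stats::cor(t(x))

  adj <- matrix(TRUE, p, p); diag(adj) <- FALSE
  wmat <- matrix(Inf, p, p)   # min |partial correlation| so far
  wsgn <- matrix(NA_real_, p, p)
  wp <- matrix(NA_real_, p, p)

  record <- function(i, j, r, pv) {
    if (abs(r) < wmat[i, j]) {
      wmat[i, j] <<- wmat[j, i] <<- abs(r)
      wsgn[i, j] <<- wsgn[j, i] <<- r
      wp[i, j] <<- wp[j, i] <<- pv
    }
  }

  l <- 0L
  repeat {
    if (l > max_order) break
    frozen <- adj  # PC-stable: conditioning candidates fixed at depth start
    any_testable <- FALSE
    pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (!adj[i, j]) next  # removed earlier at this depth
      for (side in list(c(i, j), c(j, i))) {
        a <- side[1]; b <- side[2]
        cand <- which(frozen[a, ] & seq_len(p) != b)
        if (length(cand) < l) next
        any_testable <- TRUE
        subsets <- if (l == 0L) list(integer(0)) else
          utils::combn(cand, l, simplify = FALSE)
        for (S in subsets) {
          r <- partial_cor(C, a, b, S)
          pv <- fisher_z_p(r, n, length(S))
          if (weight_from == "all" || pv <= ci_alpha) record(i, j, r, pv)
          if (pv > ci_alpha) {
            adj[i, j] <- adj[j, i] <- FALSE
            break
          }
        }
        if (!adj[i, j]) break
      }
    }
    if (!any_testable) break
    l <- l + 1L
  }

  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = p, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, t(edges),
                           attr = list(weight = wsgn[edges],
                                       p = wp[edges]))
  }
  g <- igraph::set_graph_attr(g, "ci_alpha", ci_alpha)
  igraph::set_graph_attr(g, "n", n)
}

#' Largest connected component of a graph
#'
#' @param g An igraph graph.
#' @return The induced subgraph on the largest connected node set; ties are
#'   broken toward the component containing the smallest node index. An
#'   edgeless graph collapses to a single node (with a warning).
#' @export
largest_component <- function(g) {
  stopifnot(igraph::vcount(g) > 0)
  comp <- igraph::components(g)
  best_size <- max(comp$csize)
  cand <- which(comp$csize == best_size)
  first_member <- vapply(cand, function(cc) min(which(comp$membership == cc)),
                         integer(1))
  pick <- cand[which.min(first_member)]
  if (best_size == 1 && igraph::vcount(g) > 1) {
    warning("graph has no edges; largest component is a single node")
  }
  igraph::induced_subgraph(g, which(comp$membership == pick))
}

# k-means++ center selection (seeded by the caller's RNG state)
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((X - matrix(X[centers[1], ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1] <- sample.int(n, 1, prob = prob)
    d2 <- pmin(d2, rowSums((X - matrix(X[centers[j + 1], ], n, ncol(X),
                                       byrow = TRUE))^2))
  }
  X[centers, , drop = FALSE]
}

#' Spectral partition of a connectivity graph
#'
#' Symmetric normalized Laplacian on absolute edge weights, embedding on the
#' `k` eigenvectors of smallest eigenvalue, row normalization, then k-means
#' with seeded k-means++ initialization and `n_restarts` restarts (best
#' within-cluster inertia wins).
#'
#' @param g Weighted undirected igraph (e.g. from [pc_stable_skeleton()]).
#' @param k Number of networks (default 4).
#' @param seed Integer seed for the k-means restarts.
#' @param n_restarts Number of k-means++ restarts (default 50).
#' @return Object of class `network_partition`: `assignment` (named integer
#'   vector), `k`, `embedding`, `eigenvalues`, `inertia`.
#' @export
spectral_partition <- function(g, k = 4, seed = 1, n_restarts = 50) {
  p <- igraph::vcount(g)
  if (p < k) stop(sprintf("component size %d is smaller than k = %d", p, k))
  W <- abs(as.matrix(igraph::as_adjacency_matrix(g, attr = "weight",
                                                 sparse = FALSE)))
  d <- rowSums(W)
  d[d == 0] <- 1e-12
  Dm <- 1 / sqrt(d)
  L <- diag(p) - (Dm %o% Dm) * W
  ei <- eigen((L + t(L)) / 2, symmetric = TRUE)
  emb <- ei$vectors[, p - seq_len(k) + 1, drop = FALSE]  # k smallest
  rn <- sqrt(rowSums(emb^2))
  rn[rn == 0] <- 1
  emb <- emb / rn

  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      centers <- kmeanspp_centers(emb, k)
      km <- tryCatch(
        stats::kmeans(emb, centers = centers, iter.max = 100,
                      algorithm = "Lloyd"),
        error = function(e) NULL, warning = function(w) {
          suppressWarnings(stats::kmeans(emb, centers = centers,
                                         iter.max = 200,
                                         algorithm = "Lloyd"))
        })
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  if (is.null(best)) stop("k-means failed for every restart")
  assignment <- best$cluster
  names(assignment) <- igraph::V(g)$name
  structure(list(assignment = assignment, k = k, embedding = emb,
                 eigenvalues = rev(ei$values)[seq_len(k)],
                 inertia = best$tot.withinss),
            class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  cat(sprintf("<network_partition> %d nodes into %d clusters (inertia %.3g)\n",
              length(x$assignment), x$k, x$inertia))
  print(table(cluster = x$assignment))
  invisible(x)
}

#' Correlate network centroids with target voxels
#'
#' For each cluster of the partition, averages its member node series into a
#' representative centroid, computes the Pearson correlation of every voxel
#' of the target region with the centroid, thresholds the t transform of r
#' at `p_voxel` (two-sided), and applies cluster-extent correction within
#' the target mask.
#'
#' @param partition A [spectral_partition()] result.
#' @param node_series Regions x time matrix used for the partition (rownames
#'   matching the partition's node names).
#' @param voxel_series Voxels x time matrix or 4D array of target voxels.
#' @param target_mask Logical 3D array selecting target (e.g. subcortical)
#'   voxels.
#' @param p_voxel Two-sided voxelwise threshold (default 0.001).
#' @param min_voxels Cluster-extent threshold (number or
#'   `cluster_threshold`).
#' @param connectivity Neighborhood (default 1).
#' @return List per cluster: `r` (3D array, NA outside the mask),
#'   `surviving` (logical array).
#' @export
seed_correlation_map <- function(partition, node_series, voxel_series,
                                 target_mask, p_voxel = 0.001,
                                 min_voxels = 1, connectivity = 1) {
  stopifnot(inherits(partition, "network_partition"))
  if (!any(target_mask)) stop("target mask is empty")
  V <- as_voxel_matrix(voxel_series)
  dims <- dim(target_mask)
  stopifnot(prod(dims) == nrow(V))
  n <- ncol(V)
  out <- list()
  for (cl in sort(unique(partition$assignment))) {
    members <- names(partition$assignment)[partition$assignment == cl]
    centroid <- colMeans(node_series[members, , drop = FALSE])
    idx <- which(as.vector(target_mask))
    r <- suppressWarnings(as.vector(stats::cor(t(V[idx, , drop = FALSE]),
                                               centroid)))
    r[is.na(r)] <- 0
    rmap <- array(NA_real_, dims)
    rmap[idx] <- r
    tmap <- array(NA_real_, dims)
    tmap[idx] <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
    surv <- apply_cluster_correction(tmap, dof = n - 2, p_voxel = p_voxel,
                                     min_voxels = min_voxels,
                                     connectivity = connectivity,
                                     mask = target_mask)
    out[[paste0("cluster", cl)]] <- list(r = rmap, surviving = surv)
  }
  out
}

#' Write a connectivity graph as edge-list TSV
#' @param g Graph from [pc_stable_skeleton()].
#' @param path Output path.
#' @export
write_graph_tsv <- function(g, path) {
  el <- igraph::as_edgelist(g)
  df <- data.frame(node_a = el[, 1], node_b = el[, 2],
                   weight = igraph::E(g)$weight,
                   min_test_p = igraph::E(g)$p)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
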