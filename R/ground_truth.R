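#' Planted multi-network precision matrix
#'
#' Sparse symmetric positive-definite precision over regions encoding a
#' block (network) structure: unit diagonal, a common negative off-diagonal
#' entry within each network (positive partial correlation `within`), and a
#' ring of single weak bridges between consecutive networks (partial
#' correlation `between`) so the conditional-independence graph is connected.
#'
#' @param n_networks Number of networks.
#' @param regions_per_network Regions in each network.
#' @param within Within-network partial correlation (0-1).
#' @param between Bridge partial correlation between consecutive networks.
#' @return Precision matrix with attributes `network` (region to network id)
#'   and `skeleton` (logical adjacency of the conditional-independence graph).
#' @export
planted_network_precision <- function(n_networks = 4, regions_per_network = 6,
                                      within = 0.15, between = 0.1) {
  p <- n_networks * regions_per_network
  P <- diag(p)
  net <- rep(seq_len(n_networks), each = regions_per_network)
  for (k in seq_len(n_networks)) {
    idx <- which(net == k)
    P[idx, idx] <- -within
    diag(P)[idx] <- 1
  }
  # single bridge between last region of network k and first of network k+1
  if (n_networks > 1) {
    for (k in seq_len(n_networks - 1)) {
      i <- max(which(net == k)); j <- min(which(net == k + 1))
      P[i, j] <- P[j, i] <- -between
    }
  }
  ev <- min(eigen(P, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-8) stop("planted precision not positive definite; reduce 'within'")
  attr(P, "network") <- net
  attr(P, "skeleton") <- P != 0 & !diag(p)
  P
}

#' Default planted per-network effect sizes
#'
#' Percent-signal effects of the order of 0.1% of the mean signal: a
#' visually driven occipital network with no differential coding, a
#' temporal-prefrontal network coding both value and novelty, a ventral
#' network biased to novelty, and a parietal network biased to value.
#'
#' @param n_networks Number of networks (effects recycle beyond 4).
#' @return Data frame with columns `network`, `visual`, `gb`, `nf`,
#'   `contra_bias` (percent units except the bias fraction).
#' @export
default_network_effects <- function(n_networks = 4) {
  base <- data.frame(
    network = 1:4,
    visual = c(0.5, 0.3, 0.3, 0.3),
    gb = c(0, 0.1, 0.05, 0.1),
    nf = c(0, 0.1, 0.1, 0.05),
    contra_bias = c(0, 0, 0, 0)
  )
  base[((seq_len(n_networks) - 1) %% 4) + 1, , drop = FALSE] |>
    transform(network = seq_len(n_networks))
}

# Partition the grid into n_regions contiguous boxes; returns integer array.
region_label_grid <- function(grid_dim, n_regions) {
  # split factors as close to balanced as possible, x split first so the
  # left/right hemisphere boundary falls between regions
  fx <- max(2L, 2L * floor(sqrt(n_regions / 4)))
  while (n_regions %% fx != 0) fx <- fx - 2L
  if (fx < 2L) fx <- 2L
  rest <- n_regions / fx
  fy <- floor(sqrt(rest))
  while (rest %% fy != 0) fy <- fy - 1L
  fz <- rest / fy
  cut_idx <- function(n, f) pmin(f, ceiling(seq_len(n) / (n / f)))
  cx <- cut_idx(grid_dim[1], fx)
  cy <- cut_idx(grid_dim[2], fy)
  cz <- cut_idx(grid_dim[3], fz)
  lab <- array(0L, dim = grid_dim)
  for (i in seq_len(grid_dim[1])) for (j in seq_len(grid_dim[2])) {
    lab[i, j, ] <- (cx[i] - 1L) * fy * fz + (cy[j] - 1L) * fz + cz
  }
  left_frac <- tapply(rep(cx, times = prod(grid_dim[2:3])) <= fx / 2,
                      factor(as.vector(lab), levels = seq_len(n_regions)),
                      mean)
  attr(lab, "hemisphere") <- unname(ifelse(left_frac > 0.5, "left", "right"))
  lab
}

#' Ground truth for synthetic task and rest runs
#'
#' Bundles everything the generators need: a voxel grid with integer region
#' labels, the region-to-network map, planted percent-signal effects per
#' network, a sparse precision matrix governing resting covariance, the
#' spatial noise ACF, and the temporal signal-to-noise target.
#'
#' @param grid_dim Voxel grid dimensions.
#' @param n_networks Number of functional networks.
#' @param regions_per_network Regions per network.
#' @param effects Data frame as from [default_network_effects()].
#' @param rest_precision Precision matrix over regions; default
#'   [planted_network_precision()].
#' @param acf Spatial noise ACF ([acf_params()]).
#' @param tsnr Temporal signal-to-noise target (voxel mean over noise SD).
#' @param baseline Raw-signal baseline (arbitrary units).
#' @param nuisance_loadings Length-17 percent-signal loadings of the nuisance
#'   traces onto every labeled voxel; default all zero.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(grid_dim = c(24, 24, 16), n_networks = 4,
                         regions_per_network = 6,
                         effects = default_network_effects(n_networks),
                         rest_precision = planted_network_precision(
                           n_networks, regions_per_network),
                         acf = acf_params(0.97, 1.10, 9.01),
                         tsnr = 25, baseline = 1000,
                         nuisance_loadings = rep(0, 17)) {
  n_regions <- n_networks * regions_per_network
  stopifnot(nrow(rest_precision) == n_regions,
            isTRUE(all.equal(rest_precision, t(rest_precision))),
            length(nuisance_loadings) == 17, tsnr > 0, baseline > 0)
  ev <- min(eigen(rest_precision, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop("rest_precision must be positive definite")
  labels <- region_label_grid(grid_dim, n_regions)
  network_of_region <- rep(seq_len(n_networks), each = regions_per_network)
  structure(list(
    grid_dim = grid_dim, labels = labels,
    hemisphere = attr(labels, "hemisphere"),
    n_networks = n_networks, n_regions = n_regions,
    network_of_region = network_of_region,
    effects = effects, rest_precision = rest_precision,
    acf = acf, tsnr = tsnr, baseline = baseline,
    nuisance_loadings = nuisance_loadings
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> grid %s, %d regions in %d networks, tSNR %g\n",
              paste(x$grid_dim, collapse = "x"), x$n_regions,
              x$n_networks, x$tsnr))
  invisible(x)
}

# Percent-signal effect of one condition for every region.
# type: good/bad/novel/familiar; hemifield: left/right.
region_condition_effect <- function(truth, type, hemifield) {
  eff <- truth$effects
  net <- truth$network_of_region
  contrast <- if (type %in% c("good", "bad")) eff$gb[net] else eff$nf[net]
  sign <- if (type %in% c("good", "novel")) 1 else -1
  base <- eff$visual[net] + sign * contrast / 2
  bias <- eff$contra_bias[net]
  contra <- (truth$hemisphere == "left") == (hemifield == "right")
  base * ifelse(contra, 1 + bias, 1 - bias)
}
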