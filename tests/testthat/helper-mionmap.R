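# Shared fixtures, all generated in code.

# Small ground truth for fast task-run tests: 600-voxel grid, 4 single-
# region networks, GB effect planted in network 2 only.
small_truth <- function(grid_dim = c(10, 10, 6), tsnr = 25,
                        effects = NULL) {
  if (is.null(effects)) {
    effects <- data.frame(network = 1:4,
                          visual = c(0.5, 0.3, 0.3, 0.3),
                          gb = c(0, 0.1, 0, 0.1),
                          nf = c(0, 0.1, 0.1, 0),
                          contra_bias = 0)
  }
  ground_truth(grid_dim = grid_dim, n_networks = 4, regions_per_network = 1,
               effects = effects,
               rest_precision = planted_network_precision(4, 1, within = 0,
                                                          between = 0.1),
               acf = acf_params(0.9, 1.0, 3.0), tsnr = tsnr)
}

# Concatenated input matrix for n GB runs followed by n NF runs.
dcm_concat_inputs <- function(n_each, seed0 = 0) {
  do.call(cbind, c(
    lapply(seq_len(n_each),
           function(i) dcm_input_matrix(make_design("GB", seed0 + i))),
    lapply(seq_len(n_each),
           function(i) dcm_input_matrix(make_design("NF", seed0 + 50 + i)))))
}

# Exhaustive flood-fill connected-components oracle for small grids.
floodfill_sizes <- function(flag, connectivity) {
  dims <- dim(flag)
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[rowSums(abs(off)) > 0 & rowSums(abs(off)) <= connectivity, ]
  visited <- array(FALSE, dims)
  sizes <- integer(0)
  for (start in which(flag)) {
    if (visited[start]) next
    queue <- start
    visited[start] <- TRUE
    size <- 0L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      size <- size + 1L
      co <- arrayInd(v, dims)
      for (r in seq_len(nrow(off))) {
        nb <- co + as.numeric(off[r, ])
        if (any(nb < 1) || any(nb > dims)) next
        lin <- nb[1] + (nb[2] - 1) * dims[1] + (nb[3] - 1) * dims[1] * dims[2]
        if (flag[lin] && !visited[lin]) {
          visited[lin] <- TRUE
          queue <- c(queue, lin)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sort(sizes, decreasing = TRUE)
}

# All-subsets conditional-independence oracle for the skeleton of a small
# Gaussian data set: edge (i, j) present iff every partial correlation of
# (i, j) given any subset of the remaining nodes is significant.
brute_force_skeleton <- function(x, alpha) {
  p <- nrow(x); n <- ncol(x)
  C <- stats::cor(t(x))
  adj <- matrix(FALSE, p, p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    others <- setdiff(seq_len(p), c(i, j))
    keep <- TRUE
    for (size in 0:length(others)) {
      subsets <- if (size == 0) list(integer(0)) else
        utils::combn(others, size, simplify = FALSE)
      for (S in subsets) {
        sub <- c(i, j, S)
        Pi <- solve(C[sub, sub])
        r <- -Pi[1, 2] / sqrt(Pi[1, 1] * Pi[2, 2])
        r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
        z <- sqrt(n - size - 3) * atanh(r)
        if (2 * stats::pnorm(-abs(z)) > alpha) { keep <- FALSE; break }
      }
      if (!keep) break
    }
    adj[i, j] <- adj[j, i] <- keep
  }
  adj
}

# Random 5-node Gaussian graphical model with edges strong enough that the
# conditional-independence structure is detectable given every subset:
# models whose weakest edge-wise partial correlation (over all conditioning
# subsets) falls below `min_strength` are redrawn.
random_strong_ggm <- function(seed, p = 5, min_strength = 0.2) {
  set.seed(seed)
  repeat {
    A <- matrix(0, p, p)
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      if (stats::runif(1) < 0.4) {
        A[i, j] <- A[j, i] <- sample(c(-1, 1), 1) * stats::runif(1, 0.3, 0.5)
      }
    }
    P <- A
    diag(P) <- 1.05 * pmax(rowSums(abs(A)), 1)
    C <- stats::cov2cor(solve(P))
    skel <- A != 0
    if (!any(skel)) next
    ok <- TRUE
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      if (!skel[i, j]) next
      others <- setdiff(seq_len(p), c(i, j))
      for (size in 0:length(others)) {
        subsets <- if (size == 0) list(integer(0)) else
          utils::combn(others, size, simplify = FALSE)
        for (S in subsets) {
          sub <- c(i, j, S)
          Pi <- solve(C[sub, sub])
          r <- -Pi[1, 2] / sqrt(Pi[1, 1] * Pi[2, 2])
          if (abs(r) < min_strength) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (!ok) break
    }
    if (ok) return(list(precision = P, sigma = solve(P), skeleton = skel))
  }
}

sample_mvn <- function(sigma, n, seed) {
  set.seed(seed)
  R <- chol(sigma)
  t(R) %*% matrix(stats::rnorm(nrow(sigma) * n), nrow(sigma), n)
}
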