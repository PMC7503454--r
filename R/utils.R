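#' @keywords internal
"_PACKAGE"

#' @importFrom Rcpp sourceCpp
#' @useDynLib mionmap, .registration = TRUE
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library functions never clobber user RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# First five Legendre polynomials P0..P4 evaluated on x in [-1, 1];
# columns are the drift regressors used for fourth-order detrending.
legendre_basis <- function(n, order = 4) {
  stopifnot(n >= 2, order >= 0)
  x <- seq(-1, 1, length.out = n)
  P <- matrix(0, n, order + 1)
  P[, 1] <- 1
  if (order >= 1) P[, 2] <- x
  if (order >= 2) {
    for (k in 2:order) {
      # (k) P_k = (2k-1) x P_{k-1} - (k-1) P_{k-2}
      P[, k + 1] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1]) / k
    }
  }
  colnames(P) <- paste0("drift", 0:order)
  P
}

# Causal discrete convolution of a regressor with a sampled kernel,
# truncated to the length of the input.
convolve_causal <- function(x, kernel) {
  n <- length(x)
  out <- stats::convolve(x, rev(kernel), type = "open")[seq_len(n)]
  out
}

# Flatten a 4D (x,y,z,t) array into voxels x time, remembering the grid.
flatten_bold <- function(bold) {
  d <- dim(bold)
  stopifnot(length(d) == 4)
  mat <- matrix(bold, nrow = prod(d[1:3]), ncol = d[4])
  attr(mat, "grid_dim") <- d[1:3]
  mat
}

# Accept a simulated_run, a 4D array, or a voxels x time matrix.
as_voxel_matrix <- function(x) {
  if (inherits(x, "simulated_run")) x <- x$bold
  if (is.array(x) && length(dim(x)) == 4) return(flatten_bold(x))
  if (is.matrix(x)) return(x)
  stop("expected a simulated_run, a 4D array, or a voxels x time matrix")
}

sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(0)
  stats::sd(x) / sqrt(length(x))
}
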