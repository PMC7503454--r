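test_that("bandpass filtering passes the band and kills the stopband", {
  tr_s <- 2.5
  n <- 160  # 400 s: both test frequencies fall on Fourier bins
  t <- (0:(n - 1)) * tr_s
  x <- rbind(sin(2 * pi * 0.05 * t), cos(2 * pi * 0.2 * t),
             sin(2 * pi * 0.15 * t))
  out <- preprocess_rest(x, band = c(0.01, 0.1), tr_s = tr_s)
  expect_gte(stats::sd(out[1, ]) / stats::sd(x[1, ]), 0.99)
  # 0.2 Hz is the Nyquist bin at TR 2.5 (cosine phase keeps it nonzero)
  expect_lte(max(abs(out[2, ])) / max(abs(x[2, ])), 1e-6)
  expect_lte(max(abs(out[3, ])) / max(abs(x[3, ])), 1e-6)
  expect_error(preprocess_rest(x, band = c(0.01, 0.3), tr_s = tr_s),
               "Nyquist")
})

test_that("confound regression projects shared signals out", {
  set.seed(1)
  n <- 200
  conf <- matrix(stats::rnorm(2 * n), 2)
  x <- rbind(conf[1, ], conf[1, ] * 0.5 + conf[2, ] * 0.5)
  out <- preprocess_rest(x, confounds = conf, band = c(0.01, 0.1), tr_s = 2.5)
  expect_lt(max(abs(out)), 1e-8)
})

test_that("ROI extraction averages voxels and drops sparse regions", {
  labels <- array(0L, c(4, 4, 2))
  labels[1:2, , 1] <- 1L
  labels[3:4, , 1] <- 2L
  nvox <- prod(dim(labels))
  V <- matrix(stats::rnorm(nvox * 30), nvox, 30)
  # region 2 keeps only 3 significant voxels -> dropped at min_voxels = 4
  mask <- array(FALSE, dim(labels))
  mask[labels == 1] <- TRUE
  mask[which(labels == 2)[1:3]] <- TRUE
  expect_message(out <- extract_roi_series(V, labels, mask, min_voxels = 4),
                 "dropping")
  expect_identical(out$kept, 1L)
  expect_identical(out$dropped, 2L)
  # a region of identical voxels reproduces that voxel's series
  V2 <- V
  idx1 <- which(as.vector(labels) == 1)
  V2[idx1, ] <- rep(V2[idx1[1], ], each = length(idx1))
  out2 <- extract_roi_series(V2, labels, min_voxels = 1)
  expect_equal(out2$series["region1", ], V2[idx1[1], ], ignore_attr = TRUE)
  expect_error(extract_roi_series(V, labels, array(FALSE, dim(labels))),
               "no region")
})

test_that("exactly orthogonal series give an empty skeleton", {
  q <- qr.Q(qr(matrix(stats::rnorm(200 * 3), 200, 3)))
  g <- pc_stable_skeleton(t(q), ci_alpha = 0.01)
  expect_equal(igraph::ecount(g), 0)
})

test_that("a Gaussian chain recovers X-Y, Y-Z without the X-Z edge", {
  P <- rbind(c(1, -0.4, 0), c(-0.4, 1, -0.4), c(0, -0.4, 1))
  rest <- simulate_rest(P, 2000, seed = 4)
  g <- pc_stable_skeleton(rest$x, ci_alpha = 0.01)
  el <- apply(igraph::as_edgelist(g), 1, paste, collapse = "-")
  expect_setequal(el, c("region1-region2", "region2-region3"))
  # edge weights are signed net partial correlations inside (-1, 1)
  expect_true(all(abs(igraph::E(g)$weight) < 1))
  expect_true(all(igraph::E(g)$weight > 0))  # attractive precision coupling
})

test_that("the skeleton is invariant to node ordering", {
  m <- random_strong_ggm(101)
  x <- sample_mvn(m$sigma, 1500, seed = 7)
  rownames(x) <- paste0("V", 1:5)
  g1 <- pc_stable_skeleton(x, ci_alpha = 0.01)
  perm <- c(4, 2, 5, 1, 3)
  g2 <- pc_stable_skeleton(x[perm, ], ci_alpha = 0.01)
  e1 <- apply(igraph::as_edgelist(g1), 1, function(r) paste(sort(r), collapse = "-"))
  e2 <- apply(igraph::as_edgelist(g2), 1, function(r) paste(sort(r), collapse = "-"))
  expect_setequal(e1, e2)
})

test_that("constant node series are rejected by name", {
  x <- matrix(stats::rnorm(40), 4, 10)
  x[3, ] <- 2
  rownames(x) <- paste0("node", 1:4)
  expect_error(pc_stable_skeleton(x), "node3")
})

test_that("the largest component is selected with deterministic tie-breaks", {
  g <- igraph::make_graph(~ a - b, a - c, b - c, d - e, d - f, e - f, g - h)
  lc <- largest_component(g)
  expect_setequal(igraph::V(lc)$name, c("a", "b", "c"))
  g2 <- igraph::make_empty_graph(3, directed = FALSE)
  expect_warning(lc2 <- largest_component(g2), "no edges")
  expect_equal(igraph::vcount(lc2), 1)
})

test_that("spectral partitioning splits disconnected cliques and planted blocks", {
  # two 4-cliques joined only within themselves
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 0.5; A[5:8, 5:8] <- 0.5
  diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A, "undirected", weighted = TRUE)
  igraph::V(g)$name <- paste0("n", 1:8)
  part <- spectral_partition(g, k = 2, seed = 1)
  expect_identical(length(unique(part$assignment[1:4])), 1L)
  expect_identical(length(unique(part$assignment[5:8])), 1L)
  expect_false(part$assignment[1] == part$assignment[5])

  # planted 4-block structure: within 0.6, between 0.05
  set.seed(2)
  truth <- rep(1:4, each = 5)
  W <- matrix(0.05, 20, 20)
  for (b in 1:4) W[truth == b, truth == b] <- 0.6
  diag(W) <- 0
  gp <- igraph::graph_from_adjacency_matrix(W, "undirected", weighted = TRUE)
  igraph::V(gp)$name <- paste0("r", 1:20)
  p1 <- spectral_partition(gp, k = 4, seed = 3)
  expect_equal(mclust::adjustedRandIndex(p1$assignment, truth), 1)
  # identical seeds agree exactly; different seeds agree up to labels
  p2 <- spectral_partition(gp, k = 4, seed = 3)
  expect_identical(p1$assignment, p2$assignment)
  p3 <- spectral_partition(gp, k = 4, seed = 99)
  expect_gte(mclust::adjustedRandIndex(p1$assignment, p3$assignment), 0.9)
  expect_error(spectral_partition(gp, k = 25), "smaller than k")
})

test_that("seed correlation maps are exact for self-correlation and sign flips", {
  set.seed(5)
  nodes <- matrix(stats::rnorm(4 * 300), 4, 300,
                  dimnames = list(paste0("region", 1:4), NULL))
  part <- structure(list(assignment = c(region1 = 1L, region2 = 1L,
                                        region3 = 2L, region4 = 2L),
                         k = 2L), class = "network_partition")
  dims <- c(3, 3, 2)
  centroid1 <- colMeans(nodes[1:2, ])
  V <- matrix(stats::rnorm(prod(dims) * 300), prod(dims), 300)
  V[1, ] <- centroid1
  V[2, ] <- -centroid1
  mask <- array(TRUE, dims)
  out <- seed_correlation_map(part, nodes, V, mask, min_voxels = 1)
  expect_equal(out$cluster1$r[1], 1, tolerance = 1e-12)
  expect_equal(out$cluster1$r[2], -1, tolerance = 1e-12)
  expect_true(out$cluster1$surviving[1])
  # independent-noise voxels rarely survive the correction
  expect_lte(mean(out$cluster2$surviving[-(1:2)]), 0.05)
  expect_error(seed_correlation_map(part, nodes, V, array(FALSE, dims)),
               "empty")
})

test_that("graph export writes a well-formed edge list", {
  P <- rbind(c(1, -0.4, 0), c(-0.4, 1, -0.4), c(0, -0.4, 1))
  g <- pc_stable_skeleton(simulate_rest(P, 1000, seed = 1)$x, ci_alpha = 0.01)
  tmp <- tempfile(fileext = ".tsv")
  write_graph_tsv(g, tmp)
  df <- utils::read.table(tmp, header = TRUE, sep = "\t")
  expect_identical(names(df), c("node_a", "node_b", "weight", "min_test_p"))
  expect_equal(nrow(df), as.integer(igraph::ecount(g)))
})
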