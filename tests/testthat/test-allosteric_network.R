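test_that("generalized correlation hits its analytic limits", {
  ## independent Gaussian fluctuations: R_MI near 0
  set.seed(31)
  frames <- lapply(1:4000, function(f) matrix(rnorm(9), 3, 3))
  tj <- trajectory_ensemble(frames)
  R <- generalized_correlation(tj, superpose = FALSE)$matrices[[1]]
  expect_lt(max(R[upper.tri(R)]), 0.1)
  expect_equal(diag(R), rep(1, 3))

  ## residue 2 an exact copy of residue 1: R_MI = 1 (capped)
  frames2 <- lapply(1:500, function(f) {
    x <- rnorm(3)
    rbind(x, x, rnorm(3))
  })
  R2 <- generalized_correlation(trajectory_ensemble(frames2),
                                superpose = FALSE)$matrices[[1]]
  expect_gt(R2[1, 2], 0.999)

  ## 1D jointly Gaussian pair with rho = 0.8: I = -log(1 - rho^2) / 2 and
  ## R_MI = |rho| under the Gaussian estimator with d = 1
  set.seed(32)
  x <- rnorm(20000)
  y <- 0.8 * x + sqrt(1 - 0.64) * rnorm(20000)
  S <- stats::cov(cbind(x, y))
  I <- allokit:::gaussian_mi_pair(S[1, 1, drop = FALSE],
                                  S[2, 2, drop = FALSE],
                                  S[1, 2, drop = FALSE], d = 1)
  expect_equal(I, -0.5 * log(1 - 0.8^2), tolerance = 0.02)
  expect_equal(sqrt(1 - exp(-2 * I)), 0.8, tolerance = 0.01)
})

test_that("network edges require R_MI strictly above threshold in any simulation", {
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- 0.5          # exactly at threshold: excluded
  R[1, 3] <- R[3, 1] <- 0.5 + 1e-6
  R[2, 3] <- R[3, 2] <- 1            # weight 0 allowed
  g <- build_network(R, threshold = 0.5)
  e <- g$edges
  expect_false(any(e$i == 1 & e$j == 2))
  expect_equal(e$weight[e$i == 1 & e$j == 3], -log(0.5 + 1e-6),
               tolerance = 1e-9)
  expect_equal(e$weight[e$i == 2 & e$j == 3], -log(1 - 1e-12))

  ## max over the simulation stack decides
  R1 <- diag(3); R2 <- diag(3)
  R2[1, 2] <- R2[2, 1] <- 0.9
  stack <- structure(list(matrices = list(R1, R2), estimator = "gaussian",
                          composite = FALSE, d = 3), class = "rmi_stack")
  g2 <- build_network(stack)
  expect_true(any(g2$edges$i == 1 & g2$edges$j == 2))

  ## contact gating removes non-contact pairs
  cm <- compute_contact_map(ca_structure_model(
    rbind(c(0, 0, 0), c(4, 0, 0), c(50, 0, 0))), 5, "ca-ca")
  R3 <- matrix(0.9, 3, 3); diag(R3) <- 1
  g3 <- build_network(R3, contacts = cm)
  expect_equal(nrow(g3$edges), 1)
})

test_that("Floyd-Warshall distances are exact on hand-checked and random graphs", {
  ## triangle with weights 1, 1, 3: opposite corner reached through middle
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- exp(-1)
  R[2, 3] <- R[3, 2] <- exp(-1)
  R[1, 3] <- R[3, 1] <- exp(-3)
  g <- build_network(R, threshold = 0)
  sp <- all_shortest_paths(g)
  expect_equal(sp$dist[1, 3], 2)
  expect_equal(shortest_path_nodes(sp, 1, 3), c(1, 2, 3))

  ## disconnected components have infinite cross distances
  R2 <- diag(4)
  R2[1, 2] <- R2[2, 1] <- 0.9
  R2[3, 4] <- R2[4, 3] <- 0.9
  sp2 <- all_shortest_paths(build_network(R2))
  expect_equal(sp2$dist[1, 3], Inf)
  expect_length(shortest_path_nodes(sp2, 1, 3), 0)

  ## agreement with an independent single-source algorithm
  set.seed(33)
  for (r in 1:25) {
    n <- sample(5:40, 1)
    g3 <- build_network(random_rmi(n), threshold = 0.5)
    sp3 <- all_shortest_paths(g3)
    ref <- igraph::distances(g3$graph, weights = igraph::E(g3$graph)$weight)
    expect_lt(max(abs(sp3$dist - ref)), 1e-9)
  }
})

test_that("edge betweenness equals exhaustive path enumeration on small graphs", {
  ## path graph a-b-c
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.9
  R[2, 3] <- R[3, 2] <- 0.9
  g <- build_network(R)
  eb <- edge_betweenness_map(g)
  expect_equal(eb$betweenness, brute_edge_betweenness(g), tolerance = 1e-9)

  ## random small graphs, exact agreement with enumeration
  set.seed(34)
  for (r in 1:40) {
    n <- sample(4:8, 1)
    gr <- build_network(random_rmi(n, lo = 0.1), threshold = 0.5)
    if (nrow(gr$edges) == 0) next
    ebr <- edge_betweenness_map(gr)
    expect_equal(ebr$betweenness, brute_edge_betweenness(gr),
                 tolerance = 1e-9)
  }
})

test_that("the bridge of a barbell graph has the maximum betweenness", {
  R <- diag(6)
  for (i in 1:2) for (j in (i + 1):3) R[i, j] <- R[j, i] <- 0.95
  for (i in 4:5) for (j in (i + 1):6) R[i, j] <- R[j, i] <- 0.95
  R[3, 4] <- R[4, 3] <- 0.9
  g <- build_network(R)
  eb <- edge_betweenness_map(g)
  bridge <- which(eb$i == 3 & eb$j == 4)
  expect_equal(which.max(eb$betweenness), bridge)
  expect_true(all(eb$betweenness >= 0 & eb$betweenness <= 1))
})

test_that("the unit-distance network counts intermediate residues", {
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- 0.9
  R[2, 3] <- R[3, 2] <- 0.6
  R[3, 4] <- R[4, 3] <- 0.9
  g <- build_network(R, unit_distance = TRUE)
  expect_equal(g$metric, "unit")
  expect_true(all(g$edges$weight == 1))
  sp <- all_shortest_paths(g)
  expect_equal(sp$dist[1, 4], 3)       # number of steps, not -log weights
  expect_equal(g$edges$rmi[g$edges$i == 2 & g$edges$j == 3], 0.6)
})

test_that("raising the threshold never adds edges nor shortens paths", {
  set.seed(35)
  R <- random_rmi(15)
  g1 <- build_network(R, threshold = 0.4)
  g2 <- build_network(R, threshold = 0.6)
  expect_lte(nrow(g2$edges), nrow(g1$edges))
  d1 <- all_shortest_paths(g1)$dist
  d2 <- all_shortest_paths(g2)$dist
  fin <- is.finite(d2)
  expect_true(all(d2[fin] >= d1[fin] - 1e-12))
})

test_that("communication pathways rank loopless routes and count traversals", {
  ## planted low-weight backbone 1-2-3-4-5 inside a noisy graph
  set.seed(36)
  n <- 10
  R <- random_rmi(n, lo = 0.2, hi = 0.6)
  for (k in 1:4) R[k, k + 1] <- R[k + 1, k] <- 0.99
  g <- build_network(R, threshold = 0.5)
  ps <- communication_pathways(g, effectors = 1, sensors = 5, k_paths = 3)
  best <- as.integer(strsplit(ps$paths$path[1], "-")[[1]])
  expect_equal(best, 1:5)
  expect_true(all(ps$node_counts[2:4] >= 1))

  ## adjacent effector and sensor: single edge path with its weight
  ps2 <- communication_pathways(g, effectors = 1, sensors = 2, k_paths = 1)
  expect_equal(ps2$paths$total_weight[1], -log(0.99), tolerance = 1e-9)

  ## k = 1 reduces to the predecessor-matrix path
  sp <- all_shortest_paths(g)
  expect_equal(as.integer(strsplit(ps$paths$path[
    ps$paths$rank == 1 & ps$paths$source == 1 & ps$paths$target == 5], "-")[[1]]),
    shortest_path_nodes(sp, 1, 5))

  ## unreachable pairs are reported, not raised
  R4 <- diag(4)
  R4[1, 2] <- R4[2, 1] <- 0.9
  R4[3, 4] <- R4[4, 3] <- 0.9
  g4 <- build_network(R4)
  ps4 <- communication_pathways(g4, effectors = 1, sensors = 4)
  expect_true(is.infinite(ps4$paths$total_weight[1]))
})

test_that("planted-pathway traversal counts rank backbone nodes highly", {
  set.seed(37)
  n <- 20
  R <- random_rmi(n, lo = 0.2, hi = 0.55)
  backbone <- c(1, 6, 11, 16, 20)
  for (k in seq_len(length(backbone) - 1))
    R[backbone[k], backbone[k + 1]] <- R[backbone[k + 1], backbone[k]] <- 0.98
  g <- build_network(R, threshold = 0.5)
  ps <- communication_pathways(g, effectors = 1, sensors = 20, k_paths = 5)
  mid <- backbone[2:4]
  expect_true(all(ps$node_counts[mid] >=
                  stats::quantile(ps$node_counts, 0.9)))
})
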