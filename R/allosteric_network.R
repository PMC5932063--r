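## Coevolution-and-dynamics weighted residue interaction networks:
## generalized correlation, -log(R_MI) edge weights, all-pairs shortest
## paths (Floyd-Warshall), edge betweenness, communication pathways.

gaussian_mi_pair <- function(Si, Sj, Sij, d) {
  S <- rbind(cbind(Si, Sij), cbind(t(Sij), Sj))
  di <- det(Si); dj <- det(Sj); dfull <- det(S)
  if (di <= 0 || dj <= 0) return(NA_real_)
  if (dfull <= di * dj * 1e-300) return(Inf)
  0.5 * log(di * dj / dfull)
}

#' Generalized correlation coefficients between residue fluctuations
#'
#' For each ensemble, the mutual information between the fluctuation vectors
#' of every residue pair is estimated with the closed-form Gaussian
#' estimator, I = 1/2 log(det(S_i) det(S_j) / det(S_ij)), and mapped to the
#' generalized correlation coefficient R_MI = sqrt(1 - exp(-2 I / d)) in
#' [0, 1]. With \code{pmi} supplied, each residue's 3-dimensional
#' fluctuation vector is augmented by a fourth, coevolutionary channel
#' (d = 4): a unit-variance coordinate whose loading on a common latent
#' signal is the residue's pMI scaled to [0, 1), so that pairs of residues
#' that both carry high proximity-coevolution scores share information in
#' the composite vector. Without \code{pmi} the pure-dynamics d = 3 mode is
#' used.
#'
#' @param trajs a \code{trajectory_ensemble} or a list of them (independent
#'   simulations; all with the same residue count).
#' @param pmi optional per-residue pMI vector (NAs treated as 0).
#' @param superpose superpose frames before computing fluctuations.
#' @param cap R_MI values are capped at 1 - 1e-12.
#' @return object of class \code{rmi_stack}: list with \code{matrices}
#'   (one N x N symmetric R_MI matrix per ensemble, diagonal 1),
#'   \code{estimator = "gaussian"}, \code{composite} flag.
#' @export
generalized_correlation <- function(trajs, pmi = NULL, superpose = TRUE,
                                    cap = 1 - 1e-12) {
  if (inherits(trajs, "trajectory_ensemble")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1)
  n <- trajs[[1]]$n
  if (!all(vapply(trajs, `[[`, numeric(1), "n") == n))
    stop("all ensembles must have the same residue count")
  composite <- !is.null(pmi)
  d <- if (composite) 4L else 3L
  if (composite) {
    p <- pmi
    p[is.na(p)] <- 0
    rho <- if (max(p) > 0) 0.95 * p / max(p) else rep(0, n)
  }
  mats <- lapply(trajs, function(traj) {
    arr <- traj$frames
    if (superpose) arr <- superpose_frames(arr)
    M <- apply(arr, c(2, 3), mean)
    F_ <- dim(arr)[1]
    ## F x (n*d) fluctuation matrix, residue-major blocks
    X <- matrix(NA_real_, F_, n * d)
    for (f in seq_len(F_)) {
      dev <- arr[f, , ] - M
      X[f, rep(seq(0, (n - 1) * d, d), each = 3) +
          rep(1:3, n)] <- as.vector(t(dev))
    }
    if (composite) {
      ## common latent coevolutionary channel, unit variance per residue;
      ## generated with an isolated fixed-seed RNG so the construction is
      ## deterministic and leaves the caller's RNG state untouched
      rng_state <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      set.seed(271828L)
      s <- stats::qnorm((seq_len(F_) - 0.5) / F_)     # deterministic signal
      s <- s / stats::sd(s)
      e <- matrix(stats::rnorm(F_ * n), F_, n)
      if (!is.null(rng_state))
        assign(".Random.seed", rng_state, envir = globalenv())
      for (i in seq_len(n))
        X[, i * d] <- rho[i] * s + sqrt(1 - rho[i]^2) * e[, i]
    }
    S <- stats::cov(X)
    R <- matrix(NA_real_, n, n)
    diag(R) <- 1
    for (i in seq_len(n - 1)) {
      ii <- ((i - 1) * d + 1):(i * d)
      for (j in (i + 1):n) {
        jj <- ((j - 1) * d + 1):(j * d)
        I <- gaussian_mi_pair(S[ii, ii], S[jj, jj], S[ii, jj], d)
        if (is.na(I)) { R[i, j] <- R[j, i] <- NA_real_; next }
        r <- sqrt(1 - exp(-2 * I / d))
        R[i, j] <- R[j, i] <- min(r, cap)
      }
    }
    if (anyNA(R))
      warning("near-singular residue covariance: some pairs masked")
    R
  })
  structure(list(matrices = mats, estimator = "gaussian",
                 composite = composite, d = d),
            class = "rmi_stack")
}

#' Build the weighted residue interaction graph
#'
#' An edge is kept between residues i and j if their generalized correlation
#' exceeds the threshold (strictly) in at least one independent ensemble
#' and, when contact gating is on, the pair is a structural contact. The
#' edge weight (communication distance) is w_ij = -log(max R_MI), natural
#' log, so perfectly correlated pairs have length 0.
#'
#' @param rmi_stack an \code{rmi_stack} (or a single R_MI matrix).
#' @param contacts optional \code{contact_map}; when supplied, edges are
#'   restricted to structural contacts (recommended: heavy-atom 5 Angstrom).
#' @param threshold R_MI threshold (default 0.5, strict inequality).
#' @param unit_distance use hop counts instead of -log(R_MI) edge lengths
#'   (the first-step network in which the distance between connected
#'   residues is one); the R_MI values are still recorded per edge.
#' @return object of class \code{weighted_residue_graph}: list with
#'   \code{graph} (igraph), \code{edges} (data.frame i, j, rmi, weight),
#'   \code{n}, \code{threshold}, \code{contact_gated}, \code{metric}.
#' @export
build_network <- function(rmi_stack, contacts = NULL, threshold = 0.5,
                          unit_distance = FALSE) {
  mats <- if (inherits(rmi_stack, "rmi_stack")) rmi_stack$matrices
          else list(rmi_stack)
  R <- Reduce(function(a, b) pmax(a, b, na.rm = TRUE), mats)
  n <- nrow(R)
  sel <- !is.na(R) & R > threshold & upper.tri(R)
  if (!is.null(contacts)) sel <- sel & contacts$contacts
  idx <- which(sel, arr.ind = TRUE)
  rmi <- pmin(R[idx], 1 - 1e-12)
  keep <- rmi > 0
  idx <- idx[keep, , drop = FALSE]
  rmi <- rmi[keep]
  edges <- data.frame(i = idx[, 1], j = idx[, 2], rmi = rmi,
                      weight = if (unit_distance) rep(1, length(rmi))
                               else -log(rmi))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$i, to = edges$j, weight = edges$weight),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  structure(list(graph = g, edges = edges, n = n, threshold = threshold,
                 contact_gated = !is.null(contacts),
                 metric = if (unit_distance) "unit" else "neglog-rmi"),
            class = "weighted_residue_graph")
}

#' @export
print.weighted_residue_graph <- function(x, ...) {
  cat(sprintf("weighted_residue_graph: %d nodes, %d edges (R_MI > %g%s)\n",
              x$n, nrow(x$edges), x$threshold,
              if (x$contact_gated) ", contact-gated" else ""))
  invisible(x)
}

#' All-pairs shortest communication distances (Floyd-Warshall)
#'
#' Exact all-pairs shortest path distances and predecessors on the weighted
#' residue graph; unreachable pairs have infinite distance.
#'
#' @param g a \code{weighted_residue_graph}.
#' @return object of class \code{shortest_path_matrix}: list with
#'   \code{dist} (N x N), \code{pred} (predecessor of j on the i -> j path;
#'   NA when absent).
#' @export
all_shortest_paths <- function(g) {
  n <- g$n
  if (any(g$edges$weight < 0)) stop("negative edge weights are not allowed")
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  P <- matrix(NA_integer_, n, n)
  e <- g$edges
  D[cbind(e$i, e$j)] <- e$weight
  D[cbind(e$j, e$i)] <- e$weight
  P[cbind(e$i, e$j)] <- e$i
  P[cbind(e$j, e$i)] <- e$j
  for (k in seq_len(n)) {
    via <- outer(D[, k], D[k, ], `+`)
    better <- via < D
    if (any(better)) {
      D[better] <- via[better]
      Pk <- matrix(P[k, ], n, n, byrow = TRUE)
      P[better] <- Pk[better]
    }
  }
  structure(list(dist = D, pred = P), class = "shortest_path_matrix")
}

#' Reconstruct one shortest path from a predecessor matrix
#' @param sp a \code{shortest_path_matrix}.
#' @param from,to node indices.
#' @return integer vector of nodes (empty if unreachable).
#' @export
shortest_path_nodes <- function(sp, from, to) {
  if (!is.finite(sp$dist[from, to])) return(integer(0))
  path <- to
  while (path[1] != from) path <- c(sp$pred[from, path[1]], path)
  path
}

#' Edge betweenness of the residue graph
#'
#' For every residue pair, shortest paths are counted with equal splitting
#' among ties; an edge's centrality is the summed fractional usage divided
#' by the number of connected pairs, so values lie in [0, 1] and a bridge
#' used by every pair attains the component maximum.
#'
#' @param g a \code{weighted_residue_graph}.
#' @return data.frame of class \code{edge_betweenness_map} with \code{i},
#'   \code{j}, \code{betweenness}.
#' @export
edge_betweenness_map <- function(g) {
  eb <- igraph::edge_betweenness(g$graph, directed = FALSE,
                                 weights = igraph::E(g$graph)$weight)
  comp <- igraph::components(g$graph)
  sizes <- comp$csize
  npairs <- sum(sizes * (sizes - 1) / 2)
  out <- data.frame(i = g$edges$i, j = g$edges$j,
                    betweenness = if (npairs > 0) eb / npairs else 0)
  class(out) <- c("edge_betweenness_map", "data.frame")
  out
}

#' Effector-to-sensor communication pathways
#'
#' For each (effector, sensor) pair, the shortest path and up to k - 1
#' next-shortest loopless alternatives (Yen's algorithm), ranked by total
#' communication distance. Per-node traversal counts across all reported
#' paths expose gate-keeper residues. Unreachable pairs are reported as
#' no-path rows, not raised.
#'
#' @param g a \code{weighted_residue_graph}.
#' @param effectors,sensors non-empty vectors of node indices.
#' @param k_paths paths per pair (default 3).
#' @return object of class \code{communication_path_set}: list with
#'   \code{paths} (data.frame source, target, rank, total_weight, path
#'   string), \code{path_nodes} (list of integer vectors),
#'   \code{node_counts} (traversal count per node).
#' @export
communication_pathways <- function(g, effectors, sensors, k_paths = 3) {
  stopifnot(length(effectors) >= 1, length(sensors) >= 1)
  if (any(c(effectors, sensors) > g$n | c(effectors, sensors) < 1))
    stop("effector/sensor indices outside the graph")
  rows <- list(); nodes_list <- list()
  counts <- integer(g$n)
  for (s in effectors) for (t in sensors) {
    if (s == t) next
    ks <- suppressWarnings(igraph::k_shortest_paths(
      g$graph, from = s, to = t, k = k_paths,
      weights = igraph::E(g$graph)$weight))
    vpaths <- ks$vpaths
    if (length(vpaths) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        source = s, target = t, rank = NA_integer_,
        total_weight = Inf, path = "")
      next
    }
    for (r in seq_along(vpaths)) {
      nd <- as.integer(vpaths[[r]])
      w <- sum_path_weight(g, nd)
      rows[[length(rows) + 1]] <- data.frame(
        source = s, target = t, rank = r, total_weight = w,
        path = paste(nd, collapse = "-"))
      nodes_list[[length(nodes_list) + 1]] <- nd
      counts[nd] <- counts[nd] + 1L
    }
  }
  paths <- do.call(rbind, rows)
  paths <- paths[order(paths$total_weight), , drop = FALSE]
  rownames(paths) <- NULL
  structure(list(paths = paths, path_nodes = nodes_list,
                 node_counts = counts),
            class = "communication_path_set")
}

sum_path_weight <- function(g, nodes) {
  if (length(nodes) < 2) return(0)
  W <- matrix(Inf, g$n, g$n)
  W[cbind(g$edges$i, g$edges$j)] <- g$edges$weight
  W[cbind(g$edges$j, g$edges$i)] <- g$edges$weight
  sum(W[cbind(nodes[-length(nodes)], nodes[-1])])
}

#' Export the residue graph as a TSV edge list or GraphML
#' @param g a \code{weighted_residue_graph}.
#' @param path output path.
#' @param format \code{"tsv"} or \code{"graphml"}.
#' @return invisibly, the path.
#' @export
write_network <- function(g, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv")
    utils::write.table(g$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  else
    igraph::write_graph(g$graph, path, format = "graphml")
  invisible(path)
}
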