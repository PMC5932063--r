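## shared fixtures: minimal PDB text, tiny alignments, random covariances,
## and independent oracles used across the suite

pdb_atom_line <- function(serial, elety, resid, chain, resno, x, y, z,
                          occ = 1, b = 0, element = substr(elety, 1, 1),
                          alt = " ", record = "ATOM") {
  sprintf("%-6s%5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, elety, alt, resid, chain, resno, x, y, z, occ, b,
          element)
}

## a minimal k-residue poly-ALA chain with CA atoms spaced 3.8 A on x
toy_chain_pdb <- function(k = 3, chain = "A", spacing = 3.8) {
  lines <- vapply(seq_len(k), function(i)
    pdb_atom_line(i, "CA", "ALA", chain, i, (i - 1) * spacing, 0, 0,
                  element = "C"), character(1))
  paste(c(lines, "END"), collapse = "\n")
}

## ca_trace straight from coordinates
trace_from_xyz <- function(xyz, chain = "A") {
  structure(list(
    xyz = xyz,
    residues = data.frame(chain = rep_len(chain, nrow(xyz)),
                          resno = seq_len(nrow(xyz)), insert = "",
                          resid = "ALA", stringsAsFactors = FALSE)),
    class = "ca_trace")
}

## random symmetric R_MI-like matrix in (lo, hi), diagonal 1
random_rmi <- function(n, lo = 0.2, hi = 0.99) {
  R <- matrix(stats::runif(n * n, lo, hi), n)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  R
}

## random PSD covariance_matrix for N residues
random_covariance <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(stats::rnorm((3 * n)^2), 3 * n)
  structure(list(C = crossprod(A) / (3 * n), mean = matrix(0, n, 3), n = n),
            class = "covariance_matrix")
}

## independent joint-count MI oracle (nats, pairwise-complete)
brute_mi <- function(a, b) {
  ok <- !(a %in% c("-", ".")) & !(b %in% c("-", "."))
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2) return(NA_real_)
  tab <- table(a, b)
  pj <- tab / n
  pa <- rowSums(pj); pb <- colSums(pj)
  s <- 0
  for (x in seq_len(nrow(pj))) for (y in seq_len(ncol(pj)))
    if (pj[x, y] > 0) s <- s + pj[x, y] * log(pj[x, y] / (pa[x] * pb[y]))
  as.numeric(s)
}

## exhaustive-enumeration edge betweenness oracle (equal splitting), using
## DFS over all shortest paths; normalised by connected pair count
brute_edge_betweenness <- function(g) {
  n <- g$n
  W <- matrix(Inf, n, n)
  W[cbind(g$edges$i, g$edges$j)] <- g$edges$weight
  W[cbind(g$edges$j, g$edges$i)] <- g$edges$weight
  sp <- all_shortest_paths(g)
  cnt <- numeric(nrow(g$edges))
  np <- 0
  allp <- function(i, j, d) {
    if (i == j) return(list(j))
    out <- list()
    for (k in which(is.finite(W[i, ])))
      if (abs(W[i, k] + sp$dist[k, j] - d) < 1e-9)
        for (pp in allp(k, j, sp$dist[k, j])) out <- c(out, list(c(i, pp)))
    out
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!is.finite(sp$dist[i, j])) next
    np <- np + 1
    paths <- allp(i, j, sp$dist[i, j])
    for (pp in paths) for (s in seq_len(length(pp) - 1)) {
      e <- which((g$edges$i == pp[s] & g$edges$j == pp[s + 1]) |
                 (g$edges$j == pp[s] & g$edges$i == pp[s + 1]))
      cnt[e] <- cnt[e] + 1 / length(paths)
    }
  }
  if (np == 0) return(cnt)
  cnt / np
}

## brute-force DMD reference: recompute every pair's next event from
## scratch at every step (no queue); same physics as run_dmd
brute_dmd <- function(model, X, V, n_events) {
  pr <- model$pairs
  tnow <- 0
  for (ev in seq_len(n_events)) {
    tev <- allokit:::pair_event_times(X, V, tnow, pr$i, pr$j,
                                      pr$dmin^2, pr$dmax^2)
    k <- which.min(tev)
    dt <- tev[k] - tnow
    X <- X + V * dt
    tnow <- tev[k]
    a <- pr$i[k]; b <- pr$j[k]
    rv <- X[b, ] - X[a, ]
    nv <- rv / sqrt(sum(rv^2))
    vr <- sum((V[b, ] - V[a, ]) * nv)
    V[a, ] <- V[a, ] + vr * nv
    V[b, ] <- V[b, ] - vr * nv
  }
  list(X = X, V = V, time = tnow)
}
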