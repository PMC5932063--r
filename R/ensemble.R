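## Conformational ensembles: container, elastic-network Gaussian surrogate,
## covariance, B-factors and PCA slow-mode profiles.

#' Construct a trajectory ensemble
#'
#' @param frames list of N x 3 matrices, or an F x N x 3 array.
#' @param source one of \code{"dmd"}, \code{"enm-surrogate"},
#'   \code{"external"}.
#' @param residues optional residue table aligned with the beads.
#' @return object of class \code{trajectory_ensemble}: list with
#'   \code{frames} (F x N x 3 array, Angstrom), \code{n_frames}, \code{n},
#'   \code{source}, \code{residues}.
#' @export
trajectory_ensemble <- function(frames, source = "external", residues = NULL) {
  if (is.list(frames)) {
    n <- nrow(frames[[1]])
    arr <- array(NA_real_, c(length(frames), n, 3))
    for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
    frames <- arr
  }
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] == 3, dim(frames)[1] >= 2)
  structure(list(frames = frames, n_frames = dim(frames)[1],
                 n = dim(frames)[2], source = source, residues = residues),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("trajectory_ensemble: %d frames x %d beads (source: %s)\n",
              x$n_frames, x$n, x$source))
  invisible(x)
}

#' Write a trajectory as multi-model C-alpha PDB
#' @param traj a \code{trajectory_ensemble}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_trajectory <- function(traj, path) {
  res <- traj$residues
  if (is.null(res))
    res <- data.frame(chain = "A", resno = seq_len(traj$n), resid = "ALA")
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(traj$n_frames)) {
    writeLines(sprintf("MODEL %8d", f), con)
    X <- traj$frames[f, , ]
    writeLines(sprintf("ATOM  %5d  CA  %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                       seq_len(traj$n), res$resid, res$chain, res$resno,
                       X[, 1], X[, 2], X[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB as a trajectory ensemble
#'
#' C-alpha atoms of each MODEL become one frame (external MD output can be
#' dropped in this way).
#'
#' @param path path to a multi-model PDB file.
#' @return a \code{trajectory_ensemble} with source \code{"external"}.
#' @export
read_trajectory <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  ca <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
  xyz <- pdb$xyz[, ca$xyz, drop = FALSE]
  n <- length(ca$atom)
  frames <- lapply(seq_len(nrow(xyz)), function(f)
    matrix(xyz[f, ], n, 3, byrow = TRUE))
  res <- data.frame(chain = pdb$atom$chain[ca$atom],
                    resno = pdb$atom$resno[ca$atom],
                    insert = "", resid = pdb$atom$resid[ca$atom])
  trajectory_ensemble(frames, source = "external", residues = res)
}

## anisotropic elastic-network Hessian (uniform spring constant)
enm_hessian <- function(xyz, cutoff, gamma = 1) {
  n <- nrow(xyz)
  H <- matrix(0, 3 * n, 3 * n)
  D <- as.matrix(stats::dist(xyz))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (D[i, j] >= cutoff || D[i, j] == 0) next
      r <- xyz[j, ] - xyz[i, ]
      blk <- -gamma * tcrossprod(r) / sum(r^2)
      ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
      H[ii, jj] <- blk
      H[jj, ii] <- blk
      H[ii, ii] <- H[ii, ii] - blk
      H[jj, jj] <- H[jj, jj] - blk
    }
  }
  H
}

enm_connected <- function(xyz, cutoff) {
  D <- as.matrix(stats::dist(xyz))
  adj <- D < cutoff
  diag(adj) <- FALSE
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    adj, mode = "undirected"))
  comp$no == 1
}

#' Analytic covariance of an anisotropic elastic network model
#'
#' Pseudo-inverse of the ENM Hessian with the six rigid-body modes removed,
#' scaled by \code{temperature_scale} (k_B T / gamma in Angstrom^2).
#' Optionally the Hessian is modified by extra springs (used by the synthetic
#' generators to plant features).
#'
#' @param trace a \code{ca_trace} (or N x 3 matrix).
#' @param cutoff spring cutoff in Angstrom.
#' @param temperature_scale overall covariance scale.
#' @param extra_springs optional data.frame (i, j, gamma) of additional
#'   springs.
#' @return object of class \code{covariance_matrix}: list with \code{C}
#'   (3N x 3N), \code{mean} (N x 3), \code{n}.
#' @export
enm_covariance <- function(trace, cutoff = 10, temperature_scale = 1,
                           extra_springs = NULL) {
  xyz <- if (inherits(trace, "ca_trace")) trace$xyz else as.matrix(trace)
  if (!enm_connected(xyz, cutoff))
    stop("elastic network is disconnected at cutoff ", cutoff,
         " A; increase the cutoff")
  H <- enm_hessian(xyz, cutoff)
  if (!is.null(extra_springs)) {
    for (k in seq_len(nrow(extra_springs))) {
      i <- extra_springs$i[k]; j <- extra_springs$j[k]
      g <- extra_springs$gamma[k]
      r <- xyz[j, ] - xyz[i, ]
      blk <- -g * tcrossprod(r) / sum(r^2)
      ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
      H[ii, jj] <- H[ii, jj] + blk
      H[jj, ii] <- H[jj, ii] + blk
      H[ii, ii] <- H[ii, ii] - blk
      H[jj, jj] <- H[jj, jj] - blk
    }
  }
  eg <- eigen(H, symmetric = TRUE)
  n3 <- nrow(H)
  keep <- seq_len(n3 - 6)              # drop the 6 rigid-body modes
  lam <- eg$values[keep]
  if (any(lam < 1e-8))
    stop("ENM Hessian has more than 6 near-zero modes; network too sparse")
  V <- eg$vectors[, keep, drop = FALSE]
  C <- temperature_scale * V %*% (t(V) / lam)
  C <- (C + t(C)) / 2
  structure(list(C = C, mean = xyz, n = nrow(xyz)),
            class = "covariance_matrix")
}

#' Sample a Gaussian conformational ensemble from an elastic network model
#'
#' A desk-scale surrogate for long explicit-solvent MD: frames are drawn from
#' the multivariate Gaussian whose covariance is the pseudo-inverse of the
#' anisotropic ENM Hessian (six rigid-body modes excluded).
#'
#' @param trace a \code{ca_trace}.
#' @param spring_cutoff spring cutoff in Angstrom (network must be connected).
#' @param n_frames number of frames.
#' @param temperature_scale covariance scale; 0 gives identical frames.
#' @param seed integer seed.
#' @param extra_springs optional extra springs (see
#'   \code{\link{enm_covariance}}).
#' @return a \code{trajectory_ensemble} with source \code{"enm-surrogate"}.
#' @export
sample_enm_ensemble <- function(trace, spring_cutoff = 10, n_frames = 100,
                                temperature_scale = 1, seed = NULL,
                                extra_springs = NULL) {
  xyz <- if (inherits(trace, "ca_trace")) trace$xyz else as.matrix(trace)
  if (temperature_scale == 0) {
    frames <- replicate(max(n_frames, 2), xyz, simplify = FALSE)
    traj <- trajectory_ensemble(frames, source = "enm-surrogate",
                                residues = trace$residues)
    return(traj)
  }
  cov <- enm_covariance(trace, spring_cutoff, temperature_scale,
                        extra_springs)
  traj <- make_gaussian_trajectory(cov, n_frames, seed = seed)
  traj$source <- "enm-surrogate"
  traj$residues <- if (inherits(trace, "ca_trace")) trace$residues else NULL
  traj
}

## Kabsch rotation fitting X (N x 3, centred) onto ref (centred)
kabsch_rotation <- function(X, ref) {
  s <- svd(crossprod(X, ref))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

superpose_frames <- function(arr, n_iter = 2) {
  F_ <- dim(arr)[1]
  ref <- arr[1, , ]
  ref <- sweep(ref, 2, colMeans(ref))
  for (it in seq_len(n_iter)) {
    for (f in seq_len(F_)) {
      X <- arr[f, , ]
      X <- sweep(X, 2, colMeans(X))
      arr[f, , ] <- X %*% kabsch_rotation(X, ref)
    }
    ref <- apply(arr, c(2, 3), mean)
  }
  arr
}

#' Covariance matrix of residue fluctuations over a trajectory
#'
#' Deviations from the ensemble-average structure give
#' C = (1/F) sum over frames of dR dR^T (3N x 3N). Frames are optionally
#' least-squares superposed onto the mean first (default on, removing
#' rigid-body motion).
#'
#' @param traj a \code{trajectory_ensemble} (F >= 2).
#' @param superpose superpose frames before computing deviations.
#' @return a \code{covariance_matrix} (see \code{\link{enm_covariance}}).
#' @export
compute_covariance <- function(traj, superpose = TRUE) {
  if (traj$n_frames < 2) stop("need at least 2 frames to compute covariance")
  arr <- traj$frames
  if (superpose) arr <- superpose_frames(arr)
  M <- apply(arr, c(2, 3), mean)
  F_ <- dim(arr)[1]; n <- dim(arr)[2]
  D <- matrix(NA_real_, F_, 3 * n)
  for (f in seq_len(F_)) D[f, ] <- as.vector(t(arr[f, , ] - M))
  C <- crossprod(D) / F_
  structure(list(C = C, mean = M, n = n), class = "covariance_matrix")
}

#' @export
print.covariance_matrix <- function(x, ...) {
  cat(sprintf("covariance_matrix: %d residues (3N = %d)\n", x$n, 3 * x$n))
  invisible(x)
}

#' Per-residue mean-square fluctuations and B-factors from a covariance
#'
#' msf_i is the trace of residue i's 3 x 3 diagonal block of C;
#' B_i = (8 pi^2 / 3) msf_i.
#'
#' @param C a \code{covariance_matrix}.
#' @return data.frame of class \code{mobility_profile} with \code{msf}
#'   (Angstrom^2) and \code{bfactor}.
#' @export
compute_bfactors <- function(C) {
  n <- C$n
  dg <- diag(C$C)
  msf <- dg[seq(1, 3 * n, 3)] + dg[seq(2, 3 * n, 3)] + dg[seq(3, 3 * n, 3)]
  out <- data.frame(residue = seq_len(n), msf = msf,
                    bfactor = 8 * pi^2 / 3 * msf)
  class(out) <- c("mobility_profile", "data.frame")
  out
}

running_mean <- function(x, window) {
  if (window <= 1) return(x)
  half <- floor(window / 2)
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - half):min(n, i + half)]), numeric(1))
}

#' Slow-mode displacement profile from PCA of the covariance matrix
#'
#' Eigendecomposes C; the per-residue squared displacements of the top
#' \code{n_modes} eigenvectors are averaged with eigenvalue weights and
#' normalised to sum to 1. Local minima of the smoothed profile below the
#' \code{hinge_quantile} are reported as hinges (immobilised residues
#' coordinating the collective motion); local maxima above the complementary
#' quantile as mobile peaks.
#'
#' @param C a \code{covariance_matrix}.
#' @param n_modes number of slow modes to average (default 3).
#' @param smooth_window running-mean window for extremum detection.
#' @param hinge_quantile quantile below which minima count as hinges.
#' @return object of class \code{slow_mode_profile}: list with
#'   \code{profile} (sums to 1), \code{smoothed}, \code{minima},
#'   \code{maxima}, \code{eigenvalues}, \code{modes}.
#' @export
pca_slow_modes <- function(C, n_modes = 3, smooth_window = 1,
                           hinge_quantile = 0.2) {
  n <- C$n
  if (n_modes > 3 * n) stop("n_modes exceeds 3N")
  eg <- eigen(C$C, symmetric = TRUE)
  lam <- pmax(eg$values[seq_len(n_modes)], 0)
  disp <- sapply(seq_len(n_modes), function(m) {
    v <- matrix(eg$vectors[, m], nrow = 3)
    colSums(v^2)
  })
  w <- if (sum(lam) > 0) lam / sum(lam) else rep(1 / n_modes, n_modes)
  prof <- as.vector(disp %*% w)
  prof <- prof / sum(prof)
  sm <- running_mean(prof, smooth_window)
  interior <- 2:(n - 1)
  is_min <- interior[sm[interior] < sm[interior - 1] & sm[interior] <= sm[interior + 1]]
  is_max <- interior[sm[interior] > sm[interior - 1] & sm[interior] >= sm[interior + 1]]
  qlo <- stats::quantile(sm, hinge_quantile)
  qhi <- stats::quantile(sm, 1 - hinge_quantile)
  ## chain termini can be mobile peaks too
  if (sm[1] > sm[2]) is_max <- c(1L, is_max)
  if (sm[n] > sm[n - 1]) is_max <- c(is_max, as.integer(n))
  structure(list(profile = prof, smoothed = sm,
                 minima = is_min[sm[is_min] <= qlo],
                 maxima = is_max[sm[is_max] >= qhi],
                 all_minima = is_min, all_maxima = is_max,
                 eigenvalues = eg$values[seq_len(n_modes)],
                 modes = eg$vectors[, seq_len(n_modes), drop = FALSE]),
            class = "slow_mode_profile")
}

#' @export
print.slow_mode_profile <- function(x, ...) {
  cat(sprintf("slow_mode_profile: %d residues; hinges at %s; peaks at %s\n",
              length(x$profile),
              paste(x$minima, collapse = ","),
              paste(x$maxima, collapse = ",")))
  invisible(x)
}
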