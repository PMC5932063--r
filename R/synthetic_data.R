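## Synthetic test systems with planted, recoverable features: a toy
## multi-domain dimer, alignments with planted conservation/coevolution,
## Gaussian trajectory ensembles, and PTM annotation tables.

## serpentine walk through a 3 x 3 x k cubic lattice: consecutive beads are
## always one lattice spacing apart, so the path doubles as a chain with
## uniform bond length, entering at the -x face and leaving at the +x face
serpentine_lattice <- function(n_beads, a = 3.8) {
  stopifnot(n_beads >= 5, n_beads <= 27)
  out <- matrix(NA_real_, n_beads, 3)
  for (k in seq_len(n_beads) - 1L) {
    layer <- k %/% 9L
    m <- k %% 9L
    if (layer %% 2L == 1L) m <- 8L - m
    r <- m %/% 3L
    cc <- m %% 3L
    if (r %% 2L == 1L) cc <- 2L - cc
    out[k + 1L, ] <- a * c(cc, r, layer)
  }
  out
}

#' Generate a toy multi-domain homodimer with planted features
#'
#' Each protomer is three compact serpentine-lattice bead domains
#' (pseudo-NTD/MD/CTD) joined by single linker beads, plus a floppy
#' N-terminal helical tail. The second protomer is a rigid C2 copy
#' (rotated 180 degrees about an axis through the MD-CTD linker), so the
#' protomers cross at their MD-CTD junctions and the dimer's centre of
#' motion coincides with the linker stack. Bead geometry is deterministic
#' up to a small seeded jitter, so planted features are structural.
#'
#' Planted ground truth: the \emph{hinge} is the MD-CTD linker bead --
#' it sits on the dimer's two-fold axis, so the slow collective modes
#' leave it immobile (a slow-mode minimum); the \emph{effector} is the
#' interface-forming CTD bead (most inter-protomer contacts), whose
#' fluctuations are defined in the toy's covariance model
#' (\code{\link{toy_covariance}}) as the collective mean motion of the
#' whole dimer -- globally coupled with minimal mobility; the
#' \emph{sensors} are the tail beads, whose fluctuation amplitudes are
#' scaled up. Bead spacing follows the square-well native-distance
#' convention (3.8 Angstrom bonds, 3.6 Angstrom minimum separation).
#'
#' @param beads_per_domain beads per domain (5 to 27; default 10).
#' @param tail_length floppy tail beads (default 7).
#' @param seed integer seed (residue identities and jitter).
#' @return list with \code{model} (a \code{structure_model}, chains A and B,
#'   random residue identities shared by the protomers), \code{labels}
#'   (ground truth: per-chain indices of hinge, effector, tail, linkers,
#'   domain assignment), and \code{spec}.
#' @export
make_toy_dimer <- function(beads_per_domain = 10, tail_length = 7,
                           seed = 1) {
  stopifnot(beads_per_domain >= 5)
  b <- beads_per_domain
  set.seed(seed)
  xyz <- build_protomer(b, tail_length)
  n_per <- nrow(xyz$coords)
  ## protomer B: rigid copy rotated 180 degrees about a y-parallel axis
  ## through the MD-CTD linker, stacked in z until the protomers touch
  ## comfortably; the two-fold axis pierces the crossing point
  A <- xyz$coords
  h <- xyz$hinge
  xh <- A[h, 1]
  Bc <- NULL
  for (z0 in seq(mean(range(A[, 3])), mean(range(A[, 3])) + 30, by = 0.1)) {
    cand <- cbind(2 * xh - A[, 1], A[, 2], 2 * z0 - A[, 3])
    if (min_cross_dist(A, cand) > 4.5) { Bc <- cand; break }
  }
  if (is.null(Bc)) stop("could not place the second protomer")
  coords <- rbind(A, Bc)
  chain <- rep(c("A", "B"), each = n_per)
  ## random residue identities, identical in the two protomers
  aa <- sample(AA3, n_per, replace = TRUE)
  model <- ca_structure_model(coords, chain = chain)
  model$atoms$resid <- rep(aa, 2)
  model$residues$resid <- rep(aa, 2)
  domlab <- rep(xyz$domain, 2)
  names(domlab) <- res_key(model$residues$chain, model$residues$resno,
                           model$residues$insert)
  model <- set_domain_labels(model, domlab)
  ## effector: the CTD bead with the most inter-protomer contacts (the
  ## interface-forming bead at the crossing)
  D <- as.matrix(stats::dist(coords))
  cross_contacts <- rowSums(D[1:n_per, (n_per + 1):(2 * n_per)] < 9)
  ctd <- which(xyz$domain == "CTD")
  effector <- ctd[which.max(cross_contacts[ctd])]
  labels <- list(
    n_per_protomer = n_per,
    hinge = xyz$hinge, effector = effector, tail = xyz$tail,
    linkers = xyz$linkers, domains = xyz$domain,
    sequence = paste(aa_three_to_one(aa), collapse = "")
  )
  list(model = model, labels = labels,
       spec = list(beads_per_domain = b, tail_length = tail_length,
                   seed = seed))
}

#' Ground-truth covariance model of the toy dimer
#'
#' The generator's distributional ground truth: the anisotropic
#' elastic-network covariance of the dimer geometry, with two planted
#' modifications. Tail beads get their fluctuation amplitudes scaled by
#' \code{tail_scale} (floppy sensor tails), and each protomer's effector
#' bead has its fluctuation vector replaced by the collective mean motion
#' of all other beads plus a small independent noise -- a residue that is
#' maximally globally coupled yet minimally mobile, the covariance
#' signature of an allosteric effector. The result is a valid Gaussian
#' model (a linear transform of the ENM Gaussian) from which
#' \code{\link{make_gaussian_trajectory}} draws ensembles.
#'
#' @param dimer result of \code{\link{make_toy_dimer}}.
#' @param cutoff ENM spring cutoff, Angstrom (default 9.5, chosen for the
#'   lattice geometry).
#' @param temperature_scale overall covariance scale.
#' @param tail_scale amplitude factor for tail beads (default 1.6).
#' @param effector_self weight of the effector's own elastic-network motion
#'   retained in the blend (default 0.35), keeping it strongly correlated
#'   with its structural neighbours while the collective-mean component
#'   dominates its (small) variance.
#' @param effector_noise relative variance of the effector's independent
#'   noise component.
#' @return a \code{covariance_matrix}.
#' @export
toy_covariance <- function(dimer, cutoff = 9.5, temperature_scale = 1,
                           tail_scale = 1.6, effector_self = 0.35,
                           effector_noise = 1e-3) {
  trace <- extract_ca_trace(dimer$model)
  lab <- dimer$labels
  np <- lab$n_per_protomer
  n <- 2 * np
  C <- enm_covariance(trace, cutoff = cutoff,
                      temperature_scale = temperature_scale)$C
  tails <- c(lab$tail, lab$tail + np)
  sc <- rep(1, n)
  sc[tails] <- tail_scale
  d3 <- rep(sc, each = 3)
  C <- C * outer(d3, d3)
  effs <- c(lab$effector, lab$effector + np)
  Tm <- diag(3 * n)
  for (e in effs) {
    rows <- (3 * e - 2):(3 * e)
    Tm[rows, rows] <- effector_self * diag(3)
    for (j in setdiff(seq_len(n), effs))
      Tm[cbind(rows, (3 * j - 2):(3 * j))] <-
        Tm[cbind(rows, (3 * j - 2):(3 * j))] + 1 / (n - 2)
  }
  C <- Tm %*% C %*% t(Tm)
  eps <- effector_noise * mean(diag(C))
  for (e in effs) {
    rows <- (3 * e - 2):(3 * e)
    C[cbind(rows, rows)] <- C[cbind(rows, rows)] + eps
  }
  structure(list(C = (C + t(C)) / 2, mean = trace$xyz, n = n),
            class = "covariance_matrix")
}

min_cross_dist <- function(A, B) {
  m <- Inf
  for (i in seq_len(nrow(A)))
    m <- min(m, sqrt(min((B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2 +
                         (B[, 3] - A[i, 3])^2)))
  m
}

build_protomer <- function(b, tail_length, jitter = 0.05) {
  a <- 3.8
  block <- serpentine_lattice(b, a)
  coords <- NULL
  domain <- character(0)
  linkers <- integer(0)
  domnames <- c("NTD", "MD", "CTD")
  dirs <- rbind(c(1, 0, 0), c(1, 0.6, 0), c(1, -0.6, 0),
                c(1, 0, 0.6), c(1, 0, -0.6))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  for (d in 1:3) {
    if (is.null(coords)) {
      coords <- block
      domain <- rep(domnames[d], b)
      next
    }
    ## single linker bead bridging the previous domain's exit face to the
    ## next domain's entry face, placed clash-free
    last <- coords[nrow(coords), ]
    link <- NULL
    for (k in seq_len(nrow(dirs))) {
      cand <- last + a * dirs[k, ]
      if (min(sqrt(rowSums(sweep(coords, 2, cand)^2))) >= 3.6) {
        link <- cand
        break
      }
    }
    if (is.null(link)) stop("linker placement failed")
    coords <- rbind(coords, link)
    domain <- c(domain, "linker")
    linkers <- c(linkers, nrow(coords))
    start <- link + a * c(1, 0, 0)
    offset <- start
    nxt <- sweep(block, 2, offset, "+")
    coords <- rbind(coords, nxt)
    domain <- c(domain, rep(domnames[d], b))
  }
  ## small seeded jitter breaks lattice degeneracies without disturbing
  ## bond lengths or minimum separations appreciably
  coords <- coords + matrix(stats::rnorm(length(coords), sd = jitter),
                            nrow(coords), 3)
  ## floppy N-terminal tail growing away from the body (toward -x),
  ## prepended in sequence order so residue 1 is the free end. A
  ## deterministic helical zig-zag keeps it non-collinear (six zero modes
  ## only) and moderately braced, so it is the most mobile region without
  ## swamping the slow modes.
  anchor <- coords[1, ]
  tail_xyz <- matrix(NA_real_, tail_length, 3)
  last <- anchor
  kick <- list(c(0, 1, 0), c(0, 0, 1), c(0, -1, 0), c(0, 0, -1))
  ## the helix is placed as a rigid unit (kick-cycle phase and a rotation
  ## about y are scanned until clash-free), so its internal bracing is
  ## always the same
  tail_ok <- FALSE
  for (phase in c(3, 2, 0, 1)) {
    steps <- t(vapply(seq_len(tail_length), function(k) {
      s <- c(-1, 0, 0) + 1.3 * kick[[(k - 1 + phase) %% 4 + 1]]
      s / sqrt(sum(s^2))
    }, numeric(3)))
    for (theta in c(0, 15, -15, 30, -30, 45, -45) * pi / 180) {
      R <- rbind(c(cos(theta), 0, sin(theta)), c(0, 1, 0),
                 c(-sin(theta), 0, cos(theta)))
      disp <- 3.8 * steps %*% R
      pts <- matrix(rep(anchor, each = tail_length), tail_length, 3) +
        apply(disp, 2, cumsum)
      if (min(as.matrix(stats::dist(rbind(coords, pts)))[
            seq_len(nrow(coords)), nrow(coords) + seq_len(tail_length)]) >= 3.6) {
        tail_xyz <- pts
        tail_ok <- TRUE
        break
      }
    }
    if (tail_ok) break
  }
  if (!tail_ok) stop("tail placement failed")
  coords <- rbind(tail_xyz[rev(seq_len(tail_length)), , drop = FALSE], coords)
  domain <- c(rep("tail", tail_length), domain)
  linkers <- linkers + tail_length
  tail_idx <- seq_len(tail_length)
  ## effector: middle-domain bead closest to the protomer centroid (its
  ## extra global springs are assigned at the dimer level)
  centroid <- colMeans(coords)
  md_idx <- which(domain == "MD")
  dd <- sqrt(rowSums(sweep(coords[md_idx, , drop = FALSE], 2, centroid)^2))
  effector <- md_idx[which.min(dd)]
  rownames(coords) <- NULL
  ## the planted hinge is the MD-CTD linker: the CTD (which carries the
  ## dimer interface) pivots about it in the lowest modes
  list(coords = coords, domain = domain, linkers = linkers,
       hinge = linkers[2], effector = effector, tail = tail_idx)
}

#' Generate a synthetic alignment with planted conservation and coevolution
#'
#' Independent columns are drawn from the background distribution; planted
#' conserved columns draw the consensus amino acid with probability
#' \code{conservation_level}; planted coevolving column pairs copy a random
#' bijective recoding of the first column into the second with probability
#' \code{coupling}. Gaps are sprinkled independently. When \code{query_seq}
#' is given, the first sequence (id \code{"query"}) is set to it verbatim
#' (no gaps) and conserved-column consensus letters follow it.
#'
#' @param n_seq number of sequences (>= 2; default 200).
#' @param L alignment length (default 50; ignored when \code{query_seq}
#'   fixes it).
#' @param conserved_cols column indices to plant as conserved.
#' @param conservation_level probability of the consensus letter.
#' @param coevolving_pairs 2-column matrix (or data.frame) of column pairs.
#' @param coupling copy probability for planted pairs (default 0.9).
#' @param gap_rate per-cell gap probability (default 0.05).
#' @param bg background amino-acid frequencies.
#' @param query_seq optional ungapped query sequence.
#' @param seed integer seed.
#' @return list with \code{aln} (an \code{msa}) and \code{truth} (planted
#'   conserved columns, pairs, consensus letters, bijections).
#' @export
make_synthetic_msa <- function(n_seq = 200, L = 50,
                               conserved_cols = integer(0),
                               conservation_level = 0.95,
                               coevolving_pairs = NULL, coupling = 0.9,
                               gap_rate = 0.05, bg = default_background(),
                               query_seq = NULL, seed = 1) {
  stopifnot(n_seq >= 2)
  set.seed(seed)
  if (!is.null(query_seq)) L <- nchar(query_seq)
  if (!is.null(coevolving_pairs)) {
    coevolving_pairs <- as.matrix(coevolving_pairs)
    if (max(coevolving_pairs) > L) stop("planted pair outside alignment")
  }
  if (length(conserved_cols) && max(conserved_cols) > L)
    stop("planted conserved column outside alignment")
  aa <- names(bg)
  M <- matrix(sample(aa, n_seq * L, replace = TRUE, prob = bg), n_seq, L)
  qletters <- if (!is.null(query_seq)) strsplit(query_seq, "")[[1]] else NULL
  consensus <- character(0)
  for (cc in conserved_cols) {
    letter <- if (!is.null(qletters)) qletters[cc] else sample(aa, 1)
    if (!letter %in% aa) letter <- sample(aa, 1)
    hit <- stats::runif(n_seq) < conservation_level
    M[hit, cc] <- letter
    consensus <- c(consensus, letter)
  }
  bijections <- list()
  if (!is.null(coevolving_pairs)) {
    for (r in seq_len(nrow(coevolving_pairs))) {
      a <- coevolving_pairs[r, 1]; bcol <- coevolving_pairs[r, 2]
      perm <- sample(aa)
      names(perm) <- aa
      copy <- stats::runif(n_seq) < coupling
      M[copy, bcol] <- perm[M[copy, a]]
      bijections[[r]] <- perm
    }
  }
  if (gap_rate > 0) {
    gaps <- matrix(stats::runif(n_seq * L) < gap_rate, n_seq, L)
    if (!is.null(query_seq)) gaps[1, ] <- FALSE
    M[gaps] <- "-"
  }
  if (!is.null(query_seq)) M[1, ] <- qletters
  ids <- c(if (!is.null(query_seq)) "query" else NULL,
           paste0("s", seq_len(n_seq - as.integer(!is.null(query_seq)))))
  seqs <- apply(M, 1, paste, collapse = "")
  aln <- msa_from_strings(seqs, ids)
  truth <- list(conserved_cols = conserved_cols, consensus = consensus,
                pairs = coevolving_pairs, coupling = coupling,
                conservation_level = conservation_level,
                bijections = bijections)
  list(aln = aln, truth = truth)
}

#' Draw a Gaussian trajectory ensemble from a known covariance
#'
#' Frames are mean + A z with A an eigen-factor of the target covariance and
#' z standard normal, so the sample covariance converges to the target.
#'
#' @param C_true a \code{covariance_matrix} (PSD).
#' @param n_frames number of frames (>= 2).
#' @param seed integer seed.
#' @return a \code{trajectory_ensemble} with source \code{"enm-surrogate"}.
#' @export
make_gaussian_trajectory <- function(C_true, n_frames, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eg <- eigen(C_true$C, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values)))
    stop("target covariance is not positive semidefinite")
  lam <- pmax(eg$values, 0)
  keep <- lam > 1e-12 * max(lam, 1e-300)
  A <- eg$vectors[, keep, drop = FALSE] %*% diag(sqrt(lam[keep]),
                                                 nrow = sum(keep))
  n <- C_true$n
  mu <- as.vector(t(C_true$mean))
  frames <- lapply(seq_len(max(n_frames, 2)), function(f) {
    if (sum(keep) == 0) return(C_true$mean)
    z <- stats::rnorm(sum(keep))
    matrix(mu + as.vector(A %*% z), n, 3, byrow = TRUE)
  })
  trajectory_ensemble(frames, source = "enm-surrogate")
}

#' Build a PTM annotation table on a toy dimer
#'
#' Places annotations on the planted hinge, effector, and first tail bead of
#' each requested chain, plus random background beads.
#'
#' @param dimer result of \code{\link{make_toy_dimer}}.
#' @param n_background random background sites (default 5).
#' @param chains chains to annotate (default "A").
#' @param seed integer seed.
#' @return a \code{ptm_table} data.frame with the planted role recorded in a
#'   \code{planted} column (ground-truth metadata, ignored by the mappers).
#' @export
make_ptm_table <- function(dimer, n_background = 5, chains = "A", seed = 1) {
  set.seed(seed)
  lab <- dimer$labels
  res <- dimer$model$residues
  rows <- list()
  for (ch in chains) {
    pick <- function(idx_in_chain, planted, ptm) {
      ri <- which(res$chain == ch)[idx_in_chain]
      data.frame(chain = ch, resnum = res$resno[ri], resname = res$resid[ri],
                 ptm_type = ptm, planted = planted)
    }
    rows[[length(rows) + 1]] <- pick(lab$hinge, "hinge", "phospho")
    rows[[length(rows) + 1]] <- pick(lab$effector, "effector", "phospho")
    ## the free (outermost) tail end is the strongest sensor
    rows[[length(rows) + 1]] <- pick(lab$tail[1], "sensor", "acetyl")
    plantedidx <- c(lab$hinge, lab$effector, lab$tail)
    bgpool <- setdiff(seq_len(lab$n_per_protomer), plantedidx)
    bgpick <- sample(bgpool, min(n_background, length(bgpool)))
    for (bi in bgpick)
      rows[[length(rows) + 1]] <- pick(bi, "background", "phospho")
  }
  tab <- do.call(rbind, rows)
  tab <- tab[!duplicated(tab[, c("chain", "resnum", "ptm_type")]), ]
  rownames(tab) <- NULL
  class(tab) <- c("ptm_table", "data.frame")
  tab
}

#' Write generator ground truth as a sidecar JSON
#' @param truth a list of ground-truth values.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
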