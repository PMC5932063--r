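## Perturbation response scanning: linear response of all residues to point
## forces applied at each residue in turn, and effector/sensor profiles.

#' Generate a set of perturbation force directions per residue
#'
#' Default \code{"triad"} mode draws uniformly random orthonormal triads
#' (Haar rotations); every complete triad covers the sphere exactly in
#' quadratic average, which makes the 250-force Monte-Carlo estimate of the
#' response map converge to the direction-averaged closed form with only the
#' remainder forces contributing noise. \code{"sphere"} draws independent
#' uniform directions (normalised Gaussian triples).
#'
#' @param n_residues number of residues.
#' @param count forces per residue (default 250).
#' @param seed integer seed.
#' @param mode \code{"triad"} or \code{"sphere"}.
#' @return object of class \code{force_set}: list of 3 x count unit-column
#'   matrices, one per residue.
#' @export
random_force_set <- function(n_residues, count = 250, seed = NULL,
                             mode = c("triad", "sphere")) {
  mode <- match.arg(mode)
  stopifnot(count >= 1)
  if (!is.null(seed)) set.seed(seed)
  forces <- vector("list", n_residues)
  for (i in seq_len(n_residues)) {
    if (mode == "sphere") {
      F_ <- matrix(stats::rnorm(3 * count), 3, count)
    } else {
      ntriad <- ceiling(count / 3)
      cols <- lapply(seq_len(ntriad), function(t) {
        Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
        Q
      })
      F_ <- do.call(cbind, cols)[, seq_len(count), drop = FALSE]
    }
    F_ <- sweep(F_, 2, sqrt(colSums(F_^2)), "/")
    forces[[i]] <- F_
  }
  structure(list(forces = forces, count = count, mode = mode),
            class = "force_set")
}

#' Perturbation response scan of a covariance matrix
#'
#' The inverse Hessian is taken proportional to the fluctuation covariance C
#' (linear response), so the displacement response to a force f applied at
#' residue i is dR = C F with F zero except the 3-block at i. Entry (i, j)
#' of the response map is the squared displacement of residue j averaged
#' over the forces applied at i.
#'
#' @param C a \code{covariance_matrix} (3N x 3N PSD).
#' @param forces a \code{\link{random_force_set}}; built with defaults when
#'   NULL.
#' @param n_forces forces per residue when \code{forces} is NULL.
#' @param seed seed used when building the default force set.
#' @return object of class \code{response_matrix}: list with \code{M}
#'   (N x N, entries >= 0), \code{normalization = "raw"}, \code{n_forces}.
#' @export
prs_scan <- function(C, forces = NULL, n_forces = 250, seed = NULL) {
  n <- C$n
  ev_min <- min(eigen(C$C, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-6 * max(abs(diag(C$C))))
    stop("covariance matrix is not positive semidefinite")
  if (is.null(forces)) forces <- random_force_set(n, n_forces, seed = seed)
  blk <- rep(seq_len(n), each = 3)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    Ci <- C$C[, (3 * i - 2):(3 * i), drop = FALSE]
    Dp <- Ci %*% forces$forces[[i]]            # 3N x K displacements
    M[i, ] <- rowMeans(rowsum(Dp^2, blk))
  }
  structure(list(M = M, normalization = "raw",
                 n_forces = forces$count, mode = forces$mode),
            class = "response_matrix")
}

#' Closed-form direction-averaged response map
#'
#' Averaging |C F|^2 over uniformly distributed unit force directions has a
#' closed form: with B the 3 x 3 block of C coupling residues j and i, the
#' (i, j) entry is tr(B^T B) / 3. This is the exact limit of
#' \code{\link{prs_scan}} as the number of forces grows.
#'
#' @param C a \code{covariance_matrix}.
#' @return a \code{response_matrix} with \code{normalization = "raw"} and
#'   \code{n_forces = Inf}.
#' @export
prs_closed_form <- function(C) {
  n <- C$n
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    Ci <- C$C[, (3 * i - 2):(3 * i), drop = FALSE]
    sq <- rowSums(Ci^2)
    M[i, ] <- (sq[seq(1, 3 * n, 3)] + sq[seq(2, 3 * n, 3)] +
               sq[seq(3, 3 * n, 3)]) / 3
  }
  structure(list(M = M, normalization = "raw", n_forces = Inf, mode = "exact"),
            class = "response_matrix")
}

#' Diagonal-normalise a response matrix
#'
#' Each row is divided by its diagonal entry, so the self-response becomes 1
#' and entry (i, j) measures the response at j relative to the response at
#' the perturbed residue itself.
#'
#' @param M a \code{response_matrix}.
#' @return a diagonal-normalised \code{response_matrix}.
#' @export
normalize_prs <- function(M) {
  d <- diag(M$M)
  if (any(d <= 0))
    stop("zero diagonal response at residue(s) ",
         paste(which(d <= 0), collapse = ", "), ": cannot normalise")
  M$M <- M$M / d
  M$normalization <- "diagonal-normalized"
  M
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("response_matrix: %d x %d (%s, %s forces)\n",
              nrow(x$M), ncol(x$M), x$normalization,
              format(x$n_forces)), sep = "")
  invisible(x)
}

profile_peaks <- function(x, z_threshold, min_sep = 3) {
  z <- (x - mean(x)) / max(stats::sd(x), 1e-300)
  cand <- order(z, decreasing = TRUE)
  cand <- cand[z[cand] > z_threshold]
  peaks <- integer(0)
  for (p in cand)
    if (!length(peaks) || all(abs(peaks - p) >= min_sep))
      peaks <- c(peaks, p)
  data.frame(residue = peaks, value = x[peaks], z = z[peaks])
}

#' Effector profile of a response matrix
#'
#' Mean of each row (diagonal excluded by default): the average displacement
#' the perturbation of residue i produces across the protein. Peaks are
#' residues whose z-score exceeds the threshold, with a minimum separation.
#'
#' @param M a \code{response_matrix} (typically diagonal-normalised).
#' @param exclude_diagonal drop the self-response from the mean (default).
#' @param z_threshold peak-calling z-score threshold (default 1.5).
#' @param min_sep minimum residue separation between peaks.
#' @return object of class \code{prs_profile}: list with \code{values},
#'   \code{peaks} (data.frame residue/value/z), \code{kind = "effector"}.
#' @export
effector_profile <- function(M, exclude_diagonal = TRUE, z_threshold = 1.5,
                             min_sep = 3) {
  prs_marginal(M, "effector", exclude_diagonal, z_threshold, min_sep)
}

#' Sensor profile of a response matrix
#'
#' Mean of each column (diagonal excluded by default): the average
#' displacement of residue j in response to perturbations everywhere else.
#'
#' @inheritParams effector_profile
#' @return a \code{prs_profile} with \code{kind = "sensor"}.
#' @export
sensor_profile <- function(M, exclude_diagonal = TRUE, z_threshold = 1.5,
                           min_sep = 3) {
  prs_marginal(M, "sensor", exclude_diagonal, z_threshold, min_sep)
}

prs_marginal <- function(M, kind, exclude_diagonal, z_threshold, min_sep) {
  A <- M$M
  n <- nrow(A)
  if (n < 3) stop("profiles undefined for fewer than 3 residues")
  if (exclude_diagonal) diag(A) <- NA
  vals <- if (kind == "effector") rowMeans(A, na.rm = TRUE)
          else colMeans(A, na.rm = TRUE)
  structure(list(values = vals,
                 peaks = profile_peaks(vals, z_threshold, min_sep),
                 kind = kind, z_threshold = z_threshold),
            class = "prs_profile")
}

#' @export
print.prs_profile <- function(x, ...) {
  cat(sprintf("%s profile: %d residues, peaks at %s\n", x$kind,
              length(x$values), paste(x$peaks$residue, collapse = ",")))
  invisible(x)
}

#' Write a response matrix as TSV
#' @param M a \code{response_matrix}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_response_matrix <- function(M, path) {
  utils::write.table(M$M, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
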