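## Flexibility-rigidity index (FRI): decomposition-free per-residue
## flexibility from kernel-weighted contact density.

#' Define an FRI correlation kernel
#'
#' @param kernel \code{"exponential"} (Phi(r) = exp(-(r/eta)^kappa)) or
#'   \code{"lorentz"} (Phi(r) = 1 / (1 + (r/eta)^nu)).
#' @param eta length scale, Angstrom (> 0; default 3).
#' @param power kappa (exponential) or nu (lorentz); default 2 resp. 3.
#' @return object of class \code{fri_kernel}.
#' @export
fri_kernel <- function(kernel = c("exponential", "lorentz"), eta = 3,
                       power = NULL) {
  kernel <- match.arg(kernel)
  if (is.null(power)) power <- if (kernel == "exponential") 2 else 3
  stopifnot(eta > 0, power > 0)
  structure(list(kernel = kernel, eta = eta, power = power),
            class = "fri_kernel")
}

#' Per-residue rigidity index
#'
#' mu_i = sum over j != i of Phi(r_ij) with the chosen kernel; a floor of
#' 1e-12 guards against isolated beads.
#'
#' @param coords N x 3 coordinate matrix (Angstrom) or a \code{ca_trace}.
#' @param kernel an \code{\link{fri_kernel}} (default exponential, eta = 3,
#'   kappa = 2).
#' @return numeric vector of rigidity values mu (> 0).
#' @export
rigidity_index <- function(coords, kernel = fri_kernel()) {
  xyz <- if (inherits(coords, "ca_trace")) coords$xyz else as.matrix(coords)
  if (nrow(xyz) < 2) stop("rigidity index needs at least 2 beads")
  D <- as.matrix(stats::dist(xyz))
  Phi <- if (kernel$kernel == "exponential")
    exp(-(D / kernel$eta)^kernel$power)
  else
    1 / (1 + (D / kernel$eta)^kernel$power)
  diag(Phi) <- 0
  unname(pmax(rowSums(Phi), 1e-12))
}

#' Flexibility profile, optionally ensemble-averaged
#'
#' Flexibility is the reciprocal rigidity f_i = 1 / mu_i. When a trajectory
#' is supplied the index is computed per frame and averaged over frames.
#'
#' @param mu per-residue rigidity (ignored when \code{ensemble} is given).
#' @param ensemble optional \code{trajectory_ensemble}; per-frame rigidity is
#'   computed from each frame's coordinates.
#' @param kernel an \code{\link{fri_kernel}} used in ensemble mode.
#' @param normalize min-max normalise the flexibility for plotting.
#' @return data.frame of class \code{flexibility_profile} with \code{mu},
#'   \code{flex}, and in ensemble mode \code{flex_sd}.
#' @export
flexibility_profile <- function(mu = NULL, ensemble = NULL,
                                kernel = fri_kernel(), normalize = FALSE) {
  if (!is.null(ensemble)) {
    fmat <- sapply(seq_len(ensemble$n_frames), function(f)
      1 / rigidity_index(ensemble$frames[f, , ], kernel))
    flex <- rowMeans(fmat)
    mu <- 1 / flex
    flex_sd <- apply(fmat, 1, stats::sd)
  } else {
    if (is.null(mu)) stop("supply mu or an ensemble")
    if (any(mu <= 0)) stop("rigidity values must be positive")
    flex <- 1 / mu
    flex_sd <- rep(0, length(mu))
  }
  if (normalize) {
    rng <- range(flex)
    flex <- if (diff(rng) > 0) (flex - rng[1]) / diff(rng) else flex * 0
  }
  out <- data.frame(residue = seq_along(mu), mu = mu, flex = flex,
                    flex_sd = flex_sd)
  class(out) <- c("flexibility_profile", "data.frame")
  out
}
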