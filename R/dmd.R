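## Event-driven discrete molecular dynamics with square-well pair potentials
## on C-alpha beads.

#' Build a square-well interaction model from a native C-alpha trace
#'
#' Bonded (chain-consecutive) bead pairs get a narrow well (half-width
#' \code{sigma_bond} = 0.05 by default, keeping CA-CA distances near the
#' 3.8 Angstrom equilibrium value); non-consecutive pairs closer than
#' \code{r_c} = 8 Angstrom in the native conformation get a wider well
#' (\code{sigma_nonbond} = 0.1). Each pair is confined to
#' [(1 - sigma) r0, (1 + sigma) r0] where r0 is its native distance.
#'
#' @param trace a \code{ca_trace} (the native conformation).
#' @param r_c interaction cutoff for non-consecutive pairs, Angstrom.
#' @param sigma_bond half-width for bonded pairs.
#' @param sigma_nonbond half-width for non-bonded pairs.
#' @return object of class \code{square_well_model}: list with \code{pairs}
#'   (data.frame i, j, r0, sigma, dmin, dmax, bonded), \code{xyz0}, and the
#'   residue table.
#' @export
build_square_well_model <- function(trace, r_c = 8,
                                    sigma_bond = 0.05, sigma_nonbond = 0.1) {
  xyz <- trace$xyz
  n <- nrow(xyz)
  stopifnot(n >= 2)
  D <- as.matrix(stats::dist(xyz))
  chain <- trace$residues$chain
  bonded_i <- which(chain[-n] == chain[-1])      # consecutive within a chain
  bonds <- cbind(bonded_i, bonded_i + 1L)
  bad <- D[bonds] < 2.5 | D[bonds] > 4.5
  if (any(bad))
    warning(sprintf("%d bonded pair(s) have native distance outside [2.5, 4.5] A",
                    sum(bad)))
  nb <- which(upper.tri(D) & D < r_c, arr.ind = TRUE)
  is_bond <- (nb[, 2] - nb[, 1] == 1L) & chain[nb[, 1]] == chain[nb[, 2]]
  nonb <- nb[!is_bond, , drop = FALSE]
  pairs <- data.frame(
    i = c(bonds[, 1], nonb[, 1]),
    j = c(bonds[, 2], nonb[, 2]),
    bonded = rep(c(TRUE, FALSE), c(nrow(bonds), nrow(nonb)))
  )
  pairs$r0 <- D[cbind(pairs$i, pairs$j)]
  pairs$sigma <- ifelse(pairs$bonded, sigma_bond, sigma_nonbond)
  pairs$dmin <- (1 - pairs$sigma) * pairs$r0
  pairs$dmax <- (1 + pairs$sigma) * pairs$r0
  structure(list(pairs = pairs, xyz0 = xyz, residues = trace$residues,
                 r_c = r_c),
            class = "square_well_model")
}

#' @export
print.square_well_model <- function(x, ...) {
  cat(sprintf("square_well_model: %d beads, %d pairs (%d bonded)\n",
              nrow(x$xyz0), nrow(x$pairs), sum(x$pairs$bonded)))
  invisible(x)
}

## next absolute wall-crossing time for the given pairs
## (Inf when no crossing ahead); guards snap immediate reflections for
## marginally penetrated walls
pair_event_times <- function(X, V, tnow, pi_, pj_, dmin2, dmax2) {
  r <- X[pj_, , drop = FALSE] - X[pi_, , drop = FALSE]
  v <- V[pj_, , drop = FALSE] - V[pi_, , drop = FALSE]
  a <- rowSums(v * v)
  b <- rowSums(r * v)
  r2 <- rowSums(r * r)
  t_out <- rep(Inf, length(a))
  mv <- a > 0
  co <- r2 - dmax2
  disc <- b^2 - a * co
  ok <- mv & disc >= 0
  t_out[ok] <- (-b[ok] + sqrt(disc[ok])) / a[ok]
  ## outside the outer wall moving outward: reflect immediately
  t_out[mv & co > 0 & b >= 0] <- 0
  t_in <- rep(Inf, length(a))
  ci <- r2 - dmin2
  disc2 <- b^2 - a * ci
  ok2 <- mv & b < 0 & disc2 >= 0 & ci > 0
  t_in[ok2] <- (-b[ok2] - sqrt(disc2[ok2])) / a[ok2]
  ## penetrated below the inner wall while approaching: reflect immediately
  t_in[mv & ci < 0 & b < 0] <- 0
  t <- pmin(t_out, t_in)
  t[t < 0] <- Inf
  tnow + t
}

## project a configuration into the feasible well region (used only when a
## supplied start violates constraints)
project_to_wells <- function(X, pairs, max_iter = 1000, tol = 1e-9) {
  for (it in seq_len(max_iter)) {
    r <- X[pairs$j, , drop = FALSE] - X[pairs$i, , drop = FALSE]
    d <- sqrt(rowSums(r * r))
    lo <- d < pairs$dmin * (1 + tol)
    hi <- d > pairs$dmax * (1 - tol)
    viol <- which(lo | hi)
    if (!length(viol)) return(list(X = X, iters = it - 1))
    for (k in viol) {
      i <- pairs$i[k]; j <- pairs$j[k]
      rv <- X[j, ] - X[i, ]
      dk <- sqrt(sum(rv^2))
      target <- if (dk < pairs$dmin[k]) pairs$dmin[k] * (1 + 2 * tol)
                else pairs$dmax[k] * (1 - 2 * tol)
      shift <- rv / dk * (target - dk) / 2
      X[i, ] <- X[i, ] - shift
      X[j, ] <- X[j, ] + shift
    }
  }
  stop("could not project start configuration into the square wells")
}

#' Run event-driven square-well discrete molecular dynamics
#'
#' Beads move ballistically between collisions; at each wall crossing the
#' normal component of the relative velocity of the colliding pair is
#' reflected elastically (equal masses), conserving energy and momentum.
#' Initial velocities are drawn from the Maxwell-Boltzmann distribution at
#' the requested reduced temperature (mass = 1, k_B = 1). Frames are sampled
#' either every \code{sample_every} collision events or, if \code{sample_dt}
#' is given, at regular time intervals. An optional Andersen-style thermostat
#' resamples all velocities every \code{thermo_interval} time units
#' (default off; note that an unthermostatted run is microcanonical and for
#' very small systems conserved quantities such as relative angular momentum
#' prevent full canonical sampling).
#'
#' @param model a \code{square_well_model}.
#' @param start starting coordinates (N x 3); default the native conformation.
#'   A start violating well constraints is projected into the feasible region
#'   first (logged).
#' @param temperature reduced temperature for velocity initialisation.
#' @param n_events number of collision events to run.
#' @param sample_every sample a frame every this many collision events.
#' @param sample_dt if non-NULL, sample at this time interval instead.
#' @param burn_in collision events to discard before sampling.
#' @param thermo_interval Andersen velocity-resampling interval (time units);
#'   NULL disables the thermostat.
#' @param seed integer seed.
#' @return a \code{trajectory_ensemble} (see
#'   \code{\link{trajectory_ensemble}}) with source \code{"dmd"} and extra
#'   fields \code{ke_initial}, \code{ke_final}, \code{momentum_initial},
#'   \code{momentum_final}, \code{n_events}, \code{time}.
#' @export
run_dmd <- function(model, start = NULL, temperature = 1, n_events = 10000,
                    sample_every = 100, sample_dt = NULL, burn_in = 0,
                    thermo_interval = NULL, seed = NULL) {
  if (n_events <= 0) stop("n_events must be positive")
  if (!is.null(seed)) set.seed(seed)
  X <- if (is.null(start)) model$xyz0 else as.matrix(start)
  n <- nrow(X)
  pr <- model$pairs
  d0 <- sqrt(rowSums((X[pr$j, , drop = FALSE] - X[pr$i, , drop = FALSE])^2))
  if (any(d0 < pr$dmin | d0 > pr$dmax)) {
    message("run_dmd: start violates well constraints; projecting into wells")
    X <- project_to_wells(X, pr)$X
  }
  V <- matrix(stats::rnorm(3 * n, sd = sqrt(temperature)), n, 3)
  V <- sweep(V, 2, colMeans(V))             # remove centre-of-mass drift
  ke0 <- 0.5 * sum(V^2)
  p0 <- colSums(V)

  pi_ <- pr$i; pj_ <- pr$j
  dmin2 <- pr$dmin^2; dmax2 <- pr$dmax^2
  ## adjacency: pair indices touching each bead
  touch <- lapply(seq_len(n), function(b) which(pi_ == b | pj_ == b))
  tnow <- 0
  tev <- pair_event_times(X, V, tnow, pi_, pj_, dmin2, dmax2)
  frames <- list()
  times <- numeric(0)
  next_sample_t <- if (!is.null(sample_dt)) sample_dt else Inf
  next_thermo_t <- if (!is.null(thermo_interval)) thermo_interval else Inf
  ev <- 0L
  while (ev < n_events) {
    k <- which.min(tev)
    t_next <- tev[k]
    if (!is.finite(t_next)) stop("no pending events: system is unconstrained")
    ## interleave timed thermostat / sampling actions before the collision
    if (min(next_sample_t, next_thermo_t) < t_next) {
      t_act <- min(next_sample_t, next_thermo_t)
      X <- X + V * (t_act - tnow)
      tnow <- t_act
      if (next_thermo_t <= next_sample_t) {
        V <- matrix(stats::rnorm(3 * n, sd = sqrt(temperature)), n, 3)
        V <- sweep(V, 2, colMeans(V))
        tev <- pair_event_times(X, V, tnow, pi_, pj_, dmin2, dmax2)
        next_thermo_t <- next_thermo_t + thermo_interval
      } else {
        if (ev >= burn_in) {
          frames[[length(frames) + 1L]] <- X
          times <- c(times, tnow)
        }
        next_sample_t <- next_sample_t + sample_dt
      }
      next
    }
    X <- X + V * (t_next - tnow)
    tnow <- t_next
    a <- pi_[k]; b <- pj_[k]
    rv <- X[b, ] - X[a, ]
    nv <- rv / sqrt(sum(rv^2))
    vr <- sum((V[b, ] - V[a, ]) * nv)
    V[a, ] <- V[a, ] + vr * nv
    V[b, ] <- V[b, ] - vr * nv
    upd <- unique(c(touch[[a]], touch[[b]]))
    tev[upd] <- pair_event_times(X, V, tnow, pi_[upd], pj_[upd],
                                 dmin2[upd], dmax2[upd])
    ev <- ev + 1L
    if (is.null(sample_dt) && ev > burn_in && ev %% sample_every == 0L) {
      frames[[length(frames) + 1L]] <- X
      times <- c(times, tnow)
    }
  }
  if (length(frames) < 2) {
    frames <- c(frames, list(X))
    times <- c(times, tnow)
    if (length(frames) < 2) {
      frames <- c(list(model$xyz0), frames)
      times <- c(0, times)
    }
  }
  traj <- trajectory_ensemble(frames, source = "dmd",
                              residues = model$residues)
  traj$ke_initial <- ke0
  traj$ke_final <- 0.5 * sum(V^2)
  traj$momentum_initial <- p0
  traj$momentum_final <- colSums(V)
  traj$n_events <- ev
  traj$time <- tnow
  traj$times <- times
  traj
}

#' Maximum relative well violation over a trajectory
#'
#' For every frame and pair, the larger of (d - dmax)/dmax and
#' (dmin - d)/dmin; zero or negative means all constraints hold.
#'
#' @param model a \code{square_well_model}.
#' @param traj a \code{trajectory_ensemble} over the same beads.
#' @return the maximum relative violation (a small number ~1e-12 means the
#'   hard walls held).
#' @export
max_well_violation <- function(model, traj) {
  pr <- model$pairs
  worst <- -Inf
  for (f in seq_len(traj$n_frames)) {
    X <- traj$frames[f, , ]
    d <- sqrt(rowSums((X[pr$j, , drop = FALSE] - X[pr$i, , drop = FALSE])^2))
    worst <- max(worst, (d - pr$dmax) / pr$dmax, (pr$dmin - d) / pr$dmin)
  }
  worst
}
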