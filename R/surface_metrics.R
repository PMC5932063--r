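## Solvent accessibility (dot-sphere SASA), relative accessibility classes,
## and residue depth from the retained surface dot set.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, H = 1.20, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

## deterministic golden-spiral point set on the unit sphere
sphere_dots <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area by the dot-sphere (Shrake-Rupley) method
#'
#' Each heavy atom carries a deterministic golden-spiral dot set on its
#' solvent-expanded sphere (van der Waals radius + probe); dots inside any
#' neighbouring expanded sphere are occluded. Surviving dots are retained for
#' residue-depth computation. Hydrogens are ignored. For C-alpha-only input
#' (all atoms named CA) a coarse mode is used with a 3.0 Angstrom bead
#' radius.
#'
#' @param model a \code{structure_model}.
#' @param probe probe radius, Angstrom (default 1.4, water).
#' @param n_dots dots per atom (default 960).
#' @return object of class \code{sasa_profile}: list with \code{atom_area},
#'   \code{residue} (data.frame chain, resno, resid, sasa), the retained
#'   \code{surface_dots} (matrix, with \code{atom} index attribute),
#'   \code{probe}, \code{n_dots}, \code{mode} ("all-atom" or "coarse").
#' @export
compute_sasa <- function(model, probe = 1.4, n_dots = 960) {
  at <- model$atoms
  at <- at[at$is_protein & !at$is_hydrogen, , drop = FALSE]
  coarse <- all(at$elety == "CA")
  if (coarse) {
    rad <- rep(3.0, nrow(at))
  } else {
    el <- toupper(trimws(at$elesy))
    el[el == ""] <- substr(gsub("[0-9]", "", at$elety[el == ""]), 1, 1)
    rad <- VDW_RADII[el]
    if (anyNA(rad))
      stop("no van der Waals radius for element(s): ",
           paste(unique(el[is.na(rad)]), collapse = ", "))
  }
  R <- rad + probe
  xyz <- cbind(at$x, at$y, at$z)
  n <- nrow(at)
  dots <- sphere_dots(n_dots)
  D <- as.matrix(stats::dist(xyz))
  area <- numeric(n)
  surf <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- which(D[i, ] < R[i] + R & seq_len(n) != i)
    pts <- sweep(dots * R[i], 2, xyz[i, ], "+")
    keep <- rep(TRUE, n_dots)
    for (j in nb) {
      dd <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
            (pts[, 3] - xyz[j, 3])^2
      keep <- keep & dd >= R[j]^2
      if (!any(keep)) break
    }
    area[i] <- 4 * pi * R[i]^2 * sum(keep) / n_dots
    if (any(keep)) surf[[i]] <- pts[keep, , drop = FALSE]
  }
  surf_mat <- do.call(rbind, surf)
  surf_atom <- rep(seq_len(n), vapply(surf, function(s)
    if (is.null(s)) 0L else nrow(s), integer(1)))
  key <- res_key(at$chain, at$resno, at$insert)
  rk <- res_key(model$residues$chain, model$residues$resno,
                model$residues$insert)
  ridx <- match(key, rk)
  res_sasa <- rep(0, nrow(model$residues))
  agg <- tapply(area, ridx, sum)
  res_sasa[as.integer(names(agg))] <- agg
  residue <- data.frame(chain = model$residues$chain,
                        resno = model$residues$resno,
                        resid = model$residues$resid,
                        sasa = res_sasa)
  structure(list(atom_area = area, atom_table = at, atom_res_index = ridx,
                 atom_radius = unname(rad),
                 residue = residue, surface_dots = surf_mat,
                 surface_dot_atom = surf_atom, probe = probe,
                 n_dots = n_dots, mode = if (coarse) "coarse" else "all-atom"),
            class = "sasa_profile")
}

#' @export
print.sasa_profile <- function(x, ...) {
  cat(sprintf("sasa_profile (%s): %d residues, total %.1f A^2\n",
              x$mode, nrow(x$residue), sum(x$residue$sasa)))
  invisible(x)
}

#' Built-in unfolded-state (Gly-X-Gly) reference accessibilities
#'
#' Theoretical maximal accessible areas per residue type (Angstrom^2),
#' after Tien et al.; override with a two-column TSV via
#' \code{\link{read_background}}-style loading.
#'
#' @return named numeric vector over the 20 residue types (3-letter codes).
#' @export
default_max_accessibility <- function() {
  c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
    GLU = 223, GLN = 225, GLY = 104, HIS = 224, ILE = 197,
    LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
    SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)
}

#' Relative solvent accessibility and exposure classes
#'
#' RSA is the observed residue SASA as a percentage of the unfolded-state
#' reference for that residue type. A residue is classed exposed if RSA
#' exceeds 50\%, buried if below 20\%, intermediate otherwise; residues with
#' RSA below 10\% are additionally flagged deeply buried. Values above 150\%
#' (distorted geometry) are capped with a warning. In coarse (C-alpha bead)
#' mode exposure classes are suppressed.
#'
#' @param sasa a \code{sasa_profile}.
#' @param ref named reference accessibilities (default
#'   \code{\link{default_max_accessibility}}).
#' @return data.frame of class \code{rsa_profile} with \code{chain},
#'   \code{resno}, \code{resid}, \code{sasa}, \code{rsa} (percent),
#'   \code{class}, \code{deeply_buried}.
#' @export
relative_accessibility <- function(sasa, ref = default_max_accessibility()) {
  res <- sasa$residue
  missing <- setdiff(unique(res$resid), names(ref))
  if (length(missing) && sasa$mode != "coarse")
    stop("no reference accessibility for residue type(s): ",
         paste(missing, collapse = ", "))
  if (sasa$mode == "coarse") {
    message("relative_accessibility: coarse C-alpha mode; exposure classes suppressed")
    rv <- rep(NA_real_, nrow(res))
    cls <- rep(NA_character_, nrow(res))
    out <- data.frame(res, rsa = rv, class = cls, deeply_buried = NA)
  } else {
    rv <- 100 * res$sasa / ref[res$resid]
    if (any(rv > 150)) {
      warning(sprintf("%d residue(s) with RSA > 150%%; capped", sum(rv > 150)))
      rv[rv > 150] <- 150
    }
    cls <- ifelse(rv > 50, "exposed", ifelse(rv < 20, "buried", "intermediate"))
    out <- data.frame(res, rsa = unname(rv), class = cls,
                      deeply_buried = rv < 10)
  }
  class(out) <- c("rsa_profile", "data.frame")
  out
}

#' Residue depth from the accessible-surface dot set
#'
#' Depth of an atom is its minimum Euclidean distance to any retained
#' accessible-surface dot, so surface atoms have depth near zero; per residue
#' both the mean and the minimum over its atoms are reported. This dot-based
#' depth is a deterministic proxy for solvent-box residue depth and is
#' monotone-equivalent to it on compact structures.
#'
#' @param model the \code{structure_model} the SASA was computed on.
#' @param sasa the matching \code{sasa_profile} (surface dots retained).
#' @return data.frame of class \code{rd_profile} with \code{chain},
#'   \code{resno}, \code{rd_mean}, \code{rd_min} (Angstrom).
#' @export
residue_depth <- function(model, sasa) {
  if (is.null(sasa$surface_dots) || nrow(sasa$surface_dots) == 0)
    stop("empty surface dot set: residue depth undefined")
  at <- sasa$atom_table
  xyz <- cbind(at$x, at$y, at$z)
  S <- sasa$surface_dots
  ## depth = distance from the atom to the accessible surface; an atom
  ## owning a surviving dot is on the surface (depth 0)
  depth <- vapply(seq_len(nrow(xyz)), function(i) {
    dmin <- sqrt(min((S[, 1] - xyz[i, 1])^2 + (S[, 2] - xyz[i, 2])^2 +
                     (S[, 3] - xyz[i, 3])^2))
    max(dmin - sasa$atom_radius[i] - sasa$probe, 0)
  }, numeric(1))
  ridx <- sasa$atom_res_index
  n <- nrow(model$residues)
  rd_mean <- rep(NA_real_, n); rd_min <- rep(NA_real_, n)
  m <- tapply(depth, ridx, mean); mn <- tapply(depth, ridx, min)
  rd_mean[as.integer(names(m))] <- m
  rd_min[as.integer(names(mn))] <- mn
  out <- data.frame(chain = model$residues$chain,
                    resno = model$residues$resno,
                    rd_mean = rd_mean, rd_min = rd_min)
  class(out) <- c("rd_profile", "data.frame")
  out
}

#' Ensemble-averaged residue SASA over trajectory frames
#'
#' Computes the per-residue accessible area for every frame of the ensemble
#' and returns the mean (and standard deviation) over frames, so equilibrium
#' profiles reflect the whole conformational ensemble rather than one
#' structure.
#'
#' @param model a \code{structure_model} supplying chain/residue identities.
#' @param traj a \code{trajectory_ensemble} with one bead per residue.
#' @param probe probe radius, Angstrom.
#' @param n_dots dots per atom.
#' @return data.frame with \code{chain}, \code{resno}, \code{sasa_mean},
#'   \code{sasa_sd}.
#' @export
ensemble_sasa <- function(model, traj, probe = 1.4, n_dots = 240) {
  per_frame <- sapply(seq_len(traj$n_frames), function(f) {
    m <- ca_structure_model(traj$frames[f, , ],
                            chain = model$residues$chain)
    m$atoms$resid <- model$residues$resid
    m$residues$resid <- model$residues$resid
    compute_sasa(m, probe = probe, n_dots = n_dots)$residue$sasa
  })
  data.frame(chain = model$residues$chain, resno = model$residues$resno,
             sasa_mean = rowMeans(per_frame),
             sasa_sd = apply(per_frame, 1, stats::sd))
}

#' Write accessibility/depth profiles as TSV
#' @param rsa an \code{rsa_profile}.
#' @param rd an \code{rd_profile} on the same residues.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_surface_profile <- function(rsa, rd, path) {
  df <- data.frame(chain = rsa$chain, resnum = rsa$resno, sasa = rsa$sasa,
                   rsa = rsa$rsa, class = rsa$class,
                   rd_mean = rd$rd_mean, rd_min = rd$rd_min)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
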