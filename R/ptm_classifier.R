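## Integration: flag conserved PTM sites and assign functional roles
## (hinge / effector / sensor / carrier) from the combined profiles.

#' Flag conserved PTM sites
#'
#' A mapped PTM site is flagged conserved when the KL conservation of its
#' alignment column is markedly higher than the column average, quantified
#' as mean + k_sd standard deviations over all scored columns. Sites
#' without a mapped column are reported unknown and excluded from the set.
#'
#' @param cons a \code{conservation_profile}.
#' @param sites mapped PTM sites (the \code{mapped} element of
#'   \code{\link{map_ptm_sites}}, with \code{res_index}).
#' @param colmap a \code{column_map} linking residues to columns.
#' @param k_sd threshold multiplier (default 1).
#' @return list with \code{table} (per-site data.frame: res_index, column,
#'   kl, conserved, unknown), \code{conserved_res} (residue indices),
#'   \code{threshold}.
#' @export
conserved_ptms <- function(cons, sites, colmap, k_sd = 1.0) {
  kl <- cons$kl
  thr <- mean(kl, na.rm = TRUE) + k_sd * stats::sd(kl, na.rm = TRUE)
  col_of <- colmap$column[match(sites$res_index, colmap$res_index)]
  site_kl <- kl[col_of]
  unknown <- is.na(col_of) | is.na(site_kl)
  conserved <- !unknown & site_kl > thr
  tab <- data.frame(res_index = sites$res_index, column = col_of,
                    kl = site_kl, conserved = conserved, unknown = unknown)
  list(table = tab, conserved_res = sites$res_index[conserved],
       threshold = thr)
}

role_z <- function(x) (x - mean(x, na.rm = TRUE)) / max(stats::sd(x, na.rm = TRUE), 1e-300)

#' Average per-residue values across homodimer protomers
#'
#' Residues at the same position of each chain are averaged; a warning is
#' emitted when the protomers disagree by more than 20\% relative
#' (symmetry deviation).
#'
#' @param values per-residue numeric vector.
#' @param chains chain id per residue.
#' @return vector of the same length with each entry replaced by its
#'   cross-protomer mean.
#' @export
average_protomers <- function(values, chains) {
  pos <- stats::ave(seq_along(values), chains, FUN = seq_along)
  key <- pos
  means <- tapply(values, key, mean, na.rm = TRUE)
  avg <- as.numeric(means[as.character(key)])
  rel <- abs(values - avg) / pmax(abs(avg), 1e-12)
  if (stats::median(rel, na.rm = TRUE) > 0.2)
    warning("protomer profiles deviate by more than 20% (symmetry warning)")
  avg
}

#' Classify PTM sites into allosteric roles
#'
#' Roles are non-exclusive: a site is an \emph{effector} when its
#' effector-profile z-score exceeds \code{z_eff}; a \emph{sensor} when its
#' sensor z-score exceeds \code{z_sen}; a \emph{hinge} when it lies within
#' \code{hinge_window} residues of a slow-mode local minimum; a
#' \emph{carrier} when it lies in a slow-mode local-maximum region or its
#' sensor value reaches the top quartile. Sites matching nothing are
#' \code{none}. With \code{chains} supplied, profiles are first averaged
#' across homodimer protomers.
#'
#' @param effector,sensor \code{prs_profile} objects (or numeric vectors).
#' @param slow_modes a \code{slow_mode_profile}.
#' @param conserved result of \code{\link{conserved_ptms}} (or NULL).
#' @param sites mapped PTM site table with \code{res_index}.
#' @param z_eff,z_sen z-score thresholds (default 1.5).
#' @param hinge_window residue window around slow-mode minima (default 2).
#' @param carrier_quantile sensor quantile for the carrier rule.
#' @param chains optional chain id per residue for protomer averaging.
#' @return data.frame of class \code{ptm_roles}: one row per site with the
#'   supporting scores, \code{conserved}, and \code{roles}
#'   (comma-separated).
#' @export
classify_roles <- function(effector, sensor, slow_modes, conserved, sites,
                           z_eff = 1.5, z_sen = 1.5, hinge_window = 2,
                           carrier_quantile = 0.75, chains = NULL) {
  if (nrow(sites) == 0) {
    out <- data.frame(res_index = integer(0), effector_z = numeric(0),
                      sensor_z = numeric(0), slow_mode = numeric(0),
                      conserved = logical(0), roles = character(0))
    class(out) <- c("ptm_roles", "data.frame")
    return(out)
  }
  ev <- if (inherits(effector, "prs_profile")) effector$values else effector
  sv <- if (inherits(sensor, "prs_profile")) sensor$values else sensor
  sm <- slow_modes$profile
  minima <- slow_modes$minima
  maxima <- slow_modes$maxima
  if (!is.null(chains)) {
    ev <- average_protomers(ev, chains)
    sv <- average_protomers(sv, chains)
  }
  ez <- role_z(ev)
  sz <- role_z(sv)
  sq <- stats::quantile(sv, carrier_quantile, na.rm = TRUE)
  cons_res <- if (is.null(conserved)) integer(0) else conserved$conserved_res
  rows <- lapply(seq_len(nrow(sites)), function(r) {
    i <- sites$res_index[r]
    roles <- character(0)
    if (length(minima) && min(abs(minima - i)) <= hinge_window)
      roles <- c(roles, "hinge")
    if (ez[i] > z_eff) roles <- c(roles, "effector")
    if (sz[i] > z_sen) roles <- c(roles, "sensor")
    if ((length(maxima) && min(abs(maxima - i)) <= hinge_window) ||
        sv[i] > sq)
      roles <- c(roles, "carrier")
    if (!length(roles)) roles <- "none"
    data.frame(res_index = i, effector_z = ez[i], sensor_z = sz[i],
               slow_mode = sm[i], conserved = i %in% cons_res,
               roles = paste(roles, collapse = ","))
  })
  out <- do.call(rbind, rows)
  extra <- sites[, intersect(c("chain", "resnum", "resname", "ptm_type",
                               "planted"), names(sites)), drop = FALSE]
  out <- cbind(extra, out)
  rownames(out) <- NULL
  class(out) <- c("ptm_roles", "data.frame")
  out
}

#' Assemble the per-site summary report
#'
#' One row per mapped PTM site collecting every available score, plus
#' machine-readable run metadata (seeds, thresholds, package version).
#'
#' @param roles a \code{ptm_roles} table.
#' @param profiles optional named list of extra per-residue vectors or
#'   data.frames (e.g. rsa, rd, fri, bfactor) indexed by residue.
#' @param metadata named list of run parameters.
#' @return object of class \code{ptm_report}: list with \code{table} and
#'   \code{metadata}.
#' @export
summarize_ptm_analysis <- function(roles, profiles = list(),
                                   metadata = list()) {
  tab <- roles
  for (nm in names(profiles)) {
    v <- profiles[[nm]]
    if (is.data.frame(v)) v <- v[[ncol(v)]]
    tab[[nm]] <- v[tab$res_index]
  }
  metadata$package_version <- as.character(utils::packageVersion("allokit"))
  structure(list(table = tab, metadata = metadata), class = "ptm_report")
}

#' Write a PTM report as TSV plus JSON metadata
#' @param report a \code{ptm_report}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_ptm_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$table, file.path(dir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(metadata = report$metadata, sites = report$table),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' @export
print.ptm_report <- function(x, ...) {
  cat(sprintf("ptm_report: %d sites\n", nrow(x$table)))
  print(utils::head(x$table, 10))
  invisible(x)
}
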