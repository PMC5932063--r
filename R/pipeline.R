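## End-to-end orchestration on synthetic or user-supplied inputs.

#' Default pipeline configuration
#'
#' All stage parameters with their defaults; thresholds that have an
#' established printed value (MI threshold 6.5, proximity 5 Angstrom,
#' square-well cutoff 8 Angstrom, R_MI threshold 0.5, 250 perturbation
#' forces) default to those values.
#'
#' @return named list of parameters.
#' @export
default_config <- function() {
  list(
    beads_per_domain = 10, tail_length = 7,
    use_msa = TRUE,
    msa_n_seq = 200, msa_conservation_level = 0.95, msa_coupling = 0.9,
    msa_gap_rate = 0.05, msa_n_pairs = 5, mi_threshold = 6.5,
    mi_shuffles = 25,
    pmi_cutoff = 5, pmi_coarse_cutoff = 8,
    enm_cutoff = 9.5, enm_frames = 400, enm_temperature = 1, n_sims = 2,
    prs_forces = 250,
    net_threshold = 0.5, k_paths = 3,
    conservation_k = 1.0, z_eff = 1.5, z_sen = 1.5, hinge_window = 2,
    carrier_quantile = 0.75,
    n_background_sites = 5
  )
}

#' Read a pipeline configuration file (YAML)
#' @param path YAML file with any subset of \code{\link{default_config}}.
#' @return full configuration list (file values over defaults).
#' @export
read_run_config <- function(path) {
  cfg <- default_config()
  usr <- yaml::read_yaml(path)
  cfg[names(usr)] <- usr
  cfg
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full allosteric PTM analysis pipeline on a synthetic system
#'
#' Generates the toy dimer, synthetic alignment and PTM table, runs every
#' analysis stage in dependency order (structure, coevolution, dynamics,
#' surface/FRI/PRS/slow modes, network, classification) and writes all
#' artifacts under \code{output_dir}. Without an alignment
#' (\code{use_msa = FALSE}) the coevolution-dependent outputs are skipped
#' and the network is built in pure-dynamics mode.
#'
#' @param output_dir artifact directory (created; default a tempdir).
#' @param seed master seed; every stage seed is derived from it.
#' @param config named list overriding \code{\link{default_config}}.
#' @return invisible list with all intermediate objects and the
#'   \code{report}.
#' @export
run_full_pipeline <- function(output_dir = tempfile("allokit_run_"),
                              seed = 7, config = list()) {
  cfg <- default_config()
  cfg[names(config)] <- config
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(c(cfg, seed = seed), file.path(output_dir, "config.yaml"))

  ## --- structure -----------------------------------------------------
  dimer <- run_stage("synth", make_toy_dimer(cfg$beads_per_domain,
                                             cfg$tail_length, seed = seed))
  model <- dimer$model
  trace <- extract_ca_trace(model)
  n <- nrow(trace$xyz)
  chains <- trace$residues$chain
  write_structure(model, file.path(output_dir, "structure.pdb"))
  write_ground_truth(dimer$labels[c("hinge", "effector", "tail", "linkers",
                                    "n_per_protomer")],
                     file.path(output_dir, "ground_truth.json"))
  ptm_tab <- make_ptm_table(dimer, cfg$n_background_sites, chains = "A",
                            seed = seed + 1)
  write_ptm_table(ptm_tab, file.path(output_dir, "ptm_sites.tsv"))
  mapped <- map_ptm_sites(ptm_tab, model)

  ## contact map: heavy-atom 5 A on all-atom input; CA-only toy input uses
  ## a CA-CA cutoff instead
  cm <- run_stage("contacts", compute_contact_map(
    model, cutoff = cfg$pmi_coarse_cutoff, metric = "ca-ca"))

  ## --- coevolution ---------------------------------------------------
  colmap <- NULL; cons <- NULL; pmi <- NULL; cmi <- NULL
  if (isTRUE(cfg$use_msa)) {
    nper <- dimer$labels$n_per_protomer
    conserved_cols <- unique(c(dimer$labels$hinge, dimer$labels$effector))
    pairpool <- setdiff(seq_len(nper), conserved_cols)
    set.seed(seed + 2)
    pairs <- matrix(sample(pairpool, 2 * cfg$msa_n_pairs), ncol = 2)
    syn <- run_stage("msa", make_synthetic_msa(
      n_seq = cfg$msa_n_seq, conserved_cols = conserved_cols,
      conservation_level = cfg$msa_conservation_level,
      coevolving_pairs = pairs, coupling = cfg$msa_coupling,
      gap_rate = cfg$msa_gap_rate, query_seq = dimer$labels$sequence,
      seed = seed + 3))
    colmap <- run_stage("colmap", map_columns_to_residues(
      syn$aln, model, "query"))
    cons <- run_stage("kl", kl_conservation(syn$aln))
    mim <- run_stage("mi", mutual_information_matrix(
      syn$aln, correction = "zscore", n_shuffle = cfg$mi_shuffles,
      seed = seed + 4))
    cmi <- cumulative_mi(mim, t = cfg$mi_threshold)
    pmi <- run_stage("pmi", proximity_mi(cmi, cm, colmap))
  }

  ## --- dynamics ------------------------------------------------------
  C_true <- run_stage("cov_model", toy_covariance(
    dimer, cutoff = cfg$enm_cutoff,
    temperature_scale = cfg$enm_temperature))
  trajs <- run_stage("ensemble", lapply(seq_len(cfg$n_sims), function(s) {
    tj <- make_gaussian_trajectory(C_true, cfg$enm_frames,
                                   seed = seed + 10 + s)
    tj$residues <- trace$residues
    tj
  }))
  C <- run_stage("covariance", compute_covariance(trajs[[1]]))
  bf <- compute_bfactors(C)
  slow <- run_stage("slow_modes", pca_slow_modes(C))

  ## --- surface / flexibility ----------------------------------------
  sasa <- run_stage("sasa", compute_sasa(model))
  rsa <- suppressMessages(relative_accessibility(sasa))
  rd <- run_stage("depth", residue_depth(model, sasa))
  fri <- run_stage("fri", flexibility_profile(ensemble = trajs[[1]]))

  ## --- PRS -----------------------------------------------------------
  prs <- run_stage("prs", prs_scan(C, n_forces = cfg$prs_forces,
                                   seed = seed + 20))
  prs_norm <- normalize_prs(prs)
  eff <- effector_profile(prs_norm)
  sen <- sensor_profile(prs_norm)

  ## --- network -------------------------------------------------------
  rmi <- run_stage("rmi", generalized_correlation(trajs, pmi = pmi))
  net <- run_stage("network", build_network(rmi, contacts = cm,
                                            threshold = cfg$net_threshold))
  sp <- run_stage("paths", all_shortest_paths(net))
  eb <- edge_betweenness_map(net)
  path_set <- NULL
  if (nrow(eff$peaks) && nrow(sen$peaks))
    path_set <- run_stage("pathways", communication_pathways(
      net, eff$peaks$residue, sen$peaks$residue, k_paths = cfg$k_paths))

  ## --- classification ------------------------------------------------
  conserved <- if (!is.null(cons))
    conserved_ptms(cons, mapped$mapped, colmap, k_sd = cfg$conservation_k)
  roles <- run_stage("classify", classify_roles(
    eff, sen, slow, conserved, mapped$mapped,
    z_eff = cfg$z_eff, z_sen = cfg$z_sen,
    hinge_window = cfg$hinge_window,
    carrier_quantile = cfg$carrier_quantile, chains = chains))
  profiles <- list(bfactor = bf$bfactor, fri_flex = fri$flex,
                   sasa = rsa$sasa, rd_mean = rd$rd_mean)
  if (!is.null(pmi)) profiles$pmi <- pmi
  report <- summarize_ptm_analysis(roles, profiles,
                                   metadata = c(cfg, seed = seed))
  write_ptm_report(report, output_dir)
  write_network(net, file.path(output_dir, "network.tsv"))
  write_trajectory(trajs[[1]], file.path(output_dir, "ensemble.pdb"))

  invisible(list(config = cfg, seed = seed, dimer = dimer, model = model,
                 trace = trace, contacts = cm, colmap = colmap,
                 conservation = cons, cmi = cmi, pmi = pmi,
                 trajectories = trajs, covariance = C, bfactors = bf,
                 slow_modes = slow, sasa = sasa, rsa = rsa, rd = rd,
                 fri = fri, prs = prs_norm, effector = eff, sensor = sen,
                 rmi = rmi, network = net, shortest_paths = sp,
                 betweenness = eb, pathways = path_set,
                 ptm_sites = mapped, roles = roles, report = report,
                 output_dir = output_dir))
}
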