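test_that("toy dimer geometry is counted, bonded, and reproducible", {
  d <- make_toy_dimer(beads_per_domain = 10, tail_length = 7, seed = 1)
  lab <- d$labels
  np <- lab$n_per_protomer
  expect_equal(np, 3 * 10 + 2 + 7)
  expect_equal(n_residues(d$model), 2 * np)
  expect_equal(unique(d$model$residues$chain), c("A", "B"))

  tr <- extract_ca_trace(d$model)
  ## consecutive beads within a chain are bonded at 3.8 A
  for (ch in c("A", "B")) {
    xyz <- tr$xyz[tr$residues$chain == ch, ]
    bonds <- sqrt(rowSums((xyz[-1, ] - xyz[-nrow(xyz), ])^2))
    expect_true(all(abs(bonds - 3.8) < 0.5))
  }
  ## minimum separation respected
  expect_gt(min(stats::dist(tr$xyz)), 3.4)

  ## planted indices valid; the hinge is the MD-CTD linker
  expect_equal(lab$hinge, lab$linkers[2])
  expect_equal(lab$domains[lab$hinge], "linker")
  expect_true(all(lab$domains[lab$tail] == "tail"))
  expect_equal(lab$domains[lab$effector], "CTD")

  ## same seed, same coordinates; protomers identical up to rigid motion
  d2 <- make_toy_dimer(seed = 1)
  expect_identical(extract_ca_trace(d2$model)$xyz, tr$xyz)
  A <- tr$xyz[1:np, ]; B <- tr$xyz[(np + 1):(2 * np), ]
  dA <- stats::dist(A); dB <- stats::dist(B)
  expect_equal(as.vector(dA), as.vector(dB), tolerance = 1e-9)
})

test_that("the toy covariance is PSD with planted amplitude structure", {
  d <- make_toy_dimer(seed = 2)
  lab <- d$labels
  np <- lab$n_per_protomer
  Ct <- toy_covariance(d)
  ev <- eigen(Ct$C, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))
  msf <- compute_bfactors(Ct)$msf
  ## tails are the most mobile, the effector the least
  expect_equal(which.max(msf) %in% c(lab$tail, lab$tail + np), TRUE)
  expect_true(which.min(msf) %in% c(lab$effector, lab$effector + np))
})

test_that("synthetic alignments carry their planted statistics", {
  ## full coupling: empirical MI approaches the column entropy
  syn <- make_synthetic_msa(n_seq = 400, L = 6,
                            coevolving_pairs = cbind(2, 5),
                            coupling = 1, gap_rate = 0, seed = 3)
  M <- mutual_information_matrix(syn$aln, correction = "raw")$scores
  p <- table(syn$aln$mat[, 2]) / 400
  H <- -sum(p * log(p))
  expect_equal(M[2, 5], H, tolerance = 1e-9)

  ## full conservation: single amino acid with KL = ln(1/Q)
  syn2 <- make_synthetic_msa(n_seq = 100, L = 4, conserved_cols = 2,
                             conservation_level = 1, gap_rate = 0, seed = 4)
  aa <- syn2$truth$consensus
  expect_equal(length(unique(syn2$aln$mat[, 2])), 1)
  kl <- kl_conservation(syn2$aln)
  expect_equal(kl$kl[2], log(1 / default_background()[[aa]]),
               tolerance = 1e-9)

  ## zero coupling: planted pair indistinguishable from background
  syn3 <- make_synthetic_msa(n_seq = 150, L = 10,
                             coevolving_pairs = cbind(2, 7),
                             coupling = 0, gap_rate = 0, seed = 5)
  z <- mutual_information_matrix(syn3$aln, correction = "zscore",
                                 n_shuffle = 15, seed = 6)$scores
  expect_lt(z[2, 7], 2)

  ## determinism and spec errors
  a1 <- make_synthetic_msa(n_seq = 20, L = 5, seed = 9)$aln$mat
  a2 <- make_synthetic_msa(n_seq = 20, L = 5, seed = 9)$aln$mat
  expect_identical(a1, a2)
  expect_error(make_synthetic_msa(L = 4, coevolving_pairs = cbind(2, 9)),
               "outside")
})

test_that("query-anchored alignments embed the query ungapped", {
  d <- make_toy_dimer(seed = 1)
  syn <- make_synthetic_msa(n_seq = 50, query_seq = d$labels$sequence,
                            conserved_cols = d$labels$hinge, seed = 7)
  expect_equal(syn$aln$ids[1], "query")
  expect_equal(paste(syn$aln$mat[1, ], collapse = ""), d$labels$sequence)
  expect_equal(syn$truth$consensus,
               substr(d$labels$sequence, d$labels$hinge, d$labels$hinge))
})

test_that("gaussian trajectories are seeded and converge to their target", {
  Ct <- random_covariance(6, seed = 8)
  t1 <- make_gaussian_trajectory(Ct, 50, seed = 9)
  t2 <- make_gaussian_trajectory(Ct, 50, seed = 9)
  expect_identical(t1$frames, t2$frames)

  tbig <- make_gaussian_trajectory(Ct, 10000, seed = 10)
  Ch <- compute_covariance(tbig, superpose = FALSE)
  expect_lt(norm(Ch$C - Ct$C, "F") / norm(Ct$C, "F"), 0.05)

  ## zero covariance: identical frames
  C0 <- structure(list(C = matrix(0, 9, 9), mean = matrix(1, 3, 3), n = 3),
                  class = "covariance_matrix")
  t0 <- make_gaussian_trajectory(C0, 4)
  expect_equal(t0$frames[1, , ], t0$frames[4, , ])

  Cneg <- structure(list(C = diag(c(1, -1, rep(1, 7))),
                         mean = matrix(0, 3, 3), n = 3),
                    class = "covariance_matrix")
  expect_error(make_gaussian_trajectory(Cneg, 5), "positive semidefinite")
})

test_that("PTM tables place planted and background sites that all map", {
  d <- make_toy_dimer(seed = 1)
  tab <- make_ptm_table(d, n_background = 5, seed = 2)
  expect_equal(nrow(tab), 8)
  expect_setequal(unique(tab$planted),
                  c("hinge", "effector", "sensor", "background"))
  mapped <- map_ptm_sites(tab, d$model)
  expect_equal(nrow(mapped$unmapped), 0)
  ## the sensor site sits on the free tail end
  expect_equal(tab$resnum[tab$planted == "sensor"], d$labels$tail[1])
})

test_that("ground truth sidecars are valid JSON", {
  d <- make_toy_dimer(seed = 1)
  f <- tempfile(fileext = ".json")
  write_ground_truth(d$labels[c("hinge", "effector", "tail")], f)
  gt <- jsonlite::read_json(f)
  expect_equal(gt$hinge, d$labels$hinge)
})
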