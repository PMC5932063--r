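test_that("column frequencies exclude gaps and flag all-gap columns", {
  aln <- msa_from_strings(c("AA-", "AA-", "GA-", "GA-"))
  f1 <- column_frequencies(aln, 1)
  expect_equal(f1$freq[["A"]], 0.5)
  expect_equal(f1$freq[["G"]], 0.5)
  expect_equal(column_frequencies(aln, 2)$freq[["A"]], 1)
  expect_warning(f3 <- column_frequencies(aln, 3), "all gaps")
  expect_true(f3$undefined)

  aln2 <- msa_from_strings(c("A", "-", "A", "-"))
  f <- column_frequencies(aln2, 1)
  expect_equal(f$freq[["A"]], 1)
  expect_equal(f$gap_fraction, 0.5)
})

test_that("KL conservation matches hand-computed values and is non-negative", {
  bg <- default_background()
  ## a column whose frequencies equal the background exactly: KL = 0
  ## (two symbols with matching frequencies, renormalised background)
  bg2 <- c(A = 0.25, G = 0.75)
  aln <- msa_from_strings(c("A", "G", "G", "G"))
  kl <- kl_conservation(aln, bg = bg2)
  expect_equal(kl$kl[1], 0)

  ## fully conserved alanine against Q(A) = 0.08
  bg3 <- c(A = 0.08, G = 0.92)
  aln2 <- msa_from_strings(c("A", "A", "A", "A"))
  expect_equal(kl_conservation(aln2, bg = bg3)$kl[1], log(1 / 0.08),
               tolerance = 1e-12)

  ## uniform over 20 against uniform background is exactly 0
  unif <- stats::setNames(rep(1 / 20, 20),
                          strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
  ## one column containing each residue type exactly once
  aln4 <- msa_from_strings(names(unif))
  expect_equal(kl_conservation(aln4, bg = unif)$kl[1], 0, tolerance = 1e-12)

  ## random columns are always >= 0 (Gibbs inequality)
  set.seed(7)
  for (r in 1:10) {
    aln5 <- msa_from_strings(replicate(20, paste(
      sample(names(bg), 8, TRUE, prob = bg), collapse = "")))
    expect_true(all(kl_conservation(aln5)$kl >= -1e-12))
  }
})

test_that("high-gap columns are flagged unreliable", {
  aln <- msa_from_strings(c("A-", "A-", "A-", "AA"))
  kl <- kl_conservation(aln, max_gap = 0.5)
  expect_false(kl$unreliable[1])
  expect_true(kl$unreliable[2])
})

test_that("raw MI matches limiting cases and information bounds", {
  ## two fully conserved columns share a single joint state: MI = 0
  aln <- msa_from_strings(rep("AC", 12))
  M <- mutual_information_matrix(aln, correction = "raw")$scores
  expect_equal(M[1, 2], 0)

  ## perfectly covarying binary columns, 50/50: MI = ln 2
  aln2 <- msa_from_strings(rep(c("AC", "GH"), 8))
  M2 <- mutual_information_matrix(aln2, correction = "raw")$scores
  expect_equal(M2[1, 2], log(2), tolerance = 1e-12)

  ## 0 <= MI <= min(H_i, H_j) on random alignments
  set.seed(11)
  for (r in 1:10) {
    aln3 <- msa_from_strings(replicate(20, paste(
      sample(c("A", "C", "D", "E"), 4, TRUE), collapse = "")))
    M3 <- mutual_information_matrix(aln3, correction = "raw")$scores
    H <- vapply(1:4, function(j) {
      p <- table(aln3$mat[, j]) / 20
      -sum(p * log(p))
    }, numeric(1))
    for (i in 1:3) for (j in (i + 1):4) {
      expect_gte(M3[i, j], -1e-12)
      expect_lte(M3[i, j], min(H[i], H[j]) + 1e-12)
    }
  }
})

test_that("raw MI equals the brute-force joint-count oracle on small alignments", {
  set.seed(13)
  for (r in 1:60) {
    L <- sample(2:6, 1)
    N <- sample(5:30, 1)
    aln <- msa_from_strings(replicate(N, paste(
      sample(c("A", "C", "D", "E", "F", "-"), L, TRUE), collapse = "")))
    M <- mutual_information_matrix(aln, correction = "raw",
                                   min_joint = 2)$scores
    for (i in seq_len(L - 1)) for (j in (i + 1):L) {
      e <- brute_mi(aln$mat[, i], aln$mat[, j])
      if (!is.na(M[i, j]) && !is.na(e))
        expect_equal(M[i, j], e, tolerance = 1e-12)
    }
  }
})

test_that("pairs with too few joint observations are masked", {
  aln <- msa_from_strings(c("A-", "-C", "A-", "-C", "AC"))
  M <- mutual_information_matrix(aln, correction = "raw",
                                 min_joint = 3)$scores
  expect_true(is.na(M[1, 2]))
})

test_that("column shuffling destroys planted covariation (z-MI below 2)", {
  syn <- make_synthetic_msa(n_seq = 150, L = 20,
                            coevolving_pairs = cbind(3, 12),
                            coupling = 0.95, gap_rate = 0, seed = 21)
  z <- mutual_information_matrix(syn$aln, correction = "zscore",
                                 n_shuffle = 15, seed = 22)$scores
  expect_gt(z[3, 12], 6.5)
  ## shuffle all columns independently: planted signal gone
  set.seed(23)
  shuf <- apply(syn$aln$mat, 2, sample)
  aln2 <- msa_from_strings(apply(shuf, 1, paste, collapse = ""))
  z2 <- mutual_information_matrix(aln2, correction = "zscore",
                                  n_shuffle = 15, seed = 24)$scores
  expect_lt(z2[3, 12], 2)
})

test_that("planted coevolving pairs are recovered with high precision", {
  pairs <- cbind(c(3, 10, 20, 30, 40), c(7, 15, 25, 35, 45))
  syn <- make_synthetic_msa(n_seq = 200, L = 50, coevolving_pairs = pairs,
                            coupling = 0.9, seed = 31)
  z <- mutual_information_matrix(syn$aln, correction = "zscore",
                                 n_shuffle = 25, seed = 32)$scores
  z[lower.tri(z, diag = TRUE)] <- NA
  top <- arrayInd(order(z, decreasing = TRUE, na.last = NA)[1:5], dim(z))
  hits <- sum(apply(top, 1, function(p)
    any((pairs[, 1] == p[1] & pairs[, 2] == p[2]) |
        (pairs[, 1] == p[2] & pairs[, 2] == p[1]))))
  expect_gte(hits / 5, 0.9)
})

test_that("cumulative MI sums entries strictly above the threshold", {
  M <- matrix(0, 4, 4)
  M[1, 2] <- M[2, 1] <- 7
  M[1, 3] <- M[3, 1] <- 8
  M[1, 4] <- M[4, 1] <- 3
  diag(M) <- NA
  expect_equal(cumulative_mi(M, t = 6.5)[1], 15)
  expect_equal(cumulative_mi(M, t = 100), rep(0, 4))
  ## boundary: exactly at threshold is excluded
  M[1, 4] <- M[4, 1] <- 6.5
  expect_equal(cumulative_mi(M, t = 6.5)[1], 15)
})

test_that("pMI averages cMI over the self-inclusive contact neighbourhood", {
  ## two residues 4 A apart: neighbourhood of each is both residues
  xyz <- rbind(c(0, 0, 0), c(4, 0, 0), c(100, 0, 0))
  m <- ca_structure_model(xyz)
  cm <- compute_contact_map(m, 5, "ca-ca")
  colmap <- data.frame(column = 1:3, chain = "A", res_index = 1:3)
  pmi <- proximity_mi(c(2, 4, 10), cm, colmap)
  expect_equal(pmi[1], 3)
  expect_equal(pmi[2], 3)
  ## isolated residue keeps its own cMI
  expect_equal(pmi[3], 10)

  ## pair 6 A apart with a 5 A threshold: excluded from each other
  xyz2 <- rbind(c(0, 0, 0), c(6, 0, 0))
  cm2 <- compute_contact_map(ca_structure_model(xyz2), 5, "ca-ca")
  pmi2 <- proximity_mi(c(2, 4), cm2, data.frame(column = 1:2, chain = "A",
                                                res_index = 1:2))
  expect_equal(pmi2, c(2, 4))

  ## residues without a mapped column are masked
  pmi3 <- proximity_mi(c(2), cm2, data.frame(column = 1, chain = "A",
                                             res_index = 1))
  expect_true(is.na(pmi3[2]))
})

test_that("alignment columns map injectively onto structure residues", {
  m <- ca_structure_model(matrix(rnorm(27), 9, 3))
  seqres <- c("ALA", "CYS", "ASP", "GLU", "PHE", "GLY", "HIS", "ILE", "LYS")
  m$residues$resid <- seqres
  m$atoms$resid <- seqres

  ## identity
  aln <- msa_from_strings(c("ACDEFGHIK", "ACDEFGHIK"), c("query", "o"))
  cm <- map_columns_to_residues(aln, m, "query")
  expect_equal(cm$column, cm$res_index)
  expect_false(any(duplicated(cm$res_index)))

  ## structure missing two terminal residues: those columns unmapped
  m2 <- ca_structure_model(matrix(rnorm(21), 7, 3))
  m2$residues$resid <- seqres[1:7]
  m2$atoms$resid <- seqres[1:7]
  cm2 <- map_columns_to_residues(aln, m2, "query")
  expect_equal(sort(cm2$column), 1:7)

  ## query with one internal insertion: flanks map, insertion unmapped
  aln3 <- msa_from_strings(c("ACDEWFGHIK", "ACDEWFGHIK"), c("query", "o"))
  cm3 <- map_columns_to_residues(aln3, m, "query", min_identity = 0.85)
  expect_false(5 %in% cm3$column)
  expect_equal(cm3$res_index[match(c(4, 6), cm3$column)], c(4, 5))

  ## unknown id and low identity raise
  expect_error(map_columns_to_residues(aln, m, "nope"), "not found")
  alnbad <- msa_from_strings(c("WWWWWWWWW", "WWWWWWWWW"), c("query", "o"))
  expect_error(map_columns_to_residues(alnbad, m, "query"), "identity")
})

test_that("FASTA and Stockholm alignments read into equivalent objects", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACD-E", ">s2", "ACDFE"), fa)
  a1 <- read_alignment(fa)
  expect_equal(a1$N, 2)
  expect_equal(a1$L, 5)
  st <- tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "s1 ACD-E", "s2 ACDFE", "//"), st)
  a2 <- read_alignment(st)
  expect_equal(a2$mat, a1$mat, ignore_attr = TRUE)
})
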