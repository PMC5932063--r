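test_that("PDB parsing produces counted, ordered residue models", {
  m <- load_structure(toy_chain_pdb(3))
  expect_s3_class(m, "structure_model")
  expect_equal(n_residues(m), 3)

  two <- paste(c(
    vapply(1:5, function(i) pdb_atom_line(i, "CA", "ALA", "B", i,
                                          i * 3.8, 0, 0), character(1)),
    vapply(1:5, function(i) pdb_atom_line(5 + i, "CA", "GLY", "A", i,
                                          i * 3.8, 5, 0), character(1)),
    "END"), collapse = "\n")
  m2 <- load_structure(two)
  expect_equal(n_residues(m2), 10)
  expect_equal(m2$residues$chain, rep(c("A", "B"), each = 5))
})

test_that("malformed and empty inputs raise informative errors", {
  bad <- paste(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    sub("   0.000", "  xx.000", pdb_atom_line(2, "CA", "ALA", "A", 2,
                                              0, 1, 0), fixed = TRUE),
    "END"), collapse = "\n")
  expect_error(load_structure(bad), "line")
  expect_error(load_structure("REMARK nothing here"), "ATOM")
  ## water-only file has atoms but no protein residues
  hoh <- paste(pdb_atom_line(1, "O", "HOH", "A", 1, 0, 0, 0,
                             record = "HETATM", element = "O"), sep = "\n")
  expect_error(load_structure(hoh), "zero protein atoms")
})

test_that("altloc keeps the highest-occupancy conformer", {
  txt <- paste(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.4, alt = "A"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 9, 9, 9, occ = 0.6, alt = "B"),
    "END"), collapse = "\n")
  m <- load_structure(txt)
  ca <- m$atoms[m$atoms$elety == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 9)
})

test_that("non-protein atoms are retained but excluded from residues", {
  txt <- paste(c(
    toy_chain_pdb(2),
    pdb_atom_line(10, "O", "HOH", "A", 99, 20, 0, 0, record = "HETATM",
                  element = "O")), collapse = "\n")
  txt <- sub("END\n", "", txt, fixed = TRUE)
  m <- load_structure(txt)
  expect_equal(n_residues(m), 2)
  expect_true(any(!m$atoms$is_protein))
})

test_that("CA trace extraction skips residues without CA and enforces N >= 2", {
  m <- load_structure(toy_chain_pdb(3))
  tr <- extract_ca_trace(m)
  expect_equal(nrow(tr$xyz), 3)
  d <- sqrt(rowSums((tr$xyz[-1, , drop = FALSE] -
                     tr$xyz[-3, , drop = FALSE])^2))
  expect_equal(d, c(3.8, 3.8))

  ## middle residue has only a CB atom
  txt <- paste(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CB", "ALA", "A", 2, 3.8, 0, 0),
    pdb_atom_line(3, "CA", "ALA", "A", 3, 7.6, 0, 0),
    "END"), collapse = "\n")
  expect_message(tr2 <- extract_ca_trace(load_structure(txt)), "skipped")
  expect_equal(nrow(tr2$xyz), 2)

  expect_error(extract_ca_trace(load_structure(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0))), "fewer than 2")
})

test_that("contact maps honour the strict cutoff and both metrics", {
  ## two residues whose closest heavy atoms are 4.0 A apart
  txt <- paste(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CB", "ALA", "A", 1, 1, 0, 0),
    pdb_atom_line(3, "CA", "ALA", "A", 2, 8, 0, 0),
    pdb_atom_line(4, "CB", "ALA", "A", 2, 5, 0, 0),
    "END"), collapse = "\n")
  m <- load_structure(txt)
  expect_true(compute_contact_map(m, 5, "heavy-atom-min")$contacts[1, 2])
  expect_false(compute_contact_map(m, 3.9, "heavy-atom-min")$contacts[1, 2])

  ## linear chain: each interior bead contacts i+-1 and i+-2 only at 8 A
  ch <- load_structure(toy_chain_pdb(7))
  cm <- compute_contact_map(ch, 8, "ca-ca")
  for (i in 1:7) for (j in 1:7)
    expect_equal(cm$contacts[i, j], i != j && abs(i - j) <= 2,
                 info = paste(i, j))
  expect_error(compute_contact_map(m, 5, "nope"))
})

test_that("contact maps are symmetric with false diagonal; heavy-atom is a superset of ca-ca", {
  set.seed(41)
  for (rep in 1:5) {
    xyz <- matrix(rnorm(30, sd = 5), 10, 3)
    m <- ca_structure_model(xyz)
    cm <- compute_contact_map(m, 7, "ca-ca")
    expect_true(isSymmetric(cm$contacts))
    expect_false(any(diag(cm$contacts)))
    ha <- compute_contact_map(m, 7, "heavy-atom-min")
    ## CA-only model: heavy-atom minimum distance equals the CA distance,
    ## so the two must agree; with side chains it can only add contacts
    expect_true(all(ha$contacts >= cm$contacts))
  }
})

test_that("PTM sites map onto residues with mismatch flags and unmapped rows", {
  m <- load_structure(toy_chain_pdb(3))
  tab <- data.frame(chain = c("A", "B", "A"), resnum = c(1, 1, 2),
                    resname = c("ALA", "ALA", "SER"),
                    ptm_type = "phospho")
  res <- map_ptm_sites(tab, m)
  expect_equal(nrow(res$mapped), 2)
  expect_equal(nrow(res$unmapped), 1)
  expect_equal(res$unmapped$chain, "B")
  ## SER annotated where the structure has ALA: mapped but flagged
  expect_true(res$mapped$name_mismatch[res$mapped$resnum == 2])
  expect_false(res$mapped$name_mismatch[res$mapped$resnum == 1])
  expect_error(map_ptm_sites(tab[0, ], m), "empty")
})

test_that("PDB round-trip preserves residue count, order, and CA coordinates", {
  d <- make_toy_dimer(seed = 3)
  f <- tempfile(fileext = ".pdb")
  write_structure(d$model, f)
  m2 <- load_structure(f)
  expect_equal(n_residues(m2), n_residues(d$model))
  expect_equal(m2$residues$chain, d$model$residues$chain)
  expect_equal(extract_ca_trace(m2)$xyz, extract_ca_trace(d$model)$xyz,
               tolerance = 1e-3)
})

test_that("PTM tables round-trip through TSV", {
  d <- make_toy_dimer(seed = 1)
  tab <- make_ptm_table(d, n_background = 5, seed = 2)
  f <- tempfile(fileext = ".tsv")
  write_ptm_table(tab, f)
  tab2 <- read_ptm_table(f)
  expect_equal(tab2$resnum, tab$resnum)
  expect_equal(tab2$ptm_type, tab$ptm_type)
  res <- map_ptm_sites(tab2, d$model)
  expect_equal(nrow(res$unmapped), 0)
})
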