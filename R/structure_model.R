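## Residue-level structure models, contact maps, PTM annotation mapping.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
         "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
names(AA1) <- AA3

#' Convert 3-letter residue codes to 1-letter codes
#'
#' Unknown codes become \code{"X"}.
#'
#' @param resid character vector of 3-letter residue names.
#' @return character vector of 1-letter codes.
#' @export
aa_three_to_one <- function(resid) {
  out <- AA1[toupper(resid)]
  out[is.na(out)] <- "X"
  unname(out)
}

res_key <- function(chain, resno, insert = "") {
  insert[is.na(insert)] <- ""
  paste(chain, resno, insert, sep = "|")
}

is_hydrogen_atom <- function(elesy, elety) {
  hy <- !is.na(elesy) & toupper(trimws(elesy)) == "H"
  ## fall back on the atom-name heuristic when the element column is absent
  noel <- is.na(elesy) | trimws(elesy) == ""
  nm <- toupper(trimws(elety))
  hy[noel] <- grepl("^[0-9]?H", nm[noel])
  hy
}

#' Parse a structure from PDB-format text
#'
#' Reads ATOM/HETATM records (honouring altloc and insertion codes), keeps the
#' highest-occupancy alternate conformer (ties broken by file order), and
#' builds an ordered residue table. Water and other non-protein residues are
#' retained as atoms flagged non-protein but excluded from the residue list.
#'
#' @param pdb_text character: either a path to a PDB file or PDB-format text
#'   (a single string with newlines, or a vector of lines).
#' @return an object of class \code{structure_model}: a list with
#'   \itemize{
#'     \item \code{atoms}: data.frame with columns \code{record, eleno, elety,
#'       alt, resid, chain, resno, insert, x, y, z, occ, b, elesy,
#'       is_protein, is_hydrogen}
#'     \item \code{residues}: data.frame (\code{chain, resno, insert, resid})
#'       ordered chain then residue number, protein residues only
#'     \item \code{domain_labels}: optional named character vector keyed by
#'       residue (set with \code{\link{set_domain_labels}})
#'   }
#' @export
load_structure <- function(pdb_text) {
  lines <- pdb_lines(pdb_text)
  sel <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(sel)) stop("no ATOM/HETATM records found in PDB input")
  recs <- lines[sel]
  lineno <- which(sel)

  fw <- function(from, to) trimws(substr(recs, from, to))
  num <- function(txt, what) {
    v <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(v) & trimws(txt) != "")
    if (length(bad))
      stop(sprintf("malformed %s field at PDB line %d: '%s'",
                   what, lineno[bad[1]], recs[bad[1]]))
    v
  }
  atoms <- data.frame(
    record = trimws(substr(recs, 1, 6)),
    eleno  = suppressWarnings(as.integer(fw(7, 11))),
    elety  = fw(13, 16),
    alt    = substr(recs, 17, 17),
    resid  = fw(18, 20),
    chain  = substr(recs, 22, 22),
    resno  = suppressWarnings(as.integer(fw(23, 26))),
    insert = trimws(substr(recs, 27, 27)),
    x = num(substr(recs, 31, 38), "x coordinate"),
    y = num(substr(recs, 39, 46), "y coordinate"),
    z = num(substr(recs, 47, 54), "z coordinate"),
    occ = suppressWarnings(as.numeric(fw(55, 60))),
    b = suppressWarnings(as.numeric(fw(61, 66))),
    elesy = trimws(substr(recs, 77, 78)),
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z)) {
    bad <- which(is.na(atoms$x) | is.na(atoms$y) | is.na(atoms$z))[1]
    stop(sprintf("malformed coordinate field at PDB line %d", lineno[bad]))
  }
  atoms$occ[is.na(atoms$occ)] <- 1
  atoms$alt <- trimws(atoms$alt)

  ## altloc resolution: keep the highest-occupancy conformer per atom slot,
  ## ties resolved in favour of the first encountered
  slot <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "|")
  keep <- rep(TRUE, nrow(atoms))
  if (any(atoms$alt != "")) {
    ord <- order(slot, -atoms$occ, seq_len(nrow(atoms)))
    keep_first <- !duplicated(slot[ord])
    keep <- logical(nrow(atoms))
    keep[ord] <- keep_first
  }
  atoms <- atoms[keep, , drop = FALSE]

  atoms$is_protein <- atoms$resid %in% AA3
  atoms$is_hydrogen <- is_hydrogen_atom(atoms$elesy, atoms$elety)
  if (!any(atoms$is_protein)) stop("structure contains zero protein atoms")

  prot <- atoms[atoms$is_protein, , drop = FALSE]
  key <- res_key(prot$chain, prot$resno, prot$insert)
  first <- !duplicated(key)
  residues <- data.frame(
    chain = prot$chain[first], resno = prot$resno[first],
    insert = prot$insert[first], resid = prot$resid[first],
    stringsAsFactors = FALSE
  )
  residues <- residues[order(residues$chain, residues$resno, residues$insert), ,
                       drop = FALSE]
  rownames(residues) <- NULL

  structure(list(atoms = atoms, residues = residues, domain_labels = NULL),
            class = "structure_model")
}

pdb_lines <- function(pdb_text) {
  if (length(pdb_text) == 1 && !grepl("\n", pdb_text) && file.exists(pdb_text))
    return(readLines(pdb_text, warn = FALSE))
  if (length(pdb_text) == 1) return(strsplit(pdb_text, "\n", fixed = TRUE)[[1]])
  pdb_text
}

#' @export
print.structure_model <- function(x, ...) {
  nch <- length(unique(x$residues$chain))
  cat(sprintf("structure_model: %d protein residues in %d chain(s), %d atoms\n",
              nrow(x$residues), nch, nrow(x$atoms)))
  invisible(x)
}

#' Number of protein residues in a structure model
#' @param model a \code{structure_model}.
#' @return integer count.
#' @export
n_residues <- function(model) nrow(model$residues)

#' Attach domain labels to residues
#'
#' @param model a \code{structure_model}.
#' @param labels named character vector; names are \code{"chain|resno"} or
#'   plain residue indices, values are domain names (e.g. NTD/MD/CTD).
#' @return the model with \code{domain_labels} set.
#' @export
set_domain_labels <- function(model, labels) {
  model$domain_labels <- labels
  model
}

#' One-letter amino-acid sequence of a structure model
#'
#' @param model a \code{structure_model}.
#' @param chain optional chain identifier; default all chains concatenated in
#'   residue order.
#' @return single string.
#' @export
structure_sequence <- function(model, chain = NULL) {
  res <- model$residues
  if (!is.null(chain)) res <- res[res$chain %in% chain, , drop = FALSE]
  paste(aa_three_to_one(res$resid), collapse = "")
}

#' Extract the C-alpha bead trace of a structure
#'
#' One bead per protein residue that has a CA atom; residues lacking a CA are
#' skipped with a message.
#'
#' @param model a \code{structure_model}.
#' @return object of class \code{ca_trace}: list with \code{xyz} (N x 3
#'   matrix, Angstrom) and \code{residues} (data.frame chain/resno/insert/resid
#'   aligned with the rows of \code{xyz}).
#' @export
extract_ca_trace <- function(model) {
  at <- model$atoms
  ca <- at[at$is_protein & at$elety == "CA" & at$alt %in% c("", "A"), ,
           drop = FALSE]
  key_res <- res_key(model$residues$chain, model$residues$resno,
                     model$residues$insert)
  key_ca <- res_key(ca$chain, ca$resno, ca$insert)
  idx <- match(key_res, key_ca)
  missing <- which(is.na(idx))
  if (length(missing))
    message(sprintf("extract_ca_trace: %d residue(s) lack a CA atom and were skipped",
                    length(missing)))
  present <- which(!is.na(idx))
  if (length(present) < 2)
    stop("fewer than 2 residues with CA atoms: cannot build a trace")
  ord <- idx[present]
  xyz <- cbind(ca$x[ord], ca$y[ord], ca$z[ord])
  colnames(xyz) <- c("x", "y", "z")
  structure(list(xyz = xyz,
                 residues = model$residues[present, , drop = FALSE]),
            class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("ca_trace: %d beads\n", nrow(x$xyz)))
  invisible(x)
}

#' Residue-residue contact map
#'
#' Two metrics are available: \code{"heavy-atom-min"} (contact if the minimum
#' distance between any pair of non-hydrogen atoms is below the cutoff; the
#' convention used for the 5 Angstrom structural-proximity rule of the pMI
#' score) and \code{"ca-ca"} (C-alpha distance). The comparison is strict
#' (\code{distance < cutoff}).
#'
#' @param model a \code{structure_model} or, for metric \code{"ca-ca"}, a
#'   \code{ca_trace}.
#' @param cutoff distance threshold in Angstrom (> 0).
#' @param metric \code{"heavy-atom-min"} or \code{"ca-ca"}.
#' @return object of class \code{contact_map}: list with symmetric logical
#'   \code{contacts} (false diagonal), \code{cutoff}, \code{metric} and the
#'   residue table.
#' @export
compute_contact_map <- function(model, cutoff,
                                metric = c("heavy-atom-min", "ca-ca")) {
  metric <- match.arg(metric)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff > 0)
  if (metric == "ca-ca") {
    trace <- if (inherits(model, "ca_trace")) model else extract_ca_trace(model)
    D <- as.matrix(stats::dist(trace$xyz))
    residues <- trace$residues
  } else {
    if (!inherits(model, "structure_model"))
      stop("heavy-atom-min metric requires a structure_model")
    at <- model$atoms
    at <- at[at$is_protein & !at$is_hydrogen, , drop = FALSE]
    key <- res_key(at$chain, at$resno, at$insert)
    rk <- res_key(model$residues$chain, model$residues$resno,
                  model$residues$insert)
    ridx <- match(key, rk)
    n <- nrow(model$residues)
    Da <- as.matrix(stats::dist(cbind(at$x, at$y, at$z)))
    D <- matrix(Inf, n, n)
    ## min over atom pairs per residue pair
    grp <- split(seq_len(nrow(at)), ridx)
    gids <- as.integer(names(grp))
    for (a in seq_along(grp)) {
      rows <- Da[grp[[a]], , drop = FALSE]
      mins <- vapply(grp, function(cols)
        min(rows[, cols, drop = FALSE]), numeric(1))
      D[gids[a], gids] <- pmin(D[gids[a], gids], mins)
    }
    residues <- model$residues
  }
  contacts <- D < cutoff
  diag(contacts) <- FALSE
  structure(list(n_residues = nrow(residues), contacts = contacts,
                 cutoff = cutoff, metric = metric, residues = residues),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %d residues, %d contacts (%s < %g A)\n",
              x$n_residues, sum(x$contacts) / 2, x$metric, x$cutoff))
  invisible(x)
}

#' Read a PTM annotation table
#'
#' Expects a TSV with header \code{chain resnum resname ptm_type} and an
#' optional \code{conserved} column.
#'
#' @param path file path.
#' @return data.frame of class \code{ptm_table}.
#' @export
read_ptm_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("chain", "resnum", "resname", "ptm_type")
  if (!all(need %in% names(tab)))
    stop("PTM table must have columns: ", paste(need, collapse = ", "))
  dup <- duplicated(tab[, c("chain", "resnum", "ptm_type")])
  if (any(dup)) stop("duplicate (chain, resnum, ptm_type) rows in PTM table")
  class(tab) <- c("ptm_table", "data.frame")
  tab
}

#' Write a PTM annotation table to TSV
#' @param tab a PTM table data.frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_ptm_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map PTM annotations onto structure residues
#'
#' Rows whose (chain, residue number) exist in the model are mapped to residue
#' indices; residue-name mismatches are mapped but flagged. Unmapped rows are
#' returned, not raised.
#'
#' @param table PTM table (see \code{\link{read_ptm_table}}).
#' @param model a \code{structure_model}.
#' @return list with \code{mapped} (the table rows that mapped, plus
#'   \code{res_index} into \code{model$residues} and logical
#'   \code{name_mismatch}) and \code{unmapped} (rows that did not map).
#' @export
map_ptm_sites <- function(table, model) {
  if (nrow(table) == 0) stop("PTM table is empty")
  rk <- res_key(model$residues$chain, model$residues$resno,
                model$residues$insert)
  tk <- res_key(table$chain, table$resnum, "")
  idx <- match(tk, rk)
  hit <- !is.na(idx)
  mapped <- table[hit, , drop = FALSE]
  if (nrow(mapped)) {
    mapped$res_index <- idx[hit]
    mapped$name_mismatch <-
      toupper(mapped$resname) != model$residues$resid[idx[hit]]
  } else {
    mapped$res_index <- integer(0)
    mapped$name_mismatch <- logical(0)
  }
  list(mapped = mapped, unmapped = table[!hit, , drop = FALSE])
}

#' Write a structure model (or trajectory frames) as PDB text
#'
#' @param model a \code{structure_model}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_structure <- function(model, path) {
  at <- model$atoms
  elety4 <- ifelse(nchar(at$elety) >= 4, substr(at$elety, 1, 4),
                   sprintf(" %-3s", at$elety))
  lines <- sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   at$record, seq_len(nrow(at)), elety4,
                   ifelse(at$alt == "", " ", at$alt),
                   at$resid, at$chain, at$resno,
                   ifelse(at$insert == "", " ", at$insert),
                   at$x, at$y, at$z, at$occ,
                   ifelse(is.na(at$b), 0, at$b), at$elesy)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Build a C-alpha-only structure model from coordinates
#'
#' Convenience constructor used by the synthetic generators: each row of
#' \code{xyz} becomes an alanine CA bead.
#'
#' @param xyz N x 3 coordinate matrix (Angstrom).
#' @param chain chain id per row (recycled).
#' @param resno residue numbers per row; default sequential within chain.
#' @return a \code{structure_model}.
#' @export
ca_structure_model <- function(xyz, chain = "A", resno = NULL) {
  n <- nrow(xyz)
  chain <- rep_len(chain, n)
  if (is.null(resno))
    resno <- stats::ave(seq_len(n), chain, FUN = seq_along)
  atoms <- data.frame(
    record = "ATOM", eleno = seq_len(n), elety = "CA", alt = "",
    resid = "ALA", chain = chain, resno = as.integer(resno), insert = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, b = 0,
    elesy = "C", is_protein = TRUE, is_hydrogen = FALSE,
    stringsAsFactors = FALSE
  )
  residues <- atoms[, c("chain", "resno", "insert", "resid")]
  rownames(residues) <- NULL
  structure(list(atoms = atoms, residues = residues, domain_labels = NULL),
            class = "structure_model")
}

#' Export a contact map as a TSV edge list
#' @param cm a \code{contact_map}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_contact_map <- function(cm, path) {
  idx <- which(cm$contacts & upper.tri(cm$contacts), arr.ind = TRUE)
  df <- data.frame(
    chain_i = cm$residues$chain[idx[, 1]], resnum_i = cm$residues$resno[idx[, 1]],
    chain_j = cm$residues$chain[idx[, 2]], resnum_j = cm$residues$resno[idx[, 2]]
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
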