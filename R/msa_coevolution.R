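## Conservation (KL) and coevolution (MI / cMI / pMI) scores from an MSA,
## mapped onto structure residues.

GAP_CHARS <- c("-", ".", "*")

#' Construct an alignment object from sequences
#'
#' @param seqs character vector of equal-length aligned sequences
#'   (20 amino acids + gap characters \code{-}/\code{.}; other symbols are
#'   treated as gaps for scoring purposes).
#' @param ids sequence identifiers (default \code{seq1..seqN}).
#' @return object of class \code{msa}: list with \code{mat} (N x L character
#'   matrix), \code{ids}, \code{N}, \code{L}.
#' @export
msa_from_strings <- function(seqs, ids = NULL) {
  if (length(seqs) < 2) stop("alignment needs at least 2 sequences")
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("aligned sequences must all have the same length")
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- ids
  structure(list(mat = mat, ids = ids, N = length(seqs), L = L),
            class = "msa")
}

#' Read a multiple sequence alignment (FASTA or Stockholm)
#'
#' @param path file path.
#' @param format \code{"auto"} (sniff the first line), \code{"fasta"} or
#'   \code{"stockholm"}.
#' @return an \code{msa} object (see \code{\link{msa_from_strings}}).
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (grepl("^# STOCKHOLM", first)) "stockholm" else "fasta"
  }
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  seqs <- as.character(aln)
  msa_from_strings(unname(seqs), names(seqs))
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns\n", x$N, x$L))
  invisible(x)
}

## integer encoding: 0 = gap/unknown, 1..20 = amino acids in AA1 order
encode_msa <- function(aln) {
  codes <- match(aln$mat, AA1)
  codes[is.na(codes)] <- 0L
  matrix(as.integer(codes), aln$N, aln$L)
}

#' Per-column amino-acid frequencies
#'
#' Frequencies are over non-gap symbols; the gap fraction is reported
#' separately. An all-gap column yields an undefined-column result.
#'
#' @param aln an \code{msa}.
#' @param col 1-based column index.
#' @return list with \code{freq} (named numeric over observed amino acids,
#'   summing to 1), \code{gap_fraction}, and logical \code{undefined}.
#' @export
column_frequencies <- function(aln, col) {
  stopifnot(col >= 1, col <= aln$L)
  v <- aln$mat[, col]
  is_gap <- !(v %in% AA1)
  obs <- v[!is_gap]
  if (length(obs) == 0) {
    warning(sprintf("column %d is all gaps: frequencies undefined", col))
    return(list(freq = stats::setNames(numeric(0), character(0)),
                gap_fraction = 1, undefined = TRUE))
  }
  tab <- table(obs)
  list(freq = stats::setNames(as.numeric(tab) / length(obs), names(tab)),
       gap_fraction = sum(is_gap) / length(v),
       undefined = FALSE)
}

#' Built-in background amino-acid frequencies
#'
#' Database-wide average amino-acid composition (UniProtKB/Swiss-Prot),
#' normalised to sum to 1. Override with \code{\link{read_background}}.
#'
#' @return named numeric vector over the 20 amino acids.
#' @export
default_background <- function() {
  q <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.37, Q = 3.93,
         E = 6.75, G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84,
         M = 2.42, F = 3.86, P = 4.70, S = 6.56, T = 5.34, W = 1.08,
         Y = 2.92, V = 6.87)
  q / sum(q)
}

#' Read background frequencies from a two-column TSV (aa, frequency)
#' @param path file path.
#' @return named numeric vector normalised to sum to 1.
#' @export
read_background <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  q <- stats::setNames(tab[[2]], toupper(tab[[1]]))
  if (any(q <= 0)) stop("background frequencies must be positive")
  q / sum(q)
}

#' Per-column Kullback-Leibler conservation score
#'
#' For each column the score is the KL divergence of the observed amino-acid
#' frequencies P from the background Q: sum over observed amino acids of
#' P(a) * ln(P(a) / Q(a)), in nats. Columns with a gap fraction above
#' \code{max_gap} are scored but flagged unreliable.
#'
#' @param aln an \code{msa}.
#' @param bg named background frequencies (default
#'   \code{\link{default_background}}).
#' @param max_gap maximum tolerated gap fraction (default 0.5).
#' @return object of class \code{conservation_profile}: data.frame with
#'   \code{column}, \code{kl} (NA for all-gap columns), \code{gap_fraction},
#'   \code{unreliable}.
#' @export
kl_conservation <- function(aln, bg = default_background(), max_gap = 0.5) {
  kl <- rep(NA_real_, aln$L)
  gapf <- numeric(aln$L)
  for (j in seq_len(aln$L)) {
    cf <- suppressWarnings(column_frequencies(aln, j))
    gapf[j] <- cf$gap_fraction
    if (cf$undefined) next
    if (!all(names(cf$freq) %in% names(bg)))
      stop("background table does not cover amino acid(s): ",
           paste(setdiff(names(cf$freq), names(bg)), collapse = ", "))
    p <- cf$freq
    kl[j] <- sum(p * log(p / bg[names(p)]))
  }
  out <- data.frame(column = seq_len(aln$L), kl = kl, gap_fraction = gapf,
                    unreliable = gapf > max_gap)
  class(out) <- c("conservation_profile", "data.frame")
  out
}

## raw pairwise MI (nats) with pairwise-complete observations;
## pairs with fewer than min_joint joint observations are NA
raw_mi_matrix <- function(E, min_joint) {
  L <- ncol(E)
  M <- matrix(NA_real_, L, L)
  for (i in seq_len(L - 1)) {
    ei <- E[, i]
    for (j in (i + 1):L) {
      ej <- E[, j]
      ok <- ei > 0L & ej > 0L
      n <- sum(ok)
      if (n < min_joint) next
      joint <- tabulate((ei[ok] - 1L) * 20L + ej[ok], nbins = 400L)
      nz <- joint > 0L
      pj <- joint[nz] / n
      a <- ((which(nz) - 1L) %/% 20L) + 1L
      b <- ((which(nz) - 1L) %% 20L) + 1L
      pa <- tabulate(ei[ok], 20L) / n
      pb <- tabulate(ej[ok], 20L) / n
      M[i, j] <- M[j, i] <- sum(pj * log(pj / (pa[a] * pb[b])))
    }
  }
  M
}

## average-product correction on a symmetric MI matrix (NA-aware)
apc_correct <- function(M) {
  rm <- rowMeans(M, na.rm = TRUE)
  om <- mean(M[upper.tri(M)], na.rm = TRUE)
  if (!is.finite(om) || om == 0) return(M)
  M - outer(rm, rm) / om
}

#' Pairwise mutual information between alignment columns
#'
#' Raw MI is computed in nats over pairwise-complete (both columns non-gap)
#' observations. \code{"apc"} subtracts the average-product correction;
#' \code{"zscore"} additionally standardises the APC-corrected scores against
#' a null built by shuffling every column independently (destroying
#' covariation while preserving column compositions).
#'
#' @param aln an \code{msa}.
#' @param correction \code{"zscore"} (default), \code{"apc"} or \code{"raw"}.
#' @param n_shuffle number of column-shuffle replicates for the z-score null.
#' @param min_joint pairs with fewer joint observations are masked (NA).
#' @param seed optional integer seed for the shuffle null.
#' @return object of class \code{mi_matrix}: list with \code{scores}
#'   (L x L symmetric, NA diagonal; the selected variant), \code{raw},
#'   \code{correction}, \code{gap_policy}.
#' @export
mutual_information_matrix <- function(aln, correction = c("zscore", "apc", "raw"),
                                      n_shuffle = 25, min_joint = 10,
                                      seed = NULL) {
  correction <- match.arg(correction)
  stopifnot(aln$N >= 2, aln$L >= 2)
  if (!is.null(seed)) set.seed(seed)
  E <- encode_msa(aln)
  raw <- raw_mi_matrix(E, min_joint)
  scores <- switch(correction,
    raw = raw,
    apc = apc_correct(raw),
    zscore = {
      obs <- apc_correct(raw)
      s1 <- matrix(0, aln$L, aln$L)
      s2 <- matrix(0, aln$L, aln$L)
      for (r in seq_len(n_shuffle)) {
        Es <- apply(E, 2, sample)
        Ms <- apc_correct(raw_mi_matrix(Es, min_joint))
        Ms[is.na(Ms)] <- 0
        s1 <- s1 + Ms
        s2 <- s2 + Ms^2
      }
      mu <- s1 / n_shuffle
      sig <- sqrt(pmax(s2 / n_shuffle - mu^2, 0))
      sig[sig < 1e-12] <- 1e-12
      (obs - mu) / sig
    })
  diag(scores) <- NA_real_
  structure(list(scores = scores, raw = raw, correction = correction,
                 gap_policy = "pairwise-complete"),
            class = "mi_matrix")
}

#' @export
print.mi_matrix <- function(x, ...) {
  cat(sprintf("mi_matrix: %d columns, correction = %s\n",
              ncol(x$scores), x$correction))
  invisible(x)
}

#' Cumulative mutual information (cMI) per column
#'
#' cMI of column x is the sum of MI scores above the threshold over all pairs
#' involving x. The default threshold 6.5 is intended for z-scored,
#' APC-corrected MI (raw MI in nats cannot reach it); pass a raw-mode matrix
#' and a suitable threshold for a raw-scale variant.
#'
#' @param mi an \code{mi_matrix} (or plain symmetric matrix).
#' @param t threshold; only entries strictly greater than \code{t} contribute.
#' @return numeric vector of per-column cMI (>= 0).
#' @export
cumulative_mi <- function(mi, t = 6.5) {
  stopifnot(is.finite(t))
  M <- if (inherits(mi, "mi_matrix")) mi$scores else mi
  M[is.na(M) | M <= t] <- 0
  rowSums(M)
}

#' Map alignment columns to structure residues
#'
#' The ungapped query sequence is globally aligned (Needleman-Wunsch via
#' \code{Biostrings::pairwiseAlignment}) to the residue sequence of each
#' requested chain; matched positions give an injective column-to-residue
#' map, insertions and unresolved residues are left unmapped.
#'
#' @param aln an \code{msa}.
#' @param model a \code{structure_model}.
#' @param query_id id of the alignment sequence corresponding to the
#'   structure.
#' @param chains chains to map (default: all chains in the model, each mapped
#'   independently, as for a homodimer).
#' @param min_identity minimum sequence identity over matched positions
#'   (default 0.9); below this the mapping is refused.
#' @return data.frame of class \code{column_map} with \code{column},
#'   \code{chain}, \code{res_index} (row of \code{model$residues}).
#' @export
map_columns_to_residues <- function(aln, model, query_id,
                                    chains = NULL, min_identity = 0.9) {
  if (!query_id %in% aln$ids) stop("query id not found in alignment: ", query_id)
  qrow <- aln$mat[match(query_id, aln$ids), ]
  qcols <- which(qrow %in% AA1)
  qseq <- paste(qrow[qcols], collapse = "")
  if (is.null(chains)) chains <- unique(model$residues$chain)
  maps <- list()
  for (ch in chains) {
    ridx <- which(model$residues$chain == ch)
    sseq <- paste(aa_three_to_one(model$residues$resid[ridx]), collapse = "")
    pa <- Biostrings::pairwiseAlignment(qseq, sseq, type = "global",
                                        gapOpening = 10, gapExtension = 0.5)
    ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    qi <- cumsum(ap != "-")
    si <- cumsum(as_ != "-")
    both <- ap != "-" & as_ != "-"
    ident <- sum(ap[both] == as_[both]) / max(sum(both), 1)
    if (ident < min_identity)
      stop(sprintf("query/structure identity %.2f below floor %.2f for chain %s",
                   ident, min_identity, ch))
    maps[[ch]] <- data.frame(column = qcols[qi[both]], chain = ch,
                             res_index = ridx[si[both]])
  }
  out <- do.call(rbind, maps)
  rownames(out) <- NULL
  class(out) <- c("column_map", "data.frame")
  out
}

#' Proximity mutual information (pMI) per residue
#'
#' pMI of residue x is the mean cMI over the structural neighbourhood
#' \{x\} united with its contacts (the residue itself is included so that
#' isolated residues are well defined). Contacts are intended to come from
#' \code{\link{compute_contact_map}} with the heavy-atom-min metric at
#' 5 Angstrom. Residues without a mapped alignment column are NA.
#'
#' @param cmi per-column cMI vector (from \code{\link{cumulative_mi}}).
#' @param contacts a \code{contact_map} on the same structure.
#' @param colmap a \code{column_map} linking columns to residue indices.
#' @return numeric vector over residues of the contact map.
#' @export
proximity_mi <- function(cmi, contacts, colmap) {
  n <- contacts$n_residues
  res_cmi <- rep(NA_real_, n)
  res_cmi[colmap$res_index] <- cmi[colmap$column]
  out <- rep(NA_real_, n)
  for (x in seq_len(n)) {
    if (is.na(res_cmi[x])) next
    nb <- c(x, which(contacts$contacts[x, ]))
    vals <- res_cmi[nb]
    out[x] <- mean(vals, na.rm = TRUE)
  }
  out
}

#' Export conservation/coevolution profiles as TSV
#'
#' @param model a \code{structure_model}.
#' @param colmap a \code{column_map}.
#' @param kl conservation profile (per column).
#' @param cmi per-column cMI.
#' @param pmi per-residue pMI.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_coevolution_profile <- function(model, colmap, kl, cmi, pmi, path) {
  res <- model$residues
  n <- nrow(res)
  klr <- rep(NA_real_, n); cmir <- rep(NA_real_, n)
  klr[colmap$res_index] <- kl$kl[colmap$column]
  cmir[colmap$res_index] <- cmi[colmap$column]
  df <- data.frame(chain = res$chain, resnum = res$resno,
                   kl = klr, cmi = cmir, pmi = pmi)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
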