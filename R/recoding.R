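## Apply a symbol map to an alignment, preserving gap and missing symbols.
apply_recoding <- function(aln, map, target_alphabet) {
  m <- unclass(aln)
  keep <- c(.GAP, .missing_symbols(attr(aln, "alphabet")))
  out <- matrix(.MISSING, nrow(m), ncol(m), dimnames = dimnames(m))
  out[m == .GAP] <- .GAP
  out[m %in% setdiff(keep, .GAP)] <- .MISSING
  mapped <- m %in% names(map)
  out[mapped] <- map[m[mapped]]
  alignment(out, target_alphabet)
}

#' RY-recode a nucleotide alignment
#'
#' Collapses nucleotides to purines (A,G -> R) and pyrimidines (C,T -> Y),
#' which removes within-class compositional differences such as a T-for-C
#' excess; gaps stay gaps and missing symbols stay missing.
#'
#' @param aln Nucleotide [alignment()] (`nt4`; a codon alignment is accepted
#'   and loses its code binding).
#' @return `RY2` alignment.
#' @export
ry_recode <- function(aln) {
  stopifnot(attr(aln, "alphabet") == "nt4")
  map <- c(A = "R", G = "R", C = "Y", T = "Y")
  apply_recoding(aln, map, "RY2")
}

#' Six-state amino-acid recoding
#'
#' Groups amino acids into the six classes that commonly replace one
#' another: MVIL -> 1, FYW -> 2, ASTGP -> 3, DNEQ -> 4, RKH -> 5, C -> 6.
#'
#' @param aln Amino-acid [alignment()] (`aa20`).
#' @return `aa6` alignment over states 1-6.
#' @export
aa6_recode <- function(aln) {
  stopifnot(attr(aln, "alphabet") == "aa20")
  grp <- list(`1` = c("M", "V", "I", "L"),
              `2` = c("F", "Y", "W"),
              `3` = c("A", "S", "T", "G", "P"),
              `4` = c("D", "N", "E", "Q"),
              `5` = c("R", "K", "H"),
              `6` = "C")
  map <- stats::setNames(rep(names(grp), lengths(grp)), unlist(grp))
  apply_recoding(aln, map, "aa6")
}

#' Four-state amino-acid recoding
#'
#' Combines the aromatic (FYW) and hydrophobic (MVIL) classes into one state
#' and treats the rare cysteine as missing data, yielding four states that
#' are deliberately labelled A, T, G, C so that nucleotide GTR machinery
#' applies unchanged: FYWMVIL -> A, ASTGP -> T, DNEQ -> G, RKH -> C.
#'
#' @param aln Amino-acid [alignment()] (`aa20`).
#' @return `aa4` alignment.
#' @export
aa4_recode <- function(aln) {
  stopifnot(attr(aln, "alphabet") == "aa20")
  grp <- list(A = c("F", "Y", "W", "M", "V", "I", "L"),
              T = c("A", "S", "T", "G", "P"),
              G = c("D", "N", "E", "Q"),
              C = c("R", "K", "H"))
  map <- stats::setNames(rep(names(grp), lengths(grp)), unlist(grp))
  ## cysteine intentionally absent from the map -> becomes '?'
  apply_recoding(aln, map, "aa4")
}

#' Mask (or drop columns containing) selected residues
#'
#' The default masks each occurrence of the listed residues to `?`
#' (cell-level exclusion). Deleting every column containing any of the
#' residues would discard most of a typical alignment, so column dropping is
#' available only as an explicit sensitivity variant.
#'
#' @param aln Amino-acid [alignment()] (`aa20`).
#' @param residues Character vector of residues to exclude, e.g.
#'   `c("F","A","T","Y")`.
#' @param mode `"mask"` (default) or `"drop_columns"`.
#' @return Filtered `aa20` alignment.
#' @export
mask_residues <- function(aln, residues, mode = c("mask", "drop_columns")) {
  stopifnot(attr(aln, "alphabet") == "aa20")
  mode <- match.arg(mode)
  residues <- toupper(residues)
  bad <- setdiff(residues, .alphabets$aa20)
  if (length(bad)) stop("not amino-acid symbols: ", paste(bad, collapse = ", "))
  m <- unclass(aln)
  if (mode == "mask") {
    m[m %in% residues] <- .MISSING
    new_alignment(m, "aa20")
  } else {
    keep <- colSums(matrix(m %in% residues, nrow(m))) == 0L
    aln_subset_cols(aln, keep)
  }
}

#' Drop whole codon positions
#'
#' Removes the columns belonging to the listed codon positions (e.g. third
#' positions to blunt silent-site saturation). With a non-empty `drop` the
#' result is no longer in frame and is returned as a plain nucleotide
#' alignment.
#'
#' @param caln A [codon_alignment()].
#' @param drop Subset of `1:3` (empty = identity).
#' @return Nucleotide alignment (codon alignment when `drop` is empty).
#' @export
drop_codon_positions <- function(caln, drop) {
  stopifnot(inherits(caln, "mb_codon_aln"), all(drop %in% 1:3))
  if (length(drop) == 0L) return(caln)
  pos <- rep_len(1:3, ncol(caln))
  out <- aln_subset_cols(caln, !(pos %in% drop))
  class(out) <- "mb_aln"
  attr(out, "code") <- NULL
  out
}
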