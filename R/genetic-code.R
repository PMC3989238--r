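#' Genetic-code binding
#'
#' Wraps an NCBI translation table (via [Biostrings::getGeneticCode()]) into
#' the structure used throughout the package. The default, table 4
#' (mold/protozoan/coelenterate mitochondrial), is the appropriate code for
#' anthozoan mitochondria: unlike the standard code it translates TGA as
#' tryptophan, leaving TAA/TAG as the only stops and 62 sense codons.
#'
#' @param table_id Integer NCBI translation-table identifier (default 4).
#' @return Object of class `genetic_code`: list with `table_id`,
#'   `codon_to_aa` (named 64-vector, `*` = stop), `sense_codons`,
#'   `stop_codons`, and `families` (sense codons split by amino acid).
#' @examples
#' code <- genetic_code(4)
#' code$codon_to_aa[["TGA"]]  # "W" under the coelenterate mitochondrial code
#' @export
genetic_code <- function(table_id = 4L) {
  table_id <- as.integer(table_id)
  map <- Biostrings::getGeneticCode(as.character(table_id))
  map <- map[order(names(map))]  # fixed codon order: AAA..TTT
  stopifnot(length(map) == 64L)
  sense <- names(map)[map != "*"]
  structure(list(
    table_id = table_id,
    codon_to_aa = map,
    sense_codons = sense,
    stop_codons = names(map)[map == "*"],
    families = split(sense, map[sense])
  ), class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("NCBI translation table %d: %d sense codons, stops %s\n",
              x$table_id, length(x$sense_codons),
              paste(x$stop_codons, collapse = ",")))
  invisible(x)
}

#' Bind a genetic code to an in-frame nucleotide alignment
#'
#' @param x Nucleotide [alignment()] (or named character vector of
#'   sequences) whose column count is divisible by 3, frame anchored at the
#'   first column.
#' @param code A [genetic_code()].
#' @return Object of class `mb_codon_aln` (a nucleotide `mb_aln` carrying
#'   the bound code).
#' @export
codon_alignment <- function(x, code = genetic_code(4L)) {
  aln <- if (inherits(x, "mb_aln")) x else alignment(x, "nt4")
  if (attr(aln, "alphabet") != "nt4") stop("codon alignments must be nt4")
  if (ncol(aln) %% 3L != 0L)
    stop("column count ", ncol(aln), " not divisible by 3")
  stopifnot(inherits(code, "genetic_code"))
  class(aln) <- c("mb_codon_aln", "mb_aln")
  attr(aln, "code") <- code
  aln
}

## taxa x n_codon matrix of codon strings; gap/missing handling downstream
codon_matrix <- function(caln) {
  stopifnot(inherits(caln, "mb_codon_aln"))
  nc <- ncol(caln) %/% 3L
  m <- unclass(caln)
  out <- matrix("", nrow(m), nc, dimnames = list(rownames(m), NULL))
  for (j in seq_len(nc)) {
    cols <- (3L * (j - 1L) + 1L):(3L * j)
    out[, j] <- paste0(m[, cols[1]], m[, cols[2]], m[, cols[3]])
  }
  out
}

#' Translate a codon alignment
#'
#' Each codon column becomes one amino-acid column. An all-gap codon (`---`)
#' translates to a gap; a codon containing any other gap or missing symbol
#' translates to `?`. A complete codon that is a stop under the bound code is
#' an error (the alignment is expected to be in frame and protein-coding).
#'
#' @param caln A [codon_alignment()].
#' @return Amino-acid [alignment()] (`aa20`).
#' @export
translate <- function(caln) {
  code <- attr(caln, "code")
  cm <- codon_matrix(caln)
  miss <- .missing_symbols("nt4")
  aa <- matrix(.MISSING, nrow(cm), ncol(cm), dimnames = dimnames(cm))
  complete <- matrix(!grepl(paste0("[-", paste(miss, collapse = ""), "]"), cm),
                     nrow(cm))
  aa[cm == "---"] <- .GAP
  if (any(complete)) {
    tr <- code$codon_to_aa[cm[complete]]
    if (any(tr == "*")) {
      bad <- which(complete, arr.ind = TRUE)[tr == "*", , drop = FALSE]
      stop(sprintf("internal stop codon in taxon '%s' at codon %d (columns %d-%d)",
                   rownames(cm)[bad[1, 1]], bad[1, 2],
                   3L * (bad[1, 2] - 1L) + 1L, 3L * bad[1, 2]))
    }
    aa[complete] <- tr
  }
  alignment(aa, "aa20")
}

#' Reverse-translate an amino-acid alignment
#'
#' Expands each amino-acid column back to its source codon using the
#' unaligned coding sequence of each taxon; amino-acid gaps become `---` and
#' missing residues `???`. Each taxon's CDS must translate exactly to its
#' ungapped amino-acid row under the bound code.
#'
#' @param aa_aln Amino-acid [alignment()].
#' @param cds_by_taxon Named character vector of ungapped, in-frame coding
#'   sequences, one per taxon (a trailing stop codon is tolerated and
#'   dropped).
#' @param code A [genetic_code()].
#' @return A [codon_alignment()].
#' @export
reverse_translate <- function(aa_aln, cds_by_taxon, code = genetic_code(4L)) {
  stopifnot(attr(aa_aln, "alphabet") == "aa20")
  tax <- taxa(aa_aln)
  if (!all(tax %in% names(cds_by_taxon)))
    stop("missing CDS for: ", paste(setdiff(tax, names(cds_by_taxon)), collapse = ", "))
  m <- unclass(aa_aln)
  out <- matrix("", length(tax), 3L * ncol(m), dimnames = list(tax, NULL))
  for (t in tax) {
    cds <- toupper(gsub("U", "T", cds_by_taxon[[t]]))
    if (nchar(cds) %% 3L != 0L)
      stop("CDS of taxon '", t, "' is not a whole number of codons")
    codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
    if (length(codons) && code$codon_to_aa[[codons[length(codons)]]] == "*")
      codons <- codons[-length(codons)]
    row <- m[t, ]
    resid <- which(!(row %in% c(.GAP, .missing_symbols("aa20"))))
    if (length(codons) != length(resid))
      stop(sprintf("taxon '%s': CDS has %d codons but aligned row has %d residues",
                   t, length(codons), length(resid)))
    tr <- unname(code$codon_to_aa[codons])
    mism <- which(tr != row[resid])
    if (length(mism))
      stop(sprintf("taxon '%s': CDS/aa mismatch at residue %d (alignment column %d): CDS gives '%s', alignment has '%s'",
                   t, mism[1], resid[mism[1]], tr[mism[1]], row[resid[mism[1]]]))
    cod <- character(ncol(m))
    cod[row == .GAP] <- "---"
    cod[row %in% .missing_symbols("aa20")] <- "???"
    cod[resid] <- codons
    out[t, ] <- unlist(strsplit(cod, "", fixed = TRUE), use.names = FALSE)
  }
  codon_alignment(alignment(out, "nt4"), code)
}
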