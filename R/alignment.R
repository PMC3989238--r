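#' @useDynLib mitobias, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Alphabets understood by the package. aa4 deliberately reuses the
## nucleotide state names so nucleotide GTR machinery applies unchanged.
.alphabets <- list(
  nt4  = c("A", "C", "G", "T"),
  RY2  = c("R", "Y"),
  aa20 = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
  aa6  = as.character(1:6),
  aa4  = c("A", "T", "G", "C")
)

.GAP <- "-"
.MISSING <- "?"

#' Alphabet state sets
#'
#' Returns the ordered state vector for one of the five alphabets used by the
#' package: `nt4` (A,C,G,T), `RY2` (purine/pyrimidine), `aa20` (amino acids in
#' PAML order), `aa6` (six-state amino-acid recoding) and `aa4` (four-state
#' amino-acid recoding labelled A,T,G,C).
#'
#' @param alphabet Alphabet name.
#' @return Character vector of states (gap `-` and missing `?` excluded).
#' @export
alphabet_states <- function(alphabet = c("nt4", "aa20", "RY2", "aa6", "aa4")) {
  alphabet <- match.arg(alphabet)
  .alphabets[[alphabet]]
}

## symbols accepted as "missing" in a given alphabet ('X' only meaningful
## for amino-acid data; 'N' for nucleotides)
.missing_symbols <- function(alphabet) {
  switch(alphabet,
    aa20 = c(.MISSING, "X"),
    nt4  = c(.MISSING, "N"),
    c(.MISSING)
  )
}

new_alignment <- function(mat, alphabet) {
  stopifnot(is.matrix(mat), is.character(mat))
  if (is.null(rownames(mat))) stop("alignment matrix must have taxon rownames")
  structure(mat, alphabet = alphabet, class = "mb_aln")
}

#' Construct an alignment
#'
#' An alignment is a taxa-by-columns character matrix over a declared
#' alphabet, with `-` for gaps and `?` for missing data (`X` is additionally
#' accepted as missing for amino-acid data, `N` for nucleotide data).
#' Symbols outside the alphabet are replaced by `?` and counted with a
#' warning.
#'
#' @param x Named character vector of sequence strings (one per taxon), or a
#'   character matrix with taxon rownames.
#' @param alphabet One of `"nt4"`, `"aa20"`, `"RY2"`, `"aa6"`, `"aa4"`.
#' @return An object of class `mb_aln`: character matrix with attributes
#'   `alphabet` and, when symbols were replaced, `n_unknown`.
#' @examples
#' aln <- alignment(c(t1 = "ATGAAA", t2 = "ATGCAA"), "nt4")
#' n_col(aln)
#' @export
alignment <- function(x, alphabet = c("nt4", "aa20", "RY2", "aa6", "aa4")) {
  alphabet <- match.arg(alphabet)
  if (is.matrix(x)) {
    mat <- x
  } else {
    if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
      stop("sequences must be named by taxon")
    if (length(x) == 0L) stop("no sequences supplied")
    lens <- nchar(x)
    if (length(unique(lens)) != 1L)
      stop("ragged alignment: row lengths differ (", paste(lens, collapse = ", "), ")")
    mat <- matrix("", nrow = length(x), ncol = lens[1],
                  dimnames = list(names(x), NULL))
    for (i in seq_along(x)) mat[i, ] <- strsplit(x[[i]], "", fixed = TRUE)[[1]]
  }
  if (anyDuplicated(rownames(mat)))
    stop("duplicate taxon labels: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  mat[] <- toupper(mat)
  if (alphabet == "nt4") mat[mat == "U"] <- "T"
  ok <- c(.alphabets[[alphabet]], .GAP, .missing_symbols(alphabet))
  bad <- !(mat %in% ok)
  n_unknown <- sum(bad)
  if (n_unknown > 0L) {
    mat[bad] <- .MISSING
    warning(sprintf("%d symbol(s) outside the %s alphabet replaced by '?'",
                    n_unknown, alphabet))
  }
  out <- new_alignment(mat, alphabet)
  if (n_unknown > 0L) attr(out, "n_unknown") <- n_unknown
  out
}

#' @export
print.mb_aln <- function(x, ...) {
  cat(sprintf("%s alignment: %d taxa, %d columns (alphabet %s)\n",
              if (inherits(x, "mb_codon_aln")) "codon" else "sequence",
              nrow(x), ncol(x), attr(x, "alphabet")))
  invisible(x)
}

#' Alignment dimensions and labels
#'
#' @param aln An `mb_aln`.
#' @return `n_taxa`/`n_col` return integers; `taxa` the taxon labels.
#' @export
n_taxa <- function(aln) nrow(aln)

#' @rdname n_taxa
#' @export
n_col <- function(aln) ncol(aln)

#' @rdname n_taxa
#' @export
taxa <- function(aln) rownames(aln)

## keep class/attributes when subsetting columns
aln_subset_cols <- function(aln, keep) {
  mat <- unclass(aln)[, keep, drop = FALSE]
  out <- new_alignment(mat, attr(aln, "alphabet"))
  if (inherits(aln, "mb_codon_aln") && ncol(out) %% 3L == 0L) {
    class(out) <- c("mb_codon_aln", class(out))
    attr(out, "code") <- attr(aln, "code")
  }
  out
}

#' Sequence strings from an alignment
#'
#' @param aln An `mb_aln`.
#' @return Named character vector of per-taxon sequence strings.
#' @export
aln_strings <- function(aln) {
  apply(unclass(aln), 1L, paste, collapse = "")
}

is_gapmiss <- function(aln) {
  unclass(aln) == .GAP | unclass(aln) %in% .missing_symbols(attr(aln, "alphabet"))
}

#' Read an alignment from FASTA or relaxed PHYLIP
#'
#' FASTA parsing is delegated to [Biostrings::readBStringSet()]; a simple
#' relaxed (whitespace-separated, non-interleaved) PHYLIP reader is provided
#' for round-tripping files written for external tools.
#'
#' @param path File path.
#' @param alphabet Declared alphabet (see [alignment()]).
#' @param format `"auto"` (by first non-blank character), `"fasta"` or
#'   `"phylip"`.
#' @return An [alignment()] object.
#' @export
read_alignment <- function(path, alphabet = c("nt4", "aa20", "RY2", "aa6", "aa4"),
                           format = c("auto", "fasta", "phylip")) {
  alphabet <- match.arg(alphabet)
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty alignment file: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (startsWith(trimws(first), ">")) "fasta" else "phylip"
  }
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("empty alignment file: ", path)
    seqs <- as.character(set)
    names(seqs) <- sub("\\s.*$", "", names(set))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    hdr <- scan(text = lines[1], what = integer(), n = 2L, quiet = TRUE)
    body <- lines[-1]
    if (length(body) != hdr[1]) stop("PHYLIP: expected ", hdr[1], " rows")
    parts <- regmatches(body, regexpr("\\S+", body))
    seqs <- gsub("\\s", "", sub("^\\S+\\s+", "", body))
    names(seqs) <- parts
    if (any(nchar(seqs) != hdr[2]))
      stop("PHYLIP: ragged rows or wrong column count")
  }
  alignment(seqs, alphabet)
}

#' Write an alignment
#'
#' @param aln An `mb_aln`.
#' @param path Output path.
#' @param format `"fasta"` or relaxed `"phylip"` (single block, name and
#'   sequence separated by two spaces, as accepted by most ML tools).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  seqs <- aln_strings(aln)
  if (format == "fasta") {
    Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf(" %d %d", n_taxa(aln), n_col(aln)), con)
    writeLines(sprintf("%s  %s", names(seqs), seqs), con)
  }
  invisible(path)
}

#' Concatenate gene alignments
#'
#' Columns are appended gene by gene; a partition map (1-based inclusive
#' column ranges) is retained in attribute `"partition"` for per-gene
#' statistics. All genes must share the same taxon set and alphabet; no
#' silent padding is performed.
#'
#' @param alignments List of `mb_aln` objects (optionally named by gene).
#' @return Concatenated [alignment()] with a `partition` attribute
#'   (data.frame: gene, start, end).
#' @export
concatenate <- function(alignments) {
  stopifnot(length(alignments) >= 1L)
  a1 <- alignments[[1]]
  tax <- taxa(a1)
  alph <- attr(a1, "alphabet")
  for (a in alignments[-1]) {
    if (attr(a, "alphabet") != alph) stop("mixed alphabets in concatenate()")
    if (!setequal(taxa(a), tax))
      stop("taxon sets differ between genes: ",
           paste(union(setdiff(taxa(a), tax), setdiff(tax, taxa(a))), collapse = ", "))
  }
  mats <- lapply(alignments, function(a) unclass(a)[tax, , drop = FALSE])
  out <- new_alignment(do.call(cbind, mats), alph)
  lens <- vapply(mats, ncol, 0L)
  gene <- names(alignments)
  if (is.null(gene)) gene <- paste0("gene", seq_along(alignments))
  attr(out, "partition") <- data.frame(
    gene = gene,
    start = cumsum(c(1L, lens[-length(lens)])),
    end = cumsum(lens)
  )
  if (inherits(a1, "mb_codon_aln") &&
      all(vapply(alignments, inherits, TRUE, "mb_codon_aln"))) {
    class(out) <- c("mb_codon_aln", class(out))
    attr(out, "code") <- attr(a1, "code")
  }
  out
}

#' Remove columns exceeding a gap fraction
#'
#' Retains columns whose gap-or-missing fraction is at most
#' `max_gap_fraction`. On codon alignments the filter operates on whole
#' codons to preserve frame: a codon is dropped when any of its three columns
#' exceeds the threshold.
#'
#' @param aln An `mb_aln` (or codon alignment).
#' @param max_gap_fraction Maximum tolerated fraction in `[0, 1]`; `?` and
#'   `X`/`N` count as gaps here.
#' @return Filtered alignment.
#' @export
filter_gap_columns <- function(aln, max_gap_fraction = 0.5) {
  stopifnot(max_gap_fraction >= 0, max_gap_fraction <= 1)
  frac <- colMeans(is_gapmiss(aln))
  keep <- frac <= max_gap_fraction
  if (inherits(aln, "mb_codon_aln")) {
    codon_bad <- matrix(!keep, nrow = 3L)
    keep <- rep(!apply(codon_bad, 2L, any), each = 3L)
  }
  aln_subset_cols(aln, keep)
}

#' Keep only complete columns
#'
#' Retains columns containing no gap and no missing symbol at all (the
#' "no gaps or missing data" rule used before amino-acid model fitting).
#' An all-gap input yields a 0-column alignment with a warning.
#'
#' @param aln An `mb_aln`.
#' @return Filtered alignment.
#' @export
strip_incomplete_columns <- function(aln) {
  keep <- colSums(is_gapmiss(aln)) == 0L
  if (!any(keep)) warning("no complete columns remain")
  out <- aln_subset_cols(aln, keep)
  ## frame is meaningless after arbitrary column removal
  if (inherits(out, "mb_codon_aln") && !all(keep)) {
    class(out) <- "mb_aln"
    attr(out, "code") <- NULL
  }
  out
}

#' Read a taxon-to-group map
#'
#' @param path TSV/CSV file with two columns: taxon label and group label
#'   (header optional, autodetected by the literal names "taxon"/"group").
#' @return Named character vector mapping taxon to group.
#' @export
read_group_map <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          col.names = c("taxon", "group"),
                          colClasses = "character")
  if (nrow(df) && tolower(df$taxon[1]) == "taxon") df <- df[-1, , drop = FALSE]
  stats::setNames(df$group, df$taxon)
}
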