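#' Nucleotide composition at selected codon positions
#'
#' Proportions of A, C, G, T in one taxon's row, restricted to the requested
#' codon positions. Gaps and missing symbols are excluded from the
#' denominator.
#'
#' @param caln A [codon_alignment()].
#' @param taxon Taxon label.
#' @param positions Subset of `1:3` (default all three).
#' @return Named numeric vector `c(A=, C=, G=, T=)` summing to 1.
#' @export
nt_composition <- function(caln, taxon, positions = 1:3) {
  stopifnot(inherits(caln, "mb_codon_aln"),
            all(positions %in% 1:3), length(positions) >= 1L)
  if (!taxon %in% taxa(caln)) stop("unknown taxon: ", taxon)
  row <- unclass(caln)[taxon, ]
  pos <- rep_len(1:3, length(row))
  sym <- row[pos %in% positions]
  sym <- sym[sym %in% .alphabets$nt4]
  if (length(sym) == 0L) stop("no countable symbols for taxon ", taxon)
  tab <- table(factor(sym, levels = .alphabets$nt4))
  stats::setNames(as.vector(tab) / length(sym), .alphabets$nt4)
}

#' AT and GC skews
#'
#' `at_skew = (A - T)/(A + T)`, `gc_skew = (G - C)/(G + C)`. A zero
#' denominator yields `NA` with attribute `undefined = TRUE` rather than an
#' error.
#'
#' @param freq Named frequency vector with components A, C, G, T.
#' @return Named numeric `c(at_skew=, gc_skew=)`.
#' @export
skews <- function(freq) {
  stopifnot(all(c("A", "C", "G", "T") %in% names(freq)))
  at <- unname(freq["A"] + freq["T"])
  gc <- unname(freq["G"] + freq["C"])
  out <- c(at_skew = if (at > 0) unname(freq["A"] - freq["T"]) / at else NA_real_,
           gc_skew = if (gc > 0) unname(freq["G"] - freq["C"]) / gc else NA_real_)
  if (anyNA(out)) attr(out, "undefined") <- TRUE
  out
}

.FYMINK <- c("F", "Y", "M", "I", "N", "K")
.GARP <- c("G", "A", "R", "P")

#' FYMINK and GARP fractions
#'
#' FYMINK (Phe, Tyr, Met, Ile, Asn, Lys) are the amino acids encoded by
#' (A+T)-rich codons; GARP (Gly, Ala, Arg, Pro) those encoded by (G+C)-rich
#' codons. Their ratio indexes how strongly nucleotide composition has pushed
#' the encoded proteome.
#'
#' @param aa_freqs Named 20-vector of amino-acid proportions summing to 1.
#' @return List with `fymink`, `garp` and `ratio` (`NA` with attribute
#'   `undefined` when `garp` is 0).
#' @export
fymink_garp <- function(aa_freqs) {
  stopifnot(all(.alphabets$aa20 %in% names(aa_freqs)))
  fymink <- sum(aa_freqs[.FYMINK])
  garp <- sum(aa_freqs[.GARP])
  ratio <- if (garp > 0) fymink / garp else NA_real_
  out <- list(fymink = unname(fymink), garp = unname(garp), ratio = unname(ratio))
  if (is.na(ratio)) attr(out, "undefined") <- TRUE
  out
}

#' Per-taxon composition profiles
#'
#' Computes, for every taxon of a codon alignment, the base composition at
#' each codon position and overall, A+T/G+C content, AT and GC skews,
#' amino-acid frequencies of the translated row, and the FYMINK/GARP
#' statistics.
#'
#' @param caln A [codon_alignment()].
#' @return `data.frame` with one row per taxon and columns
#'   `taxon`, `A1..T1, A2..T2, A3..T3, A..T` (proportions by position and
#'   overall), `at_content`, `gc_content`, `at_skew`, `gc_skew`,
#'   `fymink`, `garp`, `fymink_garp`, plus the 20 amino-acid frequencies
#'   (`aa_A` ... `aa_V`).
#' @export
composition_profiles <- function(caln) {
  aa <- translate(caln)
  aam <- unclass(aa)
  rows <- lapply(taxa(caln), function(t) {
    by_pos <- lapply(1:3, function(p) nt_composition(caln, t, p))
    all_pos <- nt_composition(caln, t, 1:3)
    sk <- skews(all_pos)
    sym <- aam[t, ]
    sym <- sym[sym %in% .alphabets$aa20]
    aaf <- as.vector(table(factor(sym, levels = .alphabets$aa20))) / max(length(sym), 1L)
    names(aaf) <- .alphabets$aa20
    fg <- fymink_garp(aaf)
    out <- c(
      stats::setNames(unlist(by_pos), paste0(rep(c("A", "C", "G", "T"), 3),
                                             rep(1:3, each = 4))),
      all_pos,
      at_content = unname(all_pos["A"] + all_pos["T"]),
      gc_content = unname(all_pos["G"] + all_pos["C"]),
      sk,
      fymink = fg$fymink, garp = fg$garp, fymink_garp = fg$ratio,
      stats::setNames(aaf, paste0("aa_", names(aaf)))
    )
    out
  })
  df <- as.data.frame(do.call(rbind, rows))
  df <- cbind(taxon = taxa(caln), df)
  rownames(df) <- NULL
  df
}

#' Per-group means of composition profiles
#'
#' Group summaries are arithmetic means of the per-taxon statistics (ratios
#' averaged per taxon, not recomputed from pooled counts), matching the
#' convention of averaging across the species of a group.
#'
#' @param profiles Output of [composition_profiles()].
#' @param group_map Named character vector taxon -> group (see
#'   [read_group_map()]).
#' @return `data.frame` with one row per group, same statistic columns, plus
#'   `n_taxa`.
#' @export
group_summary <- function(profiles, group_map) {
  unmapped <- setdiff(profiles$taxon, names(group_map))
  if (length(unmapped))
    stop("taxa missing from group map: ", paste(unmapped, collapse = ", "))
  g <- factor(group_map[profiles$taxon])
  num <- profiles[, setdiff(names(profiles), "taxon"), drop = FALSE]
  agg <- stats::aggregate(num, by = list(group = g), FUN = mean)
  agg$n_taxa <- as.vector(table(g)[as.character(agg$group)])
  agg
}
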