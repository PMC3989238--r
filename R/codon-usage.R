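#' Codon counts for a taxon or whole alignment
#'
#' Counts complete, sense-or-stop codons; codons containing gaps or missing
#' symbols are skipped. Stop codons should not occur in protein-coding input
#' (translate() errors on them) but are counted if present so the caller can
#' inspect them.
#'
#' @param caln A [codon_alignment()].
#' @param taxon Taxon label, or `NULL` to pool all taxa.
#' @return Named integer 64-vector in alphabetical codon order.
#' @export
codon_counts <- function(caln, taxon = NULL) {
  cm <- codon_matrix(caln)
  if (!is.null(taxon)) {
    if (!taxon %in% rownames(cm)) stop("unknown taxon: ", taxon)
    cm <- cm[taxon, , drop = FALSE]
  }
  codons <- sort(names(attr(caln, "code")$codon_to_aa))
  v <- cm[!grepl("[^ACGT]", cm)]
  tab <- table(factor(v, levels = codons))
  stats::setNames(as.integer(tab), codons)
}

## Wright's homozygosity for one synonymous family; NA when undefined
.family_homozygosity <- function(counts) {
  n <- sum(counts)
  if (n < 2L) return(NA_real_)
  p <- counts / n
  f <- (n * sum(p^2) - 1) / (n - 1)
  if (f <= 0) NA_real_ else f
}

#' Effective number of codons (NC)
#'
#' Wright's NC, the codon-usage analogue of effective allele number: for each
#' synonymous family the homozygosity \eqn{\hat F = (n \sum \hat p_i^2 - 1)/(n - 1)}
#' is computed, families are grouped by size (the sizes are derived from the
#' bound genetic code, so under translation table 4 tryptophan is a two-codon
#' family and there are 62 sense codons), and
#' \eqn{NC = \sum_s K_s / \bar F_s} over family-size classes \eqn{s}, with
#' single-codon families contributing their count directly. A family with
#' undefined \eqn{\hat F} falls back to the mean of the other families of its
#' size class; a wholly undefined size class is interpolated from the
#' neighbouring classes (Wright's averaging recommendation), with a note in
#' attribute `"fallbacks"`. The result is clipped to
#' `[20, length(code$sense_codons)]`; uniform usage at large counts
#' approaches the sense-codon count and one-codon-per-amino-acid usage gives
#' 20.
#'
#' @param counts Named codon-count vector (subset or all 64 codons).
#' @param code A [genetic_code()].
#' @return NC value (numeric scalar), possibly with attribute `fallbacks`.
#' @export
effective_number_of_codons <- function(counts, code = genetic_code(4L)) {
  stopifnot(inherits(code, "genetic_code"))
  if (sum(counts) == 0) stop("all codon counts are zero")
  fams <- code$families
  sizes <- vapply(fams, length, 0L)
  fhat <- vapply(fams, function(cod) {
    x <- counts[cod]
    x[is.na(x)] <- 0L
    .family_homozygosity(x)
  }, 0)
  fallbacks <- character(0)
  nc <- 0
  fbar <- tapply(fhat, sizes, function(v) mean(v, na.rm = TRUE))
  for (s in sort(unique(sizes))) {
    ks <- sum(sizes == s)
    if (s == 1L) {
      nc <- nc + ks
      next
    }
    fb <- fbar[[as.character(s)]]
    if (!is.finite(fb)) {
      ## whole size class undefined: interpolate from neighbouring classes
      others <- fbar[names(fbar) != as.character(s)]
      others <- others[is.finite(others)]
      if (!length(others)) stop("too few data to compute NC")
      w <- 1 / abs(as.numeric(names(others)) - s)
      fb <- sum(w * others) / sum(w)
      fallbacks <- c(fallbacks, sprintf("size-%d class interpolated", s))
    }
    nc <- nc + ks / fb
  }
  nc <- min(max(nc, 20), length(code$sense_codons))
  if (length(fallbacks)) attr(nc, "fallbacks") <- fallbacks
  nc
}

#' Self-referential CAI reference weights
#'
#' Relative adaptiveness `w = count / max(count)` within each synonymous
#' family of the bound code, computed from a reference codon-count vector
#' (by default the concatenated dataset itself). Codons unobserved in the
#' reference are floored at 0.01 so the geometric mean stays finite.
#'
#' @param reference_counts Named codon counts used as the reference set.
#' @param code A [genetic_code()].
#' @return Named weight vector over sense codons, max 1 within each family.
#' @export
cai_weights <- function(reference_counts, code = genetic_code(4L)) {
  w <- stats::setNames(numeric(length(code$sense_codons)), code$sense_codons)
  for (cod in code$families) {
    x <- reference_counts[cod]
    x[is.na(x)] <- 0
    m <- max(x)
    w[cod] <- if (m > 0) pmax(x / m, 0.01) else 1 / length(cod)
  }
  w
}

#' Codon adaptation index (CAI)
#'
#' Geometric mean of the relative adaptiveness of the codons actually used,
#' taken over codons belonging to multi-codon families only (single-codon
#' families carry no choice and are excluded; under translation table 4 that
#' excludes methionine but keeps the two-codon tryptophan family).
#'
#' @param counts Named codon-count vector for the sequence(s) scored.
#' @param weights Reference weights from [cai_weights()] (or an external
#'   reference set on the same codon names).
#' @param code A [genetic_code()].
#' @return CAI in (0, 1].
#' @export
codon_adaptation_index <- function(counts, weights, code = genetic_code(4L)) {
  multi <- unlist(code$families[vapply(code$families, length, 0L) > 1L],
                  use.names = FALSE)
  x <- counts[multi]
  x[is.na(x)] <- 0
  if (sum(x) == 0) stop("no codons from multi-codon families observed")
  w <- weights[multi]
  if (anyNA(w)) stop("weights missing for codons: ",
                     paste(multi[is.na(w)], collapse = ", "))
  exp(sum(x * log(w)) / sum(x))
}

#' Codon-usage statistics for every taxon
#'
#' @param caln A [codon_alignment()].
#' @param reference_counts Optional reference counts for CAI; defaults to the
#'   pooled counts of the alignment (self-referential weights).
#' @return `data.frame` with columns `taxon`, `nc`, `cai`.
#' @export
codon_usage_stats <- function(caln, reference_counts = NULL) {
  code <- attr(caln, "code")
  if (is.null(reference_counts)) reference_counts <- codon_counts(caln)
  w <- cai_weights(reference_counts, code)
  rows <- lapply(taxa(caln), function(t) {
    cc <- codon_counts(caln, t)
    data.frame(taxon = t,
               nc = as.numeric(effective_number_of_codons(cc, code)),
               cai = codon_adaptation_index(cc, w, code))
  })
  do.call(rbind, rows)
}
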