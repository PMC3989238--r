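#' Base-frequency (BF) distance
#'
#' Half the sum of absolute differences between two taxa's frequency vectors
#' (the total-variation distance). Trees built from BF distances reflect
#' composition alone, so comparing them with substitution-based trees
#' separates compositional attraction from phylogenetic signal. Note the
#' absolute values: without them the paired differences of two probability
#' vectors cancel identically.
#'
#' @param f,g Frequency vectors over the same symbols (names compared when
#'   present). Works for base frequencies and equally for 20-symbol
#'   amino-acid frequencies.
#' @return Non-negative scalar in `[0, 1]`.
#' @export
bf_distance <- function(f, g) {
  if (length(f) != length(g)) stop("frequency vectors differ in length")
  if (!is.null(names(f)) && !is.null(names(g))) {
    if (!setequal(names(f), names(g))) stop("frequency vectors differ in symbols")
    g <- g[names(f)]
  }
  sum(abs(f - g)) / 2
}

#' Pairwise BF distance matrix
#'
#' @param profiles Numeric matrix of frequency vectors, taxa in rows
#'   (rownames = taxon ids), symbols in columns; rows should each sum to 1.
#' @return Symmetric `DistanceMatrix` (base matrix with taxon dimnames).
#' @export
bf_distance_matrix <- function(profiles) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 3L)
  n <- nrow(profiles)
  d <- matrix(0, n, n, dimnames = list(rownames(profiles), rownames(profiles)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- bf_distance(profiles[i, ], profiles[j, ])
  }
  d
}

#' LogDet (paralinear) distance matrix
#'
#' For each pair, the joint frequency matrix \eqn{\hat J} of the two rows is
#' tabulated over columns where both taxa have a definite symbol, and
#' \eqn{d = -(1/k)\,[\ln\det\hat J - \tfrac12 \sum_i \ln(f_i g_i)]}
#' with \eqn{k} the alphabet size and \eqn{f,g} the marginal frequencies.
#' LogDet is consistent under the general Markov model, i.e. it does not
#' assume stationarity or homogeneity of the substitution process, which
#' makes trees built from it robust to clade-specific composition — but the
#' guarantee applies per Markov process: pooling site classes that evolve
#' under different processes (codon positions, strong rate mixtures)
#' reintroduces a bias toward grouping compositionally similar taxa. For
#' codon alignments `by_position = TRUE` therefore computes the distance
#' separately at each codon position and sums the three components, which
#' restores the per-class assumption. Pairs with a singular joint matrix
#' are set to `Inf` and pairs with fewer than `k` shared columns to `NA`;
#' both are listed in attribute `"flagged_pairs"` rather than silently
#' imputed.
#'
#' @param aln An [alignment()] over any of the package alphabets.
#' @param by_position For a [codon_alignment()]: stratify by codon position
#'   (default TRUE for codon alignments).
#' @param positions Codon positions included when stratifying (default all
#'   three; near saturation the third-position component degenerates and is
#'   better excluded).
#' @return Symmetric matrix of distances with taxon dimnames.
#' @export
logdet_distance_matrix <- function(aln,
                                   by_position = inherits(aln, "mb_codon_aln"),
                                   positions = 1:3) {
  if (by_position) {
    if (!inherits(aln, "mb_codon_aln"))
      stop("by_position requires a codon alignment")
    parts <- lapply(positions, function(p)
      logdet_distance_matrix(drop_codon_positions(aln, setdiff(1:3, p)),
                             by_position = FALSE))
    d <- Reduce(`+`, parts)
    fl <- unlist(lapply(parts, attr, "flagged_pairs"))
    if (length(fl)) attr(d, "flagged_pairs") <- unique(fl)
    return(d)
  }
  .logdet_matrix_impl(aln)
}

.logdet_matrix_impl <- function(aln) {
  states <- .alphabets[[attr(aln, "alphabet")]]
  k <- length(states)
  m <- unclass(aln)
  n <- nrow(m)
  idx <- matrix(match(m, states), n)  # NA for gap/missing
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  flagged <- character(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(idx[i, ]) & !is.na(idx[j, ])
    ns <- sum(ok)
    if (ns < k) {
      d[i, j] <- d[j, i] <- NA_real_
      flagged <- c(flagged, sprintf("%s|%s (too few shared columns)",
                                    rownames(m)[i], rownames(m)[j]))
      next
    }
    J <- matrix(0, k, k)
    tab <- table(factor(idx[i, ok], levels = 1:k),
                 factor(idx[j, ok], levels = 1:k))
    J[] <- as.numeric(tab) / ns
    f <- rowSums(J); g <- colSums(J)
    det_j <- det(J)
    if (det_j <= 0 || any(f == 0) || any(g == 0)) {
      d[i, j] <- d[j, i] <- Inf
      flagged <- c(flagged, sprintf("%s|%s (singular joint matrix)",
                                    rownames(m)[i], rownames(m)[j]))
      next
    }
    val <- -(log(det_j) - 0.5 * sum(log(f * g))) / k
    d[i, j] <- d[j, i] <- max(val, 0)
  }
  if (length(flagged)) attr(d, "flagged_pairs") <- flagged
  d
}

#' Neighbor-joining tree with non-negative branch lengths
#'
#' Wraps [ape::nj()]; negative branch lengths (which NJ can produce on noisy
#' matrices) are floored at zero, with the number of floored edges recorded
#' in attribute `"n_floored"`.
#'
#' @param d Symmetric distance matrix with taxon dimnames (finite entries).
#' @return Unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  stopifnot(nrow(d) >= 3L)
  if (any(!is.finite(d))) stop("non-finite distances; resolve flagged pairs first")
  tr <- ape::nj(stats::as.dist(d))
  n_neg <- sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  if (n_neg > 0) attr(tr, "n_floored") <- n_neg
  tr
}

#' Minimum-evolution tree from BF distances
#'
#' Builds the composition-only tree: BF distance matrix from per-taxon
#' frequency vectors, then a minimum-evolution tree by OLS with NNI
#' improvement ([ape::fastme.ols()]), the standard heuristic for the ME
#' criterion.
#'
#' @param profiles Frequency-vector matrix as in [bf_distance_matrix()]
#'   (nucleotide or amino-acid frequencies).
#' @param nni Improve the OLS tree length by nearest-neighbor interchanges.
#' @return Unrooted `phylo` tree with non-negative branch lengths.
#' @export
bf_tree <- function(profiles, nni = TRUE) {
  d <- bf_distance_matrix(profiles)
  tr <- ape::fastme.ols(stats::as.dist(d), nni = nni)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Write a distance matrix in PHYLIP format
#'
#' @param d Symmetric matrix with taxon dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_phylip <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(formatC(rownames(d)[i], width = -12),
                     paste(sprintf("%.8f", d[i, ]), collapse = " ")), con)
  invisible(path)
}
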