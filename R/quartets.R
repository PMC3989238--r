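#' Sample quartets across groups
#'
#' Draws `n` quartets, one taxon per named group, uniformly with
#' replacement; deterministic under `seed`.
#'
#' @param group_map Named character vector taxon -> group.
#' @param pattern Character vector of four group labels defining the quartet
#'   slots (e.g. robust, complex, corallimorph, outgroup).
#' @param n Number of quartets.
#' @param seed Integer seed.
#' @return `n x 4` character matrix of taxon labels, columns named by
#'   `pattern`.
#' @export
sample_quartets <- function(group_map, pattern, n, seed) {
  stopifnot(length(pattern) == 4L)
  pools <- lapply(pattern, function(g) names(group_map)[group_map == g])
  empty <- pattern[lengths(pools) == 0L]
  if (length(empty)) stop("empty group(s): ", paste(empty, collapse = ", "))
  if (n == 0L)
    return(matrix(character(0), 0L, 4L, dimnames = list(NULL, pattern)))
  with_seed(seed, {
    out <- vapply(pools, function(p) p[sample.int(length(p), n, replace = TRUE)],
                  character(n))
    matrix(out, nrow = n, dimnames = list(NULL, pattern))
  })
}

## Jukes-Cantor-type distance matrix for any alphabet (used as the
## composition-naive comparator in calibration experiments)
#' Jukes-Cantor distance matrix
#'
#' Equal-rates correction `d = -((k-1)/k) log(1 - k p / (k-1))` of the
#' proportion of differing shared sites, over the alignment's alphabet.
#' Saturated pairs (argument of the log non-positive) are set to `Inf`.
#'
#' @param aln An [alignment()].
#' @return Symmetric distance matrix.
#' @export
jc_distance_matrix <- function(aln) {
  states <- .alphabets[[attr(aln, "alphabet")]]
  k <- length(states)
  m <- unclass(aln)
  idx <- matrix(match(m, states), nrow(m))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(idx[i, ]) & !is.na(idx[j, ])
    p <- mean(idx[i, ok] != idx[j, ok])
    arg <- 1 - k * p / (k - 1)
    d[i, j] <- d[j, i] <- if (arg <= 0) Inf else -(k - 1) / k * log(arg)
  }
  d
}

.quartet_patterns <- function(slots) {
  c(paste0(slots[1], ",", slots[2], "|", slots[3], ",", slots[4]),
    paste0(slots[1], ",", slots[3], "|", slots[2], ",", slots[4]),
    paste0(slots[1], ",", slots[4], "|", slots[2], ",", slots[3]))
}

#' Tally quartet groupings
#'
#' For each sampled quartet, determines the best-supported of the three
#' unrooted pairings and tallies the patterns. Distance methods
#' (`logdet_nj`, `jc_nj`) use the four-point condition (smallest sum of
#' within-pair distances); `ml_gtr` optimizes branch lengths on each of the
#' three quartet topologies under a reversible model and takes the highest
#' log-likelihood. Ties (score difference below `tie_tol`) and quartets
#' with undefined distances count as unresolved.
#'
#' @param aln An [alignment()] containing all quartet taxa.
#' @param quartets Matrix from [sample_quartets()].
#' @param method `"logdet_nj"`, `"jc_nj"` or `"ml_gtr"`.
#' @param model For `ml_gtr`: a [subst_model()] evaluated on each quartet
#'   (default: GTR with the alignment's empirical frequencies). Fitting the
#'   model once and re-using it across quartets keeps 1000-quartet tallies
#'   tractable.
#' @param tie_tol Score tolerance declaring a tie.
#' @return List (`QuartetTally`): `n_quartets`, `counts` (named, three
#'   patterns plus `unresolved`), `proportions`.
#' @export
tally_quartet_topologies <- function(aln, quartets,
                                     method = c("logdet_nj", "jc_nj", "ml_gtr"),
                                     model = NULL, tie_tol = 1e-6) {
  method <- match.arg(method)
  slots <- colnames(quartets)
  if (is.null(slots)) slots <- paste0("slot", 1:4)
  pats <- .quartet_patterns(slots)
  counts <- stats::setNames(integer(4), c(pats, "unresolved"))
  missing_tax <- setdiff(unique(as.vector(quartets)), taxa(aln))
  if (length(missing_tax))
    stop("quartet taxa absent from alignment: ",
         paste(missing_tax, collapse = ", "))
  if (method %in% c("logdet_nj", "jc_nj")) {
    used <- unique(as.vector(quartets))
    sub <- aln_subset_rows(aln, used)
    d <- if (method == "logdet_nj") logdet_distance_matrix(sub)
         else jc_distance_matrix(sub)
    for (q in seq_len(nrow(quartets))) {
      t4 <- quartets[q, ]
      if (length(unique(t4)) < 4L) { counts["unresolved"] <- counts["unresolved"] + 1L; next }
      s <- c(d[t4[1], t4[2]] + d[t4[3], t4[4]],
             d[t4[1], t4[3]] + d[t4[2], t4[4]],
             d[t4[1], t4[4]] + d[t4[2], t4[3]])
      if (any(!is.finite(s)) || sort(s)[2] - min(s) <= tie_tol) {
        counts["unresolved"] <- counts["unresolved"] + 1L
      } else {
        counts[which.min(s)] <- counts[which.min(s)] + 1L
      }
    }
  } else {
    if (is.null(model)) model <- model_gtr(attr(aln, "alphabet"),
                                           freqs = empirical_freqs(aln))
    for (q in seq_len(nrow(quartets))) {
      t4 <- quartets[q, ]
      if (length(unique(t4)) < 4L) { counts["unresolved"] <- counts["unresolved"] + 1L; next }
      sub <- aln_subset_rows(aln, t4)
      lnl <- vapply(quartet_topologies(t4), function(tr) {
        attr(optimize_branch_lengths(sub, tr, model,
                                     control = list(max_sweeps = 5L)), "lnL")
      }, 0)
      if (sort(lnl, decreasing = TRUE)[1] - sort(lnl, decreasing = TRUE)[2] <= tie_tol) {
        counts["unresolved"] <- counts["unresolved"] + 1L
      } else {
        counts[which.max(lnl)] <- counts[which.max(lnl)] + 1L
      }
    }
  }
  list(n_quartets = nrow(quartets), counts = counts,
       proportions = counts / max(nrow(quartets), 1L))
}

## the three unrooted quartet topologies on taxa t4 (star lengths 0.1)
quartet_topologies <- function(t4) {
  mk <- function(a, b, c, d)
    ape::read.tree(text = sprintf("((%s:0.1,%s:0.1):0.1,%s:0.1,%s:0.1);",
                                  a, b, c, d))
  list(mk(t4[1], t4[2], t4[3], t4[4]),
       mk(t4[1], t4[3], t4[2], t4[4]),
       mk(t4[1], t4[4], t4[2], t4[3]))
}

## row subset keeping class/attrs
aln_subset_rows <- function(aln, keep_taxa) {
  mat <- unclass(aln)[keep_taxa, , drop = FALSE]
  out <- new_alignment(mat, attr(aln, "alphabet"))
  if (inherits(aln, "mb_codon_aln")) {
    class(out) <- c("mb_codon_aln", class(out))
    attr(out, "code") <- attr(aln, "code")
  }
  out
}
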