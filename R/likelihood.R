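## ---- internal plumbing -----------------------------------------------------

## Compress alignment columns into site patterns and build tip partials.
## Gap and missing symbols marginalize (all-ones partial).
prep_lik_data <- function(aln, model) {
  states <- model$states
  if (attr(aln, "alphabet") != model$alphabet)
    stop("alignment alphabet '", attr(aln, "alphabet"),
         "' does not match model alphabet '", model$alphabet, "'")
  m <- unclass(aln)
  key <- apply(m, 2L, paste, collapse = "\r")
  upat <- match(key, unique(key))
  first <- which(!duplicated(key))
  patw <- as.numeric(table(factor(upat, levels = seq_along(first))))
  k <- length(states)
  npat <- length(first)
  tip <- array(0, c(k, npat, nrow(m)))
  idx <- matrix(match(m[, first, drop = FALSE], states), nrow(m))
  for (i in seq_len(nrow(m))) {
    p <- matrix(0, k, npat)
    known <- !is.na(idx[i, ])
    p[cbind(idx[i, known], which(known))] <- 1
    p[, !known] <- 1
    tip[, , i] <- p
  }
  list(tip = tip, patw = patw, site2pat = upat, npat = npat,
       taxa = rownames(m))
}

## Tree bookkeeping: postorder edge matrix with tips numbered to match the
## alignment's taxon order.
prep_tree <- function(tree, taxa) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo'")
  if (!setequal(tree$tip.label, taxa))
    stop("tree tips and alignment taxa differ")
  tree <- stats::reorder(tree, "postorder")
  perm <- match(tree$tip.label, taxa)  # tree tip i holds taxon perm[i]
  list(tree = tree,
       edge = matrix(as.integer(tree$edge), ncol = 2L),
       nnode = max(tree$edge),
       ntip = length(tree$tip.label),
       tipslice = perm)
}

## per-category site likelihood matrix (ncat x npat)
percat_lik <- function(prep, tp, eig, mix, tlen) {
  percat_site_lik_cpp(tp$edge, tp$ntip, tp$nnode,
                      prep$tip[, , tp$tipslice, drop = FALSE],
                      eig$lambda, eig$U, eig$Uinv, eig$bf,
                      tlen, mix$rates)
}

pattern_loglik <- function(percat, mix) {
  lik <- as.numeric(mix$weights %*% percat)
  log(pmax(lik, .Machine$double.xmin))
}

## ---- exported operations ---------------------------------------------------

#' Per-site log-likelihoods on a fixed tree
#'
#' Felsenstein-pruning likelihood of every alignment column under a
#' reversible model with an optional discrete-gamma / invariant-sites rate
#' mixture (equal category weights). Gaps and missing symbols are
#' marginalized over. These per-site vectors are the raw material of the
#' RELL-based topology tests and can be exported for external AU testing.
#'
#' @param aln An [alignment()] whose alphabet matches the model.
#' @param tree `phylo` tree whose tips are the alignment taxa; branch
#'   lengths in expected substitutions per site.
#' @param model A [subst_model()].
#' @return Numeric vector of per-site log-likelihoods with attributes
#'   `total` (their sum) and `topology_id` (a label, when the tree carries
#'   one in `tree$topology_id`).
#' @export
site_log_likelihoods <- function(aln, tree, model) {
  prep <- prep_lik_data(aln, model)
  tp <- prep_tree(tree, prep$taxa)
  eig <- model_eigen(model)
  mix <- mixture_rates(model)
  pl <- pattern_loglik(percat_lik(prep, tp, eig, mix, tp$tree$edge.length), mix)
  out <- pl[prep$site2pat]
  attr(out, "total") <- sum(pl * prep$patw)
  if (!is.null(tree$topology_id)) attr(out, "topology_id") <- tree$topology_id
  out
}

#' Total log-likelihood
#'
#' @inheritParams site_log_likelihoods
#' @return Scalar log-likelihood.
#' @export
tree_log_likelihood <- function(aln, tree, model) {
  prep <- prep_lik_data(aln, model)
  tp <- prep_tree(tree, prep$taxa)
  eig <- model_eigen(model)
  mix <- mixture_rates(model)
  sum(pattern_loglik(percat_lik(prep, tp, eig, mix, tp$tree$edge.length), mix) *
        prep$patw)
}

## objective over branch lengths given fixed model, on prepped structures
bl_objective <- function(prep, tp, eig, mix) {
  function(tlen) {
    -sum(pattern_loglik(percat_lik(prep, tp, eig, mix, tlen), mix) * prep$patw)
  }
}

.BL_MIN <- 1e-8
.BL_MAX <- 50

## one sweep of single-edge Brent updates using cached above/below arrays;
## returns updated lengths (arrays are computed once per sweep, so edges are
## optimized against the lengths current at the start of the sweep)
sweep_branch_lengths <- function(prep, tp, eig, mix, tlen) {
  arr <- edge_arrays_cpp(tp$edge, tp$ntip, tp$nnode,
                         prep$tip[, , tp$tipslice, drop = FALSE],
                         eig$lambda, eig$U, eig$Uinv, eig$bf,
                         tlen, mix$rates)
  nedge <- nrow(tp$edge)
  new <- tlen
  for (e in seq_len(nedge)) {
    ## spectral projection makes each branch-length trial a dot product
    C <- edge_spectral_coef_cpp(arr$above, arr$below, e - 1L, nedge,
                                eig$U, eig$Uinv, length(mix$rates))
    f <- function(t) -edge_loglik_spectral_cpp(C, eig$lambda, mix$rates,
                                               mix$weights, prep$patw, t)
    opt <- stats::optimize(f, c(.BL_MIN, .BL_MAX), tol = 1e-5)
    if (opt$objective < f(tlen[e])) new[e] <- opt$minimum
  }
  new
}

#' Optimize branch lengths on a fixed topology
#'
#' Scalar (Brent) optimization edge by edge with cached partial
#' likelihoods, iterated in sweeps; a sweep that fails to improve the
#' log-likelihood is rejected, so the reported log-likelihood never
#' decreases across sweeps. For small trees (at most 10 edges) a joint
#' quasi-Newton refinement is run as a final polish.
#'
#' @inheritParams site_log_likelihoods
#' @param control List: `max_sweeps` (default 20), `tol` (lnL change
#'   declaring convergence, default 1e-6), `polish` (joint refinement on
#'   small trees, default TRUE).
#' @return The tree with optimized `edge.length` and attribute `lnL`.
#' @export
optimize_branch_lengths <- function(aln, tree, model, control = list()) {
  ctl <- utils::modifyList(list(max_sweeps = 20L, tol = 1e-6, polish = TRUE),
                           control)
  prep <- prep_lik_data(aln, model)
  tp <- prep_tree(tree, prep$taxa)
  eig <- model_eigen(model)
  mix <- mixture_rates(model)
  obj <- bl_objective(prep, tp, eig, mix)
  tlen <- pmin(pmax(tp$tree$edge.length, .BL_MIN), .BL_MAX)
  cur <- -obj(tlen)
  for (s in seq_len(ctl$max_sweeps)) {
    cand <- sweep_branch_lengths(prep, tp, eig, mix, tlen)
    lnl <- -obj(cand)
    if (lnl < cur) break         # stale-array sweep failed to improve: stop
    improved <- lnl - cur
    tlen <- cand
    cur <- lnl
    if (improved < ctl$tol) break
  }
  if (ctl$polish && nrow(tp$edge) <= 10L) {
    fit <- stats::nlminb(tlen, obj, lower = .BL_MIN, upper = .BL_MAX,
                         control = list(rel.tol = 1e-12))
    if (-fit$objective >= cur) {
      tlen <- fit$par
      cur <- -fit$objective
    }
  }
  out <- tp$tree
  out$edge.length <- tlen
  attr(out, "lnL") <- cur
  out
}

## parse a model-family string like "GTR+G+I+F" / "JTT+G+F"
parse_family <- function(family) {
  parts <- strsplit(family, "+", fixed = TRUE)[[1]]
  base <- parts[1]
  if (!base %in% c("GTR", "JTT")) stop("unknown model family: ", family)
  list(base = base,
       gamma = "G" %in% parts,
       inv = "I" %in% parts,
       empfreq = "F" %in% parts)
}

#' Fit a substitution model on a fixed topology
#'
#' Maximum-likelihood estimation of the free parameters of a model family
#' (`"GTR[+G][+I][+F]"` on nucleotide or recoded alphabets,
#' `"JTT[+G][+I][+F]"` on amino acids) together with the branch lengths.
#' GTR exchangeabilities are estimated (last one fixed at 1); JTT
#' exchangeabilities are fixed at their published values. `+F` uses the
#' empirical state frequencies of the alignment; plain GTR also uses
#' empirical frequencies (composition is not optimized). Estimation
#' alternates branch-length sweeps with bounded quasi-Newton steps on the
#' substitution parameters.
#'
#' @inheritParams site_log_likelihoods
#' @param family Model-family string.
#' @param ncat Gamma categories when `+G` (default 5).
#' @param control Passed to [optimize_branch_lengths()]; `outer` sets the
#'   number of alternation rounds (default 4).
#' @return List with `model`, `tree` (optimized lengths), `lnL`, `n_par`,
#'   `aic`, `bic`.
#' @export
fit_model <- function(aln, tree, family = "GTR+G+F", ncat = 5L, control = list()) {
  fam <- parse_family(family)
  outer <- if (is.null(control$outer)) 4L else control$outer
  alphabet <- attr(aln, "alphabet")
  if (fam$base == "JTT" && alphabet != "aa20")
    stop("JTT applies to aa20 alignments")
  freqs <- if (fam$base == "GTR" || fam$empfreq) empirical_freqs(aln)
           else stats::setNames(.jtt_freqs, .alphabets$aa20)
  k <- length(alphabet_states(alphabet))
  n_exch <- k * (k - 1) / 2
  ## free parameters: log-exchangeabilities (GTR, last fixed), log shape,
  ## logit p_inv
  par <- c(if (fam$base == "GTR") rep(0, n_exch - 1L),
           if (fam$gamma) log(1),
           if (fam$inv) stats::qlogis(0.1))
  build <- function(par) {
    i <- 0L
    if (fam$base == "GTR") {
      exch <- c(exp(par[seq_len(n_exch - 1L)]), 1)
      i <- n_exch - 1L
    } else {
      exch <- .jtt_exchangeabilities
    }
    if (fam$gamma) { i <- i + 1L; shape <- exp(par[i]) } else shape <- NULL
    if (fam$inv) { i <- i + 1L; p_inv <- stats::plogis(par[i]) } else p_inv <- 0
    subst_model(alphabet, exch, freqs, shape = shape, ncat = ncat,
                p_inv = p_inv)
  }
  cur_tree <- tree
  model <- build(par)
  prep <- prep_lik_data(aln, model)
  lnl <- -Inf
  for (round in seq_len(outer)) {
    cur_tree <- optimize_branch_lengths(aln, cur_tree, model, control)
    if (length(par)) {
      tp <- prep_tree(cur_tree, prep$taxa)
      obj <- function(p) {
        m <- build(p)
        eig <- model_eigen(m)
        mix <- mixture_rates(m)
        -sum(pattern_loglik(percat_lik(prep, tp, eig, mix,
                                       tp$tree$edge.length), mix) * prep$patw)
      }
      fit <- stats::nlminb(par, obj, lower = -12, upper = 12)
      par <- fit$par
      model <- build(par)
    }
    new_lnl <- tree_log_likelihood(aln, cur_tree, model)
    if (new_lnl - lnl < if (is.null(control$tol)) 1e-4 else control$tol) {
      lnl <- max(lnl, new_lnl)
      break
    }
    lnl <- new_lnl
  }
  n_par <- length(par) + length(cur_tree$edge.length) + (k - 1)  # + freqs
  n <- n_col(aln)
  list(model = model, tree = cur_tree, lnL = lnl, n_par = n_par,
       aic = -2 * lnl + 2 * n_par, bic = -2 * lnl + log(n) * n_par,
       family = family)
}

#' Compare model families by information criteria
#'
#' @inheritParams fit_model
#' @param families Character vector of model-family strings.
#' @return `data.frame` with `family`, `lnL`, `n_par`, `aic`, `bic`, sorted
#'   by BIC.
#' @export
compare_models <- function(aln, tree, families, ncat = 5L, control = list()) {
  rows <- lapply(families, function(f) {
    fit <- fit_model(aln, tree, f, ncat = ncat, control = control)
    data.frame(family = f, lnL = fit$lnL, n_par = fit$n_par,
               aic = fit$aic, bic = fit$bic)
  })
  out <- do.call(rbind, rows)
  out[order(out$bic), ]
}

#' Posterior mean relative site rates
#'
#' For each site, the posterior mean of the relative rate over the model's
#' rate mixture, `ER_s = sum_c r_c P(c | site)` with
#' `P(c | s) proportional to w_c L_s(r_c)`, normalized so the mean over
#' sites is 1. Sites with no informative data (all gaps/missing) are
#' flagged in attribute `"uninformative_sites"`.
#'
#' @inheritParams site_log_likelihoods
#' @return Numeric vector of per-site rates (`SiteRates`), mean 1.
#' @export
posterior_site_rates <- function(aln, tree, model) {
  prep <- prep_lik_data(aln, model)
  tp <- prep_tree(tree, prep$taxa)
  eig <- model_eigen(model)
  mix <- mixture_rates(model)
  percat <- percat_lik(prep, tp, eig, mix, tp$tree$edge.length)
  wlik <- percat * mix$weights
  er_pat <- as.numeric(mix$rates %*% wlik) / pmax(colSums(wlik),
                                                  .Machine$double.xmin)
  er <- er_pat[prep$site2pat]
  er <- er / mean(er)
  blank <- which(colSums(is_gapmiss(aln)) == n_taxa(aln))
  if (length(blank)) attr(er, "uninformative_sites") <- blank
  er
}

#' Exclude fast-evolving sites
#'
#' Removes sites whose posterior mean relative rate strictly exceeds
#' `threshold` (sites with rate > 1 evolve faster than average; the
#' conventional cuts are > 2.99, > 1.99 and > 1.49).
#'
#' @param aln An [alignment()].
#' @param site_rates Vector from [posterior_site_rates()] (same length as
#'   the alignment).
#' @param threshold Strict upper bound on the retained sites' rates.
#' @return Filtered alignment with attribute `fraction_excluded`.
#' @export
exclude_fast_sites <- function(aln, site_rates, threshold) {
  stopifnot(length(site_rates) == n_col(aln), threshold > 0)
  keep <- !(site_rates > threshold)
  out <- aln_subset_cols(aln, keep)
  attr(out, "fraction_excluded") <- mean(!keep)
  out
}

## ---- NNI search ------------------------------------------------------------

## the two NNI rearrangements around internal edge (u, v) of a rooted-at-
## internal-node phylo; returns list of modified trees (edge matrices
## re-expressed via read.tree for safety)
nni_neighbors_edge <- function(tree, eidx) {
  edge <- tree$edge
  u <- edge[eidx, 1]; v <- edge[eidx, 2]
  ntip <- length(tree$tip.label)
  if (v <= ntip) return(list())
  kids_v <- which(edge[, 1] == v)
  sibs <- setdiff(which(edge[, 1] == u), eidx)
  if (length(sibs) == 0L || length(kids_v) < 2L) return(list())
  s <- sibs[1]
  lapply(kids_v[1:2], function(cv) {
    e2 <- edge
    e2[s, 2] <- edge[cv, 2]
    e2[cv, 2] <- edge[s, 2]
    t2 <- tree
    t2$edge <- e2
    stats::reorder(ape::reorder.phylo(t2, "cladewise"), "postorder")
  })
}

#' Greedy NNI topology search
#'
#' Hill-climbing over nearest-neighbor interchanges with branch-length
#' re-optimization of each candidate, stopping when no rearrangement
#' improves the log-likelihood by more than `tol`. Intended for the small
#' (tens of taxa) synthetic and diagnostic datasets this package targets;
#' large production searches belong in dedicated ML software.
#'
#' @inheritParams site_log_likelihoods
#' @param start_tree Starting topology; default is NJ on LogDet distances.
#' @param tol Minimum lnL improvement to accept a rearrangement
#'   (default 1e-4).
#' @param control Passed to [optimize_branch_lengths()].
#' @return List with `tree` (optimized) and `lnL`.
#' @export
nni_search <- function(aln, model, start_tree = NULL, tol = 1e-4,
                       control = list()) {
  if (is.null(start_tree)) {
    d <- logdet_distance_matrix(aln)
    if (any(!is.finite(d))) d[!is.finite(d)] <- max(d[is.finite(d)]) * 2
    start_tree <- neighbor_joining(d)
  }
  if (is.null(start_tree$edge.length))
    start_tree$edge.length <- rep(0.1, nrow(start_tree$edge))
  cur <- optimize_branch_lengths(aln, start_tree, model, control)
  cur_lnl <- attr(cur, "lnL")
  repeat {
    best <- NULL
    best_lnl <- cur_lnl
    ntip <- length(cur$tip.label)
    internal <- which(cur$edge[, 2] > ntip)
    for (e in internal) {
      for (cand in nni_neighbors_edge(cur, e)) {
        fit <- try(optimize_branch_lengths(aln, cand, model, control),
                   silent = TRUE)
        if (inherits(fit, "try-error")) next
        if (attr(fit, "lnL") > best_lnl + tol) {
          best <- fit
          best_lnl <- attr(fit, "lnL")
        }
      }
    }
    if (is.null(best)) break
    cur <- best
    cur_lnl <- best_lnl
  }
  list(tree = cur, lnL = cur_lnl)
}
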