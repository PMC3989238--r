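## run expr with a local, restored RNG state seeded deterministically
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Unconstrained (multinomial) log-likelihood
#'
#' The best possible likelihood of an alignment under any model: the
#' product of observed site-pattern frequencies,
#' `lnL = sum_p n_p log(n_p / N)`. Serves as the reference point of the
#' Goldman goodness-of-fit test; no phylogenetic model can exceed it.
#'
#' @param aln An [alignment()].
#' @return Scalar log-likelihood (non-positive).
#' @export
unconstrained_log_likelihood <- function(aln) {
  stopifnot(n_col(aln) > 0L)
  key <- apply(unclass(aln), 2L, paste, collapse = "\r")
  n_p <- table(key)
  sum(n_p * log(n_p / length(key)))
}

#' RELL bootstrap of per-site log-likelihoods
#'
#' Resamples site indices with replacement and accumulates per-topology
#' totals of the resampled per-site log-likelihoods (the RELL
#' approximation: no refitting).
#'
#' @param site_lnl Matrix of per-site log-likelihoods, one row per topology
#'   (equal site counts), rownames used as topology ids.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed (replicates are reproducible bit for bit).
#' @return `B x n_topologies` matrix of replicate totals.
#' @export
rell_bootstrap <- function(site_lnl, B, seed) {
  site_lnl <- rbind(site_lnl)
  n <- ncol(site_lnl)
  with_seed(seed, {
    out <- matrix(0, B, nrow(site_lnl),
                  dimnames = list(NULL, rownames(site_lnl)))
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      out[b, ] <- rowSums(site_lnl[, idx, drop = FALSE])
    }
    out
  })
}

#' Kishino-Hasegawa test (RELL)
#'
#' KH test of equal expected log-likelihood of two topologies: the observed
#' total difference is compared with the centered RELL bootstrap
#' distribution of the difference. The default is the classical two-sided
#' test; `alternative = "greater"` gives the one-sided p that topology B
#' beats topology A, which is the quantity the SH test bounds from above
#' (for two candidates SH reduces exactly to this one-sided comparison for
#' the non-ML topology).
#'
#' @param site_lnl_a,site_lnl_b Per-site log-likelihood vectors of the two
#'   topologies on the same alignment.
#' @param B Bootstrap replicates (default 10000).
#' @param seed Integer seed.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return List with `delta` (total A minus total B) and `p`.
#' @export
kh_test <- function(site_lnl_a, site_lnl_b, B = 10000L, seed = 1L,
                    alternative = c("two.sided", "greater")) {
  stopifnot(length(site_lnl_a) == length(site_lnl_b))
  alternative <- match.arg(alternative)
  d <- site_lnl_a - site_lnl_b
  delta <- sum(d)
  reps <- rell_bootstrap(matrix(d, nrow = 1), B, seed)[, 1]
  centered <- reps - mean(reps)
  p <- if (alternative == "two.sided") mean(abs(centered) >= abs(delta))
       else mean(centered >= delta)
  list(delta = delta, p = p)
}

#' Shimodaira-Hasegawa test (RELL)
#'
#' Standard SH test over a candidate set of topologies: replicate totals
#' are centered per topology, each replicate's best-minus-self difference
#' forms the null distribution, and each topology's observed best-minus-self
#' difference is referred to it. The maximum-likelihood topology always
#' receives the largest p-value; the test is conservative relative to KH.
#'
#' @param site_lnl Matrix of per-site log-likelihoods, one row per topology.
#' @param B Bootstrap replicates (default 10000).
#' @param seed Integer seed.
#' @return Named numeric vector of p-values, one per topology.
#' @export
sh_test <- function(site_lnl, B = 10000L, seed = 1L) {
  site_lnl <- rbind(site_lnl)
  stopifnot(nrow(site_lnl) >= 2L)
  totals <- rowSums(site_lnl)
  obs <- max(totals) - totals
  reps <- rell_bootstrap(site_lnl, B, seed)
  centered <- sweep(reps, 2L, colMeans(reps))
  dstat <- apply(centered, 1L, max) - centered
  p <- vapply(seq_along(totals), function(i) mean(dstat[, i] >= obs[i]), 0)
  names(p) <- rownames(site_lnl)
  p
}

#' Simulate an alignment under a fitted model on a tree
#'
#' Stationary simulation used by the Goldman parametric bootstrap and for
#' calibration experiments: site rates are drawn from the model's rate
#' mixture, the root state from the equilibrium frequencies, and states are
#' propagated along the tree with the model's transition matrices.
#'
#' @param tree `phylo` with branch lengths.
#' @param model A [subst_model()].
#' @param nsites Number of sites.
#' @param seed Integer seed.
#' @return An [alignment()] on the model's alphabet.
#' @export
simulate_sites <- function(tree, model, nsites, seed) {
  tp <- prep_tree(tree, tree$tip.label)
  mix <- mixture_rates(model)
  eig <- model_eigen(model)
  k <- model$k
  with_seed(seed, {
    cat_of_site <- sample.int(length(mix$rates), nsites, replace = TRUE,
                              prob = mix$weights)
    state <- matrix(0L, tp$nnode, nsites)
    root <- tp$edge[nrow(tp$edge), 1]
    state[root, ] <- sample.int(k, nsites, replace = TRUE, prob = model$freqs)
    for (e in rev(seq_len(nrow(tp$edge)))) {  # preorder
      u <- tp$edge[e, 1]; v <- tp$edge[e, 2]
      t_e <- tp$tree$edge.length[e]
      for (c in seq_along(mix$rates)) {
        sites <- which(cat_of_site == c)
        if (!length(sites)) next
        if (mix$rates[c] * t_e <= 0) {
          state[v, sites] <- state[u, sites]
        } else {
          P <- eig$U %*% diag(exp(eig$lambda * t_e * mix$rates[c])) %*% eig$Uinv
          P[P < 0] <- 0
          P <- P / rowSums(P)
          cp <- t(apply(P, 1L, cumsum))
          u01 <- stats::runif(length(sites))
          state[v, sites] <- 1L + rowSums(cp[state[u, sites], , drop = FALSE] <
                                            u01)
        }
      }
    }
    m <- matrix(model$states[state[seq_len(tp$ntip), , drop = FALSE]],
                nrow = tp$ntip,
                dimnames = list(tp$tree$tip.label, NULL))
    alignment(m, model$alphabet)
  })
}

#' Goldman (Cox) goodness-of-fit test
#'
#' Compares the fitted model's likelihood against the unconstrained
#' multinomial likelihood by parametric bootstrap: the observed deficit
#' `delta = lnL_unconstrained - lnL_model` is referred to the distribution
#' of the same deficit over datasets simulated under the fitted
#' (tree, model), each re-fitted before its deficit is measured. Refitting
#' re-estimates branch lengths and, by default, the gamma shape, holding
#' the topology and the remaining substitution parameters fixed. The
#' p-value uses the add-one convention `p = (1 + #{delta* >= delta}) /
#' (n_sim + 1)`, so it can never be exactly zero.
#'
#' @inheritParams site_log_likelihoods
#' @param n_sim Monte Carlo replicates (default 200).
#' @param seed Integer seed; replicate seeds are derived by fixed offsets.
#' @param refit `"bl_shape"` (default) or `"bl"`: whether each replicate
#'   refit re-estimates the gamma shape alongside the branch lengths.
#' @param optimize_observed Refit the observed data too before measuring
#'   `delta` (default TRUE; set FALSE when `tree`/`model` are already ML
#'   fits for this alignment).
#' @return List (`GoldmanResult`): `delta`, `delta_sim`, `p`, `n_sim`,
#'   `seed`.
#' @export
goldman_test <- function(aln, tree, model, n_sim = 200L, seed = 1L,
                         refit = c("bl_shape", "bl"),
                         optimize_observed = TRUE) {
  refit <- match.arg(refit)
  ## joint quasi-Newton refit of branch lengths (+ shape) on the compressed
  ## patterns; the workhorse for the parametric bootstrap on small trees
  refit_small <- function(a, tr, m) {
    prep <- prep_lik_data(a, m)
    tp <- prep_tree(tr, prep$taxa)
    nedge <- nrow(tp$edge)
    with_shape <- refit == "bl_shape" && !is.null(m$shape)
    ## invariants across all evaluations: eigen system, permuted tip cube
    eig <- model_eigen(m)
    tipcube <- prep$tip[, , tp$tipslice, drop = FALSE]
    obj <- function(par) {
      m2 <- m
      if (with_shape) m2$shape <- exp(par[nedge + 1L])
      mix <- mixture_rates(m2)
      percat <- percat_site_lik_cpp(tp$edge, tp$ntip, tp$nnode, tipcube,
                                    eig$lambda, eig$U, eig$Uinv, eig$bf,
                                    par[seq_len(nedge)], mix$rates)
      -sum(pattern_loglik(percat, mix) * prep$patw)
    }
    par0 <- c(pmin(pmax(tp$tree$edge.length, 1e-4), 5),
              if (with_shape) log(m$shape))
    fit <- stats::nlminb(par0, obj,
                         lower = c(rep(.BL_MIN, nedge),
                                   if (with_shape) log(0.05)),
                         upper = c(rep(.BL_MAX, nedge),
                                   if (with_shape) log(50)),
                         control = list(rel.tol = 1e-7, iter.max = 120L,
                                        eval.max = 500L))
    out <- tp$tree
    out$edge.length <- fit$par[seq_len(nedge)]
    m2 <- m
    if (with_shape) m2$shape <- exp(fit$par[nedge + 1L])
    list(tree = out, model = m2, lnL = -fit$objective)
  }
  refit_fun <- function(a, tr, m) {
    if (nrow(tr$edge) <= 9L) return(refit_small(a, tr, m))
    if (refit == "bl_shape" && !is.null(m$shape)) {
      prep <- prep_lik_data(a, m)
      cur <- tr
      cur_m <- m
      for (round in 1:2) {
        cur <- optimize_branch_lengths(a, cur, cur_m,
                                       control = list(max_sweeps = 8L))
        tp2 <- prep_tree(cur, prep$taxa)
        sobj <- function(ls) {
          m2 <- cur_m; m2$shape <- exp(ls)
          eig <- model_eigen(m2); mix <- mixture_rates(m2)
          -sum(pattern_loglik(percat_lik(prep, tp2, eig, mix,
                                         tp2$tree$edge.length), mix) *
                 prep$patw)
        }
        opt <- stats::optimize(sobj, c(log(0.05), log(50)), tol = 1e-4)
        cur_m$shape <- exp(opt$minimum)
      }
      cur <- optimize_branch_lengths(a, cur, cur_m,
                                     control = list(max_sweeps = 8L))
      list(tree = cur, model = cur_m, lnL = attr(cur, "lnL"))
    } else {
      cur <- optimize_branch_lengths(a, tr, m)
      list(tree = cur, model = m, lnL = attr(cur, "lnL"))
    }
  }
  obs <- if (optimize_observed) refit_fun(aln, tree, model)
         else list(tree = tree, model = model,
                   lnL = tree_log_likelihood(aln, tree, model))
  delta_obs <- unconstrained_log_likelihood(aln) - obs$lnL
  nsites <- n_col(aln)
  delta_sim <- numeric(n_sim)
  for (b in seq_len(n_sim)) {
    sim <- simulate_sites(obs$tree, obs$model, nsites, seed = seed + 1000L + b)
    ## a simulated dataset is never empty here, but guard against an
    ## alignment-wide invariant draw making refitting degenerate
    fit <- refit_fun(sim, obs$tree, obs$model)
    delta_sim[b] <- unconstrained_log_likelihood(sim) - fit$lnL
  }
  list(delta = delta_obs, delta_sim = delta_sim,
       p = (1 + sum(delta_sim >= delta_obs)) / (n_sim + 1),
       n_sim = n_sim, seed = seed)
}

#' Write / read site log-likelihoods in Consel-style text
#'
#' Plain-text matrix (topologies x sites) with a `ntopo nsite` header line,
#' as consumed by external AU-test software.
#'
#' @param site_lnl Matrix, one row per topology.
#' @param path File path.
#' @return `path` invisibly; the reader returns the matrix.
#' @export
write_site_lnl <- function(site_lnl, path) {
  site_lnl <- rbind(site_lnl)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(site_lnl), ncol(site_lnl)), con)
  ids <- rownames(site_lnl)
  if (is.null(ids)) ids <- paste0("topology", seq_len(nrow(site_lnl)))
  for (i in seq_len(nrow(site_lnl)))
    writeLines(paste(ids[i],
                     paste(sprintf("%.6f", site_lnl[i, ]), collapse = " ")),
               con)
  invisible(path)
}

#' @rdname write_site_lnl
#' @export
read_site_lnl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- scan(text = lines[1], what = integer(), n = 2L, quiet = TRUE)
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  out <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(hdr[2])))
  rownames(out) <- vapply(rows, `[`, "", 1L)
  out
}
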