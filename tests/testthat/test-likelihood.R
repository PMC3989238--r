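## small random tree with branch lengths, reproducible
rand_tree <- function(ntip, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(ntip))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.6)
  tr
}

test_that("pruning equals internal-state enumeration on every alphabet", {
  cases <- list(
    list(alphabet = "nt4",  model = model_gtr("nt4", c(1, 3, 1, 1, 3, 1),
                                              freqs = c(A = .35, C = .15, G = .2, T = .3),
                                              shape = 0.6, ncat = 5)),
    list(alphabet = "RY2",  model = model_gtr("RY2", freqs = c(R = .45, Y = .55),
                                              shape = 1.2, ncat = 5)),
    list(alphabet = "aa4",  model = model_gtr("aa4", freqs = c(A = .4, T = .3, G = .2, C = .1))),
    list(alphabet = "aa6",  model = model_gtr("aa6", shape = 0.9, ncat = 5, p_inv = 0.15)),
    list(alphabet = "aa20", model = model_jtt(shape = 0.8, ncat = 5))
  )
  seeds <- c(nt4 = 1, RY2 = 2, aa4 = 3, aa6 = 4, aa20 = 5)
  for (cs in cases) {
    ntip <- if (cs$alphabet == "aa20") 4L else 5L
    tr <- rand_tree(ntip, seed = seeds[[cs$alphabet]])
    aln <- random_alignment(ntip, 6, cs$alphabet,
                            seed = 100 + nchar(cs$alphabet), gap_prob = 0.12)
    rownames(aln) <- tr$tip.label
    got <- site_log_likelihoods(aln, tr, cs$model)
    want <- enumeration_site_loglik(aln, tr, cs$model)
    expect_equal(as.numeric(got), want, tolerance = 1e-8,
                 label = paste("site lnL,", cs$alphabet))
  }
})

test_that("degenerate and limiting cases have closed forms", {
  m <- model_gtr("nt4", freqs = c(A = .4, C = .1, G = .2, T = .3))
  ## zero-length branch, identical symbols: lnL = ln pi(symbol)
  tr <- ape::read.tree(text = "(a:0,b:0);")
  aln <- alignment(c(a = "G", b = "G"), "nt4")
  expect_equal(as.numeric(site_log_likelihoods(aln, tr, m)), log(0.2),
               tolerance = 1e-10)
  ## very long branches: independence, lnL -> sum of ln pi over leaves
  tr2 <- ape::read.tree(text = "(a:40,b:40);")
  aln2 <- alignment(c(a = "A", b = "T"), "nt4")
  expect_equal(as.numeric(site_log_likelihoods(aln2, tr2, m)),
               log(0.4) + log(0.3), tolerance = 1e-6)
})

test_that("lnL is invariant to taxon order and rerooting", {
  tr <- rand_tree(6, seed = 11)
  m <- model_gtr("nt4", shape = 0.7)
  aln <- simulate_sites(tr, m, 80, seed = 4)
  l0 <- attr(site_log_likelihoods(aln, tr, m), "total")
  perm <- mitobias:::aln_subset_rows(aln, rev(taxa(aln)))
  expect_equal(attr(site_log_likelihoods(perm, tr, m), "total"), l0,
               tolerance = 1e-9)
  rr <- ape::root(tr, outgroup = tr$tip.label[3], resolve.root = TRUE)
  expect_equal(attr(site_log_likelihoods(aln, rr, m), "total"), l0,
               tolerance = 1e-6)
})

test_that("gamma mixture converges to homogeneous rates as shape grows", {
  tr <- rand_tree(5, seed = 2)
  aln <- random_alignment(5, 40, "nt4", seed = 5)
  rownames(aln) <- tr$tip.label
  m_hom <- model_gtr("nt4")
  m_big <- model_gtr("nt4", shape = 5000, ncat = 5)
  expect_equal(attr(site_log_likelihoods(aln, tr, m_big), "total"),
               attr(site_log_likelihoods(aln, tr, m_hom), "total"),
               tolerance = 1e-4)
  ## discrete-gamma categories always average to 1
  for (a in c(0.1, 0.5, 1, 3)) {
    expect_equal(mean(discrete_gamma(a, 5)), 1, tolerance = 1e-9)
  }
})

test_that("engine agrees with an independent ML implementation", {
  tr <- rand_tree(6, seed = 9)
  m <- model_gtr("nt4", c(1.3, 3.2, 0.8, 1.1, 4.0, 1),
                 freqs = c(A = .31, C = .18, G = .22, T = .29),
                 shape = 0.75, ncat = 4)
  aln <- simulate_sites(tr, m, 200, seed = 8)
  pd <- phangorn::phyDat(unclass(aln), type = "DNA")
  fit <- phangorn::pml(tr, pd, bf = as.numeric(m$freqs),
                       Q = m$S[upper.tri(m$S)][order(row(m$S)[upper.tri(m$S)],
                                                     col(m$S)[upper.tri(m$S)])],
                       shape = m$shape, k = 4L)
  expect_equal(attr(site_log_likelihoods(aln, tr, m), "total"),
               as.numeric(stats::logLik(fit)), tolerance = 1e-4)
})

test_that("branch-length optimization never decreases lnL and recovers lengths", {
  tr <- rand_tree(5, seed = 21)
  m <- model_gtr("nt4", shape = 1)
  aln <- simulate_sites(tr, m, 4000, seed = 3)
  start <- tr
  start$edge.length <- rep(0.2, nrow(tr$edge))
  l_start <- tree_log_likelihood(aln, start, m)
  fit <- optimize_branch_lengths(aln, start, m)
  expect_gte(attr(fit, "lnL"), l_start)
  ## recovered lengths close to truth at 4000 sites
  ord <- match(apply(stats::reorder(tr, "postorder")$edge, 1, paste, collapse = "-"),
               apply(fit$edge, 1, paste, collapse = "-"))
  expect_equal(fit$edge.length[ord],
               stats::reorder(tr, "postorder")$edge.length,
               tolerance = 0.25)
  ## zero-variation alignment drives lengths to the lower bound
  con <- alignment(setNames(rep(strrep("A", 30), 5), tr$tip.label), "nt4")
  fit0 <- optimize_branch_lengths(con, tr, m)
  expect_true(all(fit0$edge.length < 1e-5))
})

test_that("GTR fitting recovers generating parameters from large data", {
  tr <- rand_tree(4, seed = 31)
  true_exch <- c(1.5, 4, 0.7, 1.2, 5, 1)
  m <- model_gtr("nt4", true_exch, freqs = c(A = .3, C = .2, G = .2, T = .3),
                 shape = 0.5, ncat = 5)
  aln <- simulate_sites(tr, m, 10000, seed = 12)
  fit <- fit_model(aln, tr, "GTR+G+F", ncat = 5)
  got <- fit$model$S[upper.tri(fit$model$S)][c(1, 2, 4, 3, 5, 6)]
  ## normalize both to GT = 1 and compare relative rates
  got_exch <- got / got[6]
  expect_equal(got_exch, true_exch, tolerance = 0.15)
  expect_equal(fit$model$shape, 0.5, tolerance = 0.2)
  ## lnL at fitted parameters at least matches the generating model's
  expect_gte(fit$lnL, tree_log_likelihood(aln, fit$tree, m) - 1)
})

test_that("model comparison prefers the parsimonious truth by BIC", {
  tr <- rand_tree(4, seed = 41)
  m <- model_gtr("nt4", freqs = c(A = .3, C = .2, G = .2, T = .3))
  aln <- simulate_sites(tr, m, 3000, seed = 13)
  cmp <- compare_models(aln, tr, c("GTR+F", "GTR+G+I+F"))
  expect_lte(cmp$bic[cmp$family == "GTR+F"],
             cmp$bic[cmp$family == "GTR+G+I+F"])
})

test_that("RY data fit uses the two-state model end to end", {
  tr <- rand_tree(5, seed = 51)
  nt <- simulate_sites(tr, model_gtr("nt4", shape = 1), 300, seed = 14)
  ry <- ry_recode(nt)
  m2 <- model_gtr("RY2", freqs = empirical_freqs(ry), shape = 1)
  l <- site_log_likelihoods(ry, tr, m2)
  expect_length(l, 300)
  expect_true(is.finite(attr(l, "total")))
})
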