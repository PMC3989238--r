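test_that("unconstrained lnL follows the pattern-frequency formula", {
  ## all sites share one pattern -> 0
  aln <- alignment(c(a = "AAAA", b = "CCCC"), "nt4")
  expect_equal(unconstrained_log_likelihood(aln), 0)
  ## pattern counts (3, 1): 3 ln(3/4) + ln(1/4)
  aln2 <- alignment(c(a = "AAAC", b = "CCCA"), "nt4")
  expect_equal(unconstrained_log_likelihood(aln2), 3 * log(3 / 4) + log(1 / 4))
  ## all distinct -> N ln(1/N)
  aln3 <- alignment(c(a = "ACGT", b = "AAAA"), "nt4")
  expect_equal(unconstrained_log_likelihood(aln3), 4 * log(1 / 4))
})

test_that("unconstrained lnL bounds the model lnL on random fixtures", {
  m <- model_gtr("nt4", shape = 0.9)
  for (seed in 1:20) {
    set.seed(seed)
    ntip <- sample(4:6, 1)
    tr <- ape::unroot(ape::rtree(ntip))
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.01, 1)
    aln <- simulate_sites(tr, m, sample(c(30, 100), 1), seed = seed + 500)
    fit <- optimize_branch_lengths(aln, tr, m)
    expect_gte(unconstrained_log_likelihood(aln) - attr(fit, "lnL"), -1e-6)
  }
})

test_that("RELL machinery is seeded and conserves totals", {
  set.seed(3)
  sl <- matrix(rnorm(3 * 200, -2), 3, 200,
               dimnames = list(c("t1", "t2", "t3"), NULL))
  r1 <- rell_bootstrap(sl, 50, seed = 9)
  r2 <- rell_bootstrap(sl, 50, seed = 9)
  expect_identical(r1, r2)
  ## replicate mean approximates the original totals
  expect_equal(colMeans(rell_bootstrap(sl, 4000, seed = 1)), rowSums(sl),
               tolerance = 0.02)
})

test_that("KH test behaves at the fixed points and under separation", {
  a <- rnorm(150, -3)
  expect_equal(kh_test(a, a, B = 500, seed = 1)$p, 1)
  ## constant per-site advantage: p -> 0
  kh <- kh_test(a + 0.5, a, B = 2000, seed = 2)
  expect_lt(kh$p, 0.01)
  expect_equal(kh$delta, 0.5 * 150, tolerance = 1e-9)
  ## invariant to site order
  perm <- sample(seq_along(a))
  expect_equal(kh_test(a[perm], (a - 0.2)[perm], B = 1000, seed = 5)$p,
               kh_test(a, a - 0.2, B = 1000, seed = 5)$p)
  ## bit-reproducible
  expect_identical(kh_test(a, a - 0.1, B = 1000, seed = 7),
                   kh_test(a, a - 0.1, B = 1000, seed = 7))
})

test_that("SH test is conservative, centred and gives the ML topology max p", {
  set.seed(11)
  base <- rnorm(300, -2.5)
  sl <- rbind(t1 = base + rnorm(300, 0.02),
              t2 = base,
              t3 = base - rnorm(300, 0.03, 0.1))
  p <- sh_test(sl, B = 3000, seed = 4)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(unname(which.max(rowSums(sl))), unname(which.max(p)))
  ## duplicate topologies receive equal p
  sl2 <- rbind(a = base, b = base, c = base - 0.05)
  p2 <- sh_test(sl2, B = 2000, seed = 6)
  expect_equal(unname(p2["a"]), unname(p2["b"]))
  ## all-equal vectors give p = 1 everywhere
  expect_true(all(sh_test(rbind(base, base), B = 500, seed = 8) == 1))
  ## SH bounds the one-sided pairwise comparison from above: for two
  ## candidates, SH's p for the non-ML topology equals the one-sided KH p
  pk <- kh_test(sl["t1", ], sl["t3", ], B = 3000, seed = 12,
                alternative = "greater")$p
  ps <- sh_test(sl[c("t1", "t3"), ], B = 3000, seed = 12)
  expect_gte(ps["t3"] + 0.02, pk)
})

test_that("Goldman delta is non-negative, order-invariant, never p = 0", {
  tr <- ape::unroot(ape::rtree(4))
  tr$edge.length <- rep(0.25, nrow(tr$edge))
  m <- model_gtr("nt4", shape = 1, ncat = 4)
  aln <- simulate_sites(tr, m, 150, seed = 21)
  g <- goldman_test(aln, tr, m, n_sim = 30, seed = 5)
  expect_gte(g$delta, -1e-6)
  expect_gt(g$p, 0)
  expect_lte(g$p, 1)
  ## add-one convention: smallest possible p is 1/(n_sim + 1)
  expect_gte(g$p, 1 / 31)
  ## delta invariant to site order
  perm <- mitobias:::aln_subset_cols(aln, sample(n_col(aln)))
  g2 <- goldman_test(perm, tr, m, n_sim = 5, seed = 5)
  expect_equal(g2$delta, g$delta, tolerance = 1e-4)
})

test_that("Goldman test rejects for data the model cannot fit", {
  ## data from a 2-clade compositional shift, fitted with a stationary GTR:
  ## the deficit should be extreme relative to the null simulations
  cfg <- preset_robust_like(n_per_group = c(robust = 1L, complex = 1L,
                                            corallimorph = 1L, outgroup = 1L),
                            n_codons = 400, seed = 31)
  sim <- simulate_alignment(cfg)
  tr <- sim$tree
  m <- model_gtr("nt4", freqs = empirical_freqs(sim$alignment), shape = 1)
  g <- goldman_test(sim$alignment, tr, m, n_sim = 40, seed = 6)
  expect_lte(g$p, 0.05)
})

test_that("site-lnL text round-trips for external topology testing", {
  sl <- matrix(round(rnorm(2 * 40, -3), 4), 2, 40,
               dimnames = list(c("sm", "nc"), NULL))
  f <- withr::local_tempfile(fileext = ".mt")
  write_site_lnl(sl, f)
  back <- read_site_lnl(f)
  expect_equal(back, sl, tolerance = 1e-6)
  expect_identical(rownames(back), c("sm", "nc"))
})
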