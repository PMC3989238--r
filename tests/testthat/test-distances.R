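test_that("BF distance is the half-L1 metric on frequency vectors", {
  f <- c(A = .4, C = .3, G = .2, T = .1)
  u <- c(A = .25, C = .25, G = .25, T = .25)
  expect_equal(bf_distance(f, f), 0)
  expect_equal(bf_distance(c(A = 1, C = 0, G = 0, T = 0),
                           c(A = 0, C = 1, G = 0, T = 0)), 1)
  expect_equal(bf_distance(f, u), (0.15 + 0.05 + 0.05 + 0.15) / 2)
  ## name-aware: permuted names give the same answer
  expect_equal(bf_distance(f, u[c("T", "G", "C", "A")]), bf_distance(f, u))
  expect_error(bf_distance(f, c(X = .5, Y = .5)), "length|symbols")
})

test_that("BF distance satisfies metric axioms on random triples", {
  set.seed(42)
  for (i in 1:1000) {
    p <- matrix(stats::rexp(12), 3)
    p <- p / rowSums(p)
    d12 <- bf_distance(p[1, ], p[2, ])
    d13 <- bf_distance(p[1, ], p[3, ])
    d23 <- bf_distance(p[2, ], p[3, ])
    expect_true(d12 >= 0 && d13 >= 0 && d23 >= 0)
    expect_lte(d12, d13 + d23 + 1e-12)
    expect_equal(d12, bf_distance(p[2, ], p[1, ]))
  }
})

test_that("BF matrix matches the pairwise loop and generalizes to aa", {
  set.seed(7)
  prof <- matrix(stats::rexp(5 * 20), 5,
                 dimnames = list(paste0("t", 1:5), alphabet_states("aa20")))
  prof <- prof / rowSums(prof)
  d <- bf_distance_matrix(prof)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), setNames(rep(0, 5), rownames(prof)))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(d[i, j], bf_distance(prof[i, ], prof[j, ]))
  }
  ## permutation consistency
  d2 <- bf_distance_matrix(prof[5:1, ])
  expect_equal(d2[rownames(d), colnames(d)], d)
})

test_that("LogDet distance is zero for identical rows and grows with change", {
  aln <- random_alignment(3, 400, "nt4", seed = 2)
  m <- unclass(aln)
  m[2, ] <- m[1, ]
  d <- logdet_distance_matrix(alignment(m, "nt4"), by_position = FALSE)
  expect_equal(d[1, 2], 0, tolerance = 1e-10)
  ## monotone growth with divergence on a two-taxon branch under a
  ## non-stationary process (different compositions at the two ends)
  m_from <- model_gtr("nt4", freqs = c(A = .3, C = .25, G = .25, T = .2))
  m_to <- model_gtr("nt4", freqs = c(A = .2, C = .1, G = .2, T = .5))
  set.seed(9)
  anc <- sample(m_from$states, 3000, TRUE, prob = m_from$freqs)
  dist_at <- sapply(c(0.1, 0.4, 0.9), function(t) {
    P <- transition_matrix(m_to, t)
    cp <- t(apply(P, 1, cumsum))
    der <- m_to$states[1 + rowSums(cp[match(anc, m_to$states), ] <
                                     stats::runif(3000))]
    a <- alignment(c(x = paste(anc, collapse = ""),
                     y = paste(der, collapse = "")), "nt4")
    logdet_distance_matrix(a, by_position = FALSE)[1, 2]
  })
  expect_true(all(diff(dist_at) > 0))
  ## unrelated random sequences: large or flagged
  r <- random_alignment(2, 200, "nt4", seed = 10)
  dr <- logdet_distance_matrix(r, by_position = FALSE)
  expect_true(dr[1, 2] > 0.5 || !is.finite(dr[1, 2]))
})

test_that("NJ reconstructs an additive matrix exactly", {
  ## additive distances from a known 4-taxon tree
  tr <- ape::read.tree(text = "((a:0.1,b:0.2):0.05,(c:0.3,d:0.15):0.05);")
  d <- ape::cophenetic.phylo(tr)
  nj <- neighbor_joining(d)
  expect_equal(ape::dist.topo(ape::unroot(tr), nj), setNames(0, "PH85"),
               ignore_attr = TRUE)
  ## branch lengths reproduced
  expect_equal(sort(nj$edge.length), sort(ape::unroot(tr)$edge.length),
               tolerance = 1e-8)
  ## 3 taxa: closed-form star lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  nj3 <- neighbor_joining(d3)
  expect_equal(sort(nj3$edge.length), c(1, 2, 3))
  dinf <- matrix(c(0, Inf, 1, Inf, 0, 1, 1, 1, 0), 3,
                 dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(dinf), "finite")
})

test_that("BF tree separates groups that differ only in composition", {
  ## two compositional families of frequency vectors
  set.seed(5)
  mk <- function(base, n, lab) {
    m <- t(sapply(seq_len(n), function(i) {
      f <- base + stats::runif(4, 0, 0.01); f / sum(f)
    }))
    rownames(m) <- paste0(lab, seq_len(n))
    m
  }
  prof <- rbind(mk(c(.4, .1, .1, .4), 3, "at"), mk(c(.25, .25, .25, .25), 3, "gc"))
  colnames(prof) <- alphabet_states("nt4")
  tr <- bf_tree(prof)
  expect_true(ape::is.monophyletic(ape::root(tr, "gc1"), c("at1", "at2", "at3")))
  expect_true(all(tr$edge.length >= 0))
})

test_that("distance matrices export in PHYLIP shape", {
  d <- matrix(c(0, .1, .2, .1, 0, .3, .2, .3, 0), 3,
              dimnames = list(c("ta", "tb", "tc"), c("ta", "tb", "tc")))
  f <- withr::local_tempfile(fileext = ".dist")
  write_distance_phylip(d, f)
  lines <- readLines(f)
  expect_equal(as.integer(trimws(lines[1])), 3L)
  expect_length(lines, 4L)
  got <- as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]][-1])
  expect_equal(got, d[1, ], ignore_attr = TRUE)
})
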