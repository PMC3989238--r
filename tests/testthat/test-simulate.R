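test_that("template tree encodes the generating arrangement", {
  tr <- template_tree(c(robust = 1L, complex = 1L, corallimorph = 1L,
                        outgroup = 1L))
  expect_equal(length(tr$tip.label), 4L)
  tr2 <- template_tree()
  g <- tip_groups(tr2)
  expect_equal(sort(unique(g)), c("complex", "corallimorph", "outgroup", "robust"))
  expect_equal(unname(table(g)["robust"]), 4L)
  ## the generating topology groups robust with complex
  rooted <- ape::root(tr2, "outgroup_1", resolve.root = TRUE)
  expect_true(ape::is.monophyletic(rooted, names(g)[g %in% c("robust", "complex")]))
  ## newick round trip preserves labels
  back <- ape::read.tree(text = ape::write.tree(tr2))
  expect_setequal(back$tip.label, tr2$tip.label)
})

test_that("simulation is seed-deterministic and in frame", {
  cfg <- preset_robust_like(n_codons = 120, seed = 9)
  s1 <- simulate_alignment(cfg)
  s2 <- simulate_alignment(cfg)
  expect_identical(unclass(s1$alignment)[, ], unclass(s2$alignment)[, ])
  expect_s3_class(s1$alignment, "mb_codon_aln")
  expect_equal(n_col(s1$alignment), 360L)
  ## no stop codons anywhere: translation succeeds
  expect_silent(aa <- translate(s1$alignment))
  expect_equal(n_col(aa), 120L)
  ## different seed changes the data
  cfg2 <- preset_robust_like(n_codons = 120, seed = 10)
  expect_false(identical(unclass(simulate_alignment(cfg2)$alignment)[, ],
                         unclass(s1$alignment)[, ]))
})

test_that("a null configuration is compositionally homogeneous", {
  cfg <- simulation_config(n_codons = 1500, seed = 12)
  sim <- simulate_alignment(cfg)
  prof <- composition_profiles(sim$alignment)
  g <- sim$groups[prof$taxon]
  at <- tapply(prof$at_content, g, mean)
  expect_lt(max(at) - min(at), 0.03)
})

test_that("the robust-like preset induces the documented signature", {
  cfg <- preset_robust_like(n_codons = 3000, seed = 21)
  sim <- simulate_alignment(cfg)
  prof <- composition_profiles(sim$alignment)
  g <- sim$groups[prof$taxon]
  rob <- g == "robust"
  ingroup <- g %in% c("complex", "corallimorph")
  ## T excess at first and second codon positions in the shifted clade
  t1_excess <- mean(prof$T1[rob]) - mean(prof$T1[ingroup])
  t2_excess <- mean(prof$T2[rob]) - mean(prof$T2[ingroup])
  expect_gt(t1_excess, 0.02)
  expect_gt(t2_excess, 0.005)
  ## elevated A+T overall (toward ~69% vs ~62% background)
  expect_gt(mean(prof$at_content[rob]), mean(prof$at_content[ingroup]) + 0.04)
  ## phenylalanine enrichment in the translated proteins
  expect_gt(mean(prof$aa_F[rob]), mean(prof$aa_F[ingroup]))
  ## FYMINK/GARP ratio elevated in the shifted clade
  expect_gt(mean(prof$fymink_garp[rob]), mean(prof$fymink_garp[ingroup]))
})

test_that("composition converges toward the clade target on long branches", {
  root <- c(A = 0.28, C = 0.16, G = 0.22, T = 0.34)
  target <- c(A = 0.28, C = 0.11, G = 0.22, T = 0.39)
  m <- model_gtr("nt4", c(1, 4, 1, 1, 4, 1), freqs = target)
  kl <- sapply(c(0.2, 0.6, 1.5, 4), function(t) {
    P <- transition_matrix(m, t)
    tip <- as.numeric(root %*% P)
    sum(tip * log(tip / target))
  })
  expect_true(all(diff(kl) < 0))
})

test_that("clade edges include the stem and only the clade", {
  tr <- template_tree()
  es <- mitobias:::clade_edges(tr, "robust")
  g <- tip_groups(tr)
  ntip <- length(tr$tip.label)
  ## a 4-tip clade contributes its stem edge, 2 internal and 4 pendant edges
  expect_equal(length(es), 7L)
  ## pendant edges of the clade are all included, no foreign pendant edges
  pend <- which(tr$edge[, 2] <= ntip & g[tr$tip.label[tr$edge[, 2]]] == "robust")
  expect_true(all(pend %in% es))
  foreign <- which(tr$edge[, 2] <= ntip & g[tr$tip.label[tr$edge[, 2]]] != "robust")
  expect_false(any(foreign %in% es))
})

test_that("recovery experiment classifies and sums outcomes", {
  cfg <- preset_robust_like(n_per_group = c(robust = 2L, complex = 2L,
                                            corallimorph = 2L, outgroup = 2L),
                            n_codons = 300, seed = 5)
  rec <- recovery_experiment(cfg, methods = c("ry_ml", "logdet_nj", "bf_nj"),
                             n_reps = 2, seed = 2)
  expect_setequal(rec$method, c("ry_ml", "logdet_nj", "bf_nj"))
  expect_equal(rowSums(rec[, c("monophyly", "naked_coral", "other")]),
               rep(1, 3), ignore_attr = TRUE)
})
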