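test_that("FASTA round-trip reproduces an alignment exactly", {
  aln <- random_alignment(4, 30, "aa20", seed = 3, gap_prob = 0.1)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, f)
  back <- read_alignment(f, "aa20")
  expect_identical(unclass(back)[, ], unclass(aln)[, ])
  p <- withr::local_tempfile(fileext = ".phy")
  write_alignment(aln, p, format = "phylip")
  back2 <- read_alignment(p, "aa20", format = "phylip")
  expect_identical(unclass(back2)[, ], unclass(aln)[, ])
})

test_that("reader validates input and maps unknown symbols to missing", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGTAC", ">b", "ACGT"), f)
  expect_error(read_alignment(f, "nt4"), "ragged")
  writeLines(c(">a", "ACGTAC", ">a", "ACGTAC"), f)
  expect_error(read_alignment(f, "nt4"), "duplicate")
  writeLines(character(0), f)
  expect_error(read_alignment(f, "nt4"), "empty")
  ## two identical taxa, identity round trip
  writeLines(c(">a", "ACGTAC", ">b", "ACGTAC"), f)
  aln <- read_alignment(f, "nt4")
  expect_equal(n_taxa(aln), 2L)
  expect_equal(n_col(aln), 6L)
  ## 'X' in amino-acid data is kept as missing-equivalent, not an error
  writeLines(c(">a", "MKXF"), f)
  aa <- read_alignment(f, "aa20")
  expect_identical(unname(unclass(aa)[1, 3]), "X")
  ## a truly unknown symbol is replaced by '?' with a warning
  writeLines(c(">a", "AC*T"), f)
  expect_warning(nt <- read_alignment(f, "nt4"), "replaced")
  expect_identical(unname(unclass(nt)[1, 3]), "?")
})

test_that("translation follows the bound code, gap and stop rules", {
  code4 <- genetic_code(4)
  expect_identical(unname(code4$codon_to_aa[c("TTT", "TGA")]), c("F", "W"))
  aln <- codon_alignment(c(t1 = "TTTTGA"), code4)
  expect_identical(aln_strings(translate(aln)), c(t1 = "FW"))
  ## TTT is code-invariant
  aln1 <- codon_alignment(c(t1 = "TTT"), genetic_code(1))
  expect_identical(aln_strings(translate(aln1)), c(t1 = "F"))
  ## all-gap codon stays a gap, partial gap becomes missing
  g <- codon_alignment(c(t1 = "---T--ATG"), code4)
  expect_identical(aln_strings(translate(g)), c(t1 = "-?M"))
  ## internal stop is an error naming taxon and codon
  bad <- codon_alignment(c(t1 = "ATGTAAATG"), code4)
  expect_error(translate(bad), "t1.*codon 2")
  ## TGA is a stop under the standard code but Trp under table 4
  expect_error(translate(codon_alignment(c(t1 = "TGA"), genetic_code(1))),
               "stop")
})

test_that("reverse translation inverts translation and validates the CDS", {
  code <- genetic_code(4)
  aa <- alignment(c(t1 = "F-", t2 = "FK"), "aa20")
  cds <- c(t1 = "TTT", t2 = "TTTAAA")
  rt <- reverse_translate(aa, cds, code)
  expect_identical(aln_strings(rt), c(t1 = "TTT---", t2 = "TTTAAA"))
  expect_identical(aln_strings(reverse_translate(
    alignment(c(t1 = "MK"), "aa20"), c(t1 = "ATGAAA"), code)),
    c(t1 = "ATGAAA"))
  expect_error(reverse_translate(alignment(c(t1 = "MK"), "aa20"),
                                 c(t1 = "ATGCAA"), code),
               "mismatch at residue 2")
  ## round trip on a gappy alignment: translate(reverse_translate(A)) == A
  caln <- toy_codon_alignment()
  aa2 <- translate(caln)
  m <- unclass(aa2)
  m[1, 2] <- "-"; m[3, 4] <- "-"
  aa2g <- alignment(m, "aa20")
  cds2 <- vapply(taxa(caln), function(t) {
    keep <- m[t, ] != "-"
    paste(mitobias:::codon_matrix(caln)[t, keep], collapse = "")
  }, "")
  rt2 <- reverse_translate(aa2g, cds2, genetic_code(4))
  expect_identical(aln_strings(translate(rt2)), aln_strings(aa2g))
})

test_that("concatenation records partitions and refuses mismatched taxa", {
  a <- random_alignment(3, 9, "nt4", seed = 1)
  b <- random_alignment(3, 12, "nt4", seed = 2)
  cc <- concatenate(list(g1 = a, g2 = b))
  expect_equal(n_col(cc), 21L)
  expect_equal(attr(cc, "partition")$start, c(1L, 10L))
  expect_equal(attr(cc, "partition")$end, c(9L, 21L))
  ## per-taxon symbol counts are preserved
  for (t in taxa(a)) {
    expect_equal(table(unclass(cc)[t, ]),
                 table(c(unclass(a)[t, ], unclass(b)[t, ])))
  }
  expect_identical(aln_strings(concatenate(list(a))), aln_strings(a))
  d <- random_alignment(3, 6, "nt4", seed = 3)
  rownames(d)[1] <- "zz"
  expect_error(concatenate(list(a, d)), "taxon sets differ")
})

test_that("gap-column filtering matches a brute-force scan and is idempotent", {
  ## the quoted rule: a 4-taxon column with 3 gaps is removed at 50%
  m <- matrix("A", 4, 3, dimnames = list(paste0("t", 1:4), NULL))
  m[1:3, 2] <- "-"
  aln <- alignment(m, "nt4")
  expect_equal(n_col(filter_gap_columns(aln, 0.5)), 2L)
  ## gap-free alignment unchanged
  clean <- random_alignment(5, 40, "nt4", seed = 4)
  expect_identical(aln_strings(filter_gap_columns(clean, 0)),
                   aln_strings(clean))
  ## threshold 0 equals the explicit column scan, at several gap densities
  for (gp in c(0.05, 0.3, 0.6)) {
    g <- random_alignment(5, 60, "nt4", seed = 10 + round(100 * gp),
                          gap_prob = gp)
    got <- filter_gap_columns(g, 0)
    oracle <- sum(colSums(unclass(g) == "-") == 0)
    expect_equal(n_col(got), oracle)
    expect_identical(aln_strings(filter_gap_columns(got, 0)),
                     aln_strings(got))
  }
})

test_that("codon alignments are gap-filtered by whole codons", {
  m <- matrix("A", 2, 6, dimnames = list(c("t1", "t2"), NULL))
  m[, 3] <- c("G", "G"); m[1, 2] <- "-"; m[2, 2] <- "-"
  caln <- codon_alignment(alignment(m, "nt4"), genetic_code(4))
  out <- filter_gap_columns(caln, 0.4)
  expect_equal(n_col(out), 3L)      # whole first codon dropped
  expect_s3_class(out, "mb_codon_aln")
})

test_that("strip_incomplete_columns keeps exactly the complete columns", {
  m <- matrix("C", 3, 5, dimnames = list(paste0("t", 1:3), NULL))
  m[2, 4] <- "-"
  expect_equal(n_col(strip_incomplete_columns(alignment(m, "nt4"))), 4L)
  m[] <- "-"
  expect_warning(empty <- strip_incomplete_columns(alignment(m, "nt4")),
                 "no complete columns")
  expect_equal(n_col(empty), 0L)
  ## equivalence with filter_gap_columns at a threshold below 1/n_taxa
  g <- random_alignment(6, 80, "aa20", seed = 7, gap_prob = 0.15)
  expect_identical(aln_strings(strip_incomplete_columns(g)),
                   aln_strings(filter_gap_columns(g, 1 / 6 - 1e-9)))
})
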