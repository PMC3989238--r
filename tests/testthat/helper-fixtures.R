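## Small fixtures built in code, shared across test files.

## a deterministic random alignment over a given alphabet
random_alignment <- function(n_taxa, n_col, alphabet = "nt4", seed = 1,
                             gap_prob = 0) {
  states <- alphabet_states(alphabet)
  set.seed(seed)
  m <- matrix(sample(states, n_taxa * n_col, replace = TRUE), n_taxa,
              dimnames = list(paste0("t", seq_len(n_taxa)), NULL))
  if (gap_prob > 0) m[stats::runif(length(m)) < gap_prob] <- "-"
  alignment(m, alphabet)
}

## a small in-frame coding alignment (no stops under table 4)
toy_codon_alignment <- function() {
  codon_alignment(c(
    t1 = "ATGAAATTTTGACTT",
    t2 = "ATGAAGTTCTGGCTC",
    t3 = "ATGCAATTTTGACTG",
    t4 = "ATGCAGTATTGACTA"
  ), genetic_code(4))
}

## random codon alignment free of stop codons
random_codon_alignment <- function(n_taxa, n_codons, seed = 1) {
  code <- genetic_code(4)
  set.seed(seed)
  m <- matrix(sample(code$sense_codons, n_taxa * n_codons, replace = TRUE),
              n_taxa, dimnames = list(paste0("t", seq_len(n_taxa)), NULL))
  seqs <- apply(m, 1L, paste, collapse = "")
  codon_alignment(seqs, code)
}

## brute-force site likelihood by enumerating all internal-state
## assignments on a rooted tree; the independent oracle for the pruning
## engine (works for any alphabet/model, slow: use on <= 5 taxa)
enumeration_site_loglik <- function(aln, tree, model) {
  tree <- stats::reorder(tree, "postorder")
  edge <- tree$edge
  ntip <- length(tree$tip.label)
  nnode <- max(edge)
  root <- edge[nrow(edge), 1]
  internal <- sort(unique(edge[, 1]))
  k <- model$k
  mix <- mitobias:::mixture_rates(model)
  Pe <- lapply(seq_along(mix$rates), function(c)
    lapply(seq_len(nrow(edge)), function(e)
      transition_matrix(model, tree$edge.length[e], mix$rates[c])))
  m <- unclass(aln)[tree$tip.label, , drop = FALSE]
  states <- model$states
  sapply(seq_len(ncol(m)), function(s) {
    tipstate <- match(m[, s], states)  # NA = marginalize
    lik <- 0
    for (c in seq_along(mix$rates)) {
      tot <- 0
      grid <- do.call(expand.grid, rep(list(seq_len(k)), length(internal)))
      for (g in seq_len(nrow(grid))) {
        assign_int <- as.integer(grid[g, ])
        names(assign_int) <- internal
        statevec <- integer(nnode)
        statevec[internal] <- assign_int
        pr <- unname(model$freqs[statevec[root]])
        for (e in seq_len(nrow(edge))) {
          u <- edge[e, 1]; v <- edge[e, 2]
          if (v <= ntip) {
            if (is.na(tipstate[v])) next  # sums to 1 over child states
            pr <- pr * Pe[[c]][[e]][statevec[u], tipstate[v]]
          } else {
            pr <- pr * Pe[[c]][[e]][statevec[u], statevec[v]]
          }
        }
        tot <- tot + pr
      }
      lik <- lik + mix$weights[c] * tot
    }
    log(lik)
  })
}
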