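---
title: "Diagnosing compositional bias in mitochondrial phylogenomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing compositional bias in mitochondrial phylogenomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitobias)
```

## The problem

Concatenated mitochondrial protein-coding genes are a standard marker set for
resolving deep relationships, but they carry a well-known hazard: nucleotide
composition can differ strongly between lineages. In anthozoans, one major
clade of stony corals ("Robust"-type) has mitochondrial coding sequences that
are markedly T-rich and C-poor — elevated A+T overall, with the T excess
visible even at first and second codon positions, where it forces amino-acid
replacements. The encoded proteins drift toward residues with (A+T)-rich
codons (Phe, Tyr, Met, Ile, Asn, Lys — "FYMINK") and away from residues with
(G+C)-rich codons (Gly, Ala, Arg, Pro — "GARP"). A plausible mechanism is
reduced mitochondrial DNA repair: unrepaired deamination of cytosine produces
an elevated C-to-T substitution flux, which simultaneously shifts the
equilibrium composition and accelerates the lineage, so the clade sits on a
disproportionately long branch.

Under these conditions, phylogenetic methods that assume a stationary,
homogeneous substitution process can prefer a wrong topology: shared
compositional states masquerade as shared ancestry. For corals the practical
stakes are whether corallimorpharians fall *inside* the stony corals (the
"naked coral" arrangement) or outside them (scleractinian monophyly) —
nucleotide-level and amino-acid-level analyses of the same genomes give
contradictory answers.

This package implements the diagnostic toolkit for that situation:
composition and codon-usage profiling, recodings that hide the biased
dimension of the data, composition-based and composition-robust distances,
likelihood machinery for fixed-topology comparisons, topology tests,
an absolute goodness-of-fit test, and a simulator that generates data with a
known tree and a controlled compositional shift, so that every diagnostic can
be validated against ground truth.

## Composition and codon-usage diagnostics

`composition_profiles()` computes per-taxon base composition by codon
position, A+T content, AT/GC skews, amino-acid frequencies and the
FYMINK/GARP statistics; `group_summary()` averages per-taxon statistics
within groups (means of per-taxon ratios, not ratios of pooled counts, so a
group row is exactly the average of its members).

Codon-usage bias is summarised by Wright's effective number of codons (NC)
and the codon adaptation index (CAI). Both derive their synonymous-family
structure from the genetic code actually bound to the alignment — under the
coelenterate mitochondrial code (NCBI table 4, the package default) TGA
encodes tryptophan, so there are 62 sense codons, tryptophan is a two-codon
family, and maximally even usage gives NC = 62, while using one codon per
amino acid gives NC = 20. CAI reference weights default to self-referential
weights computed from the dataset itself (relative adaptiveness
`count / max` within each family, unobserved codons floored at 0.01); an
external reference set can be supplied instead. Because the reference set is
a declared choice, CAI values are comparable within an analysis, not across
publications.

## Recodings

Three alphabet reductions target the biased dimensions of the data:

* **RY coding** (`ry_recode()`): purines vs pyrimidines. A T-for-C excess is
  a change *within* the pyrimidine class, so it is invisible after RY
  coding; what survives is transversion signal.
* **Six-state amino-acid coding** (`aa6_recode()`): MVIL / FYW / ASTGP /
  DNEQ / RKH / C. Replacements within each class — exactly the replacements
  that composition pressure drives most easily — are erased.
* **Four-state amino-acid coding** (`aa4_recode()`): the aromatic and
  hydrophobic classes are merged, cysteine becomes missing data, and the
  four states are deliberately labelled A, T, G, C so any nucleotide GTR
  machinery applies unchanged.

`mask_residues()` implements residue-level exclusion (e.g. of Phe, Ala, Thr,
Tyr, the residues most affected by the shift). Masking replaces cells with
missing data rather than deleting columns: deleting every column containing
any such residue would remove most of a mitochondrial alignment. A
column-dropping mode exists for sensitivity analysis.

## Distances

The **base-frequency (BF) distance** between two taxa is half the summed
absolute differences of their frequency vectors (the total-variation
distance). Note the absolute values: the raw paired differences of two
probability vectors cancel to zero identically, so the absolute-value form
is the only meaningful reading. Minimum-evolution trees built from BF
distances (`bf_tree()`, OLS with NNI improvement via ape) reflect
composition alone: if a BF tree groups the same taxa as a substitution-based
tree, composition is a candidate explanation for that grouping.

The **LogDet / paralinear distance** is consistent under the general Markov
model — per branch, any substitution matrix, no stationarity — which makes
it the standard composition-robust distance. Two practical limitations
matter and are handled explicitly:

* The guarantee applies *per Markov process*. Pooling site classes that
  evolve differently (codon positions; strongly different rates)
  reintroduces a bias, in expectation, toward grouping compositionally
  similar taxa — the same direction as the artifact the distance is meant to
  avoid. For codon alignments `logdet_distance_matrix()` therefore
  stratifies by codon position and sums the three components; the
  `positions` argument allows excluding a saturated position entirely.
* Near saturation the plug-in estimator degenerates (the joint-frequency
  determinant can reach zero or go negative in finite samples). Such pairs
  are flagged (`Inf`), never silently imputed; downstream users choose the
  policy (the recovery experiment replaces sporadic flagged pairs by 1.2
  times the largest estimable distance).

## Likelihood machinery

A Felsenstein-pruning engine over arbitrary finite alphabets (nucleotide,
RY, amino acid, and both recoded amino-acid alphabets) supports
GTR-type reversible models and the JTT amino-acid model, each with empirical
frequencies (+F), discrete-gamma rate variation (+G) and an invariant-site
class (+I). The gamma discretization uses equal-probability categories
represented by their conditional means, five categories by default. With an
invariant class the gamma rates are rescaled by `1/(1 - p_inv)` so the
mixture's mean rate stays exactly 1 and branch lengths remain expected
substitutions per site. Gaps and missing symbols are marginalized over.
The numerical core (per-category site likelihoods, cached edge partials, and
a spectral projection that makes single-branch-length trials a dot product)
is implemented in C++; per-site log-likelihood vectors are exact, not
approximated, since they feed the resampling tests.

Branch lengths are optimized by per-edge Brent updates against cached
partials, iterated in sweeps; a sweep that fails to improve the total
log-likelihood is rejected, so the reported log-likelihood never decreases
across sweeps, and small trees get a joint quasi-Newton polish.
`fit_model()` estimates GTR exchangeabilities, gamma shape and the invariant
fraction by alternating branch-length sweeps with bounded quasi-Newton steps;
state frequencies are always empirical, never free parameters.
`nni_search()` provides a greedy nearest-neighbour-interchange hill-climb for
the package's target scale (tens of taxa); production-scale searches belong
in dedicated ML software, whose role this package does not attempt to fill.

Posterior mean relative site rates (`posterior_site_rates()`) are the
rate-mixture expectation given each site's likelihoods, normalized to mean 1;
`exclude_fast_sites()` removes sites whose rate strictly exceeds a threshold
(the conventional cuts being > 2.99, > 1.99, > 1.49). Strict inequality
means boundary sites are retained; only sites genuinely beyond the cut go.

## Topology tests and absolute goodness of fit

`kh_test()` and `sh_test()` implement the RELL versions of the
Kishino–Hasegawa and Shimodaira–Hasegawa tests from per-site log-likelihood
vectors. KH is two-sided by default. One subtlety is worth stating
precisely: for a two-topology comparison, the SH p-value of the non-ML
topology equals the *one-sided* pairwise p — SH is conservative relative to
the one-sided comparison (and `kh_test(alternative = "greater")` exposes
exactly that quantity), not relative to the two-sided KH, which can be up to
twice as large. Site log-likelihood matrices can be written in a plain-text
topologies-by-sites format (`write_site_lnl()`) for external
multiscale-bootstrap (AU) testing, which this package deliberately does not
reimplement.

`goldman_test()` measures absolute fit: the deficit of the fitted model's
log-likelihood below the unconstrained multinomial maximum
(`sum n_p log(n_p/N)` over site patterns) is referred to its parametric
bootstrap distribution — datasets simulated under the fitted model and tree,
each refitted (branch lengths and, by default, the gamma shape; the
remaining substitution parameters are held fixed, which keeps 200
simulations desk-scale) before its own deficit is measured. P-values use the
add-one convention `(1 + #{delta* >= delta}) / (n_sim + 1)` and so are never
zero. Refits on small trees go through a joint bounded quasi-Newton
optimization of branch lengths and log-shape, which is what makes
calibration experiments with tens of thousands of refits feasible.

## The simulator

`simulate_alignment()` generates in-frame protein-coding alignments on a
labelled template tree whose generating topology has the robust-like and
complex-like clades as sisters. Key design choices:

* **Non-stationarity is branch-local equilibrium switching.** Within a
  shifted clade (stem included) the reversible process's equilibrium moves
  to per-position target vectors. This induces the compositional artifact
  while remaining analytically transparent; per-branch joint-matrix
  (fully general Markov) simulation is intentionally out of scope.
* **The long branch comes from the mechanism, not a dial.** A clade shift
  can boost the C–T exchangeability (`ct_multiplier`), and all edge
  processes are scaled against the *background* process's rate, so the
  boosted clade genuinely accumulates extra substitutions: its stem comes
  out disproportionately long. Because those extra events are pyrimidine
  transitions, they are invisible to RY coding — the property that makes RY
  a diagnostic in the first place. A flat `rate_multiplier` is available
  but defaults to 1: a uniform speed-up lengthens the clade's branches in
  *every* representation, which makes two-state RY-coded likelihood fail by
  ordinary long-branch attraction even with no compositional shift at all,
  inverting the phenomenon the simulator exists to produce.
* **Codons, not sites.** Each codon draws one gamma rate shared by its
  three positions; positions have their own relative rates (defaults 1,
  0.7, 1.6) and their own equilibrium vectors. Codons that would produce a
  stop under the bound code in any tip are resimulated wholesale, so the
  output is always translatable. This rejection step slightly distorts
  absolute position-2 composition (real coding sequences live under the
  same constraint); clade *contrasts* are unaffected.

The default `preset_robust_like()` encodes the study conditions: a
hexacoral-like background at A+T about 62% per position; a robust-like clade
shifted by +5% T at first, +3% at second and +13% at third codon positions
(all taken from C, target A+T about 69%) with a six-fold C–T boost; and an
outgroup carrying a mild shift in the same direction (about +1.8/+1.2/+4.8%
T, A+T about 64.7%, two-fold C–T boost), mirroring the intermediate A+T
content of real octocoral outgroups. That mild outgroup shift matters: it
makes the outgroup the compositionally closest neighbour of the shifted
clade, which is what lets a stationary amino-acid model pull the two
together. Template-tree depths (crown 0.18, clade stems 0.22, contested
internal edge 0.022, outgroup stem 0.27 expected substitutions per site) and
a mild across-codon gamma (shape 12) were fixed once, by pilot simulation
and by exact computation of expected paralinear distances, to a regime where
(i) the shifted clade realises most of its target composition within the
clade, (ii) the contested edge is short enough to be genuinely contestable,
and (iii) the within-position rate mixture stays mild enough that stratified
LogDet remains near-consistent. With strong within-position rate
heterogeneity (gamma shape below about 2 at these depths) even stratified
LogDet acquires an expected-value bias toward the compositional grouping —
a real limitation of the distance, documented above, not an artifact of this
implementation.

## The recovery experiment

`recovery_experiment()` is the package's central calibration: replicates are
simulated under a configuration, each replicate is analysed by several
methods on identical data, and the proportion of replicates recovering the
generating arrangement versus the naked-coral artifact is reported.
Maximum-likelihood methods adjudicate between the three clade-level
arrangements of the true within-clade subtrees by optimized log-likelihood
(a full topology search over 16 taxa per replicate would add nothing to the
question — which arrangement of the four clades wins — at many times the
cost); distance methods build a tree and classify the clade pairing it
contains. Under the default preset at 4,000 codons with 50 replicates,
amino-acid JTT likelihood recovers the true arrangement in a minority of
replicates (about 0.2–0.3, the artifact being specifically the naked-coral
grouping), while RY-coded likelihood recovers it almost always and
position-stratified LogDet neighbor joining in a clear majority; with the
shift removed, every method recovers the truth in essentially all
replicates. The test suite asserts the direction of these differences with
margins set from pilot runs, not the pilot values themselves.

## What passing tests do and do not show

The simulator emulates the compositional signature (per-position T
enrichment, elevated A+T, FYMINK/GARP shift, phenylalanine excess, a long
shifted stem) on a known tree. It does not emulate indels, selection or
codon-usage adaptation (dN/dS structure), heterotachy, site-specific
biochemical constraints (CAT-like profiles), or tRNA-pool constraints on
translation. Passing the recovery criteria therefore demonstrates that the
diagnostics behave as designed under controlled compositional
non-stationarity — it does not by itself resolve the placement of any real
clade, where additional model violations are certainly present.

## Numerical choices

Branch lengths are bounded to `[1e-8, 50]`; frequencies are floored at
1e-4 and renormalized so every model stays irreducible; eigendecompositions
of reversible rate matrices go through the symmetrized similarity transform;
transition-probability matrices are clamped at zero and renormalized
rowwise; tied quartet scores (within 1e-6) count as unresolved rather than
being broken arbitrarily; Goldman p-values use the add-one convention; all
stochastic operations take explicit integer seeds, restore the caller's RNG
state, and derive replicate seeds by fixed offsets.
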