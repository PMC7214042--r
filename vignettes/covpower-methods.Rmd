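---
title: "Covariation power analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariation power analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Compensatory substitutions at the two sides of a conserved RNA basepair
leave a covariation signature between the corresponding alignment columns.
Statistically significant covariation is strong evidence *for* a conserved
structure. The converse does not follow: an alignment with little sequence
variation cannot show covariation whether or not a structure is conserved.
`covpower` addresses the resulting asymmetry by estimating, for every
proposed basepair, the *statistical power* of the covariation test — the
probability that a truly conserved pair with that much evolutionary
variation would have been detected. Absence of covariation in a high-power
alignment is evidence against a conserved structure; in a low-power
alignment it is simply inconclusive.

## The pipeline

Given an alignment with a proposed consensus structure:

1. **Tree.** A phylogeny is built from pairwise identities with
   Jukes–Cantor corrected distances and neighbor joining, midpoint rooted.
   The original method uses a maximum-likelihood tree; tree provenance is
   orthogonal to everything downstream, so any externally built Newick tree
   can be supplied instead (`tree_path`). Negative NJ branch lengths are
   clamped to zero; ties are resolved deterministically by the underlying
   NJ implementation.
2. **Substitution counts.** The Fitch small-parsimony algorithm gives the
   minimum number of substitutions `s_i` at every column; a basepair
   `b = (i, j)` gets `s_b = s_i + s_j` (columns treated independently; the
   joint 16-state count is available as `joint_pair_substitutions()` and is
   never larger). Branch lengths are ignored by parsimony. A gapped or
   ambiguous leaf carries the full residue alphabet, so indels never create
   substitution counts — indels are modeled separately in the simulator.
   Multifurcations are resolved arbitrarily with zero-length branches, which
   cannot change the parsimony count.
3. **Covariation statistic.** The default is the G-test on the 4×4 joint
   count table of a column pair, rows gapped in either column excluded; it
   equals `2 N ln(2) · MI` exactly, where MI is mutual information in bits.
   MI and an optional average-product correction are available. Pairs with
   fewer than 3 mutually ungapped rows are reported untestable (statistic
   0, E-value equal to the correction factor).
4. **Null distribution and E-values.** Null alignments preserve the tree,
   the gap pattern, the per-column composition and the overall divergence of
   the input while evolving every column independently, which destroys
   pairwise correlation. Statistics from all pairs of all null alignments
   are pooled; the E-value of an observed score is the number of tests times
   the add-one-smoothed fraction of null statistics at or above it.
   Significance means E-value below 0.05.
5. **Power.** An empirical curve power(s) — the frequency with which
   basepairs with `s` substitutions reach E < 0.05 — is evaluated at every
   proposed pair; `cov-bp-exp = Σ_b power(s_b)` is the expected number of
   significant pairs and `alignment power = cov-bp-exp / B` the expected
   fraction. Alignments with alignment power strictly above 10% are
   classified high-power.

### Test modes

`one_set` tests all `L(L−1)/2` column pairs with that single correction
factor. `two_set` (required for power reporting, which needs a proposed
structure) runs two independent tests against the shared null: the `B`
proposed pairs with correction factor `B`, and the remaining
`L(L−1)/2 − B` pairs with their own factor. Basepair E-values in two-set
mode are therefore never larger than the corresponding one-set E-values.

## The null model in detail

Each column is re-evolved down the tree under an F81-type process whose
stationary distribution is the column's composition and whose rate is
proportional to the column's Fitch count `s_i`. Two calibrations proved
necessary and are worth recording:

* **Composition shrinkage.** Leaves are phylogenetically correlated, so raw
  column frequencies are a concentrated, biased estimate of the stationary
  composition. A null built on raw frequencies must over-substitute to
  reach the input's divergence, which inflates its parsimony counts. Column
  compositions are shrunk 30% toward uniform before simulation.
* **Rate factor.** Parsimony counts are minima and miss multiple hits, so
  matching expected substitution *events* to `s_i` leaves nulls visibly
  less diverged than their input. A global rate factor (secant search on
  its logarithm, three trial simulations per evaluation) is calibrated so
  the nulls reproduce the input's average pairwise identity; with the
  shrinkage above, the nulls then also reproduce the per-column Fitch
  counts to within ±25% for columns with `s_i ≥ 5` across the regimes the
  test suite samples (identities ~0.4–0.8).

Columns with `s_i = 0` are copied verbatim (a zero-rate process), as are
all gap and ambiguity cells.

The default null size is 20 alignments with a floor of 1e5 pooled null pair
statistics (the floor bounds E-value resolution; more alignments are
generated when `L` is small). The empirical survival function uses add-one
smoothing rather than the parametric tail fit of the reference
implementation — a documented fidelity gap; smoothed E-values are
conservative, which the calibration tests confirm (the false-positive rate
per test set stays below the E-value budget).

## The simulator

`simulate_alignment()` emulates the generation of synthetic structural
alignments with controlled size and diversity: the template's tree is
subsampled to `n_taxa`, a random template sequence becomes the root (gap
and ambiguous positions are imputed from the model's stationary
distributions), and branch lengths are rescaled by a factor found by
bisection on its logarithm over `[1e-3, 1e2]` until the simulated average
identity is within ±2 percentage points of the target, three trial
simulations per evaluation, at most 30 iterations. Because a single
returned alignment is noisier than the trial mean the bisection converged
on, the function draws three candidate alignments at the final scale and
returns the one closest to the target.

The substitution model is deliberately simple and fully configurable:

* Unpaired columns: F81 with composition taken from the template
  (pseudocount 1), one expected substitution per site per unit branch
  length.
* Paired columns: a 16-state F81-style process over ordered basepairs with
  stationary composition AU = UA = GC = CG = 0.22, GU = UG = 0.05 and the
  ten non-canonical pairs at 0.002 each — reversible, canonical-biased, one
  expected pair event per unit branch length. Any reversible pair-biased
  model reproduces the qualitative contract (covariation at paired columns,
  none elsewhere); the identity-targeting bisection absorbs the overall
  rate normalization.
* Indels: Poisson events per branch at rate 0.02 per site per unit branch
  length each for insertion and deletion, geometric lengths with parameter
  0.6 (mean 2.5). Deletions never remove paired columns and insertions open
  new unpaired columns (gaps in all other rows), so the annotated structure
  stays valid throughout; columns gapped in every output row are dropped.

What the generator does *not* emulate: alignment error (sequences are never
misaligned — the COOLAIR-style artifact of spurious covariation from
slid primary-sequence conservation cannot arise), rate variation across
sites beyond the structure dichotomy, non-reversible or context-dependent
substitution, and base-stacking or loop constraints. A green simulation
test therefore establishes internal consistency of the method, not realism
of any particular biological alignment.

## The power curve

Basepairs are binned by integer `s` (equal-occupancy binning is available
as a plotting convention only); each bin's empirical power is the fraction
of its pairs with E < 0.05. Fitting uses every bin with `s ≤ 150` but only
bins with at least 80% power beyond that, where occupancy is sparse and
noisy. The default fit is weighted isotonic regression: power must be
usable as a probability and is monotone in `s` by the method's own premise,
whereas the reference implementation's unconstrained degree-10 polynomial
(offered here as `fit_mode = "polynomial"`) need not be monotone. The
single-parameter family `1 − e^{−λs}` is available for comparison
(`fit_mode = "exponential"`) and fits sigmoidal data visibly worse. Curves
are clamped into [0, 1], forced through power(0) = 0, set to 1 above
`clamp_hi = 226` (parity with the reference implementation's convention),
evaluated by linear interpolation between knots, and serialized as
two-column text. Fractional `s` is supported at evaluation time only;
substitution counts themselves are unweighted integers.

The curve shipped in `inst/extdata/power_curve_synthetic_default.tsv` was
fitted on simulated structural alignments (a 60-sequence, 72-column,
18-pair synthetic template family; 15/25/40 taxa × identities 0.35–0.95)
and is labelled synthetic: it reproduces the fitting *procedure*, not the
reference implementation's hardcoded table, whose values are not published.
On these short simulated alignments power saturates near `s ≈ 11`, far
below 226: power at a given `s` depends in reality on alignment length
through the multiple-test correction, and treating power(s) as a function
of `s` alone is a deliberate approximation shared with the original
method. Refit on your own annotated families with `cmd_fit_power()` when
absolute power values matter.

## Numerical and interface choices

* Column indices are 1-based everywhere, matching R and the reporting
  convention of the field's tools.
* `T` is normalized to `U` on input; residue comparison is
  case-insensitive; gap characters `- . _ ~` are equivalent; ambiguity
  codes become a single missing symbol that parsimony treats as a wildcard.
  All columns are eligible for testing, including lowercase (insert-state)
  ones.
* Jukes–Cantor distances are capped at 10 at saturation.
* All stochastic stages derive child seeds deterministically from one
  top-level seed; identical configuration and seed give byte-identical
  outputs.
* Classed conditions distinguish format errors (CLI exit code 2) from
  statistical precondition failures (exit code 3).

## Known limitations

* E-value resolution is bounded by the pooled null size
  (`n_tests / (1 + pooled)` is the smallest achievable E-value); raise
  `min_null_stats` for deeply significant reporting.
* The identity calibration of the null is aggregate; individual columns in
  strongly saturated alignments (identity below ~40%) can drift outside the
  ±25% substitution-count band.
* Power estimates inherit the curve's training distribution; the shipped
  synthetic curve is calibrated for alignments broadly similar to its
  training dimensions.
* No parametric null-tail fitting, no sequence weighting, no
  maximum-likelihood tree inference.
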