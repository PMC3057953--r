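---
title: "Signal diagnostics for phylogenomic supermatrices: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal diagnostics for phylogenomic supermatrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloqc)
```

## The problem

Concatenating hundreds of genes does not, by itself, resolve a phylogeny.
Large supermatrices amplify *non-phylogenetic* signal along with the genuine
kind: undetected multiple substitutions (saturation) make fast-evolving
lineages look alike, contaminated or paralogous sequences inject branches
that belong to another part of the tree, and sparse taxon sampling plus
distant outgroups creates the classic long-branch-attraction (LBA)
geometry in which the two longest branches find each other regardless of
history. phyloqc packages the quality-control side of this problem: it
quantifies saturation, screens genes for well-supported conflicts with the
concatenated topology, profiles missing data, and orchestrates
taxon-deletion and outgroup-pruning reanalyses — together with a simulator
that generates supermatrices whose true history, rates and implanted
artifacts are known, so every diagnostic can be validated end to end.

Model-based tree inference itself (ML programs, Bayesian CAT analyses) is
deliberately out of scope: externally inferred trees enter as Newick files.
The internal engine (distances + neighbor joining + bootstrap) exists so
that the full pipeline runs at desk scale with no external binaries.

## The saturation statistic

For every pair of taxa we have two distances:

* the **uncorrected (p) distance** $p_{ij}$ — the fraction of differing
  sites over the columns where neither sequence is missing (pairwise
  deletion), and
* the **patristic distance** $d_{ij}$ — the sum of branch lengths along the
  path joining $i$ and $j$ in a reference tree, typically the best tree of
  a model-based analysis, whose branch lengths estimate the *true* number
  of substitutions per site.

`saturation_slope()` fits, by ordinary least squares with a free intercept,

$$ p_{ij} = \alpha + \beta \, d_{ij} + \varepsilon_{ij} $$

and reports $\beta$. When every substitution is still visible, observed
differences accumulate exactly as fast as tree distance and $\beta = 1$;
as multiple substitutions pile up, $p$ plateaus (at $\tfrac{s-1}{s}$ for
$s$ states under an equal-frequency model) while $d$ keeps growing, so the
slope is *compressed below 1*. Heavily saturated datasets land around
0.3–0.5. Two conventions are worth making explicit:

* **Orientation.** The observed distance is the response and the patristic
  distance the regressor. This is the orientation under which "no
  saturation" means slope 1 and more saturation means a smaller slope;
  plots of the same data with the axes exchanged produce slopes above 1
  and are not comparable to our values.
* **Free intercept.** The line is not forced through the origin. For
  unsaturated data the intercept estimates to 0 anyway, and a free
  intercept keeps the slope robust to small additive biases (e.g. a floor
  of observable differences created by alignment error). Users comparing
  against a through-the-origin fit should expect small differences.

Even mildly diverged data sit slightly below 1: under a uniform
$s$-state model the local slope at distance $d$ is $e^{-s d/(s-1)}$, about
0.96 at $d = 0.03$. The package's baseline "unsaturated" test condition is
therefore a tree whose *maximum tip-to-tip path* is 0.05
substitutions/site, where the expected slope stays within 0.05 of 1.

`saturation_by_partition()` applies the same fit per gene against one
fixed tree and ranks genes by decreasing slope. This is the gene-selection
view: genes with high slopes carry the least eroded signal, and a
concatenation restricted to them trades length for quality.

Mixed nucleotide/protein supermatrices are treated as one cloud of points
(a difference is a difference); the per-partition table is available when
alphabet-pure analyses are wanted.

## The congruence screen

`congruence_screen()` operationalizes an a-posteriori orthology check:
if a gene is orthologous and clean, its tree can disagree with the
concatenated tree only where resolution is weak. So we look at every
*supported* branch — bootstrap support at least 70 by default, the
conventional cut-off — of every single-gene tree, and ask whether that
bipartition can coexist with the reference topology restricted to the
gene's taxon set. Formally, two splits $A|B$ and $C|D$ of one taxon set
are compatible iff at least one of $A\cap C$, $A\cap D$, $B\cap C$,
$B\cap D$ is empty; a supported gene split incompatible with any split of
the restricted reference is a conflict.

Bookkeeping choices:

* The conflict rate pools genes: total conflicting supported splits over
  total supported splits across all gene trees. A per-gene table and the
  explicit conflict list (split + support) accompany it.
* Restricting the reference to a gene's taxa collapses unsampled regions;
  when several reference edges merge, the merged edge keeps the maximum of
  their supports. Patristic distances among retained taxa are unchanged by
  restriction (this is tested).
* Genes with fewer than 4 shared taxa have no non-trivial splits and
  contribute zero supported branches (logged, not an error).
* If no split anywhere reaches the threshold the report says so explicitly
  (`no_testable_branches`) and the rate is reported as 0 rather than NaN.
* Conflicts are reported, not classified: deciding whether a conflict is
  contamination, paralogy or reconstruction error requires inspection that
  is out of scope.

Note one property that does *not* hold in general: the conflict rate need
not decrease as the threshold rises. Implanted contaminations tend to
carry maximal support, so raising the threshold can empty the denominator
faster than the numerator. The monotone quantities are the supported and
conflicting *counts*.

## Missing data

All of `-`, `?`, and `N`/`X` count as missing, for the overall fraction
(`missing_fraction()`), the per-taxon profile (`per_taxon_missing()`),
and pairwise deletion in `p_distance()`. The corpus this package targets
does not distinguish indels from absent sequence when quantifying
incompleteness, and neither do we; users who need gap-aware statistics
can recode before import. Concatenation fills absent gene-by-taxon blocks
with `?`, so the supermatrix missing fraction is the weighted mean of the
per-gene fractions plus the fill.

## The internal inference engine

* **Distances.** p-distances use pairwise deletion; pairs with no
  comparable column are undefined (`NaN`), never silently 0. Corrections
  come from the $s$-state Poisson family:
  $d = -\tfrac{s-1}{s}\,\ln(1 - \tfrac{s}{s-1} p)$, and its gamma-rates
  counterpart $d = a\,\tfrac{s-1}{s}\,[(1-\tfrac{s}{s-1}p)^{-1/a} - 1]$.
  These closed forms are enough to reproduce every under/over-correction
  phenomenon the diagnostics probe; empirical exchangeability matrices
  (LG, WAG) belong to the external ML programs. At or beyond the plateau
  $p \ge (s-1)/s$ the correction is undefined and flagged, not raised.
* **Neighbor joining** follows the standard Q-criterion agglomeration with
  two determinism guarantees: ties are broken by the lexicographically
  smallest pair of cluster names, and negative intermediate branch length
  estimates are clamped to zero with the deficit moved to the sibling
  edge, preserving path lengths through the new node. On additive
  matrices the generating tree is recovered to floating-point accuracy
  (tested against brute-force path sums and `ape::nj`).
* **Bootstrap** resamples columns with replacement (site bootstrap;
  partition boundaries are ignored — gene-level resampling is a
  non-goal), re-infers with the same distance model, and labels each
  internal edge of the point tree with the percentage of replicates
  containing its bipartition. Replicate $r$ uses seed $\texttt{seed}+r$.
  A replicate whose resampled matrix leaves some pair undefined cannot be
  analyzed; such replicates are dropped from the denominator and counted
  in an attribute, which keeps supports honest on gappy data at the cost
  of a slightly smaller effective $B$.

## The simulator

`simulate_supermatrix()` evolves each site independently down the
spec's tree under a continuous-time reversible model whose off-diagonal
rates are exchangeability × target frequency, normalized so that a branch
length is the expected number of substitutions per site *at that site's
rate*. Site rate = discrete-gamma category rate (4 categories,
equal-probability quantile means, via `phangorn::discrete.gamma`) × the
gene's rate multiplier. Site-heterogeneity follows the CAT convention:
profiles differ only in their equilibrium frequencies, exchangeabilities
stay uniform. With uniform exchangeabilities the process has the closed
F81-type kernel $P(t) = e^{-t/\beta} I + (1-e^{-t/\beta})\,\mathbf 1 \pi^\top$
with $\beta = 1 - \sum_x \pi_x^2$, so simulation is exact — no matrix
exponentials, and the single-branch divergence law
$\mathbb E[p] = \beta(1-e^{-t/\beta})$ gives a sharp Monte-Carlo test.
General symmetric exchangeabilities are supported through an
eigendecomposition of the similarity-transformed generator.

Randomness is structured as one stream per (gene, site), derived from the
master seed by an integer hash. Consequences: the same spec and seed give
a byte-identical supermatrix, and adding genes (or lengthening later
genes) never perturbs earlier ones — which makes incremental scenario
construction reproducible.

`cat_profiles()` draws sparse profiles from a symmetric Dirichlet with
concentration 0.2 over 20 states, i.e. roughly 3–6 effectively accepted
amino acids per profile — the regime empirical CAT profiles occupy. This
is what makes the LBA reproduction work mechanically: on a long branch the
site forgets its parent state and redraws from a small accepted set, so
two long branches converge on the same states at a rate far above what a
site-homogeneous analysis expects.

What the generator deliberately does **not** emulate: indels and alignment
error, codon structure, sequencing artifacts/frameshifts, ambiguity codes,
heterotachy (profiles are constant along the tree), and incomplete lineage
sorting. Passing tests therefore demonstrate that the diagnostics behave
correctly for substitutional noise, rate heterogeneity, compositional
site-heterogeneity, contamination and missing data — not that they are
robust to misalignment or ILS-driven discordance.

## Study conditions baked into the benchmark scenarios

The scenario functions (`nj_additive_check`, `saturation_scaling_check`,
`congruence_screen_check`, `lba_check`) fix the following conditions,
which the test suite and `scripts/acceptance.R` reuse unchanged:

* *Oracle check*: 200 random binary trees with 6–10 leaves, branch
  lengths uniform on [0.05, 0.5].
* *Saturation scaling*: balanced 8-taxon tree, diameter 0.05
  substitutions/site, multipliers ×1/×5/×20, uniform 4-state model,
  10,000 sites, slopes averaged over 3 seeds. The reanalysis mimics a
  user: Poisson-corrected NJ tree, then `saturation_slope()` against it.
* *Congruence ground truth*: 10-taxon reference with 0.1-long internal
  edges, 20 genes × 1,000 sites, two implanted transfers
  (`t1→t8` in gene05, `t2→t9` in gene13), bootstrap B = 100 with Poisson
  correction, threshold 70.
* *LBA*: quartet with short terminals 0.05, central edge 0.05, long
  terminals ∈ {0.5, 1.0, 2.0}; 10 Dirichlet(0.2) profiles, 5,000 sites,
  50 replicate seeds, uncorrected-distance NJ. The wrong (long-with-long)
  topology dominates already at 0.5 under this mixture, and the expected
  p-distance algebra shows why: with $\beta \approx 0.75$ the long–long
  pair sum $p(2L{+}0.1) + p(0.15)$ drops below the true pairing's
  $2\,p(L{+}0.05)$ for every $L$ in the scanned range.

These sizes keep the whole validation suite in the minutes range on one
CPU while leaving each statistic far from its decision boundary.

## Experiments module

`run_conditions()` evaluates each focal clade *on its surviving members
only* within each condition — the natural way to compare, say, sponge
monophyly across samplings that keep different sponges. Clades reduced
below 2 survivors (or spanning all but one leaf, where the split is
trivial) are `not_evaluable`; a clade whose split is simply not in the
tree is `absent`; `compare_conditions()` propagates both as labels, never
as numeric zeros. With externally supplied trees the run is pure
bookkeeping and bit-stable. `outgroup_series()` builds one condition per
near-to-far prefix of the outgroup groups, which is how "does adding the
distant outgroup destabilize the ingroup?" is asked operationally.

## Numerical conventions and degenerate inputs

* Supports are stored on the 0–100 scale; inputs on [0, 1] are rescaled
  with a warning. Missing branch lengths parse to 0 with a warning;
  negative ones are errors; zero-length edges are legal (star-like
  scenarios need them).
* Partition tables are 1-based inclusive, non-overlapping, covering.
* Splits are canonically keyed by the side containing the
  lexicographically smallest taxon, so set comparisons are string
  comparisons.
* `mask_missing()` never touches already-missing cells, errors when asked
  to go *below* the current fraction, and lands within one masking unit of
  the target.
* The alphabet validator is strict (residues + `-?NX` only); ambiguity
  codes must be recoded upstream. This is a deliberate trade of
  convenience for the guarantee that every downstream count is exact.

## Known limitations

The engine is distance-based: its trees are a stand-in for, not a
replacement of, likelihood or Bayesian inference, and bootstrap values on
distance trees are typically conservative relative to ML bootstraps on
the same data. The congruence screen inherits the reference tree's
errors — a wrong reference manufactures "conflicts" in perfectly clean
genes. The saturation slope summarizes a cloud by one number; strongly
heterogeneous pair sets (e.g. dense ingroup + one distant outgroup) can
hide distinct regimes inside one slope, which is why the per-partition
and restricted-taxa workflows exist.
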