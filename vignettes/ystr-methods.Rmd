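---
title: "Y-STR haplotype statistics, R_ST structure and simulation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Y-STR haplotype statistics, R_ST structure and simulation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystrkit)
```

This vignette documents the statistical methods, numerical conventions
and design decisions behind `ystrkit`. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The data model

A Y-STR haplotype is the joint allele profile of one male over a panel
of loci. Alleles are repeat counts, but real typing data contain three
further states that the model must carry rather than discard:

* **intermediate alleles** such as `34.1` — 34 full repeats plus a
  partial repeat. The value sorts between 34 and 35 and enters distance
  computations as the decimal 34.1. Repeat sizes are stored internally
  in tenths of a repeat (integers divided by 10), so `34.1` is exact and
  no binary floating-point artefact can reorder alleles or split
  frequency classes. Forensic nomenclature is decimal; tenths cover it.
* **null alleles** — no amplification product. The token `null`
  (case-insensitive on read, lowercase on write) is a distinct allele
  class: it matches only null in haplotype comparison and forms its own
  frequency class.
* **duplication variants** — two peaks at a normally single-copy locus.
  Serialized `a,b` ascending (hyphen accepted on read; the comma dialect
  is canonical because a hyphen could not coexist with decimal points in
  some tools' exports). Stored as a sorted multiset, so `13,14` and
  `14,13` are the same call.

The genuinely multi-copy locus DYS385ab holds an unordered pair as a
matter of biology, not anomaly; it is flagged per panel
(`multi_copy`) and its pair is compared as a sorted multiset.

The five built-in panels follow the standard kit definitions and are
strictly nested. Marker counts (9, 12, 17, 23, 26) count DYS385ab as two
markers, as kit vendors do; the locus *lists* store it as one entry.
DYS389II is stored exactly as the kit reports it, with no subtraction of
DYS389I — no published transformation justifies altering typed values.

## Forensic estimators

With allele-class counts $c_i$ at a locus, $n_{obs} = \sum_i c_i$ allele
copies and $P_i = c_i / n_{obs}$:

$$GD = \frac{n\,(1 - \sum_i P_i^2)}{n - 1}$$

where $n$ is the **number of sampled males**, not the number of allele
copies. The two differ only when a duplication inflates the copy count
(e.g. 101 copies from 100 males) or at a multi-copy locus (186 copies
from 100 males after anomalies). This convention is a deliberate design
decision: applied to the packaged 26-locus frequency table it reproduces
the published per-locus diversity values at 24 of 25 loci to all four
printed decimals, including the duplication-inflated locus DYS19
(0.7163) and the multi-copy DYS385ab (0.8763), neither of which is
reproduced by using the copy count as $n$. The single exception, DYS449
(computed 0.8468 vs printed 0.8472), is not reproducible under either
convention and its published computation is undocumented; the test suite
asserts the 24 reproducible loci and the discrepancy is left visible.

Null alleles are a frequency class like any other, and every copy of a
duplication counts — both choices validated the same way.

Haplotype-level parameters use the spectrum of haplotype counts after
projection to a panel ($k$ distinct, $u$ singletons, $n$ males):
HD is the same estimator on haplotype frequencies, $MP = \sum_i p_i^2$,
$DC = k/n$, $PUH = u/n$. The identity
$HD = \frac{n}{n-1}(1 - MP)$ holds exactly and is asserted to $10^{-12}$.

The standard error attached to HD is the square root of Nei's (1987)
sampling variance of the diversity estimator:

$$V(\hat H) = \frac{2}{n(n-1)}\Big[2(n-2)\big(\textstyle\sum p_i^3 -
(\sum p_i^2)^2\big) + \sum p_i^2 - (\sum p_i^2)^2\Big]$$

Published forensic tables print HD ± SE without stating a formula, and
the printed SEs are *not* reproduced by this estimator (an all-singleton
spectrum of 100 gives ≈ 0.0015 where 0.0001 is printed); the SE column
is therefore reported for completeness but excluded from acceptance
checks. Report tables round half away from zero at 4 decimals, matching
printed-table conventions; `digits = NULL` disables rounding.

## R_ST and AMOVA

The molecular distance between two haplotypes is the sum over included
single-copy loci of the squared repeat-size difference — the natural
metric under the stepwise mutation model, and the convention behind
R_ST. Policy decisions, each exposed as a flag:

* loci where either call is null or duplicated are skipped for that pair
  (pairwise deletion) with **no renormalization** — the additive SSD
  framework has no place for rescaling;
* DYS385ab is excluded by default (no unambiguous pairing of the two
  copies); an optional policy pairs sorted values and sums both squared
  differences;
* intermediate alleles contribute their decimal size.

The two-level AMOVA computes, for $N$ individuals in $P$ populations,
$SSD_{total}$ and $SSD_{within}$ (the SSD of a group is the sum of its
pairwise squared distances divided by group size), mean squares from
$df_{among} = P-1$ and $df_{within} = N-P$, and solves the moment
equations: $\sigma^2_w = MSD_w$,
$\sigma^2_a = (MSD_a - MSD_w)/\bar n$ with
$\bar n = (N - \sum_j n_j^2/N)/(P-1)$. Then
$\Phi = R_{ST} = \sigma^2_a / (\sigma^2_a + \sigma^2_w)$. Negative
estimates are reported as computed — published pairwise tables print
negatives and clamping is a display decision, not an estimation one.
When every distance is zero, $\Phi$ is defined as 0. The three-level
decomposition (among groups / among populations within groups / within)
uses the standard coefficients and reports $\Phi_{CT}, \Phi_{SC},
\Phi_{ST}$; a single group falls back to the two-level analysis with a
warning.

Permutation significance reassigns individuals to populations (sizes
preserved; whole populations to groups for $\Phi_{CT}$) and uses the
add-one estimator $p = (1 + \#\{\Phi^* \ge \Phi\})/(B+1)$ with a stated
integer seed, default $B = 10{,}000$. Note that when the observed
statistic is at its maximum (complete separation), permutations that
recreate the exact partition also attain it, so the smallest achievable
p is not $1/(B+1)$ in expectation — the tests account for this.

The implementation is verified against a brute-force oracle that
enumerates all pairwise distances with explicit loops and solves the
moment equations directly, on instances of up to 10 individuals, to
$10^{-9}$, and the decomposition's additivity, shift/scale invariance
($\Phi$ unchanged when all sizes at a locus are shifted by a constant or
multiplied by $c$) are asserted as properties.

## Ordination and phylogeny

**MDS** is classical Torgerson scaling: $B = -\frac12 J D^{(2)} J$,
coordinates from the top-$k$ eigenvectors scaled by the square roots of
non-negative eigenvalues. Negative input entries (possible for R_ST) are
clamped to zero before squaring; negative eigenvalues (non-Euclidean
input) contribute zero-filled dimensions and are reported. The published
ordinations were made with an online tool whose algorithm is
unspecified, so coordinates are comparable only up to
rotation/reflection/scale; correctness is asserted on *recovered
distances* (planar configurations reproduce their distance matrices to
$10^{-9}$, cross-checked against `stats::cmdscale`). $k$ defaults to 2,
matching conventional two-dimensional plots.

**Neighbor joining** implements Saitou–Nei agglomeration with the
$Q$-matrix criterion and standard branch-length formulas. Ties in $Q$
are broken by the lexicographically smallest pair of cluster
representative labels (the smallest leaf label in each cluster), making
output deterministic across platforms. Negative branch lengths are kept
by default; `clamp = TRUE` zeroes a negative join branch and transfers
the deficit to its sister so paths through the joined node are
preserved (the standard workaround). Additive matrices are recovered
exactly (topology and branch lengths, $10^{-9}$) and random matrices
agree with `ape::nj`. Newick output uses 15 significant digits — the
default 10 would break the $10^{-12}$ round-trip contract.

## Linear discriminant analysis

The marker-exclusion rule mirrors mixed-kit practice: multi-copy
markers (DYS385ab, and the DYS389 pair, whose second fragment contains
the first) are excluded structurally; any locus with null or duplicated
calls in **more than one** sample across all populations is excluded,
while a single anomalous sample does not disqualify a locus. Applied to
a fixture encoding the published anomaly census, the rule returns
exactly the published nine-marker list — including the retention of
DYS448 (one null) and of Y_GATA_H4, whose single null proved to be a
technical artefact. The truncated name "Y_GATA_H" in the published
marker list is read as Y_GATA_H4; the package flags this reading here
rather than assuming it silently elsewhere.

LDA solves the generalized eigenproblem of between-class versus pooled
within-class scatter of raw allele sizes (intermediate alleles as
decimals, no dummy coding — sizes are ordinal, consistent with R_ST).
The solve whitens with a Cholesky factor of $W$; the independent test
oracle computes `eigen(solve(W) %*% B)` directly. At most
$\min(m, g-1)$ factors are kept; percent discrimination is each
eigenvalue over their sum, summing to 100. Determinism: each axis is
signed so the first marker's loading is non-negative. A singular $W$ is
ridge-regularized with $\lambda = 10^{-8}\,\mathrm{tr}(W)/m$ and a
warning. Samples with anomalies at retained markers are dropped listwise
with a logged count (published methods are silent on this; listwise
deletion is the simplest defensible choice). Whether variables should be
standardized first is unstated in the published analysis; the default is
raw sizes with `standardize = TRUE` available. Marker–factor
correlations are plain Pearson correlations of allele sizes with factor
scores; zero-variance markers yield `NA`.

## The simulator: the stated world

The generator exists to give every analysis stage a testable input with
the right statistical structure, not to be demographically realistic.

* **Model**: forward simulation of independent lineages. Founders evolve
  from a common ancestral haplotype along a population tree; each
  sampled lineage then evolves independently for `within` generations.
  Mutation is symmetric single-step (±1 repeat, fair coin) per locus per
  generation with a reflecting floor at one repeat; multi-step mutations
  are not modeled.
* **Defaults**: mutation rate 0.002 per locus per generation (the
  accepted order of magnitude for Y-STR average mutation rates),
  divergence 300 generations, within-population depth 100 generations,
  ancestral allele 14 repeats (a typical modal Y-STR allele). These
  values were chosen once as a realistic forensic scenario and are not
  tuned to test outcomes.
* **Admixture** copies each of $n$ haplotypes from a random member of
  source A with probability $\alpha$, else from B — a one-generation
  hybrid gene pool.
* **Anomaly injection** converts calls to null / duplication /
  intermediate independently per (sample, locus) at stated rates, so the
  expected anomaly count is $n \times L \times$ rate; the distributional
  test calibrates to the observed forensic burden of 5 anomalies per
  100 × 26 typings.
* **Marginal resampling** draws each locus independently from published
  allele frequencies. This *destroys haplotype linkage by construction*:
  per-locus statistics converge to the inputs (asserted), but
  haplotype-level parameters of a resample are meaningless as estimates
  of the real population's HD/MP/DC and are never compared to published
  haplotype tables.

What a green simulation test establishes: that the estimators recover
the ordering and qualitative geometry they claim (divergence raises
R_ST monotonically; a 50/50 admixed population falls between its
sources on NJ paths and the first MDS axis in ≥ 90% of seeded
replicates). What it does not establish: calibration against any real
demographic history, coalescent variance structure, linkage between
loci on real Y chromosomes, or mutation-rate heterogeneity across loci.

## Numerical conventions and degenerate inputs

* Allele sizes: exact tenths of a repeat; canonical serialization via
  integer formatting (no `%f` artefacts).
* Report rounding: half away from zero at 4 decimals, display only.
* Estimators requiring $n \ge 2$ raise explicit errors below that.
* Empty comparisons (all loci excluded for a pair) raise an error naming
  both samples rather than returning 0.
* All stochastic entry points take an integer `seed`; equal seeds give
  byte-identical outputs (asserted for the simulator's tables).
* The permutation p-value can never be 0 (add-one estimator).

## Known limitations

* Published pairwise R_ST tables, MDS plots, LDA percentages and the
  grouped-AMOVA p-value cannot be reproduced without the external
  reference datasets (≈ 7,700 haplotypes from 23 populations) that are
  not deposited; the acceptance suite substitutes oracle-verified
  properties for these.
* The SE printed next to published HD values comes from an unidentified
  estimator; Nei's variance is reported instead and excluded from
  acceptance.
* DYS449's published gene diversity (0.8472) is not reproduced by any
  counting convention examined; the packaged table carries the printed
  frequencies and the discrepancy is documented rather than patched.
* The forward simulator is not a coalescent: within-population allele
  frequency spectra have the variance of independent lineages, not of a
  genealogy. That is adequate for exercising estimators, not for
  demographic inference.
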