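---
title: "Ranking populations for conservation from haplotype data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking populations for conservation from haplotype data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapconserv)
```

## The problem

Given aligned haploid sequences (here, mitochondrial control-region
fragments) sampled from several populations of one species complex, which
populations should a conservation program protect first? Single diversity
indices give conflicting answers: haplotype diversity Hd measures the
evenness and abundance of haplotypes, while nucleotide diversity Pi and
the mean pairwise difference count K measure how *different* those
haplotypes are. A population can rank high on one and low on another.
`hapconserv` implements two models that each collapse the evidence into
one ranking, plus the haplotype-level statistics they consume.

## Statistics panel

All statistics are computed on the *used columns*: under the
`complete_deletion` policy (the only one implemented, and the default of
the classic DnaSP workflow) every alignment column containing a gap `-`
or an ambiguous `N` in any sequence is dropped, so haplotype identity,
site classification and distances all refer to one consistent site set.
Columns are 1-based in every user-facing report.

Per population the panel holds: sample size S; haplotype count H
(sequences identical on the used columns collapse to one haplotype);
polymorphic sites Nps, split into parsimony-informative sites Pis (at
least two residues each carried by at least two sequences) and singleton
variable sites Svs (all other polymorphic sites, i.e. at most one residue
reaches two copies). This is the MEGA-style partition, so
`Nps = Svs + Pis` holds identically — including at three-allele columns
such as (A, A, G, C), which count as singletons. Hd uses Nei's unbiased
estimator `n/(n-1) * (1 - sum p_i^2)` (standard error per Nei 1987);
K is the mean pairwise difference count and `Pi = K / L`. A population
with a single sequence is reported as zeros with a `degenerate` flag
rather than dropped, so tables keep their shape.

Between populations the package reports uncorrected per-site p-distances
(mean over all between-population pairs, i.e. Dxy; within-population
means on the diagonal). Distance correction models (e.g. K2P) belong to
tree building, which is out of scope here — clades enter as *input*.
Differentiation is the Hudson-type pairwise `Fst = 1 - Hw/Hb` with Hw the
mean of the two within-population mean pairwise difference counts and Hb
the between-population mean. Gene flow uses the island-model convention
`Nm = (1 - Fst)/(4 Fst)`; it is a convention, not an estimate with
confidence — negative or zero Fst yields a flagged infinite Nm, and small
negative Fst estimates are reported as computed, flagged, never clamped.

## Model 1: composite diversity score

Across populations Hd, Pi and K are strongly positively correlated
(`correlation_screen()` reports Pearson r with two-sided t-tests on n−2
degrees of freedom, flagged at the 0.01 level). That justifies a
one-dimensional summary. The score is principal-component based:

1. standardize each index over populations (mean 0, sample variance 1,
   n−1 denominator);
2. eigendecompose the 3×3 *correlation* matrix (not the covariance — the
   indices live on wildly different scales: Pi is O(0.01), K is O(10));
3. take the unit-norm eigenvector `v` of the leading eigenvalue λ₁,
   oriented so `Σv > 0` (the sign of an eigenvector is arbitrary; this
   convention makes "more diverse" mean "higher score" whenever the
   indices are positively correlated, and falls back to "first nonzero
   loading positive" if the loadings sum to zero);
4. score `Fz(F1)_p = z_p · v`.

The scores are exactly zero-mean with sample variance λ₁, and
`100·λ₁/3` is the variance explained. Only the first component is
extracted; the remaining eigenvalues are kept for diagnostics. The score
is deliberately the plain projection `z·v` — not divided by √λ₁ and not
a regression-method factor score; on the bundled eight-population panel
this convention reproduces the reference scores (2.456 for the top
population, −2.188 for the bottom) and the 81.5% variance share, which is
how the convention was fixed. A leading eigenvalue with multiplicity
above one leaves the axis unidentified and is an error, as is any
constant index column; at least 3 populations are required.

```{r score}
cs <- composite_score(gymnocypris_diversity())
cs
rank_by_score(cs)
```

## Model 2: genetic-contribution decomposition

The composite score treats every haplotype equally and ignores *which*
population holds the rare ones. The second model decomposes haplotype
richness. Each distinct haplotype carries one unit, split equally among
the `m_h` populations carrying it, giving the total contribution
`R_T(k) = Σ 1/m_h` over the haplotypes present in population k. The
within-population component is the head-count share `R_S(k) = H_k/K`,
and the distinctiveness component is the remainder
`R_D(k) = R_T(k) − R_S(k) ≥ 0`, which grows with private haplotypes.
`Σ_k R_T(k)` always equals the group's distinct-haplotype count.
Contribution rates scale the deviation from the group mean by the summed
haplotype counts, `C_X(k)% = 100 (R_X(k) − mean R_X) / Σ H_j`; they sum
to zero by construction, so a positive `C_RT%` reads "this population
pulls the group's richness above average — a priority".

Only presence/absence enters: the decomposition is invariant to sampling
depth per haplotype, and (for fixed per-population shared-haplotype
multiplicities) to which particular populations are paired by sharing —
both properties are asserted in the tests. Computations use double
precision; the components are sums of reciprocals `1/m_h` with
`m_h ≤ K`, so results are exact to well below the displayed precision
(R at 3 decimals, C% at 4).

With a clade assignment (one clade per haplotype; per-sequence maps are
lifted and must be consistent within a haplotype) the decomposition is
repeated inside each clade, with populations holding none of the clade's
haplotypes removed first, shrinking K. A clade held by a single
population is reported descriptively: its rates would compare the
population with itself, so they are `NA` rather than 0, and the
population is flagged as the trivial priority.

```{r contrib}
g   <- generate_alignment(fixture_clade_A())
inc <- collapse_haplotypes(g$alignment, g$pops)
display_table(contribution_analysis(inc)$overall)
```

## Synthetic data generator

Real multi-population data sets are large and cannot ship with a
package; the generator makes every statistic testable offline.
A `synthetic_config()` pins the haplotype incidence *exactly*: the
carrier populations and copy counts of every haplotype. Realization
draws one random ancestral sequence and derives haplotype *i* by
substituting a dedicated block of `min_pairwise_differences` positions —
disjoint blocks per haplotype, so any two haplotypes differ at both
their blocks and distinctness needs no rejection sampling; generation is
byte-deterministic given the seed. The default length is 656 bp, a
typical control-region fragment. Two fixtures, `fixture_clade_A()`
(7 populations, 48 haplotypes, three of them shared pairwise) and
`fixture_clade_C()` (4 populations, 119 haplotypes, one shared),
reproduce published clade decompositions end-to-end and anchor the
acceptance checks; `random_incidence()` drives the property tests
(carrier sets uniform over non-empty population subsets, copy counts
1 + geometric, capped).

What the generator does *not* emulate: mutational processes (no
transition/transversion structure, no rate heterogeneity), recombination
(none, as for mtDNA), demography, or realistic haplotype frequency
spectra. Passing tests therefore demonstrate the *accounting* — that the
statistics and both models compute what they claim on data with known
truth — not that the models are robust to sequencing error or sampling
bias in real surveys.

## Numerical and design notes

- Population order everywhere is first appearance in the population map;
  ranking ties keep that order.
- The correlation-screen significance test is the standard two-sided
  t-test on r; only the 0.01 flag is surfaced.
- Reference tables computed elsewhere may round intermediates: the
  bundled clade tables' printed rates differ from exact values by up to
  one unit in the fourth decimal, and tests compare at that resolution.
- Pi·L = K holds to machine precision and is asserted, as are the PCA
  trace identity Σλ = 3, zero-mean scores, score variance = λ₁, the
  contribution zero-sums and richness conservation.
- Problem sizes in the shipped test suite: oracle sweeps use up to 30
  sequences × 50 sites (hundreds of instances), invariant sweeps use
  1000 random incidences with up to 6 populations × 40 haplotypes, and
  round-trip checks cover 100+ generator seeds — sizes chosen so the
  brute-force oracles are unarguably correct and the suite stays quick.

## Limitations

- Rarefaction-standardized allelic richness (sample-size-corrected) is
  not implemented; the equal-share decomposition is presence-based.
- Nm is a transform of Fst under island-model assumptions that rarely
  hold; treat it as descriptive.
- The composite score is defined for exactly the three indices (Hd, Pi,
  K); feeding other panels is possible but unvalidated.
- Bootstrap uncertainty for contributions and scores is not provided.
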