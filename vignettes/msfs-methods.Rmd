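---
title: "Methylation site frequency spectra: model, inference, simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation site frequency spectra: model, inference, simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimsfs)
```

## The problem

Cytosine methylation in plant genomes is heritable across generations, and
at CG dinucleotides it changes state spontaneously — gains at a per-site,
per-haploid-genome, per-generation rate μ_UM and losses at μ_MU — several
orders of magnitude faster than DNA mutates. Treating the methylation
state of a CG site as a two-state epiallele (M/U), a sample of n
accessions from a panmictic population carries, at each segregating site,
some number b of unmethylated copies. The counts d(n,b) of sites per class
b = 1..n−1 form the methylation site frequency spectrum (mSFS), the
epigenetic analogue of the site frequency spectrum of population genetics
— except that epimutation is *reversible* and *fast*, so the
infinite-sites machinery of classical SFS theory does not apply and a
reversible-mutation stationary model is used instead.

## The stationary sampling model

`sampling_probability()` implements the stationary distribution of a
Wright–Fisher population with reversible epimutation, drift and genic
selection. With population-scaled rates α = 4Nμ_UM (gain), β = 4Nμ_MU
(loss; bias r = β/α) and selection σ = 2Ns — fitnesses 1+2s, 1+s, 1 for
U/U, M/U, M/M — the probability that b of n sampled epihaplotypes carry U
is

$$ p_{n,b} = \binom{n}{b}
   \frac{F(\beta+b;\,\alpha+\beta+n;\,2\sigma)\,\beta_{(b)}\,\alpha_{(n-b)}}
        {F(\beta;\,\alpha+\beta;\,2\sigma)\,(\alpha+\beta)_{(n)}}, $$

with F Kummer's confluent hypergeometric function and $d_{(j)}$ rising
factorials. N and μ enter only through their products: they cannot be
disentangled from a single stationary spectrum, which is why the package
never represents them separately in `pop_params()`.

Monomorphic sites carry no information about segregation, so inference
conditions on segregating sites: $q_{n,b} = p_{n,b}/p_{seg}$,
$p_{seg} = 1 - p_{n,0} - p_{n,n}$, and, assuming independent sites,
$\log L = \sum_b d_{n,b} \log q_{n,b}$ up to a data-only constant.

Numerical choices:

* Every factor is computed in log space (log-gamma differences for rising
  factorials, a log-space series for F) with a single exponentiation at
  the end; at n = 92 with α of order 0.1 the linear-space factors
  underflow long before the ratio does.
* For negative arguments (σ < 0) the Kummer transformation
  F(a;b;z) = e^z F(b−a;b;−z) is applied first, after which all series
  terms are positive and no cancellation occurs. In this model the first
  parameter never exceeds the second, so terms are dominated by z^j/j!
  and the series cannot overflow in double precision over the fitting
  domain. Convergence is declared when a term falls below 1e-16 of the
  running sum (past j > z); a hard cap of 1e5 terms turns pathological
  inputs into errors rather than silent inaccuracy.
* $p_{seg}$ is accumulated as a log-sum-exp over the segregating classes
  rather than as 1 − p₀ − pₙ, which loses precision exactly in the
  small-α regime where almost all mass is monomorphic.
* One notational wrinkle in the source material: the sampling formula is
  printed with both "a" and "α" for the same parameter; the package
  treats this as typographical and uses α throughout.

The series evaluation and the grid likelihood are in C++ (Rcpp): the grid
search evaluates ~1.3e4 parameter triples × (n+1) hypergeometric series
per refinement round, which is seconds in C++ and minutes in pure R.

## Maximum-likelihood fitting

The likelihood surface is explored by grid search (`fit_msfs()`), the
estimation strategy the stationary model was published with. Defaults in
`msfs_grid()`: 25 log-spaced α values in [1e-3, 1e2], 25 log-spaced r
values in [1e-2, 1e2], 21 linear σ values in [−10, 10] with 0 included
exactly, then two refinement rounds that re-center each range on the
current optimum and shrink it five-fold. The ranges bracket the
population-scaled values plausible for outcrossing plant panels (α of
order 0.01–10) with two orders of magnitude of margin; the published
source states only that a grid search was used, so resolution and
refinement are this package's own choices, validated by the
parameter-recovery tests.

The neutral model is fitted on the σ = 0 plane with the same procedure,
and model selection is by maximized likelihood — with one necessary
refinement. Because the neutral model is nested inside the selection
model, the σ-free maximum is never lower, and a bare comparison would
declare "selection" on every dataset. The package therefore treats
likelihood gains up to the one-degree-of-freedom likelihood-ratio margin
(qchisq(0.95, 1)/2 ≈ 1.92) as ties, broken toward neutrality and then
toward smaller α (parsimony: at equal fit, prefer the simpler
explanation). The raw Δlog-likelihood and the LRT p-value are always
reported so a caller can apply a different rule. Profile-likelihood
intervals
(`profile_interval()`) are read off the evaluated grid; the source
provides no uncertainty summaries, so these are labelled as the package's
addition.

Fractional counts (from projection, below) are accepted by the
likelihood; multinomial asymptotics then hold only approximately, which
the fit object does not hide — `glance()` reports the effective count.

## From bisulfite calls to an mSFS

`read_cytosine_report()` reads the common per-cytosine TSV (chromosome,
1-based position, strand, context, methylated reads, total reads);
internally all coordinates are 0-based half-open, GFF3 is 1-based
inclusive and BED 0-based half-open, each format on its native
convention. CG sites are strand-collapsed by default
(`collapse_cg_strands()`): CG methylation is maintained symmetrically, so
the two cytosines of a dinucleotide are one epiallele and their reads are
pooled; a flag disables this.

Binarization (`binarize_calls()`) defaults to min_coverage = 3 and an
inclusive methylation-level threshold of 0.5. The filtering used for the
published 92-accession analysis is not reproducible from the main text,
so these defaults are deliberately conservative, configurable, and should
be revisited for real data. Increasing methylated reads at fixed coverage
can never flip a call from M to U (monotonicity), and level exactly at
the threshold is called M.

Missing data policy: the default is complete cases (`"intersection"` in
`assemble_call_matrix()`); the alternative is union assembly followed by
hypergeometric projection (`project_msfs()`) of each site's U-count b out
of k callable accessions down to a common size m, with subsample weights
dhyper(j; b, k−b, m). Projection yields expected (fractional) counts —
standard practice for projected spectra, avoiding stochastic subsampling
noise. Whether the published analysis used complete cases or projection
is not stated; both paths are first-class here.

`build_msfs()` discards monomorphic sites and keeps the accounting
(input sites = segregating + monomorphic + missing-dropped) explicit.
Gene-body methylation classes (`classify_gene_methylation()`) follow the
standard heuristic: BM genes methylate more than 90% of CG sites and
fewer than 5% of CHG and CHH sites (the CHG/CHH condition screens out
TE-like methylation); all-below-5% is UM. Classification is
per-accession; consensus across accessions is left to the caller.

## Simulators and what they emulate

The simulators are both the synthetic-data generators and the independent
oracles for the inference code.

* `simulate_ma_pedigree()` propagates independent selfing lines from one
  founder, one haploid epihaplotype per line — matching the
  per-haploid-genome definition of the rates; diploid dynamics belong to
  the Wright–Fisher simulator. Default rates are the published A.
  thaliana MA-line estimates (`athaliana_rates()`): genome-wide gain
  2.56e-4 / loss 6.3e-4, genes 3.48e-4 / 1.47e-3, TEs 3.24e-4 / 1.2e-5.
* `divergence_curve()` gives the expected pairwise mismatch
  D(t) = 2·π_M·π_U·(1 − λ^{2t}), π_M = μ_UM/(μ_UM+μ_MU),
  λ = 1 − μ_UM − μ_MU. The closed form is derived here (the source states
  only that divergence saturates); it is validated in the test suite
  against exact two-chain matrix-power enumeration and against pedigree
  Monte Carlo before being used as an oracle for anything else. Under the
  genome-wide rates, divergence reaches 99% of its asymptote in
  `log(0.01)/(2*log(lambda))` ≈ 2600 generations; published commentary
  citing an earlier model puts the figure near 4000, and the package
  reports its own closed-form value rather than targeting that number
  (the relaxation-rate convention of the cited model differs by a factor
  of two).
* `simulate_wright_fisher()` evolves 2N copies per site with per-copy
  epimutation followed by selection-weighted binomial resampling, weight
  1+s per U copy — under random mating exactly the 1+2s/1+s/1 diploid
  scheme of the sampling model. Burn-in defaults to
  20/(μ_UM + μ_MU + 1/(2N)) generations, about twenty relaxation times of
  the joint epimutation-drift process from a stationary-frequency start.
  The acceptance suite checks the sampled spectrum against the analytic
  q(n,b) in total variation (< 0.02 at N = 200, 1e5 sites).
* `simulate_msfs_counts()` draws class counts directly from q(n,b) — the
  fast generator for recovery experiments. `simulate_call_matrix()` is
  the end-to-end panel generator (default n = 92 accessions, the
  species-wide sample size of the motivating analysis): stationary-model
  site states including monomorphic sites, negative-binomial coverage
  (mean 20×, size 5 — typical WGBS depth with realistic overdispersion),
  binomial methylated reads around true levels 0.95/0.05 (a conversion-
  error proxy), and 5% missing entries by default.

What the synthetic data do **not** emulate: linkage between sites (the
model assumes independence, and the simulators draw sites independently),
population structure (the model is panmictic), context-dependent CHG/CHH
inheritance (only CG-style two-state dynamics are simulated; context
labels are carried through untouched), region/DMR calling (a two-state
region matrix can be supplied, but calling regions is out of scope), and
locus-specific rate variation beyond the gene/TE/genome-wide classes.
Passing tests therefore demonstrate correctness of the inference
machinery under the model's own assumptions, not robustness to structure,
linkage or rate heterogeneity in real panels.

Reproducibility: each simulator takes a `seed` and restores the caller's
RNG state afterwards; identical seeds give bit-identical outputs. Draws
are vectorized in a fixed order, so reproducibility is per-configuration:
changing `n_sites` reshuffles the stream rather than extending it.

## Problem sizes used in the packaged checks

The test suite and the acceptance script run: pedigree rate recovery at
1e6 sites × 30 generations × 2 lines; bias-parameter recovery from 1e5
segregating sites at n = 92; Wright–Fisher spectrum validation at
N = 200 with 1e5 replicate sites; divergence validation at 2e5 sites.
These sizes put Monte Carlo error well below the tolerances being
asserted (3 binomial/Monte-Carlo standard errors; 10% on r̂; total
variation 0.02) while keeping a full run in the minutes range.

## Known limitations

* The stationary model assumes equilibrium; a bottlenecked or expanding
  population distorts the mSFS in ways the fit will absorb into biased
  α̂, r̂, σ̂. Time-dependent extensions are out of scope.
* α and β are population-scaled; per-generation rates and N are not
  separately identifiable from a stationary spectrum.
* Grid search guarantees only grid-resolution optimality; the two
  refinement rounds make this sub-percent in practice (see the recovery
  tests), but a likelihood surface with multiple ridges at equal height
  would be reported by its parsimony tie-break, not enumerated.
* At n = 2 the conditional spectrum is parameter-free (q ≡ 1), so σ is
  unidentifiable; `fit_msfs()` refuses σ-free fits below n = 3.
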