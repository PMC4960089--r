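---
title: "Detecting within-season selection from paired seedling and seed samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting within-season selection from paired seedling and seed samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In an open-pollinated crop stand (the motivating system is pearl millet in
Sahelian farmers' fields), viability selection acting between seedling
emergence and seed maturity changes allele frequencies at loci that affect
survival and reproduction during the season. Two samples bracket that
window: ~100 genotyped seedlings early in the season and ~100 genotypes from
the bulked seed harvest. The difficulty is that a frequency difference
between the two samples is expected even under neutrality, from two sources:
binomial sampling noise in each sample, and one generation of genetic drift
in a population whose effective size Ne may be only a few hundred. `temposel`
implements an inference chain that separates selection from those two
sources, plus a synthetic-data generator that reproduces the whole study
design with known truth so every stage can be validated.

## The inference chain

**1. Signed frequency change and G-test.** For each candidate ("focal")
biallelic locus, the change `delta = freq(focal allele, seed) −
freq(focal allele, seedling)` is reported with a plain log-likelihood-ratio
G-test on the 2×k allele-count table (`G = 2 Σ O ln(O/E)`, chi-square upper
tail, `df` counting only alleles with a nonzero pooled total, `0·ln 0 = 0`).
No small-sample correction is applied: with ~200 allele draws per stage the
uncorrected statistic is adequate, and calibration is verified by simulation
rather than assumed. Across many sites, the number of nominally significant
tests is judged against the exact binomial upper tail
`P(X ≥ k), X ~ Bin(n_sites, α)` (`binomial_multiplicity()`).

A caveat the package makes explicit: the G-test's null hypothesis is "no
difference beyond *sampling*". When Ne is small, drift alone violates it,
so the G-test over-rejects slightly (at Ne ≈ 300 and n = 100 the variance
inflation is ~17%, pushing the 5% level to ~7%). The G-test is therefore a
descriptive first pass; the decision test is the drift-corrected outlier
test below. Our own G-test calibration check accordingly runs at large Ne,
where the G-test's null actually holds.

**2. Drift-corrected temporal F_ST outlier test.** The differentiation
between the two temporal samples is measured per allele by the two-sample
Weir–Cockerham theta computed from allele counts (each sample treated as a
draw of `2n` alleles; the method-of-moments ANOVA form). The observed theta
of a focal allele is ranked in two neutral reference distributions:

* an *empirical null*: one theta per allele observed at each of nine
  multi-allelic microsatellite loci (~173 alleles), scored allele-vs-rest
  with the same estimator and on the same two samples;
* a *simulated null*: 100,000 Wright–Fisher replicates, each drawing an
  initial frequency `p ~ U(0,1)`, one generation of drift
  `p' = Bin(2Ne, p)/(2Ne)`, and binomial samples of `2n₁` and `2n₂` alleles
  from `p` and `p'`; replicates whose pooled sample is monomorphic are
  redrawn so the null always holds exactly `reps` defined values.

The p-value is the rank convention `p = #(null ≥ observed)/N`, reported at
the resolution floor `1/N` (never 0) with a `below_resolution` flag. The
test is one-sided: selection is detected as excess differentiation only.

A note on the null's location: for this two-sample estimator the neutral
expectation after one generation of drift is close to `1/(4Ne)`, not
`1/(2Ne)` — the ANOVA decomposition apportions the single-branch drift
variance between the two samples. The package's tests pin the simulated
null to that analytic location.

**3. Temporal effective size.** Ne is estimated from the microsatellites by
a pseudo-likelihood temporal method: for each segregating allele (scored
against the rest), the likelihood of Ne integrates a uniform prior on the
unknown population frequency and sums the exact one-generation binomial
drift transition,

```
L(Ne) = E_{j ~ BetaBin(2Ne, x1+1, m1−x1+1)} [ Bin(x2; m2, j/(2Ne)) ],
```

where `x1/m1` and `x2/m2` are the allele's counts in the two samples. The
beta-binomial arises in closed form from the uniform prior, so no numerical
quadrature over the frequency is needed; the sum over drift outcomes `j` is
exact when the plausible window is small and strided-with-renormalisation
when `2Ne` is large (the summand is smooth in `j`; the stride error is
orders of magnitude below Monte-Carlo noise anywhere it is used, and is
checked against a brute-force enumeration oracle in the tests). Per-allele
log-likelihoods are added — a pseudo-likelihood, since alleles of one locus
are negatively dependent — and profiled on a logarithmic grid of 50 Ne
values from the sample size to 10⁵. The 95% bounds are the crossings of
−1.92 (half the 95% chi-square(1) quantile) on the relative curve,
interpolated on log Ne. Both samples are treated as drawn independently of
reproduction.

When the sample is much smaller than the true Ne, the information about
large Ne vanishes and the curve goes flat at the top of the grid: the MLE
and upper bound are then unreliable and the estimate is flagged
`upper_unresolved`. The *lower* bound remains informative, and the pipeline
deliberately uses it (the year's smallest lower bound across reference
sites) to parameterise the simulated null: underestimating Ne widens the
null, making the outlier test conservative.

**4. ABC estimation of the selection coefficient.** For loci flagged by the
outlier test, a viability-selection model with dominance assigns fitnesses
`1, 1−hs, 1−s` to genotypes `AA, Aa, aa`, where `a` (frequency `q` at the
seedling stage) is the disfavoured allele. After selection on
Hardy–Weinberg proportions,

```
f(AA) = (1−q)²/D,  f(Aa) = 2q(1−q)(1−hs)/D,  f(aa) = q²(1−s)/D,
D = 2hsq(q−1) + 1 − sq².
```

One simulation draws `s ~ U(0,1)`, applies selection, genotype-level
multinomial drift with `Ne` individuals (no re-pairing of gametes between
the two stages — drift acts on the three genotype classes directly),
and a multinomial sample of `Ns` individuals (with replacement). The draw
is accepted when a chi-square comparison of the simulated and observed
genotype classes has `p ≥ 0.5`; the posterior is the accepted set, reported
as median and 2.5–97.5% quantiles. `q` is taken from the seedling sample
(the model's pre-selection state); `h` is a fixed input, not estimated.
A point-estimate check (`validate_fit()`) simulates the average genotype
frequencies at the posterior median and G-tests the observed counts
against them.

*Chi-square convention.* The comparison is a two-sample (contingency)
chi-square of the 2×3 table of observed and simulated counts, not a
goodness-of-fit of the observation against the simulated frequencies
treated as exact. Both conventions are defensible; we chose the two-sample
form because it credits sampling noise on both sides, which keeps the
posterior honestly wide when the data carry little information about `s`:
at `s_true = 0.02` (Ne = 300, Ns = 100) the acceptance suite checks that
the 95% interval width stays above 0.5, the method's way of admitting
ignorance at weak selection, whereas the goodness-of-fit form shrinks the
interval well below that. Genotype classes absent from both rows are dropped with
the df reduced. Expected counts below 1 do not abort the test; the
acceptance tolerance absorbs the approximation.

The stopping rule (accept 1,000 draws, cap at 10⁶ simulations) is a
package default; an acceptance rate below 10⁻⁴ at the cap raises a
diagnostic error instead of returning a misleading posterior.

## The synthetic study and what it does (not) show

`study_template()` fixes the study conditions: 17 sites × 2 years, 100 + 100
diploid individuals per site-year, true diploid Ne = 300 (inside the
130–400 range such fields display), two focal genes and nine microsatellites
totalling 173 allele labels, microsatellite frequencies drawn once per
site-year from a symmetric Dirichlet(5) so most alleles are actually
observed at n = 100. Fourteen of the 68 site-year × focal-locus
combinations experience selection with `s = 0.9`, `h = 0`, and the
disfavoured allele starting at `q0 = 0.6`; the remainder are neutral at
`q0 = 0.5/0.4`. More selected combinations fall in the first year,
mirroring a design in which selection pressure differs between seasons.

The selected regime was chosen at design time by a power analysis, not
fitted afterwards: at `s = 0.7` with the disfavoured allele at one half,
the outlier test barely clears a majority detection rate even against a
null whose Ne matches the truth (the power property test asserts exactly
that), so a study built there would be uninformative; moving to `s = 0.9`
with the disfavoured allele initially in the majority (`q0 = 0.6`) —
stronger selection against a recessive homozygote with more homozygotes
exposed to it — lifts the end-to-end flag rate above 90% even under the
conservative lower-bound null, as the acceptance run shows. `s = 0.9` is
also inside the range over which the ABC estimator itself is validated.
The flip side is stated plainly: the default study demonstrates detection
of *strong* selection only. Weak selection (`s ≲ 0.3`) at this design
scale is not detectable by any of these tests, and the ABC interval widths
are the package's way of admitting that.

Other deliberate simplifications of the generator: one generation separates
the stages (selection → drift → sample, exactly the generative model the
ABC stage assumes); loci drift independently (markers span different
linkage groups); microsatellite mutation is off (negligible over one
generation); there is no pollen gene flow between fields, no seed import,
and no human selection — `migration_effect()` exists precisely to bound the
first omission. Real data additionally contain genotyping failures (the
reader drops missing calls per locus and reports them), allele-binning
noise, and possibly non-multinomial family structure in the bulked seed
sample; passing tests on the generator say nothing about those.

## Numerical choices and degenerate inputs

* Theta is undefined when the pooled sample is monomorphic; this raises a
  distinct condition class (`temposel_monomorphic_error`) so callers can
  skip such alleles deliberately, as the empirical null and the calibration
  harness do. Simulated-null replicates that land there are redrawn.
* Rank p-values are floored at `1/reps` with `below_resolution = TRUE`.
* The drift sum in the Ne likelihood truncates the beta-binomial window at
  ±12 SD and caps the evaluation points at ~2,000 with renormalisation;
  the enumeration oracle in the tests bounds the error at <10⁻⁶ where
  exact, <10⁻⁴ where strided.
* Ne values entering gamete draws are rounded to integers, never below the
  sample sizes.
* Profile bounds interpolate linearly on log Ne between grid points; if the
  curve never drops 1.92 units below the maximum on the low side, the lower
  bound is reported at the grid floor (the sample size) — it cannot be less.
* ABC with `df = 0` after class dropping accepts only an exact match.
* One master seed derives all per-stage, per-site-year seeds
  deterministically, so pipeline runs are byte-identical and partial reruns
  reproduce.

## Problem sizes used by the test-suite

The recovery and calibration checks run at the study's own design scale
(Ne = 300, 100 + 100 individuals, 173 alleles) with replicate counts chosen
to keep Monte-Carlo error well inside the asserted bands: 1,000+ neutral
site-years for null calibration, 50 replicate site-years for Ne recovery,
20 ABC replicates per true `s`, and one full 17 × 2 study end to end.
Simulated nulls use 10⁵ replicates where a single distribution is shared
and 4,000–5,000 where one is built per site-year.

## Known limitations

* The Ne estimator's point estimate is unusable when `n ≪ Ne` (by design
  only the lower bound is consumed downstream); its pseudo-likelihood
  ignores within-locus dependence among alleles, so the profile interval is
  approximate and is validated by coverage simulation, not theory.
* `h` and `s` are not jointly identifiable from one genotype table; `h` is
  an input.
* A single seed-stage sample of ~100 genotypes after drift at Ne ≈ 300
  carries limited information about `s`: the sampling noise of the
  observation alone propagates to roughly ±0.1 on any unbiased estimate,
  so replicate posterior medians at intermediate `s` scatter accordingly.
  The recovery checks in the acceptance suite measure exactly this
  scatter; tighter estimates need larger samples or larger Ne, as the
  recovery grid shows.
* The outlier test shares one simulated null across loci of a site-year
  only through Ne and the sample sizes; per-locus sample-size differences
  (missing data) are honoured, but linkage between focal loci is not
  modelled.
* All tests assume the two samples come from the same closed population;
  migration, seed import and human selection are out of model.
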