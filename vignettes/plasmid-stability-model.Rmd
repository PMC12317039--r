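---
title: "Modeling low-copy plasmid segregation, stability and competition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling low-copy plasmid segregation, stability and competition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidstab)
```

## Scope and assumptions

`plasmidstab` models the inheritance of up to two low-copy plasmid
variants in a clonally growing bacterial population.  The model tracks
*cell types*: the pair `(i1, i2)` of plasmid copy numbers at cell birth,
bounded by `i1 + i2 <= 2 n_c`.  Its core assumptions are:

* **Deterministic growth.** Every cell divides once per generation; there
  are no population bottlenecks, no generic cell death and no growth-rate
  differences between host types.  The only death process is
  post-segregational killing.
* **Full assortment stochasticity.** Replication, monomerization,
  assortment and killing are modeled with their exact per-division
  probability distributions.
* **Neutral backbones.** The two variants differ only in their stability
  parameters; there is no fitness cost, no resistance-marker asymmetry
  and no conjugative transfer.
* **No heteromultimer fusion** between the two variants: copies of
  different variants never join into a common segregating unit.
* **At most one TA carrier.** Configurations in which both competing
  variants encode a toxin-antitoxin system raise an explicit
  unsupported-configuration error instead of a guessed extension.

## The life cycle

A variant is a probability triplet created with `plasmid_variant()`:

| parameter | meaning | preset value |
|-----------|---------|--------------|
| `p_def` | probability that a newly replicated copy is removed from the segregating pool (unresolved multimers); copies present at birth are never removed | 0.494 (U, P, T, PT) |
| `p_par` | probability that a pair of copies of a partition-carrying variant is actively split one-copy-per-daughter | 0.456 (P, PT) |
| `p_eff` | probability that a daughter which lost every copy of a TA-carrying variant present in its parent is killed | 0.883 (T, PT) |

All three are per-division probabilities (dimensionless, in `[0, 1]`).
The copy-number parameter `n_c` (default 5, matching a measured mean
copy number of about 5.09 for the plasmids these presets describe) sets
the birth-state saturation; cells replicate to `2 n_c` copies before
division.

One generation composes four stages:

1. **Replication (Pólya urn).** Copies are drawn uniformly at random,
   each returned together with its replicate, until the cell holds
   `2 n_c` copies.  The number of replications won by variant 1 follows
   the Pólya–Eggenberger distribution; `replication_pmf()` evaluates it
   in closed form with rising factorials.  A plasmid-free cell stays
   plasmid-free; a homoplasmic cell deterministically fills up with its
   only variant.
2. **Monomerization.** Each new copy of variant `v` survives into the
   segregating pool independently with probability `1 - p_def(v)`.  The
   two variants are depleted independently, each with its own `p_def`;
   the removal acts after the urn has finished (removed copies are not
   re-replicated).
3. **Division.** For a partition-carrying variant with pool `J`,
   `floor(J / 2)` pairs form *within* the variant (no cross-variant
   pairing, since the pairing count is attached to the variant-specific
   pool).  A Binomial(`floor(J/2)`, `p_par`) number of pairs is split one
   copy per daughter; everything else — the copies of failed pairs plus
   the odd unpaired copy — is assorted to the daughters by independent
   fair coin flips.  We group the failed-pair copies with the unpaired
   copy because both are simply "not successfully partitioned"; the
   marginal pmf is implemented by conditioning on the number of split
   pairs.  Without a partition system this reduces to Binomial(`J`,
   1/2).  The two daughters are exchangeable: one daughter's copy pair
   determines its sister's.
4. **Post-segregational killing.** A daughter whose count of a
   TA-carrying variant dropped to zero while its parent carried that
   variant survives with probability `1 - p_eff`, regardless of the
   other variant's fate — carrying the competitor does not protect
   against the toxin.

`build_kernel()` composes the three distributions by exact summation over
the intermediate copy-number lattice (supports are at most
`(2 n_c + 1)^2`), then applies the survival factor:
`A[j, i] = 2 p(i -> j) p_surv(i -> j)` is the expected number of
surviving `j`-type daughters per dividing `i`-type cell.  No Monte-Carlo
enters the kernel.  With `n_c = 5` the state space has 66 states and a
kernel builds in well under a second.

### Numerical conventions

* States are ordered lexicographically by `(i1 + i2, i1)`; the layout is
  stable and recorded in every export.
* Probabilities are kept in linear space; at this scale (supports of a
  few dozen, probabilities down to `2^-10`) log-space arithmetic is
  unnecessary.  Probability tables are validated to sum to 1 within
  `1e-12`.
* For a TA-free configuration every kernel column sums to exactly 2 (two
  daughters, no death); with a TA carrier, columns of carrier parents sum
  to less than 2.

## Propagation, persistence and competition

`propagate()` iterates `x(g+1) = A x(g) / |A x(g)|` with the entry-sum
(L1) norm — the natural norm for proportion vectors.  Renormalizing every
generation is algebraically identical to normalizing `A^g x0` once at the
end, but keeps all magnitudes near 1 for any horizon (entries of `A^g`
grow like `2^g`).

`persistence()` starts from a single-copy homoplasmic founder `(1, 0)`
and reports the host curve `h(g) = 1 -` (plasmid-free proportion).  The
**half-life** is where `h` crosses 0.5: log-linear interpolation between
the bracketing integer generations, rounded half-up to an integer.  If
`h(g_max) > 0.5` the summary says so (`reached = FALSE`) instead of
raising an error.

Two conventions deserve comment, because they matter at the level of a
few generations:

* **Founder choice.** Starting from `(1, 0)` includes an early transient:
  a single-copy founder replicates through a pool with `2 n_c - 1` *new*
  copies, so its first divisions lose slightly more plasmids than the
  quasi-stationary host population does.  For an exponentially decaying
  variant the transient-free value would be `ln(0.5) / ln(1 - r/2)`
  (709.4 for the stable preset, 43.2 for U, 169.7 for P); the
  founder-`(1,0)` curve crosses 0.5 a few generations earlier (41.6 for
  U, 166.9 for P).  The package consistently reports the curve crossing
  from founder `(1, 0)`; the asymptotic value can always be obtained
  from `asymptotic_seg_rate()`.
* **Rounding.** Nearest-integer (half-up) rounding of the interpolated
  crossing.

`asymptotic_seg_rate()` computes `r = 2 - lambda` with `lambda` the
dominant eigenvalue of the host-to-host block (states with `i1 > 0`,
`i2 = 0`), by power iteration from a uniform start vector (relative
tolerance `1e-12`, at most `1e5` iterations; the block is primitive, so
the iteration converges and is cross-checked against a dense
eigendecomposition in the tests).  Killing only affects transitions into
the plasmid-free state, so a TA system leaves the host block — and hence
`r` — untouched: the host curves of the T and U presets decay at the
same asymptotic rate even though their half-lives differ by roughly 100
generations.  The per-generation decay *factors* of the two curves
converge like `h_T(g)` itself (the killing term in the population-growth
normalization is proportional to the remaining host fraction), reaching
`~2e-4` around generation 400 and `1e-6` only beyond ~900 generations.

`compete()` starts from the heteroplasmic founder `(1, 1)` and scans the
difference between the two homoplasmic-host proportions.  Generation 0
ties (both classes empty) are ignored; the crossing is the first integer
generation at or after the sign change.  Heteroplasmic cells are
transient in every preset pairing — they fall below 10% of the
population within 7–11 generations (the slowest decline is the PT-vs-S
pairing, which crosses 10% at generation 11 because killing removes both
plasmid-free cells *and* nascent homoplasmic-S cells).

## The Monte-Carlo oracle

`simulate_divisions()` replays the life cycle event by event — sequential
urn draws, per-replicate removal flips, pair-splitting flips, fair coin
assortment, survival flips — without using any kernel quantity, and
`oracle_check()` compares the resulting daughter-state frequencies
against `p(i -> j) p_surv` with a chi-squared goodness-of-fit test
(categories pooled to keep expected counts at 5 or more).
`simulate_population()` grows whole populations with a subsampling cap
(default `1e5` cells): once the doubling population exceeds the cap it
is multinomially subsampled, which keeps class frequencies unbiased; the
reported `se` is the per-generation binomial error, and the cumulative
Monte-Carlo error under the cap grows like `se * sqrt(generations)`.
All functions accept an explicit seed and are bit-reproducible given it;
randomness goes through R's global generator, seeded on entry.

## Synthetic persistence data and calibration

`generate_persistence()` emulates a serial-transfer stability
experiment: per variant and replicate, the *true* host fraction at
transfer `t` is the deterministic `h(g_t)` with
`g_t = t log2(dilution_factor)` (6.64 generations per 1:100 transfer),
and the observed host-positive count among `plating_n` colonies is a
Binomial(`plating_n`, `h`) draw — plating is the only noise source.  The
defaults (8 replicates, 5 transfers, 1:100 dilution, 100 colonies)
mirror the stability experiments that motivated the presets; with these
defaults the unstable preset loses on average about 8–9 percentage
points of hosts per transfer and the stable preset well under 1%.  An
optional beta-binomial overdispersion factor adds between-replicate
variance; the default is pure binomial because replicate-level variance
beyond plating noise is not separately identified in such designs.  The
generator does **not** emulate colony-picking hierarchies, marker
effects, fitness costs, heteromultimer formation, or drift in the
regrowing culture itself (regrowth is treated as deterministic), so
parameter-recovery results certify the estimator under the model's own
noise assumptions, not under every feature of real data.

`fit_parameter()` maximizes the binomial likelihood of the colony counts
against `h(g)` over a single free parameter on `[0, 1]`
(`stats::optimize`, absolute tolerance `1e-6`; non-integer generations
are handled by log-linear interpolation of the host curve, and the
single-plasmid chain is evaluated on the reduced 11-state homoplasmic
space, which agrees with the full kernel to machine precision).  The
calibration is sequential: `p_def` first from the unstable variant's
data, then `p_par` and `p_eff` from the partition and TA variants with
`p_def` held fixed — each parameter is identified by the variant whose
phenotype isolates it.  Degenerate data (no observed loss) produce a
flagged boundary estimate rather than an error.

Confidence intervals come from a nonparametric bootstrap over
*replicates* (not colonies), the replicate being the independent
experimental unit.  Each resample is re-estimated on a 401-point
likelihood grid with local quadratic refinement — the aggregated
per-transfer counts make this a single matrix product per resample, so
1000 resamples cost about as much as one exact fit.  The default
interval is `estimate ± t(df = replicates - 1) * SE`, where `SE` is the
bootstrap standard deviation corrected by the textbook
`sqrt(n / (n - 1))` small-sample factor for cluster bootstraps; with
5–8 replicates the plain percentile interval (available via
`ci_method = "percentile"`) noticeably under-covers, while the
t-interval stays near nominal coverage.  The test suite verifies this
operationally: 50 seeded recovery rounds per parameter at the default
design require the 95% interval to cover the generating value at least
90% of the time.

## Problem sizes used by the tests

The suite builds kernels at `n_c` 1–6, verifies the replication pmf
against exhaustive urn-path enumeration at small `n_c`, compares
Monte-Carlo daughter frequencies at `1e5` divisions per parent state
across all five presets, propagates persistence curves to 1000–1500
generations, and runs the 50-round recovery experiment at the default
synthetic design.  These sizes keep every check exact or
sampling-error-dominated while the whole suite runs in a few minutes.

## Known limitations

* Only two variants per cell; no three-way competitions.
* The both-variants-TA case is deliberately unsupported.
* Host fitness effects, conjugation and copy-number evolution are out of
  scope; `n_c` is a fixed input, not estimated from persistence data.
* Crossing generations and half-lives are reported at integer
  resolution; conclusions at sub-generation resolution should use the
  continuous values (`half_life_continuous`) directly.
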