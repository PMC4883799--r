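---
title: "Models and methods behind ibdgeo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ibdgeo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

ibdgeo studies recent demography in admixed, geographically structured
populations from two signals: identity-by-descent (IBD) segments shared
between pairs of individuals, and the lengths of local-ancestry tracts
within individuals. This vignette describes the models, their assumptions,
the numerical choices, and what the synthetic-data generators do and do not
emulate. Every empirical statement here is computed by the package's test
suite or analysis scripts.

## IBD segment filtering

IBD callers over-report sharing around assembly gaps and structural
variants, producing loci overlapped by orders of magnitude more segments
than the genome-wide average. `detect_forbidden_regions()` counts, on a
regular genetic-coordinate grid (default step 0.05 cM — a computable
surrogate for "every position"; the exact resolution is configurable and
logged), the number of segments overlapping each grid point, marks points
whose count exceeds a threshold (default 25,000, roughly 5/3 of a typical
genome-wide mean of 15,000; an automatic mode applies that multiplier to the
observed mean), and merges flagged intervals closer than 0.1 cM.
`filter_by_forbidden()` removes segments overlapping a forbidden region
unless their largest contiguous extent outside the forbidden union is at
least 3 cM — long genuine segments spanning a troublesome locus carry enough
independent evidence to keep. The one-sided reading of the flank rule (one
sufficient flank, measured as maximal contiguous extent) is a deliberate
choice, logged by the filter; requiring both flanks would be stricter than
the stated rationale supports. Filtering is idempotent.

## Pairwise, regional, and distance-binned relatedness

Relatedness between two individuals is the total genome length shared
through IBD segments within a length window; the defaults are the three
windows [3, 10), [10, 18), [18, Inf) cM, with long segments (18 cM or more,
expected common ancestor within about 8 generations) the most informative
about recent history. `build_relatedness_matrices()` produces the pairwise
total-length matrix L and count matrix N, zeroes the diagonal (self-IBD) and
all pairs on a close-relative exclusion list (kinship coefficient of 0.1 or
more in the intended application). Regional relatedness divides the summed
L over relevant pairs by the number of *possible* pairs — n1·n2 between
distinct strata, n1(n1−1)/2 within one — and suppresses estimates based on
fewer than a configurable number of possible pairs (10,000 in the intended
display use), since such cells are noise-dominated.

`distance_decay_curve()` assigns each unordered pair to a kilometre bin by
the Euclidean distance between km-projected sampling coordinates (the map
projection is the caller's responsibility). The default bins
[0,1), [1,101), [101,201), ... put same-location pairs in the first bin;
bin means are reported at midpoints (51 km for [1,101)). Empty bins are
flagged `NA`, never zero-filled.

## The diffusion–coalescent isolation-by-distance model

Parent–offspring displacement is modelled as an isotropic planar random
walk, giving the lineage kernel
φ(x, t|x₀) = exp(−|x−x₀|²/4Dt)/(4πDt) with diffusion constant D
(km²/generation). Convolving two kernels and applying the local coalescence
rate 1/(2n dA) — n is the effective *diploid* density, so a deme of area dA
holds 2n dA haploids; the literature uses both haploid and diploid density
conventions, and we fix the one that makes the coalescence rate
1/(2n dA) — yields the pair coalescence-time density

p(t|R) = exp(−R²/8Dt) / (16πnDt).

Conditional on coalescence at t, the length of the IBD segment spanning a
locus is length-biased exponential, p(l|t) = (2t)² l exp(−2tl) (l in
Morgans). The expected fraction of genome shared through segments with
length in [l_min, l_max] follows by double integration; substituting
u = R√(l/D) and using ∫u K₂(u) du = −u K₁(u) − 2K₀(u) gives the closed form

E[f|R] = [2K₀(R/r_min) − 2K₀(R/r_max) + (R/r_min)K₁(R/r_min)
          − (R/r_max)K₁(R/r_max)] / (16πnD),

with r_i = √(D/l_i) and K_α the modified Bessel function of the second
kind. Printed renderings of this closed form are easy to garble
typographically, so the implementation is *defined* by the double integral: the
closed form is gated in the tests by an adaptive-quadrature oracle of the
defining integral (agreement to 1e-6 relative over a 108-point grid in n,
D, window and R) and by the small-R limit log(l_max/l_min)/(16πnD). Total
expected sharing sums 2 L_c E[f|R] over chromosomes with the window capped
at each chromosome length, plus a distance-independent background b (cM)
capturing IBD-calling false positives and pre-colonial coancestry. The
per-generation mobility implied by a fit is the RMS displacement √(4D).

`fit_decay()` minimizes weighted least squares (weights 1/SE², unit weights
if SEs are absent) between binned means and the model, on the linear scale
by default (the log scale is available behind a flag; the linear objective
is the default because the SEs are computed on that scale). Initialization
scans logarithmic grids n ∈ [0.1, 100] km⁻², D ∈ [1, 1000] km²/gen with the
background profiled out in closed form, then refines by Nelder–Mead on
(log n, log D, b); everything is deterministic. With (n, D) held fixed only
b is refit — the cross-window prediction mode.

### Finite-genome correction

The infinite-genome p(l|t) overstates long-segment sharing on short
chromosomes. Viewing a chromosome as a length-L_c window onto the
stationary segment process (breakpoints Poisson with rate 2t), the expected
shared fraction in segments of observed length ≥ l_min has the closed form
e^(−2t·l_min) (1 + 2t·l_min(1 − l_min/L_c)), which reduces to the familiar
e^(−2tl)(1+2tl) tail as L_c → ∞. `finite_genome_ibd()` integrates this
against p(t|R) numerically from t_min (default 1, excluding the unphysical
continuous-time region t < 1). Refitting a curve generated by the
infinite-genome model with the corrected model lowers the fitted density by
roughly 15% while the model still reproduces the curve — the correction
mostly re-labels parameters rather than changing fit quality; the tests
assert the direction of the density shift only, because the exact split
between n and D along their ridge depends on the sampling design.

### Expected TMRCA given segment length

With an exponential coalescence prior p(g) = e^(−g/N)/N, the posterior of
the MRCA time given a spanning segment of length l Morgans is
Gamma(3, 2l + 1/N); its mean 3/(2l + 1/N) is the implementation. The gap to
the large-N limit 3/(2l) is exactly 1/(2lN + 1) — note the scale is 1/(2lN),
not 1/N, which matters for short segments; the tests assert the exact
relation. An 18 cM segment implies an expected common ancestor about 8.3
generations back.

## Census-based relatedness and the element-permutation Mantel test

Census microdata give weighted counts m_ij of migration-active adults (ages
20–30 by default) observed in region j having been born in region i, pooled
into generations by a 30-year generation time (census years 1900–1920 →
generation 3, 1930–1950 → 2, 1960–1980 → 1). Column-normalizing by total
inbound *including* external immigration gives P^(g), the probability that
the ancestor of a resident of j one generation up lived in i (columns sum
to ≤ 1; the deficit is external origin). Composing P̄ = P^(3)P^(2)P^(1)
accumulates all three-generation routes; a single-generation analysis (by
region of birth) uses P^(3) alone. Under pre-migration random mating at
constant regional sizes N_k, expected recent coancestry between regions i
and j is I_ij = Σ_k P̄_ki P̄_kj / N_k — symmetric, and directly comparable
with the genomic regional matrix.

The significance test permutes the *elements* of one matrix (not rows and
columns jointly, as the classical Mantel convention would; the classical
variant is available behind a flag for comparison, and a 3×3 south-by-north
block selection is declarative, not hard-coded). For nine or fewer elements
all permutations are enumerated (9! = 362,880); otherwise a seeded uniform
sample is used. The p-value is the fraction of permutations whose Pearson
correlation reaches the observed one; ties count against the hypothesis,
the conservative choice. Because the permutation leaves the permuted
matrix's standard deviation invariant, the enumeration reduces to cross
products and is exact and fast.

## Dating admixture from ancestry tract lengths

A pulse-admixture history is written as underscore-separated events, oldest
first, one letter per source population (`pp_xp`: founding pulse from both,
then a second pulse from population 2). Event times are continuous; a pulse
at a fractional time contributes migrants to the two adjacent integer
generations with linear weights. Given the fixed present-day ancestry
totals, per-event migrant fractions are recovered from an exactly solvable
"contribution" parameterization (each pulse's contribution to present-day
ancestry), leaving as free parameters the event times plus one relative
contribution per doubly-pulsed population — so `pp` has one free parameter,
`pp_xp` three, `pxp_xpx` two, `ppp_xpx` three, and the four-parameter
families four, matching the convention used for the information criteria.

### Two expected-histogram engines

The expected tract-length histogram on finite chromosomes is computed from
a stationary Markov jump process along the genome whose states carry the
ancestry label, using phase-type machinery: interior tracts, end-censored
tracts and uninterrupted whole chromosomes are all accounted for via
matrix-exponential integrals (computed by one augmented block exponential,
robust to singular sub-generators), and the decomposition conserves each
ancestry's total expected length to machine precision.

The classical engine (`engine = "markov"`) uses states (arrival generation
t, ancestry): a lineage is interrupted at rate t−1 per Morgan (one per
meiosis within the admixed pedigree — a founder's own meiosis cannot switch
ancestry, so g = 1 yields uninterrupted chromosomes) and redraws an
independent lineage conditioned on arriving above the interruption level.
This supports arbitrary multi-pulse schedules and is the default for
fitting. It is, however, measurably biased: a second crossover at the same
meiosis level returns to the *previous* lineage, not an independent one. At
g = 2 the exact law is elementary — a haplotype alternates between its
parent's two pure haplotypes, so the probability of an uninterrupted
1-Morgan chromosome is Σ_p α_p² + Σ_p α_p(1−α_p)e^(−1) ≈ 0.684 at α = 0.5 —
and forward simulation reproduces it, while the independent-redraw engine
gives 0.61 and under-counts the shortest tracts by ~25% at g = 6.

The pedigree engine (`engine = "pedigree"`, single-pulse integer times)
tracks that alternation: its state is the active leaf's ancestry plus the
current leaf ancestry of the inactive co-branch at each of the g−1 meiosis
levels. A crossover at level u (rate 1 per Morgan per level) swaps the
active leaf with the level-u co-branch, records the old active ancestry as
the new co-branch, and freshens the co-branches inside the newly entered
subtree; inactive co-branches evolve as two-state Markov chains at their
exact marginal switch rate (the co-branch at level u heads a depth-(g−u)
subtree, whose unconditional ancestry-switch rate is (g−u−1)·2Σα_p(1−α_p)
per Morgan, implemented as jump rates (g−u−1)·α_p′). The stationary law is
the product measure, so ancestry proportions are conserved exactly. The
engine is exact at g = 2 and much closer to forward simulation at all g;
residual per-bin bias of 1–5% remains at g = 8 (Markovization of co-branch
memory, loss of deep revisit correlations) and is resolvable beyond 3
Monte-Carlo SE once validation exceeds roughly two thousand haplotypes —
the acceptance suite reports this honestly rather than averaging it away.

### Fitting, model choice, calibration

`fit_pulse_model()` maximizes the Poisson likelihood of per-bin,
per-ancestry counts over event times and relative contributions, excluding
bins below 11.7 cM (the first two default 5.85 cM bins; short tracts are
enriched in local-ancestry false positives) from the objective while still
reporting predictions for them. A brute-force grid (default 0.25-generation
steps over 1–20, 0.05 steps for relative contributions) precedes
derivative-free refinement; the procedure is deterministic. AIC = 2k −
2logL and BIC = k log(n) − 2logL use the free-parameter counts above and
n = bins × populations; at the likelihood gaps reported for two-pulse
versus single-pulse fits (hundreds of units) both criteria reject the
single pulse.

Generation-time calibration regresses the per-birth-cohort fitted pulse
time g on mean birth year: with a fixed calendar onset, individuals born τ
years later are one generation *further* from the onset, so the slope is
+1/τ (a non-positive slope contradicts a shared onset and raises an
error). Calendar conversion is T = T_s − (g−1)τ with T_s the cohort mean
birth year; rounding to whole years happens only at the reporting layer.
The X-versus-autosome sex-bias solver uses a = (m+f)/2 and x = (m+2f)/3 per
ancestry; the unconstrained per-ancestry solution m = 4a−3x, f = 3x−2a
automatically sums to one across ancestries, so constraints bite only when
a coordinate leaves [0,1], in which case a penalized box-constrained least
squares (L-BFGS-B, soft simplex penalty) is solved and the residual
reported; infeasible inputs (residual above a tolerance) are an error.
Bootstrap confidence intervals resample individuals — never tracts — with
replacement, relabelling drawn copies so that statistics counting
individuals remain correct, and report percentile intervals; failed
replicates are dropped with a warning.

## Synthetic-data generators

All generators are pure functions of their parameters and seed.

**Pairwise IBD** (`simulate_pair_ibd`, `simulate_pair_totals`): segments for
a pair at distance R form a Poisson process over (coalescence time,
length): the per-chromosome count intensity is 2L_c · p(t|R) · 2t(e^(−2ta) −
e^(−2tb)) and lengths given t are window-truncated exponentials with rate
2t, so the *expected total shared length equals the analytic expectation
exactly*, including the t < 1 region (the count mean comes from adaptive
quadrature of the intensity; t is drawn by inverse CDF on a 4096-point
logarithmic grid, l by exact inverse CDF). Only this first moment is part
of the contract; the count-length construction fixes the higher moments and
they are what the decay-curve SEs measure. The background channel is a
distance-independent Poisson process whose lengths are truncated
exponentials at a characteristic rate 2/l_min, calibrated so its expected
total is b. The generator does not emulate linkage between overlapping
pairs, haplotype phase, or genotyping error.

**Forward Wright–Fisher tracts** (`simulate_wf_admixture_tracts`): a
monoecious, constant-size diploid population with selfing excluded; the
discrete migration schedule of a pulse model replaces a binomial fraction
of each generation with unadmixed migrants; each meiosis recombines as a
Poisson process of rate 1 per Morgan per chromosome. Haplotypes tile their
chromosomes exactly. Finite N adds drift: at the 50-diploid scale used for
engine validation, realized ancestry proportions drift by several percent,
which the replicate-based Monte-Carlo errors absorb.

**Census tables** (`simulate_census_tables`): Poisson counts around
per-route intensities plus external inflow; ground truth retained.

**Birth-year cohorts** (`simulate_birth_year_admixture`): g = 1 +
(T_s − T0)/τ per group plus Gaussian noise clamped at one generation. The
per-group noise used in the recovery tests, 0.12 generations, matches the
sampling error of a tract fit on a few hundred individuals (scaled from
reported whole-cohort bootstrap widths).

## Problem sizes used by the test and acceptance suites

Chosen to make each check informative at interactive runtimes: the
closed-form/quadrature comparison uses a 108-point parameter grid; decay
parameter recovery uses 5,000 pairs per bin at 21 distances (0.5 km and
26–976 km in 50-km steps — a dense clinic design; 100-km display bins leave
n and D under-resolved along their ridge) over 50 seeded replicates,
requiring both parameters within 15% in at least 90%; tract-engine
validation uses 10⁴ haplotypes on one 1-Morgan chromosome at g = 2 and
twenty replicate 50-diploid populations on the full 22-autosome map at
g ∈ {6, 8}; bootstrap coverage uses 200 calibration datasets of 60
individuals with 200 resamples each. The default genome map ships 22
autosome lengths totalling ≈35.5 Morgans.

## Known limitations

The spatial model assumes constant density and diffusion on an infinite
plane; heterogeneous landscapes and anisotropy are out of scope, and the
uniform background term absorbs long-range migration rather than modelling
it. The census relatedness metric assumes pre-migration random mating at
constant regional sizes. The tract engines are finite-memory approximations
of a non-Markov process; their residual bias at deep pulse times is
quantified above. The element-permutation Mantel test deliberately departs from
the classical row/column exchangeability argument,
so its p-values are not exchangeability-exact in the classical sense — the
classical variant is provided for comparison.
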