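---
title: "Temporal drug co-prescription networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal drug co-prescription networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpnflow)
library(data.table)
```

## The model

A drug prescription network (DPN) represents same-day co-prescription at
the population level. Medications are grouped into $n = 24$ therapeutic
classes by longest-prefix rules over the Anatomical Therapeutic Chemical
(ATC) hierarchy: the thirteen non-nervous anatomical roots (A, B, C, D, G,
H, J, L, M, P, R, S, V) each form a class, and the nervous-system root N is
split into anesthetics (N01), analgesics (N02), antiepileptics (N03),
antiparkinson drugs (N04), antipsychotics (N05A), anxiolytics (N05B),
hypnotics/sedatives (N05C), antidepressants (N06A), psychostimulants
(N06B), antidementia drugs (N06D), and other nervous-system drugs (N07).

For patient $p$ on day $t$, the individual network $A_p^t$ is the binary
symmetric $24\times 24$ adjacency with $A_{ij} = 1$ iff classes $i \neq j$
both have at least one actively supplied medication that day (zero
diagonal). The population network is the element-wise sum
$A^t = \sum_p A_p^t$: off-diagonal entries count patients with the pair
concurrently active, the diagonal counts patients with the single class
active and is excluded from network analysis (no self-loops).

"Actively supplied" is derived from dispensing records: a dispensing on
date $d$ with $s$ days supplied covers the half-open day interval
$[d, d+s)$, clipped to the study window, with 0-based day indices.
Overlapping refills of the same ATC code are merged by day-level union by
default; a `shift` policy that postpones the refill until the previous
supply runs out is available, since registries do not record which rule the
dispensing pharmacy effectively implements. When two dispensings of a code
cover the same day, the most recent dispensing's dose ratio wins — the
latest prescription reflects the current regimen.

### DDD edge weighting

Raw counts treat every co-prescription equally, but prescribed daily doses
differ from the WHO defined daily dose (DDD). Each medication's dose ratio
$d$ (prescribed daily dose / DDD) gets a Gaussian kernel weight centred at
the baseline ratio 1,

$$\omega(d) = \frac{1}{\sigma\sqrt{2\pi}}
  \exp\!\left(-\frac{(d-1)^2}{2\sigma^2}\right), \qquad \sigma = \tfrac13,$$

and an edge averages its two endpoint weights,
$\omega_{ij} = \tfrac12(\omega_i + \omega_j)$. Two genuinely open choices
are exposed as options rather than silently decided:

* **`combine`** — the default `multiply_counts` multiplies the pair weight
  into the co-prescription count, so edges keep frequency information; the
  alternative `literal_eq4` stores the bare pair weight wherever the count
  is positive. The frequency-free variant makes centrality independent of
  how often a pair is co-prescribed, which contradicts the empirical
  observation that highly dispensed classes have high centrality, so it is
  not the default.
* **`mode`** — `per_record` (default) weights each active medication by its
  own dose ratio (averaged within patient-day-class); `class_mean` uses one
  weight per class from the class's mean ratio. Registries report
  within-class dose variation, which only `per_record` uses.

Note that the kernel's peak value is $3/\sqrt{2\pi} \approx 1.197$, not 1;
`peak_normalized = TRUE` rescales the maximum to exactly 1. Only relative
weights matter for eigenvector centrality (it is scale-invariant), so the
default keeps the plain density form.

### Eigenvector centrality and the 1/n baseline

Node importance is the dominant eigenvector of the day's weighted
adjacency, $c_i = \lambda^{-1} \sum_{j \neq i} W_{ji} c_j$, normalised so
$\sum_i c_i = 1$ (L1). With this normalisation a uniformly connected
unweighted network has $c_i = 1/n$ exactly, so $1/24$ serves as the
high/low threshold; ties at exactly $1/24$ are classified low because
"high" is defined strictly.

Numerically, `eigenvector_centrality()` runs power iteration from the
uniform vector with L1 tolerance $10^{-10}$ (cap 10,000 iterations) on the
shifted matrix $W + \alpha I$ with $\alpha = 0.1 \max_i \sum_j W_{ij}$.
The shift leaves eigenvectors unchanged but makes the leading eigenvalue
strictly dominant even for bipartite graphs, whose $\pm\lambda$ pair would
otherwise make plain power iteration oscillate (the star graph is the
canonical failure case). The reported $\lambda$ is the Rayleigh quotient on
the unshifted matrix. Tests cross-check against a dense symmetric
eigensolver to $10^{-8}$ in the sup norm. Days with an all-zero weighted
matrix yield missing centrality flagged non-converged — returning the
uniform vector would silently count as data. For disconnected graphs the
iteration converges to the dominant component's eigenvector, with the
other components near 0.

Daily centralities are aggregated to ISO-8601 weeks (`"YYYY-Www"`) as the
mean over converged days; dispensing and patient counts are summed within
the week and the dispensing-to-patient ratio recomputed from the weekly
sums. The daily-to-weekly aggregation function for centrality is a package
choice (mean), as is the eigensolver; neither has a canonical convention.

## Co-prescription statistics and subgroups

The unit is the *prescription-day*: one medication active on one day (7
medications on one day = 7 prescription-days). Medications are counted as
distinct ATC level-5 codes, not classes — same-class co-prescription (two
or more distinct focal-class medications on a day, counting the
focal-class medications) would be invisible at class granularity. For a
focal class, multi-class co-prescription counts the non-focal medications
on patient-days with at least one focal and one non-focal medication
active. Per-person yearly means divide by the year's focal cohort
(patients with ≥1 focal-class dispensing that calendar year), a
denominator choice documented here because summaries of this shape rarely
state one.

Subgroups: age `<65` vs `>=65` evaluated per calendar year (age = year −
birth year; the registry carries no birth day), so a cohort whose entry
age is capped at 65 still develops a `>=65` subgroup in later years; and
general polypharmacy, ≥5 distinct medications on each of ≥30 consecutive
days anywhere in the window (runs may span year boundaries; the flag is
monotone in exposure). Subgroup networks are rebuilt with identical
parameters, and because each patient-day lands in exactly one subgroup of
a partition, subgroup count matrices sum *exactly* (integer equality) to
the population matrices — a conservation law the tests assert.

## Seasonality tools

Seasonal structure is inspected on detrended data. The detrending method
is a package choice (none is canonical): a centred moving average (window
29 days for daily series, 13 weeks for weekly; edges shrink the window
symmetrically), or the SSA stage-1 trend for pipeline consistency. The
correlogram uses the standard biased (1/N) autocovariance estimator —
which keeps the ACF sequence positive semi-definite — with PACF from the
Durbin–Levinson recursion (via `stats::acf`/`stats::pacf`) and the
white-noise band $\pm 1.96/\sqrt{N}$. Seasonal deconstruction reshapes
daily series by ISO week (positions Mon..Sun) and weekly series by year
(positions = ISO week numbers) for overlap inspection.

## Two-stage singular spectrum analysis

SSA embeds a series of length $N$ into its $L \times K$ Hankel trajectory
matrix ($K = N - L + 1$), takes the SVD, and reconstructs component series
from selected eigentriples by anti-diagonal averaging. The implementation
computes the anti-diagonal sums of each rank-1 term $d_i u_i v_i^\top$ as
the polynomial convolution of $u_i$ and $v_i$, then divides by the
anti-diagonal lengths; reconstruction from all eigentriples reproduces the
input to $10^{-8}$ relative error (tested on random series).

The two-stage procedure targets weekly series: stage 1 uses $L = 52$ (one
year of weeks) and extracts the trend as the leading eigentriple's
reconstruction (configurable to a group, e.g. $\{1, 2\}$, when the trend
is not rank-1); stage 2 re-embeds the residual with the maximal window
$L = \lfloor N/2 \rfloor$ and reports the top $k = 25$ oscillatory
components $F_1..F_k$ by singular value. The headline reconstruction is
trend $+ F_1 + F_2$. Variance shares default to squared singular values
over the stage total; a reconstructed-variance estimator is available
(`share_method = "variance"`) because "share of variability" admits both
readings. The minimum length is $2L_1 = 104$ weeks — two full years.

Long-term change is tested with the Mann–Kendall statistic
$S = \sum_{i<j} \mathrm{sign}(x_j - x_i)$, tie-corrected variance
$\mathrm{var}(S) = [n(n-1)(2n+5) - \sum_t t(t-1)(2t+5)]/18$, continuity
correction and two-sided normal p-value. The pipeline reports the test for
both the raw weekly series and the extracted SSA trend, labelled
`_raw`/`_ssa_trend`, since either is a defensible target ("the extracted
trend, residuals, and oscillatory components were evaluated" admits both).
On white noise the empirical type-I error at $\alpha = 0.05$ sits in
[0.03, 0.07] (tested over 2000 replicates).

## The synthetic registry

Real dispensing registries are proprietary, so the package ships a
generator that reproduces the statistical structure the analysis assumes,
and the whole pipeline is validated against planted structure. Events for
each patient × class follow an inhomogeneous Poisson process with daily
intensity

$$\text{base}_c \times \text{weekday}(t) \times \text{seasonal}(t)
  \times \text{trend}_c(t) \times \exp(\ell_c z_p - \ell_c^2/2),$$

where $z_p$ is a patient-level latent multimorbidity factor (standard
normal plus an age shift of $0.5\,(\text{age}-40)/25$), and $\ell_c$ are
class loadings, larger for chronic-disease classes (cardiovascular 0.8,
alimentary/blood 0.7, analgesics 0.6, ...). The $-\ell_c^2/2$ term keeps
the population-average intensity equal to the base rate. Defaults:

* class base rates proportional to observed class dispensing shares,
  scaled to 20 dispensings per patient-year — enough that daily networks
  are non-degenerate (no empty days) from roughly 500 patients up;
* weekday multipliers proportional to observed mean daily volumes
  (Monday ≈ 2.6 × Saturday), normalised to mean 1;
* yearly seasonality as a cosine with relative amplitude 0.08 peaking
  mid-January — mild, as registry data shows;
* class trends +2 %/year for antidepressants, −2 %/year for anxiolytics,
  flat elsewhere;
* female share 0.633; ages uniform 20–64 at window start;
* days supplied from {7, 14, 30, 90} with probabilities
  {0.15, 0.2, 0.5, 0.15};
* per-record DDD ratios from per-class lognormals moment-matched to
  reported class means (< 1) and SDs, truncated to (0, 3].

Patients whose Poisson draws produced no antidepressant or anxiolytic
dispensing receive one injected index dispensing, because the cohort is
*defined* by at least one such dispensing. The generator is deterministic
given its seed.

`planted_hub_class` plants a recoverable co-prescription hub: its
intensity is set to `hub_boost` (default 3) times the *largest* class base
rate and its loading to the maximum loading. The boost is defined relative
to the largest class deliberately — a multiplicative boost of a rare class
would stay rare and could never reach top-2 centrality, making recovery
checks vacuous.

### What the generator does not emulate

No adherence gaps, stockpiling, dose tapering, prescriber or pharmacy
effects, drug-level correlation beyond the shared latent factor, age- or
sex-specific class preferences, or abrupt policy changes. Passing tests
therefore show that the *pipeline* recovers structure it is pointed at
(planted hubs, trends, cycles, conservation laws), not that real
registries satisfy the generator's assumptions.

## Problem sizes and reproducibility

The test-suite and acceptance computations use 2000-patient single-year
registries for recovery sweeps (20 seeds), a 500-patient year for
conservation, 100 random 24×24 matrices for the eigensolver cross-check,
100 random length-261 series for SSA completeness, and 2000 white-noise
replicates for Mann–Kendall calibration — sizes at which every stochastic
property is stable across seeds while a full run stays in the minutes
range on one core. `run_pipeline()` writes a manifest (config hash, seed,
row counts) and re-running with the same config and seed reproduces every
table byte for byte.

## Known limitations

* Age is year-resolution (registries carry birth year only), so age-group
  boundaries are fuzzy by up to a year.
* The 24-node design cannot see drug-level structure inside a class
  beyond the same-class prescription-day counts.
* Eigenvector centrality on near-empty days is dominated by a handful of
  patients; the high/low classification is meaningful only aggregated
  over time.
* The two supported refill policies bracket, but do not model, real
  dispensing behaviour.

## A worked example

```{r example, eval = FALSE}
win <- study_window("2018-01-01", "2019-12-31")
cfg <- pipeline_config(
  sim = simulation_config(n_patients = 500, window = win, seed = 1),
  window = win, seed = 1)
res <- run_pipeline(cfg, "dpn-demo")
verify_outputs("dpn-demo")
```

See the README for the numbers this prints and how to reproduce the
package's headline results with `scripts/acceptance.R`.
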