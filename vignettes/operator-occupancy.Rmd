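---
title: "Operator occupancy, apparent cooperativity, and the EMSA Hill pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Operator occupancy, apparent cooperativity, and the EMSA Hill pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopfit)
```

## The system and the model

Type IV toxin–antitoxin antitoxins of the AbiEi/Rv2827c family repress their
own operon by binding tandem 23-bp inverted-repeat (IR) operators in the
promoter. The Rv2827c promoter of *M. tuberculosis* carries four such
repeats in two pairs (13 bp spacers within a pair, 4 bp between pairs,
within −1..−131 of the start codon), and the antitoxin binds them with
measured affinities spanning almost three orders of magnitude: IR1 0.0205,
IR4 0.121, IR2 0.862, IR3 11.0 µM. `coopfit` models this as an equilibrium
grand-canonical ensemble over the $2^n$ occupancy configurations of $n \le 8$
sites: at free repressor concentration $c$, configuration $S$ has Boltzmann
weight

$$ w(S) = \prod_{i \in S} \frac{c}{K_i} \;\prod_{i<j \in S} \omega_{ij}, $$

normalised by exhaustive enumeration. The coupling factors $\omega_{ij}$
default to 1 (independent sites), which is how the measured system behaves;
$\omega > 1$ is exposed to model the contrasting, positively cooperative
AbiEi-type promoters. We do not fit $\omega$ by default: with a handful of
titration lanes per gel, coupling and affinity are practically confounded,
so coupling is configuration, not a free parameter.

Marginalising $w$ over the number of bound sites gives the predicted band
species $k = 0..n$ of a native gel; for $\omega = 1$ this is exactly the
Poisson-binomial distribution of independent per-site occupancies
$p_i = c/(c+K_i)$, which the test suite uses as an independent convolution
oracle. Fractional saturation is the mean per-site occupancy $Y = E[k]/n$.

Two assumptions are worth stating. First, the titrated concentration is
treated as *free* protein: EMSA probes are used in trace amounts (hundreds
of femtomoles in a 10 µl reaction) relative to the Kd range, so ligand
depletion is negligible. Second, the model predicts only *how many* sites
are bound, not which gel band corresponds to which site identity; nothing in
a band count constrains species-to-site assignment.

## Apparent cooperativity and the Hill pipeline

The Hill coefficient is defined operationally, the way a bench scientist
extracts it: transform a saturation curve to
$(\log_{10} c,\ \log_{10}\theta)$ with $\theta = Y/(1-Y)$, and take the
slope at $\log\theta = 0$ (half saturation). For the model itself,
`apparent_hill_coefficient()` locates half saturation by bisection on
log-concentration (tolerance $10^{-10}$ in $Y$; bracketing is guaranteed
because $Y$ is continuous and strictly increasing) and differentiates by a
central difference with relative step $10^{-4}$ in log space. A single site
gives exactly 1; two identical sites with $\omega = 10^6$ approach 2; and
independent sites with a wide affinity ladder give a value below 1:

```{r}
m <- rv2827c_promoter_model()
apparent_hill_coefficient(m)
```

This is the package's central scientific point: *negative apparent
cooperativity needs no anti-cooperative interaction*. A descending ladder of
affinities produces sequential, ever-weaker binding steps, and the composite
Hill slope drops below 1. The spread matters, not the absolute scale: at a
fixed geometric-mean affinity, widening the ladder monotonically lowers
$n_H$ (a property the tests check on a three-site spread ladder).

For experimental tables the pipeline is `band_table_to_saturation()` →
`hill_transform()` → `hill_fit()`:

* **Y definition.** Densitometry reports one intensity per band species.
  The default reading is the classic bound-over-total fraction (all shifted
  species counted as bound). For multi-band gels this saturates as soon as
  the tightest site fills; the `saturation = "per_site"` option instead
  weights each species by its occupancy count, $Y = \sum_k k I_k / (n \sum_k
  I_k)$, which equals the model's fractional saturation and resolves the
  affinity ladder. The two coincide on single-site gels, where all the
  package's quantitative benchmarks live. (The per-site weighting is what
  reproduces the negative classification from a simulated four-band gel;
  the bound-fraction reading of the same gel is a different observable and
  classifies near 1.)
* **Exclusions.** Zero-concentration lanes and points with $Y \le \epsilon$
  or $Y \ge 1-\epsilon$ ($\epsilon = 10^{-6}$) carry no Hill information and
  are excluded, with the count reported so filtering is auditable.
* **Local window.** The Hill slope is defined at half saturation, so the
  line is fitted by OLS over points with $|\log_{10}\theta| \le 1$ (roughly
  $Y \in [0.09, 0.91]$), falling back to the 4 points nearest the origin if
  the window is too sparse. This is standard Hill-plot practice and is
  robust on 8–16-lane titrations; the window is configurable.
* **Kd extraction.** $K_d = 10^{x\text{-intercept}}$, base-10 logarithms
  throughout (the extraction formula forces the base). On points drawn from
  an exact Hill law the generating $n$ and $K_d$ are recovered to machine
  accuracy.
* **Classification.** $n_H$ below $1 - 0.10$ is negative, above $1 + 0.10$
  positive, otherwise non-cooperative. The 0.10 dead band absorbs the
  slope scatter of triplicate 5%-noise titrations (where simulated
  single-site gels classify non-cooperative in well over 95% of runs)
  without swallowing genuinely cooperative systems.

## Kd fitting

`fit_single_site()` fits $Y = c/(c+K_d)$ with $K_d$ on a log scale;
optimisation is a deterministic log-spaced multi-start (5 starts per decade
over the observed concentration range ±2 decades) refined by `nlminb`, with
ties broken by residual then by lower $K_d$. `fit_multisite()` fits the full
independent-site band model to all band fractions at once by
Levenberg–Marquardt least squares from a small deterministic family of
spread-pattern starts, reporting the recovered Kd multiset sorted ascending
(the likelihood is permutation-invariant for independent sites). Curves that
never leave 0 or 1 are rejected as non-identifiable rather than fitted.

## Scanning for inverted repeats

`find_inverted_repeats()` scans every (left-arm position, spacer) placement
and counts Hamming mismatches between the left arm and the reverse
complement of the right arm. Defaults (arm 23 bp, spacers 0–20 bp, up to 4
mismatches) admit the operator architectures seen in this antitoxin family —
3 bp spacers in the AbiEi promoter, 13 bp in the Rv2827c one — and the
visible degeneracy of their consensus. Coordinates are 1-based inclusive;
`to_promoter_coordinates()` converts to negative offsets anchored at the
translational start (−1 is the base immediately upstream), matching how
promoter probes are described. Ambiguity codes are rejected so mismatch
counts stay unambiguous.

One subtlety is deliberate: a strong repeat also matches at *jittered*
placements (arm start shifted by one base, spacer changed by two) whenever a
flanking base happens to pair, and such a jitter ties the true placement's
mismatch count about a quarter of the time. The default `overlap = "best"`
collapses overlapping hits (lowest mismatches, then leftmost) and may
therefore represent a repeat by a placement one base off; `overlap = "all"`
keeps every qualifying placement, among which the true one is always
present. Recovery benchmarks use `"all"` membership for exactly this
reason. Background false positives are a non-issue at 23 bp arms and ≤2
mismatches (the per-placement hit probability is below $10^{-10}$).

`consensus_matrix()` builds a position-frequency matrix over aligned arms
with a majority-rule consensus (ties as IUPAC codes), and
`score_arm_against_consensus()` scores candidate arms as
$\sum_p (1 - f_p(\text{base}_p))$.

## Reporter assays

`miller_units()` implements the kinetic Miller-unit convention for plate
readers: the OLS slope of OD420 against time in minutes, times 5000, divided
by the OD600 at the first time point. The slope uses the full one-hour
series by default (an optional window handles wells that saturate);
negative slopes are returned as computed but flagged. Activities are
normalised to a named control (`normalize_activity()`, control ≡ 1, ratio
uncertainty by the first-order delta method for independent estimates) and
induction effects summarised as `repression_ratio()` — values below 1 mean
negative autoregulation.

## Synthetic data: what it emulates and what it does not

The generators replace wet-lab inputs with seeded, parameterised stand-ins:

* `simulate_emsa()` — expected band intensities are `total_probe_intensity ×
  band_distribution`; each band gets independent multiplicative lognormal
  noise (median-1 factors, default $\sigma = 0.05$) plus optional additive
  background. Lognormal noise keeps intensities positive and matches
  densitometry error structure; 5% is a realistic per-band quantification
  error for clean fluorescent gels. Defaults: a zero-protein lane plus 12
  log-spaced lanes spanning ±2 decades around the affinity under study, in
  triplicate — the titration layout of a careful gel-shift series.
* `mutate_probe()` — polyC replacement of a repeat is modelled as deletion
  of that site (one binding event lost per replaced repeat), which is what
  replacing an operator with a cytosine tract does to a gel.
* `plant_inverted_repeats()` — uniform random background with planted pairs
  whose right arm is the reverse complement of the left carrying an exact
  number of point mutations; ground truth is returned alongside.
* `simulate_reporter()` — transcription proportional to the probability the
  promoter is repressor-free, linear OD420 ramps with Gaussian noise, OD600
  drawn near 0.5 (mid-log).

What passing these benchmarks shows: the estimators are unbiased and precise
under the stated noise laws, the pipeline's algebra round-trips exactly, and
the classification logic behaves at realistic noise. What it does not show:
robustness to gel artefacts that are not multiplicative per-band noise
(smearing, lane-to-lane transfer variation, saturated pixels), to probe
depletion at very tight affinities, or to growth-phase effects in reporter
wells. Real titration grids are also rarely as regular as the synthetic
defaults.

## Numerical choices and degenerate inputs

* Distribution enumeration is exact ($n \le 8$, so at most 256 terms);
  probabilities are normalised to 1 within $10^{-12}$ by construction.
* Bisection brackets for half saturation start at $[\min K_i / 10^4,\
  \max K_i \cdot 10^4]$ and widen defensively if coupling shifts the
  midpoint.
* All concentrations are µM internally; file readers convert from the
  declared `conc_unit` column at parse time.
* Zero-total-intensity lanes, all-zero or all-saturated curves, Hill point
  sets at a single concentration, and non-positive Hill slopes raise classed
  errors (`coopfit_empty_lane`, `coopfit_nonidentifiable`,
  `coopfit_singular_fit`, `coopfit_pathological_fit`) rather than returning
  silently wrong numbers.
* Every generator takes an explicit seed and restores the caller's RNG
  state; `run_demo()` output is byte-identical across runs with the same
  seed.

Benchmark problem sizes were chosen to characterise the estimators while
staying desk-scale: 100 randomised models for the convolution oracle, 1000
planted sequences for scanner recovery, 500 seeded titrations (200 in the
unit suite) for the noise-robustness medians.

## Interfaces

The analysis functions are the package's primary interface; `run_pipeline()`
drives them from JSON/YAML configs with validated keys, provenance blocks
(version, config hash, seed) in every result, and atomic writes so failed
runs leave no partial outputs. A thin command-line wrapper is installed at
`system.file("cli", "coopfit.R", package = "coopfit")` with subcommands
`simulate-emsa`, `analyze-emsa`, `fit-sites`, `scan-ir`, `miller` and
`demo`.

## Known limitations

* The occupancy model is equilibrium-only: no on/off kinetics, no DNA
  bending mechanics, no protein–protein interface prediction.
* Fitting $\omega$ is deliberately not exposed; strongly coupled models can
  be *simulated* and analysed, but affinity/coupling decomposition from
  band tables alone is ill-posed at realistic lane counts.
* The scanner does exhaustive fixed-arm-length scans; it is not a
  genome-scale motif discovery tool, and the native operator sequences of
  any particular promoter must be supplied by the user.
* Band species are counts of bound proteins; supershift identity (which
  site a given shifted band represents) is outside the model.
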