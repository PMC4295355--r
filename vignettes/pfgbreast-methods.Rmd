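---
title: "Models and methods in pfgbreast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in pfgbreast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfgbreast)
```

## The physical model

Water in excised breast tissue behaves, on the time scale of a
pulsed-field-gradient (PFG) NMR experiment, like two pools in slow exchange:
a fast diffusion phase (FDP) with coefficient $D_{FDP} \sim 10^{-9}\,
\mathrm{m^2/s}$, loosely identified with less hindered water, and a slow
diffusion phase (SDP) with $D_{SDP} \sim 10^{-11}\, \mathrm{m^2/s}$. The
normalized stimulated-echo amplitude then decays biexponentially with the
diffusion weighting $b$:

$$
\frac{A(g)}{A(0)} = P_1 e^{-b D_{FDP}} + P_2 e^{-b D_{SDP}},
\qquad P_1 + P_2 = 1,
\qquad b = \gamma^2 \delta^2 g^2 t_d ,
$$

where $\gamma$ is the proton gyromagnetic ratio, $\delta$ the gradient pulse
duration, $g$ its amplitude and $t_d$ the diffusion time. The initial slope
of $\ln A$ versus $b$ estimates the population-weighted apparent diffusion
coefficient

$$
\mathrm{ADC} = P_1 D_{FDP} + P_2 D_{SDP},
$$

the quantity that in-vivo diffusion MRI reports. All estimates are
*apparent*: restriction and exchange make them depend on the acquisition
(notably $t_d$), so fit results carry the acquisition as metadata and are
never extrapolated to zero echo time.

`pfg_signal` implements this forward model ([compute_b_value()],
[biexp_signal()], [weighted_adc()], [synthesize_curve()]). Two acquisition
fixtures are bundled:

* `acquisition_default()` — $\gamma = 2.675\times 10^{8}$ rad/s/T, $\delta =
  0.2$ ms, $t_d = 20$ ms, $2\tau = 20$ ms, gradient ramp $0$–$4$ T/m in 25
  steps (the geometry under which the reference group tables were measured).
  The gradient step schedule between the minimum and maximum amplitude is
  not part of the published acquisition; the uniform 25-step ramp is this
  package's fixture choice.
* `acquisition_extended()` — the same ramp at $t_d \in \{11, 50, 200,
  800\}$ ms, pooled into one b-grid reaching $3.7\times10^{10}\,
  \mathrm{s/m^2}$. The slow phase is only identifiable when $\max(b)\,
  D_{SDP} \gtrsim 0.3$; at $t_d = 20$ ms alone it attenuates by barely 1.5%,
  which is why all inverse-problem work defaults to the extended fixture.

Synthesis adds zero-mean Gaussian noise to the amplitudes. Additive Gaussian
(rather than Rician) noise is adequate here because fixture amplitudes stay
far above the noise floor; negative noisy amplitudes are dropped before any
log-domain fit. The default `noise_sigma = 0.005` corresponds to a b = 0
signal-to-noise ratio of 200, a realistic figure for a bench-top
spectrometer averaging a ~0.25 g specimen.

## Peel-off decomposition with nonlinear refinement

`decay_fitting` inverts measured or synthesized curves:

1. **Slow phase.** A least-squares line through $(b, \ln A)$ over the
   largest-$b$ `tail_fraction` (default 0.4) of the points, further
   restricted to $b \ge 3/\mathrm{ADC}_0$ (with $\mathrm{ADC}_0$ the
   initial-slope estimate, a lower bound on $D_{FDP}$) whenever at least
   three points survive. There the fast phase contributes under 5% of the
   signal. The slow coefficient is minus the slope; its population is the
   exponentiated intercept.
2. **Stripping.** The fitted slow component is subtracted. Residuals below
   $10^{-6} A(0)$ *or* below 5% of the peak residual are discarded: once the
   fast phase has decayed, residuals are noise plus slow-fit mismatch, and
   their logarithms would drag the fast-phase slope toward zero. The fast
   component is fitted to the surviving log-residuals.
3. **Closure.** Populations are renormalized to sum to one (a warning is
   raised if they missed closure by more than 5% beforehand).
4. **Refinement** (default on). The stripped estimates seed a
   Levenberg–Marquardt fit of the full two-term model in the amplitude
   domain. The two rates are log-parameterized: they are positive by
   construction, they differ by two orders of magnitude, and the log scale
   keeps the Jacobian well conditioned — with a plain parameterization the
   solver can encounter a singular gradient at poor stripped starts. The
   refined solution is kept only if it does not increase the residual RMS.

Stripping fits the slow phase first, the standard order for multiexponential
peel-off. Log-domain stripping is unweighted, as is the amplitude-domain
refinement; with amplitude-additive noise the refinement is then the
maximum-likelihood fit. On noise-free extended-fixture curves the stripped
estimates land within ~0.2% of the generating parameters and refinement
reaches machine precision; at `noise_sigma = 0.005` the refined estimates
scatter by roughly 0.5–2% depending on how strongly the slow phase is
attenuated.

Effectively single-phase curves (e.g. the water calibration standard, a
single exponential with $D = 2.7\times10^{-9}\ \mathrm{m^2/s}$, independent
of $t_d$) leave too few usable residuals and raise a classed
stripping-failure error; [fit_decay_curves()] then falls back to
[fit_mono()].

The initial-slope ADC uses the first `n_initial = 3` points by default — the
smallest window that still averages some noise. It is only as good as the
small-b sampling: on the extended fixture the three smallest nonzero
b-values span less than $10^{7}\ \mathrm{s/m^2}$, so at finite noise the
3-point slope is noise-dominated and a wider window (or the
population-weighted ADC of the fitted components) should be preferred.

## Composition regression and its unit contract

`quad_regression` links diffusion parameters to six-part morphometry:
parenchyma (P), stroma (St), adipose tissue (AT), pericellular edema (PCE),
perivascular edema (PVE) and vessels (V), in percent of a histological
section. PVE is excluded from every design because it is determined by the
other constituents (the six parts tile the section). The published general
formula is not available, so the designs are inferred from the printed
equations: *pure quadratic* (intercept, linears, squares; $1 + 2k$ terms)
for the five morphology predictors, *full second order* (plus pairwise
products; $1 + 2k + k(k-1)/2$ terms) for the two- and three-parameter
diffusion models. Both builders are exposed.

The regression layer works on fixed scaled units — $D_{FDP}$ in
$10^{-9}\ \mathrm{m^2/s}$, $D_{SDP}$ in $10^{-11}\ \mathrm{m^2/s}$ — so
that all magnitudes are of order 0.3–4 and the published coefficients apply
directly. Conversions are exact multiplications ([d_fast_to_scaled()] and
friends). Predictors are never standardized, for the same reason. Fitting is
ordinary least squares with $R^2 = 1 - SS_{res}/SS_{tot}$ (defined as 0 for
a constant response); per-coefficient t-tests are reported for information
and no terms are pruned. Rank-deficient designs abort with the offending
columns named, rather than silently dropping terms.

The three published composition models are shipped as a plain-text
coefficient table (`inst/extdata/reference_coefficients.tsv`) and exposed by
[reference_predictors()]. Two transcription ambiguities are resolved there
and flagged in the file: an ambiguous exponent printed on the first
quadratic term of the fast-phase equation (encoded as $P^2$), and mixed
decimal separators in the morphology score.

## Cancer-probability scoring

`cancer_scoring` evaluates the three published CanP surfaces
([canp_reference_models()]): a pure-quadratic surface over (P, St, AT, PCE,
V) and full second-order surfaces over $(D_{FDP}, D_{SDP})$ and $(D_{FDP},
D_{SDP}, P_1)$. The raw polynomial score is clamped to $[0, 1]$ — realizing
the published 0-to-1 probability convention and the flat plateaus of the
published response surfaces, which the source never states as an explicit
clamp — and a specimen is labelled malignant when the clamped probability
reaches the threshold. No threshold is published; 0.5 is the default and it
is configurable. At that threshold the published control-group mean point
$(1.25, 1.67, 0.48)$ scores 0.32 (two-parameter model) and 0.05
(three-parameter model), and the cancer-group mean point $(0.97, 0.86,
0.75)$ saturates at probability 1 under both.

[fit_canp()] refits a surface to labelled specimens by OLS on the 0/1
indicator — a linear-probability quadratic surface, mirroring how the
published equations were obtained. Logistic regression is deliberately not
offered, to keep refits comparable with the published models; the package
also reports $R^2$ and confusion counts separately and never treats $R^2$
as a diagnostic accuracy. Diffusion inputs outside $[0.01, 100]$ trigger a
suspicious-units warning (SI inputs would silently collapse every quadratic
term).

## Cohort statistics

`cohort_stats` mirrors the published table layouts: per-group mean ± SD,
range and high/low ratio ([group_summary()]; the ratio is undefined when the
minimum is not positive, and a singleton has ratio 1); Wilcoxon rank-sum
comparisons; and Spearman correlations of each diffusion parameter with each
constituent within subgroups — the control group and the stroma classes
below/at-or-above 50% (the high class uses $\ge 50$, matching the published
headers), with the whole cancer group available as a fourth subgroup.

All p-values are two-sided (the source reports inequalities without stating
sidedness) and no multiple-testing correction is applied, matching the
source; outputs are plain tables so any correction can be applied
downstream. The rank-sum p is exact — full enumeration of rank assignments,
valid under ties via mid-ranks — whenever both groups have at most 10
observations or the pooled sample at most 12; beyond that a tie-corrected,
continuity-corrected normal approximation is used (it agrees with the exact
p to within 0.02 at 10 + 10). Spearman's $\rho$ is the Pearson correlation
of mid-ranks, with a t-approximation p-value and, for $n \le 12$, a
permutation alternative (exhaustive for $n \le 7$).

## The synthetic cohort

No per-specimen raw data are published, so `synthetic_cohort` emulates the
study from its printed group statistics: 6 control and 11 cancer specimens
(the cancer group carrying T2N0M0/T2N1M0 sublabels 6:5), each with a
six-part composition and diffusion parameters, plus synthesized decay
curves.

**Compositions.** Only per-variable mean/SD/range are published, with no
joint distribution, so each constituent is drawn from an independent
truncated normal — the minimal assumption. Two calibration choices matter:

* The published ranges are asymmetric about the means, so a truncated normal
  *centered* at the published mean would have a biased mean (the six raw
  truncated means sum to ~115%). The underlying location is therefore
  calibrated (by root finding) so that the *truncated* mean equals the
  published mean.
* The six parts of a section must tile it. Each draw is normalized to a
  100% total by rescaling the slack above the published minima — in both
  directions, skipped when the raw sum is already within $100 \pm 0.5$ —
  and clipping at the published maxima. This preserves the published
  ranges exactly and keeps group means within ~0.5 percentage points of the
  published values; a one-sided proportional rescale (shrinking only
  over-100 draws) would bias the cancer parenchyma mean down by ~4 points
  and can violate the published minima. Lower truncation is at 0.01% where
  the published range starts there.

The price of the sum constraint is that marginal SDs shrink relative to the
printed ones and mild negative correlations appear between constituents;
the printed inter-variable correlation structure is unpublished and is not
emulated.

**Diffusion parameters.** In `group_parameter` mode, $(D_{FDP}, D_{SDP},
P_1)$ are drawn from mean-calibrated truncated normals of the published
group statistics. The published cancer-group $D_{SDP}$ row (0.86 ± 0.68,
range 0.40–3.84) is internally inconsistent with its own TNM sub-columns
(means ≥ 1.75); the numbers are kept verbatim, and the sub-column statistics
are available as optional overrides. In `equation_driven` mode the
parameters are computed from the published composition surfaces plus
Gaussian residuals whose variance is calibrated once per cohort as
$\sigma^2 = \mathrm{Var}(\hat y)(1 - R^2)/R^2$, so that refitting recovers
the target $R^2$ (defaults 0.92 / 0.81 / 0.93). Compositions where the
published surfaces extrapolate to non-physical values — negative
diffusivity or a spin population outside $(0, 1)$ — lie outside the
surfaces' domain of validity and are redrawn; residual resampling then
enforces positivity and the fast-over-slow ordering against noise
excursions. $P_1$ is clipped to $(0.001, 0.999)$ after noise.

Everything is reproducible: each specimen consumes seed streams derived from
the configuration seed and its cohort index, so results do not depend on
group ordering, and the caller's RNG state is never disturbed.

**What the generator does not emulate.** No $T_1/T_2$ relaxation weighting —
in real stimulated-echo data the apparent $P_1$ drifts upward with $t_d$
because the phases relax at different rates, so pooling diffusion times into
one extended b-grid is an idealization valid only in this relaxation-free
model. No inter-phase exchange, no restricted-geometry or tortuosity
effects, no Rician noise floor, and no inter-constituent correlation
structure beyond the sum constraint. Passing tests therefore demonstrate
correctness of the estimators under the stated two-phase model, not
robustness to those real-data effects.

## Pipeline and formats

`workbench_io` chains simulate → fit → regress → score → summarize
([run_pipeline()]) with stage-dependency checks before anything runs,
atomic writes (a failed stage leaves `.partial` files), per-stage timing,
and a JSON manifest recording the seed, parameter hash, warnings (e.g.
mono-fit fallbacks) and outputs; every output file begins with `#` comment
lines carrying the seed and parameter hash, and re-running a configuration
reproduces every output byte. All exchange formats are delimited text with
period decimals and a header row: long-format curve tables
(`curve_id, b_value_si, amplitude`), the 14-column specimen table, and
matrix-format surface grids. [validate_specimen_table()] checks the schema,
period-decimal parsability, composition invariants and unit-scale
plausibility ($D_{FDP}$ in $[0.1, 5]\times10^{-9}$, $D_{SDP}$ in $[0.1,
10]\times10^{-11}$, $P_1 \in [0,1]$) and returns a row-level error report.
A thin command-line dispatcher over these functions ships in
`inst/scripts/pfg-workbench.R`.

## Numerical choices and problem sizes

Defaults, chosen once: `tail_fraction = 0.4`; residual floor $10^{-6} A(0)$
plus 5% of peak residual; `n_initial = 3`; refinement on, 500 LM iterations;
decision threshold 0.5; stroma cut at ≥ 50%; noise `sigma = 0.005`;
equation-driven targets $R^2 = (0.92, 0.81, 0.93)$. Test and verification
problem sizes: parameter-recovery cohorts of 200 specimens, $R^2$
calibration at $n = 200$ over 10 seeds, Monte-Carlo noise calibration at
$10^4$ amplitudes, composition fidelity at $10^4$ draws, and exhaustive
enumeration oracles up to pooled $n = 12$ (rank sums) and $n = 6$
(permutation Spearman). A 200-specimen generate-and-fit cycle takes on the
order of a second on one CPU.

## Known limitations

* The fitter is strictly two-phase: three or more components, regularized
  spectra (NNLS/ILT) and relaxation-corrected populations are out of scope.
* The initial-slope ADC at default settings is unreliable at finite noise
  when the small-b grid is very dense (see above).
* The slow phase is weakly encoded when $\max(b) D_{SDP} \lesssim 0.3$; for
  the published cancer-group range this happens below $D_{SDP} \approx
  0.9\times10^{-11}\ \mathrm{m^2/s}$, where slow-coefficient recovery
  degrades from ~1% to several percent at the default noise.
* The published scoring surfaces are used as-is; nothing here validates them
  on external data, and refits on 17-specimen cohorts are as unstable as any
  11-coefficient fit on 17 points.
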