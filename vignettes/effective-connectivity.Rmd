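---
title: "Granger causal effective connectivity for developmental fNIRS: methods"
author: "fnirsGCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Granger causal effective connectivity for developmental fNIRS: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Children recognize faces of their own racial group faster and more
accurately than faces of other groups (the behavioral other-race
effect). The neural counterpart of this asymmetry — differences in how
cortical regions exchange information while processing own- versus
other-race faces — can be probed with functional near-infrared
spectroscopy (fNIRS): oxy-hemoglobin concentration change is recorded
at 10 Hz over a 46-channel montage (channels 1–24 over the frontal
cortex, 25–46 over the occipital cortex), once per task condition
(own-race and other-race face recognition), from a developmental cohort
of roughly 124 children aged ~3–13 years.

`fnirsGCA` implements the full analysis of such a design:

1. per-channel preprocessing of the oxy-Hb series,
2. pairwise (bivariate) Granger causality between all ordered channel
   pairs, yielding one weighted directed *causal map* per participant
   and condition,
3. per-edge group inference — a repeated-measures ANOVA of condition by
   continuous age, with subsample-averaged partial eta-squared effect
   sizes tested against a condition-scramble permutation null,
4. the neural other-race effect (NORE, the own-minus-other edge weight)
   and its age correlation, and
5. assembly of significant-edge directed networks classified by
   anatomical area pair and developmental trend.

Because no recorded cohort ships with the package, a synthetic cohort
generator (`generateCohort()`) plants known directed couplings with
age- and condition-dependent strength so every stage can be validated
end to end.

# The causality model

For channels $A$ and $B$ with preprocessed series $X_A$, $X_B$, each
series is fitted with a reduced autoregression on its own lags,

$$X_A(t) = a_0 + \sum_{i=1}^{p} a_i X_A(t-i) + \varepsilon_A(t),$$

and with a full model augmented by the other channel's lags,

$$X_A(t) = a_0' + \sum_{i=1}^{p} a_i' X_A(t-i)
          + \sum_{i=1}^{p} b_i' X_B(t-i) + \varepsilon_{BA}(t).$$

The magnitude of Granger causality is the Geweke log variance ratio

$$G(B \to A) = \ln \frac{\operatorname{var}(\varepsilon_A)}
                         {\operatorname{var}(\varepsilon_{BA})} \ge 0 ,$$

with residual variances as maximum-likelihood ($1/T_{\mathrm{eff}}$)
estimates. Note the orientation: some write-ups of this statistic print
the ratio with the full-model variance on top, which is nonpositive
under least-squares nesting; since the weights are treated as
nonnegative "intensities" throughout, the conventional reduced/full
orientation is implemented and this choice is deliberate.

Three further choices the model text leaves open:

* **Order selection.** One common order $p$ per pair (used by both
  directions, reduced and full models) minimizes the bivariate VAR BIC
  $T_{\mathrm{eff}} \ln \det \Sigma + k \ln T_{\mathrm{eff}}$ over
  $p = 1..p_{\max}$, ties toward the smaller order. All candidates are
  scored on the common sample that conditions on $p_{\max}$ initial
  values. $p_{\max}$ defaults to 10 (one second at 10 Hz) and is
  configurable.
* **ML variance.** The $1/T_{\mathrm{eff}}$ residual variance (not the
  dof-corrected one) guarantees $G \ge 0$ exactly; values are clamped
  at zero against floating-point jitter.
* **Session, not trials.** One causal map per participant and condition
  is computed from the full preprocessed session series; fixation
  periods are not excised. GC is strictly bivariate — no conditional or
  multivariate variant — so indirect paths can leak into pairwise
  weights (see *Limitations*).

Under independence $T_{\mathrm{eff}} \cdot G$ is asymptotically
$\chi^2_p$, so null weights carry a small-sample bias of about
$p/T_{\mathrm{eff}}$; the tests verify both the bias and the quantiles.

# Preprocessing

The chain runs in a fixed order, per channel, and is recorded in the
recording's provenance; re-running it on a preprocessed recording is an
error.

1. **HRF-shaped low-pass** (`hrfLowpass()`): causal convolution with
   the canonical double-gamma hemodynamic response function (peak delay
   6 s, undershoot delay 16 s, unit dispersions, peak:undershoot ratio
   6), sampled at `fs` over 32 s and normalized to unit sum. The onset
   is reflect-padded so output length equals input length and no filter
   transient biases the subsequent VAR fits. This suppresses cardiac
   (~1.2 Hz) and respiratory (~0.3 Hz) oscillations.
2. **Detrending** (`detrendRecording()`): the reference pipeline used a
   wavelet-MDL detrend whose internals are delegated to external
   software and not specified; the default here is a transparent
   substitute — projection onto a discrete-cosine basis of periods
   longer than 128 s plus mean and linear trend (an SPM-style
   high-pass). A `wavelet_mdl` option implements the same intent as a
   Haar pyramid whose coarse (approximation) coefficients are removed
   at the depth minimizing a minimum-description-length score
   $\tfrac{n}{2}\ln(\mathrm{RSS}/n) + k \ln n$; candidate depths extend
   two dyadic levels below the nominal cutoff scale because smooth
   drift leaks into finer bands, and the MDL penalty is what protects
   genuine signal from over-removal.
3. **Two-point baseline correction** (`baselineCorrect()`): per
   channel, the straight line through the means of the 2-s pre-task and
   post-task baseline windows is subtracted, zeroing both window means.

# Group statistics

## The ANOVA reduction

With a two-level within-participant factor (condition) and a continuous
between-participant covariate (age), the repeated-measures ANOVA
reduces exactly to two ordinary regressions on per-participant summary
scores, $M_i = (y_{i,\mathrm{own}} + y_{i,\mathrm{other}})/2$ and
$D_i = y_{i,\mathrm{own}} - y_{i,\mathrm{other}}$:

* age main effect — slope of $M$ on centered age,
* condition (race) main effect — intercept of $D$ on centered age,
* age-by-condition interaction — slope of $D$ on centered age,

each $F(1, N-2)$; with $N = 124$ this reproduces the reference
denominator df of 122, and
$\eta_p^2 = F \, \mathrm{df}_1 / (F \, \mathrm{df}_1 + \mathrm{df}_2)$.
Age is mean-centered, so the race effect is evaluated at the cohort
mean age (the reference analysis is silent on this; centering is the
standard covariate convention). The reduction is verified against an
independent `lm()`-based oracle to 1e-8.

## Bootstrap-averaged effect sizes and the permutation null

The observed edge statistic is the mean partial eta-squared over `B`
random 50% subsamples drawn without replacement ("down-sampling";
drawing with replacement is the other reading of the source text). The
null scrambles the two condition labels per participant — a fair-coin
sign flip of $D_i$, the exchangeability-preserving scheme for paired
data — and the decision rule is membership in the top 5% of the null
distribution, reported via the add-one permutation p-value
$(1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + B) < 0.05$.

One design question the procedure's verbal description leaves open is
what exactly a null replicate is. Two schemes are implemented
(`scheme=` in `permutationNull()`, `edgeInference()`,
`cohortEdgeStats()`):

* `"averaged"` (default): every condition-flip replicate is averaged
  over the *same fixed collection* of subsamples used for the observed
  statistic. Observed and null values are then exchangeable under the
  per-participant flip group, so the top-5% rule has its nominal 5%
  size — which is exactly what the package's calibration acceptance
  check measures (200 null cohorts, $N = 124$, $B = 500$).
* `"single"`: the literal reading — each replicate is one flip plus one
  fresh subsample. The null then carries subsampling dispersion that
  the averaged observed statistic does not have, making the test
  conservative (it rejects well below 5%). It is retained for
  comparability, not as the default.

Condition flips leave participant means $M_i$ unchanged, so the
scramble null is degenerate for the age main effect; the age effect's
null is instead built by permuting ages across participants. This
deviation is recorded in the output provenance.

No cross-edge multiplicity correction is applied beyond this procedure,
matching the reference analysis; `p.adjust` can of course be applied to
the returned `permP_*` columns by the user.

## NORE, trends and post-hoc tests

The neural other-race effect of an edge is the per-participant
difference $D_i$ itself; its Pearson correlation with age (two-sided
t-based p) is reported per edge. Interaction-significant edges are
classified into four developmental subtypes from per-condition
least-squares slopes of weight on age: a slope is called "up"/"down"
when its two-sided p < 0.05, else "flat" (the reference description
never defines how "did not change with age" was judged; an uncorrected
per-slope call is the transparent choice), and the sign of the NORE-age
correlation selects the positive or negative family. Edges matching no
pattern are reported unclassified rather than forced. Post-hoc paired
and two-sample t-tests split the cohort at the age median by default
(the reference's younger/older split is undefined).

# The synthetic cohort

`synthConfig()` defaults state the emulated design: 124 participants,
ages continuous on [3.25, 13.49] years, 46 channels at 10 Hz, 20 test
trials of 3 s stimulus + 10 s fixation with 2 s pre/post padding
(2640 samples per condition). Choices where the design is open, made
once:

* **Ages uniform** by default — uniform maximizes leverage for
  age-slope recovery; a truncated-normal option with the reference
  moments (mean 7.77, SD 2.80) exists.
* **Signal model**: every channel is an AR(1) with self-coefficient 0.3
  (mildly smooth, hemodynamic-like fluctuations) driven by unit
  Gaussian innovations; planted couplings are injected at lag 1 by
  default (the simplest structure Granger causality must recover) with
  strength $c(a, \mathrm{cond}) = \mathrm{base} + \mathrm{ageSlope}
  \cdot a + [\mathrm{own}](\mathrm{condOffset} + \mathrm{interSlope}
  \cdot a)$. Configurations whose VAR is non-stationary anywhere in the
  cohort are rejected at generation time.
* **Nuisance**: cardiac (1.2 Hz, amplitude 0.5), respiratory (0.3 Hz,
  0.5) and Mayer-wave (0.1 Hz, 0.8) sinusoids with per-participant
  random phases shared between the two conditions of a participant —
  amplitudes of the order of the signal SD, so the benefit of
  preprocessing is measurable.
* **Recovery scenario**: the packaged tests plant three directed
  interaction edges with base 0.2 and interSlope 0.007 per year. This
  scale was set so that the *recovered* interaction effects resemble
  small effects typical of developmental connectivity studies
  (NORE-age correlations around 0.45 and bootstrap-averaged
  $\eta_p^2$ around 0.2, versus reference-scale printed correlations of
  0.24–0.30) while keeping recall stable; much stronger couplings are
  unrealistic and also exaggerate pairwise-GC leakage around planted
  edges.

What the generator does **not** emulate: motion artifacts, optical
density to concentration conversion, spatially correlated optode noise,
task-locked evoked responses, or hemodynamic blurring by default (a
`hrfSmoothing` flag convolves the generated series with the HRF kernel
when that is wanted). A green recovery test therefore establishes that
the pipeline recovers planted linear VAR structure under physiological
drift — not that it would be robust to artifacts the generator does not
produce.

# Numerical choices and degenerate inputs

* All fits condition on the longest candidate lag so reduced/full model
  pairs share rows; nonnegativity of $G$ is then exact, and tiny
  negative values from floating point are clamped to zero.
* BIC ties break toward the smaller order (`which.min`).
* Constant (degenerate) channels make the lag design singular; in
  `causalMap()` their incident edges become `NA` (not zero) with a
  warning, and downstream edge statistics skip undefined edges.
* Degenerate subsets (zero age variance) are redrawn with a capped
  retry count; identical conditions give race/interaction $F = 0$
  (0/0 is resolved to "no evidence"), and a zero-variance difference
  score with nonzero mean flags a degenerate race test.
* The permutation p-value uses the add-one estimator, so it is never 0
  and the top-5% rule at $B = 500$ has size $25/501 \approx 4.99\%$.

# Limitations

* Pairwise GC is not conditional GC: strong planted couplings bleed
  into neighboring edges (a channel whose predictability changes with
  condition shifts all of its bivariate fits slightly). The recovery
  acceptance check quantifies this as the false-edge rate; at the
  packaged recovery scale it stays near the nominal size, but at
  coupling strengths several times larger it visibly exceeds it.
* The HRF low-pass removes most high-frequency information by design;
  causal structure living mainly above ~0.5 Hz is attenuated, and the
  BIC typically responds to the induced smoothness by selecting large
  orders.
* The wavelet-MDL detrend is a reconstruction of an unspecified
  external step, not a re-implementation; the DCT default is the
  reproducible reference path.
* Effect sizes from 50% subsamples are biased upward relative to
  full-sample values (smaller denominator df); the procedure compares
  like with like, but the `boot_*` columns should not be read as
  unbiased estimates of population $\eta_p^2$.
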