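---
title: "Linear and nonlinear brain-muscle connectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear and nonlinear brain-muscle connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After a hemiparetic stroke, damage to the corticospinal tract (the direct,
few-synapse motor pathway) is thought to shift control of the paretic arm
toward indirect, multi-synaptic pathways descending from the contralesional
hemisphere via the brainstem. This shift expresses itself clinically as the
flexion synergy: involuntary elbow/wrist/finger flexion coupled to shoulder
abduction. Classical corticomuscular coherence — iso-frequency coherence
between scalp EEG and surface EMG — sees mostly the direct pathway, because
each synaptic stage of an indirect pathway acts approximately as a static
nonlinearity on the descending drive, dispersing coherent power across
frequency ratios rather than keeping it at one frequency. Quantifying that
cross-frequency (nonlinear) coupling is the point of this package.

`bmconn` implements the full analysis chain: preprocessing of synchronized
EEG/EMG/torque recordings, a cross-spectral connectivity (CSC) estimator
covering both iso-frequency and n:m cross-frequency coupling, summary
indices (EEG-power Laterality Index, nonlinear-over-linear N-L index,
maximum voluntary torque with a consistency rule, flexion-synergy ratio),
an assumption-gated group-comparison stage, and a synthetic generator that
stands in for human recordings so every stage is testable end to end.

## The estimator

Signals are cut into 1 s epochs with 250 ms overlap, giving Fourier
coefficients $X_l(f)$, $Y_l(f)$ per epoch $l$ on an exact 1 Hz grid.
For a frequency pair $(f_X, f_Y)$ with $n : m = f_X : f_Y$ in lowest terms,
the cross-spectral connectivity is

$$
\mathrm{CSC}(f_X, f_Y) \;=\;
\frac{\bigl|\tfrac1L \sum_l X_l(f_X)^{\,m}\, \overline{Y_l(f_Y)^{\,n}}\bigr|}
     {\sqrt{\tfrac1L \sum_l |X_l(f_X)|^{2m}\;\cdot\;
            \tfrac1L \sum_l |Y_l(f_Y)|^{2n}}}
$$

Raising $X$ to $m$ and $Y$ to $n$ makes both factors rotate at the common
frequency $m f_X = n f_Y$, so a consistent n:m phase relation accumulates
coherently over epochs. Two choices here were genuinely open and are worth
stating:

* **Denominator.** The square-rooted product of the matching higher-order
  auto-spectra is used, so that the statistic is bounded by 1 through the
  Cauchy–Schwarz inequality and reduces *exactly* to classical magnitude
  coherence at $n = m = 1$. Without the square root the statistic is not
  dimensionless and can exceed 1.
* **Exponent assignment.** The exponents follow phase matching ($X^m$
  against $Y^n$), and the denominator orders mirror the numerator's
  exponents. This is isolated in one kernel function so an alternative
  convention can be swapped in.

The traversal covers integer $f_X \in [1, 100]$ Hz (EEG) and
$f_Y \in [20, 100]$ Hz (EMG): all iso-frequency pairs in the intersection
(linear kind) and all $f_X \neq f_Y$ with $\gcd(f_X, f_Y) > 1$ (nonlinear
kind), with $n = f_X/g$, $m = f_Y/g$. The pair list is deterministic and
sorted; `enumerate_pairs()` materializes it as a data frame.

Numerically, coefficients are renormalized to unit RMS per channel and
frequency before exponentiation. The statistic is invariant to that
rescaling in exact arithmetic, but without it $|c|^{2m}$ underflows to zero
for high orders (coefficients of order $10^{-3}$ raised to powers up to
100), which would masquerade as silent channels. True silent channels
(zero denominator) yield `NA`, are counted, and are reported as missing
rather than imputed.

## Indices

* **Laterality Index**: per-channel power is the epoch-averaged RMS
  amplitude; $LI = (CS - IS)/(CS + IS)$ where $CS$ sums the nine
  sensorimotor electrodes (FC/C/CP 1-3-5 or 2-4-6) of the
  contralateral/ipsilesional hemisphere and $IS$ the other nine.
  $LI > 0$ means contralateral/ipsilesional dominance.
* **N-L index**: $\mathrm{NL} = (S_N - S_L)/(S_N + S_L)$, contrasting
  aggregated nonlinear against linear CSC. The default (`literal` mode,
  `sum` aggregation) follows the index's printed definition, which splits
  electrodes by hemisphere: $S_L$ over the contralateral/ipsilesional set,
  $S_N$ over the ipsilateral/contralesional set. Because it is not
  resolvable whether that split is intentional, a `pooled` mode (both sums
  over all 18 electrodes) is first-class, as is `mean` aggregation — the
  nonlinear pair set (~2200 pairs) is 30 times larger than the linear one
  (81), so a raw sum is mechanically pushed toward $+1$ regardless of the
  physiology; the per-pair mean removes that imbalance.
* **MVT**: mean of three maximal efforts, accepted only when the spread
  (max − min) is at most 10% of the mean; otherwise `NA` with a warning,
  signalling that trials must be repeated.
* **Flexion-synergy ratio**: mean involuntary elbow-flexion torque over
  all hold windows, divided by the elbow-flexion MVT. The mean over the
  hold (rather than a median or plateau estimate) was chosen for
  simplicity and linearity; on simulated holds the three summaries differ
  negligibly.

## Preprocessing

Zero-phase filtering uses 4th-order Butterworth high-pass and low-pass
stages in cascade, each applied forward and backward (net zero phase,
doubled attenuation slope), with odd-reflection padding scaled to the
slowest band edge to suppress start-up transients. The cascade, rather
than a single band-pass design, keeps the recursion stable when the low
edge is a tiny fraction of Nyquist (1 Hz at 2048 Hz sampling). Measured
attenuation of the implemented chain exceeds 100 dB one decade outside
the band — comfortably past the 40 dB the analysis requires. The notch is
a 58–62 Hz Butterworth band-stop of the same construction.

EMG is band-passed 20–100 Hz, full-wave rectified, and normalized to the
single-sample peak of the rectified maximal-effort recording (the simplest
reproducible reading of "peak rectified EMG"; a smoothed peak would only
rescale the dimensionless envelope). Epochs never straddle trial
boundaries; a 10 s hold yields exactly 13 epochs. EEG epochs whose peak
amplitude on any channel exceeds 100 µV (configurable) are rejected, and
the same epochs are dropped from the EMG stream to keep the cross-spectra
aligned. An optional `artifact_hook` on the filtered continuous EEG is the
integration point for component-based artifact removal (e.g. ICA), which
is published prior work and not re-implemented here; the default is
pass-through.

## The synthetic generator

`simulate_subject()` emulates the statistical structure the analysis
assumes, not the biophysics:

* **Cortical source**: band-limited (8–30 Hz) Gaussian noise — filtered
  white noise — so epoch-to-epoch phase variability is realistic and
  coherence estimation is nontrivial.
* **EEG**: the source is projected onto the 18 sensorimotor electrodes
  with amplitude `lateral_ratio` on the CS hemisphere versus 1 on the IS
  hemisphere (0.3 elsewhere), plus per-channel pink noise at
  `snr_eeg` = 15 dB. The montage is 32 10/20 labels: the 18 sensorimotor
  electrodes the indices require plus 14 standard sites.
* **EMG**: a broadband carrier (20 – min(400, 0.45·fs) Hz white noise) is
  amplitude-modulated by the pathway drive and white sensor noise is
  added (`snr_emg` = 10 dB, `modulation_depth` = 0.3 — chosen so the
  recovered iso-frequency coherence lands in the 0.1–0.4 range typical of
  corticomuscular coherence). The drive is
  $\alpha\,\mathrm{lin}(t) + \beta(\mathrm{load})\,N_k(\mathrm{nl}(t))$,
  where the two pathway inputs are the source delayed by 10 ms (direct)
  and 30 ms (indirect).
* **Indirect pathway** $N_k$: $k$ = 3 cascaded static stages
  $u \mapsto u + 0.5u^2$, re-standardized per stage. A static map on a
  Gaussian input retains a component exactly proportional to the input
  (Bussgang), which would leak *linear* coherence through the indirect
  pathway; that projection is removed, so $\alpha$ and $\beta$ control
  the linear and nonlinear couplings separately. `load_scaling` doubles
  $\beta$ at the 40% load, encoding progressive indirect-pathway
  recruitment.
* **Torque**: holds sit at the target fraction of the shoulder-abduction
  MVT with slow (0.2–1.5 Hz) fluctuation; the elbow-flexion channel
  carries `ef_synergy_ratio` × EF-MVT during holds. The MVT condition is
  three 3 s maximal efforts on both axes with a stronger EMG carrier.

Within a recording the generator is stationary — rest gaps carry the same
statistics as holds and are simply never analysed — and pathway delays are
circular so signal length and stationarity are exact. Group presets
(`group_preset()`) encode the study conditions: stroke subjects get
$\alpha = 0.4$, $\beta = 1.2$, $\lambda$ = 0.85/0.75 at the 20/40% loads
and synergy ratios 0.15/0.35; controls get $\alpha = 1.2$, $\beta = 0.15$,
$\lambda = 1.3$ and synergy ratios 0.02/0.03.

What the generator does **not** emulate: volume conduction or any head
model (channels share one source plus independent noise), neural-mass or
conductance-based dynamics, nonstationarity within holds, movement or
ocular artifacts, and electrode impedance drift. Passing tests on this
generator therefore demonstrate that the estimators recover the coupling
structure they were designed for — not that they are robust to everything
real recordings contain.

## What the estimator can and cannot show at this scale

Two properties of the CSC null matter when interpreting the N-L index, and
both are visible in this package's own measurements:

1. **Order-dependent null bias.** Under independence the expected CSC at
   $n = m = 1$ is $\approx \sqrt{\pi/4L}$ (about 0.05 at $L = 325$
   epochs), but for high coupling orders the epoch products $X^m\bar Y^n$
   are heavy-tailed and the normalized modulus of their mean is *smaller*
   (about 0.02 on average over the full nonlinear pair set). The mean
   over the ~2200 nonlinear pairs therefore starts about 0.03 *below*
   the mean over the 81 linear pairs even when no coupling of either kind
   exists. At very high orders the opposite degeneracy appears in single
   pairs: when one epoch dominates both heavy-tailed sums, CSC approaches
   1 regardless of phase (the values remain within [0, 1]; they are
   simply uninformative at those orders and small $L$).
2. **Intermodulation dilution.** With a broadband Gaussian source, the
   $2f$ bin of a squared signal mixes every frequency pair summing to
   $2f$, of which only the $(f, f)$ diagonal is phase-locked to
   $X(f)^2$; over a 22 Hz-wide band this caps the true 1:2 CSC near
   0.1–0.2 at *any* SNR.

Together these mean the pooled/mean N-L index of a purely nonlinear
recording (α = 0) still sits below zero at feasible epoch counts: the
real nonlinear lift (< 100 truly coupled pairs at ≲ 0.1 above their null)
cannot overcome the 0.03 null-bias gap spread over the full pair set. The
index is nevertheless strictly increasing in the nonlinear gain and
strictly decreasing in the linear share, so *contrasts* of the index —
between groups, between loads, along a gain sweep — are meaningful where
its absolute sign is not. The test suite asserts exactly the monotone
behaviour; the sign-at-α=0 expectation is asserted once in the acceptance
suite and documented as failing for the reasons above. Analyses that sum
only suprathreshold connectivity (screened against the permutation null,
`permutation_null()`) would restore an interpretable sign, at the cost of
a screening threshold; that variant is deliberately left out of the
index's contract.

## Statistics

Shapiro–Wilk (per sample) and Levene (across samples) gate the
comparisons at α = 0.05. Load comparisons within a group are paired t
tests — one-tailed for the stroke group, with the hypothesized directions
(N-L up, LI down, synergy up at the higher load), two-tailed for
controls. Group comparisons are one-tailed two-sample t tests, pooled
when the Levene gate passes and Welch otherwise. A "paired Welch" is not
a defined procedure, so heteroscedasticity in a paired comparison only
logs a warning (the paired t needs no homoscedasticity). Degenerate
inputs (zero-variance differences) return exact limits (t = 0, one-tailed
p = 0.5 / two-tailed 1 for identity; p = 0 for a certain in-direction
effect) rather than NaN. No multiple-testing correction is applied,
matching the analysis design this package reproduces.

## Problem sizes

The defaults mirror the acquisition protocol: 2048 Hz sampling, 25 trials
of 10 s holds, giving 325 epochs. The package's own test and acceptance
runs use reduced sizes chosen to keep the full pipeline cheap while
leaving every spectral quantity identical: 512 or 256 Hz sampling (all
band edges and the 1 Hz grid are unchanged; 100 Hz stays below Nyquist),
4–25 trials depending on how many epochs the property under test needs,
and 8 + 8 simulated subjects for cohort runs. Parameter-recovery checks
(laterality ratio, gain monotonicity) use 130–325 epochs; estimator
identities (oracle equivalence, perfect coupling, bounds) are
size-independent.
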