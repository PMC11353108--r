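---
title: "From tetrapolar impedance to tissue conductivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From tetrapolar impedance to tissue conductivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetracond)
```

## The measurement model

A tetrapolar (four-electrode) probe injects current through its outer
needles and senses voltage on the inner pair, removing electrode–tissue
contact impedance from the reading. A swept-frequency analyser reports the
complex impedance $Z(f) = R(f) + iX(f)$ at 256 log-spaced frequencies from
3 kHz to 1 MHz. The quantity of physiological interest is the bulk
conductivity $\sigma(f)$ in S/m.

Three relations connect them. The conductance is the real part of the
admittance,
$$G(f) = \frac{R}{R^2 + X^2},$$
and for an ideal measurement $\sigma = \kappa\,G$ with $\kappa$ the probe's
cell constant (units 1/m; default 25 1/m, an order-of-magnitude value for a
1 mm-spaced needle tetrapole, giving tissue impedances of tens to hundreds
of ohms). Real instruments are not ideal: stray capacitance and lead
inductance bend the high-frequency end of the spectrum. The calibration
exploits a saline buffer whose true conductivity $\sigma_{ref}$ is flat in
frequency, so any frequency dependence of its *measured* conductance is
instrumental. The conversion factor
$$k(f) = \frac{\sigma_{ref}}{G_{buffer}(f)}$$
absorbs $\kappa$ and the instrument response at once, and
$$\sigma_{tissue}(f) = k(f)\, G_{tissue}(f).$$

For a distortion-free instrument $k(f) \equiv \kappa$ exactly; with
distortion, $k(f)$ cancels whatever is *common* to buffer and tissue. The
cancellation is exact for multiplicative common-mode errors and approximate
for the full parasitic network, because the distortion depends on the
impedance level of the device under test and tissue does not sit at the
buffer's impedance. The package quantifies this residual rather than hiding
it: under default parasitics the calibrated error is $\sim 10^{-5}$ at
3 kHz and a few percent at 1 MHz, and calibrating with the 0.062 S/m buffer
instead of the 0.25 S/m one shifts the 1 MHz result by $\sim 0.1\%$. The
0.25 S/m buffer is the default because its impedance is closest to tissue
at low frequency.

Two deliberate strictnesses: grids are never interpolated (a tissue
spectrum must share the buffer's sweep, to a relative tolerance of
$10^{-9}$ per point), because interpolation would silently bend $k(f)$
exactly where the parasitics are steep; and $k(f)$ is applied raw, without
smoothing — smoothing would trade a documented variance for an undocumented
bias, and the self-calibration identity ($k \cdot G_{buffer} \equiv
\sigma_{ref}$) would no longer hold by construction.

Records whose spectra cannot be calibrated (singular impedance, mismatched
grid, non-positive conductivity) are dropped and logged with a reason,
never imputed; per-condition group sizes therefore vary, as they do in
clinical practice where technically invalid records are excluded.

Temperature is carried as metadata only. In vivo and ex vivo tissue sit at
different temperatures (≈ 36 °C vs ≈ 20 °C) and conductivity is
temperature-dependent, but no correction is applied by default: the in
vivo/ex vivo contrast *includes* the temperature difference as measured,
and any correction factor would be tissue-specific guesswork. The
`calibrate_cohort()` surface deliberately has no hidden correction.

## The forward simulator

The simulator exists so that the full chain — acquisition, calibration,
cohort statistics — can be validated against known ground truth. It
emulates:

* **Tissue dispersion.** Impedance follows the Cole model
  $Z(f) = R_\infty + (R_0 - R_\infty)/(1 + (if/f_c)^\alpha)$, the standard
  empirical description of the β-dispersion band; with $R_0 > R_\infty$ the
  derived $\sigma(f)$ rises monotonically with frequency, as liver tissue's
  does.
* **Buffers.** Purely resistive, frequency-flat, measured with the same
  cell constant as tissue (same physical probe).
* **Instrument parasitics.** A minimal two-element network — series lead
  inductance, stray capacitance in parallel with the device under test:
  $Z_{meas} = i\omega L + Z/(1 + i\omega C Z)$. Defaults
  ($L = 0.5\,\mu$H, $C = 0.5$ nF) are set so the distortion is material at
  1 MHz (> 5 % of $|Z|$ for tissue-like impedances) and negligible at
  3 kHz, reproducing the characteristic pre-calibration magnitude rise and
  phase roll at the top of the band.
* **Cohort structure.** Six groups (normal / tumor / cirrhotic × in vivo /
  ex vivo) with group sizes and conductivity distributions matching the
  liver study the package models: e.g. in vivo tumor (n = 16)
  0.41 ± 0.10 S/m at 3 kHz and 0.78 ± 0.24 S/m at 1 MHz.

### How a patient is drawn

Each patient gets a pair of conductivity anchors
$(\sigma_{3\,\mathrm{kHz}}, \sigma_{1\,\mathrm{MHz}})$:

1. **Marginals.** Each anchor follows a normal distribution truncated to
   positive values. The configured mean/SD are treated as moments of the
   *realized* (truncated) distribution, and the parent parameters are
   solved by moment inversion — so the sample mean of a simulated group is
   an unbiased estimate of the configured mean. Using the configured values
   as pre-truncation parameters instead would bias groups whose SD is large
   relative to the mean by up to several percent. Configurations whose SD
   is unattainable under positivity truncation are rejected as errors.
2. **Within-patient coherence.** The two anchors are coupled through a
   Gaussian copula with latent correlation 0.8 (configurable): a patient
   who conducts well at 3 kHz conducts well at 1 MHz. Besides realism, this
   makes violations of the physiological ordering
   $\sigma_{1\,\mathrm{MHz}} > \sigma_{3\,\mathrm{kHz}}$ rare (~0.1 %);
   violating pairs are redrawn, with negligible effect on the marginals.
   Under independent draws the redraw would noticeably inflate the
   high-frequency mean of wide, overlapping groups.
3. **Cole mapping.** Dispersion shape parameters are drawn uniformly —
   $f_c \in [10, 100]$ kHz, $\alpha \in [0.8, 1]$ — and $(R_0, R_\infty)$
   are then solved (damped 2-D Newton with analytic Jacobian, initialised
   at the limit mapping $R_0 = \kappa/\sigma_{3\,\mathrm{kHz}}$,
   $R_\infty = \kappa/\sigma_{1\,\mathrm{MHz}}$) so that
   $\kappa\,\mathrm{Re}(1/Z)$ equals the drawn anchors *exactly at the band
   edges*. Anchoring at 3 kHz and 1 MHz rather than at the DC and
   infinite-frequency limits matters: with $\alpha < 1$ the dispersion
   tails are heavy, and limit-anchored parameters would miss the band-edge
   targets by up to ~15 % for strongly dispersive groups, destroying the
   correspondence between configured and realized group statistics.
4. **Feasibility.** A given $(f_c, \alpha)$ bounds the achievable
   conductivity rise across the band (at $f_c = 100$ kHz, $\alpha = 0.8$
   the ceiling is ≈ 4×). Draws that cannot span the patient's rise are
   replaced — first by redrawing $(f_c, \alpha)$, then down a deterministic
   ladder toward lower $f_c$ and $\alpha \to 1$ — without ever touching the
   anchors, so the anchor distribution is preserved. The default $f_c$
   range stops at 100 kHz because higher characteristic frequencies cannot
   produce the 3–4× rise real liver groups exhibit. Only anchor pairs whose
   rise exceeds even the ladder's ceiling (requiring
   $\sigma_{3\,\mathrm{kHz}} < 1$ mS/m, below any liver tissue) are redrawn
   outright (~0.1 % of draws in the widest group).

Randomness is seeded per group through a deterministic hash of the group
label, so adding a group never perturbs the draws of existing ones, and the
whole cohort is byte-reproducible from one integer seed.

### What the simulator does not emulate

Electrode polarization, tissue heterogeneity and anisotropy, inter-patient
pairing (each record is drawn independently even when a real patient
contributes several conditions), temperature drift, and measurement noise
beyond the deterministic parasitic network. Passing recovery tests on
simulated cohorts therefore demonstrates the *pipeline's* correctness —
that the calibration algebra, exclusion logic and statistics do what they
claim — not that the Cole model captures every feature of clinical spectra.

## Cohort statistics

* **Analysis frequencies.** Five targets (3, 30, 300, 607, 1000 kHz) are
  mapped to the nearest grid frequency; ties break toward the lower
  frequency, and the frequency actually used is always reported.
* **Summaries.** Sample mean and SD (n − 1 denominator) per group; a group
  of one reports its mean with SD absent — not zero. Cirrhotic tissue is
  its own class, never pooled with normal.
* **Ratios.** Ratios of *group means* (Tin/Nin, Tin/Tex, Tex/Nin, Tin/Cin,
  Tex/Cin, Nin/Cin), not means of per-patient ratios: groups are unequal
  and unpaired, so per-patient ratios are undefined for most records. Raw
  values are kept alongside 1-decimal rounding (half away from zero) for
  report rendering. With this definition the chain identity
  $r(A,C) = r(A,B)\,r(B,C)$ holds exactly before rounding. Recomputing the
  bundled reference summary table this way reproduces 11 of the 12
  checkable printed ratio cells at 3 and 1000 kHz; the remaining cell
  (in vivo tumor vs cirrhotic at 3 kHz, printed 4.4 vs computed
  0.41/0.09 ≈ 4.6) appears to reflect a different intermediate rounding in
  the source report, and both values are surfaced rather than reconciled.
* **Hypothesis testing.** The path is always nonparametric: small
  per-condition n (3–16) makes normality screening uninformative, and the
  conclusions rest on the tie-corrected Kruskal–Wallis test throughout.
  Mid-ranks over the pooled sample give
  $H = \tfrac{12}{N(N+1)} \sum_i n_i(\bar r_i - \tfrac{N+1}{2})^2$,
  corrected by $H^* = H / (1 - \sum(t^3 - t)/(N^3 - N))$, with p from the
  upper χ² tail on k − 1 degrees of freedom. All-identical data are a
  degenerate-ties error, not a p-value. The implementation is checked
  against `stats::kruskal.test` as an independent oracle in the test suite.

## Field geometry

Around a long cylindrical electrode of radius $r_0$ the field decays as
$E(r)/E_0 = r_0/r$. With the 3 mm in-line array centred in a tumor of
smallest dimension $d$, the outermost electrode sits $(d - 3)/2$ mm from
the boundary. The radial coordinate is taken from the electrode *axis*:
for the default $r_0 = 0.175$ mm and a 10 mm tumor this gives
$0.175/3.5 = 5\,\%$ at the boundary, the conventional worked value. A
surface-measured distance would give $0.175/3.675 = 4.8\,\%$; the axis
convention is implemented because it is the one under which the standard
numbers are exact, and the ambiguity only matters at the ~5 % level of the
estimate itself.

## Reference tables

The package bundles the published group summaries, ratio table,
tumor-type breakdowns and per-patient 1 MHz values of a 19-patient
hepatic-resection cohort as plain-CSV fixtures. Three cells whose printed
form had an obvious dropped decimal point ("012", "041", "043") are stored
normalized and flagged `typo_normalized`; inconsistencies in the source
(e.g. a stated n = 16 against 15 printed values) are preserved as printed,
not repaired.

## Problem sizes and numerical tolerances in the test suite

The suite validates: exact parasitic-free round-trips (50–56 records, full
256-point grids, recovery to $10^{-10}$ relative); anchor-moment recovery
at n = 200 per group against 3-standard-error bands; type-I error of the
rank test over 2 000 null cohorts of 4 × 15 observations (acceptance band
0.03–0.07 at α = 0.05); and agreement of the conductance algebra with
direct complex arithmetic to $10^{-12}$ relative over 1 000 random spectra.
These sizes were chosen so each statistical check has enough resolution to
fail meaningfully while the whole suite runs in well under a minute on one
core.

## Known limitations

* The cell constant default is an order-of-magnitude estimate; absolute
  conductivities from uncalibrated spectra inherit its uncertainty (the
  buffer calibration removes it entirely, which is the point of the
  method).
* The two-element parasitic network reproduces the qualitative
  high-frequency artefact structure but is not a fitted model of any
  specific analyser.
* Ratio and summary reproduction against the bundled reference tables is
  limited by the 2-decimal precision of the printed values.
* The instrument's true 256-frequency grid is unpublished; the default
  log-spaced grid is the standard sweep design and pins both endpoints
  exactly.
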