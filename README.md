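# tetracond

Buffer-calibrated tetrapolar bioimpedance spectroscopy and tissue
conductivity analysis in R.

## The problem

Electric-field therapies for liver tumors — irreversible electroporation
(IRE) and radiofrequency ablation — and impedance-based tissue diagnostics
all depend on the electrical conductivity σ (S/m) of the target tissue in
the 3 kHz – 1 MHz band. Swept-frequency tetrapolar probes measure the
complex impedance Z(f) = R + iX at hundreds of frequencies, but converting
that into conductivity requires (a) a geometric cell constant for the probe
and (b) compensation for the instrument's stray capacitance and lead
inductance, which corrupt the high-frequency readings.

`tetracond` implements the standard saline-buffer calibration for this
problem, the cohort-level statistics used to compare tissue classes
(normal / tumor / cirrhotic liver, in vivo / ex vivo), and the electrode
field-geometry estimates that bound the minimal measurable tumor size. A
Cole-dispersion forward simulator generates realistic synthetic cohorts so
every stage can be exercised and validated without clinical data.

## The method

From each measured spectrum, the conductance (real part of the admittance
Y = 1/Z) is

&nbsp;&nbsp;&nbsp;&nbsp;G(f) = R / (R² + X²).

A saline reference buffer of known, frequency-flat conductivity σ_ref
(default 0.25 S/m) measured on the same sweep yields a per-frequency
conversion factor

&nbsp;&nbsp;&nbsp;&nbsp;k(f) = σ_ref / G_buffer(f),

which absorbs both the probe's cell constant and the instrument's frequency
response. Tissue conductivity follows as

&nbsp;&nbsp;&nbsp;&nbsp;σ_tissue(f) = k(f) · G_tissue(f).

Group comparisons use sample means ± SD at five analysis frequencies
(3, 30, 300, 607, 1000 kHz), ratios of group means between tissue
conditions, and the tie-corrected Kruskal–Wallis rank test (H referred to a
χ² distribution with k − 1 degrees of freedom). Field geometry uses the
cylindrical-electrode decay E(r)/E0 = r0/r.

## Worked example

Simulate a full measurement session (56 records across six tissue
conditions, three reference buffers, instrument parasitics on), calibrate
against the 0.25 S/m buffer, and summarize:

```r
library(tetracond)

sim <- generate_cohort(simulation_config(seed = 1))
cal <- calibrate_cohort(sim$records, sim$buffers[["Reference #3"]])
s   <- summarize_groups(cal)
subset(s, frequency_khz == 3)
#>    tissue_class   state frequency_khz frequency_hz_used  n   mean      sd
#> 1     cirrhotic ex_vivo             3              3000  3 0.1625 0.00336
#> 6     cirrhotic in_vivo             3              3000  3 0.0866 0.01264
#> 11       normal ex_vivo             3              3000 16 0.1199 0.05501
#> 16       normal in_vivo             3              3000 15 0.1388 0.04264
#> 21        tumor ex_vivo             3              3000  3 0.3204 0.06754
#> 26        tumor in_vivo             3              3000 16 0.3770 0.10699
```

At 3 kHz the simulated in vivo tumor group (0.38 ± 0.11 S/m) sits well
above in vivo normal tissue (0.14 ± 0.04 S/m), the separation the method is
designed to detect. Ratios of group means and the omnibus rank test:

```r
subset(ratio_table(s), frequency_khz == 3)[, c("ratio", "value", "value_rounded")]
#>     ratio value value_rounded
#> 1 Tin/Nin  2.72           2.7
#> 2 Tin/Tex  1.18           1.2
#> 3 Tex/Nin  2.31           2.3
#> 4 Tin/Cin  4.35           4.4
#> 5 Tex/Cin  3.70           3.7
#> 6 Nin/Cin  1.60           1.6

significance_report(cal)
#>   frequency_khz n_groups h_statistic degrees_freedom  p_value significant
#> 1             3        6        40.1               5 1.46e-07        TRUE
#> ...
#> 5          1000        6        36.3               5 8.20e-07        TRUE
```

The package also bundles the published reference values of a 19-patient
hepatic-resection cohort. The tie-corrected Kruskal–Wallis test across its
four 1 MHz tissue groups:

```r
kruskal_wallis(reference_patient_1mhz_groups())
#> Kruskal-Wallis: H = 28.5385 (df = 3), p = 2.8e-06 [tie-corrected]
```

conductivity separates the tissue conditions decisively. Finally, the
field-geometry bound for the smallest commonly resected tumors:

```r
boundary_effect_estimate(10)   # 10 mm tumor, default 3 mm array, r0 = 0.175 mm
#> [1] 0.05
```

i.e. tissue beyond a 10 mm tumor's boundary sees ≤ 5 % of the electrode
surface field, so boundary contamination is a small-tumor (< 10 mm) concern
only.

A command-line wrapper with `simulate` / `analyze` / `geometry` / `run`
subcommands is provided in `inst/cli/tetracond.R`.

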