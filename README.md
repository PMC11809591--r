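# poslabel

Carbon-positional ¹³C enrichment analysis of GC-(TOF)MS in-source
fragments, built around the paired-fragment measurement of
3-phosphoglycerate (3PGA).

## The problem

RUBISCO fixes CO₂ into the 1-C carboxyl position of 3PGA; the
Calvin–Benson–Bassham (CBB) cycle then redistributes assimilated carbon
into the 2-C and 3-C positions. Bulk labeling assays cannot separate the
two activities because they do not resolve carbon positions. GC-MS
in-source fragmentation can: trimethylsilylated 3PGA yields a fragment
containing all three metabolite carbons (1,2,3-C₃, nominal m/z 459) and a
fragment containing only 2,3-C₂ (m/z 357), measured in the same
chromatogram. Because the fractional enrichment of a substructure is the
average enrichment over its carbon positions,

    E13C_123 = (E1 + E2 + E3) / 3
    E13C_23  = (E2 + E3) / 2
    =>  E1   = 3 * E13C_123 - 2 * E13C_23

the unmeasurable 1-C enrichment follows from the measurable pair. With a
calibrated 3PGA concentration `C_3PGA`, molar positional ¹³C
concentrations are `C13C_1 = 1·E1·C`, `C13C_23 = 2·E23·C`,
`C13C_123 = 3·E123·C` (additive by construction), and fitting a logistic
`I(t) = i_max / (1 + exp(-a (t - t_mid)))` to a ¹³CO₂ pulse time course
gives the assimilation rate `A13C = i_max·a/4` (the midpoint slope) and
the midpoint time per positional group.

The package covers the whole chain for users of dynamic isotope-labeling
GC-MS: formula/mass bookkeeping of derivatized fragments, correction of
measured isotopologue distributions for natural isotope abundance (NIA,
¹³C 1.109% plus H/N/O/Si heavy isotopes from derivatization moieties) and
tracer purity, the positional algebra above, calibration-based absolute
quantification, kinetic rate fitting, EMP/OPP/RUBISCO carbon-fate-map
predictions for tracer validation, and a seeded synthetic-data generator
that stands in for instrument files.

## Worked example

Simulate a wild-type-like steady-state ¹³CO₂ pulse experiment (3
replicates, 0–60 min), run the pipeline, and read off the positional
rates:

```r
library(poslabel)

bundle <- emit_isotopologue_table(sim_config("WT", "HC-HC", seed = 42))
cal    <- simulate_calibration_series(seed = 43)
res    <- run_pipeline(bundle$measurements, bundle$metadata, cal,
                       config = pipeline_config(n_starts = 300))
print(res)
#> <poslabel_pipeline>
#>   corrected enrichments: 72 sample-fragments
#>   paired positional samples: 18
#>   calibration: r^2 = 0.99457, linear 1-150 ng
#>   rate fits: 9 series; 0 not detected (n.d.)
#>   ...

subset(res$fits, replicate == 1,
       select = c(series, i_max, t_mid, a13c, fit_class))
#>     series    i_max    t_mid      a13c fit_class
#>   c13c_123 4.222634 7.948105 0.4848864 sigmoidal
#>    c13c_23 2.706395 8.889630 0.3535168 sigmoidal
#>     c13c_1 1.507052 6.152927 0.1794446 sigmoidal
```

`i_max` is the plateau (nmol ¹³C·OD₇₅₀⁻¹·mL⁻¹), `t_mid` the midpoint time
in minutes, and `a13c` the assimilation rate in nmol·OD₇₅₀⁻¹·mL⁻¹·min⁻¹.
The 1-C midpoint precedes the 2,3-C₂ midpoint — carboxylation labels 1-C
before CBB turnover reaches 2,3-C₂. A CBB-deficient preset
(`sim_config("gapdh2", ...)`) labels 1-C only; the pipeline reports its
2,3-C₂ series as `n.d.`.

Carbon-fate predictions for tracer validation:

```r
predict_positional_enrichment(c(3, 4), f_emp = 1, f_opp = 0)
#>        e1       e23      e123
#> 1.0000000 0.0000000 0.3333333
predict_positional_enrichment(c(3, 4), f_emp = 0, f_opp = 1)[["e1"]]
#> [1] 0.8
```

A thin command-line wrapper with `simulate`, `pipeline` and
`predict-map` subcommands ships in `inst/cli/poslabel.R`.

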