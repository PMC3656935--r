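# acartia

Bioenergetic prediction of hypoxia effects on the coastal copepod
*Acartia tonsa*.

Coastal bottom waters increasingly go hypoxic in summer, and *A. tonsa* —
one of the most abundant estuarine copepods and a key fish-food link — often
resides in them. Whether a given water parcel is harmless, sub-lethally
limiting, or lethal to the copepod depends not on a fixed concentration
standard but on oxygen *partial pressure* relative to the animal's
temperature-driven metabolic demand. This package is for zooplankton
ecologists and coastal modellers who want to translate routine monitoring
data (temperature, salinity, dissolved oxygen in any common unit) into
predicted copepod vital rates.

## The model

Below a critical oxygen partial pressure, diffusive supply caps respiration
linearly in PO₂. At the 18 °C reference the maximum attainable (analogous)
respiration rate is

    ARR = 34.9 · PO₂ − 20.5        [µg O₂ mg dw⁻¹ d⁻¹, PO₂ in kPa]

Two reference rates define thresholds, scaled to ambient temperature with a
salinity-dependent Q10 (1.5 / 2.03 / 2.22 at salinity 15 / 25 / 35):

    P_crit(T,S) = (261.5 · Q10^((T−18)/10) + 20.5) / 34.9     → 8.1 kPa at 18 °C
    P_leth(T,S) = ( 91.0 · Q10^((T−18)/10) + 20.5) / 34.9     → 3.2 kPa at 18 °C

Below `P_crit`, egg production and somatic growth follow the line
(`EPR = 0.00379·ARR` µg dw µg dw⁻¹ d⁻¹, `G = 1.014·ARR` µg C mg dw⁻¹ d⁻¹);
below `P_leth`, 24-h copepodite mortality rises linearly from 0 to 100 % at
`P_leth/2`. The package also converts heterogeneous vital-rate measurements
*into* ARR (the pipeline that parameterized the line), fits the line to
such data, computes bottle-incubation grazing rates (Frost equations), and
generates seeded synthetic datasets for every input format.

## Worked example

Thresholds across temperatures, then classification of three depths at a
warm, brackish station (oxygen supplied in mg/L and converted internally):

```r
library(acartia)

hypoxia_thresholds(c(5, 18, 28), S = 25)
#>   temperature salinity  q10  pcrit pcrit_se pleth pleth_se
#> 1           5       25 2.03  3.572      1.7 1.626      1.7
#> 2          18       25 2.03  8.080      1.7 3.195      1.7
#> 3          28       25 2.03 15.798      1.7 5.881      1.7

po2 <- o2_convert(c(6.5, 3.0, 1.2), "mg_per_L", "kPa",
                  temperature = 26, salinity = 12)
predict_hypoxia_effects(data.frame(label = c("surface", "mid", "bottom"),
                                   temperature = 26, salinity = 12,
                                   po2 = po2))
#>     label temperature salinity po2_kpa pcrit_kpa pleth_kpa   arr egg_production
#> 1 surface          26       12   17.96        11      4.19    NA             NA
#> 2     mid          26       12    8.29        11      4.19 268.8          1.018
#> 3  bottom          26       12    3.32        11      4.19  95.2          0.361
#>   somatic_growth mortality_24h    effect
#> 1             NA            NA      none
#> 2          272.6         0.000 sublethal
#> 3           96.6         0.419    lethal
```

Reading: at 26 °C the critical threshold is already 11 kPa, so the
mid-depth sample (8.3 kPa ≈ 3 mg/L — *above* the traditional 2 mg/L
hypoxia standard) is predicted sub-lethally limiting, with oxygen-limited
egg production of 1.02 µg dw µg dw⁻¹ d⁻¹; the bottom sample is below the
4.2 kPa lethal threshold with a 42 % chance of death within 24 h.

A command-line wrapper with subcommands (`convert`, `arr`, `fit`,
`thresholds`, `predict`, `grazing`, `simulate`) is installed at
`system.file("scripts", "acartia-cli.R", package = "acartia")`.

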