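Package: acartia
Title: Bioenergetic Model of Hypoxia Effects on the Copepod Acartia tonsa
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts sub-lethal and lethal effects of low dissolved oxygen on
    the coastal planktonic copepod Acartia tonsa. Converts heterogeneous vital
    rate measurements (egg production, somatic growth, ingestion) to analogous
    respiration rates via fixed bioenergetic factors, fits the oxygen-limited
    maximum respiration line, derives temperature- and salinity-specific
    critical (Pcrit) and lethal (Pleth) oxygen partial pressures with Q10
    scaling, and predicts egg production, somatic growth, and 24-h mortality
    probability from environmental temperature, salinity, and oxygen. Includes
    dissolved oxygen unit conversions (kPa, percent saturation, mg/L, mL/L)
    using Benson-Krause solubility, Frost bottle-incubation grazing
    calculations, and seeded synthetic data generators for all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
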