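Package: queftsNPK
Title: Balanced N-P-K Uptake Requirements for Soybean with the QUEFTS Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate balanced nitrogen, phosphorus and potassium
    uptake requirements of soybean from field-trial data with the QUEFTS
    (Quantitative Evaluation of the Fertility of Tropical Soils) yield model.
    Computes plot-level nutrient uptakes, internal efficiencies and harvest
    indices from seed and straw measurements; calibrates maximum-accumulation
    and maximum-dilution envelope coefficients by symmetric percentile
    exclusion of internal efficiencies; runs the forward uptake-to-yield
    engine with pairwise nutrient interactions and a yield-potential plateau;
    inverts it to obtain the balanced uptake requirement curve
    (linear-parabolic-plateau) with per-tonne requirements, internal
    efficiencies and seed-removal accounting; and provides RMSE-based
    validation statistics plus a synthetic field-trial generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
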