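Package: colonmech
Title: Anisotropic Hyperelastic Modelling of Colorectal Tissue Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constitutive modelling and experimental data processing for
    uniaxial tensile testing of colorectal tissue. Implements an anisotropic
    hyperelastic strain-energy model (Yeoh isotropic matrix reinforced by two
    in-plane fiber families with polynomial pseudo-invariant terms), the
    closed-form incompressible uniaxial stress response in the circumferential
    and longitudinal directions, two-objective evolutionary parameter
    identification with Pareto-front selection, a raw tensile-test processing
    pipeline (polynomial smoothing, Butterworth slope filtering, loading-onset
    detection, stress-strain normalisation), specimen width tracking from
    video frames, and a synthetic-data generator emulating the full
    experiment so every stage is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
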