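Package: saxsdecomp
Title: Decomposition of Small-Angle X-ray Scattering Profiles into
    Generalized Guinier-Porod Components
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing one-dimensional small-angle X-ray
    scattering (SAXS) profiles of semi-dilute and concentrated polymer
    systems. Profiles are decomposed into sums of generalized
    Guinier-Porod components plus an optional Porod power-law shoulder by
    weighted nonlinear least squares, with automated initialization from
    Kratky-plot peak positions. Fitted radii of gyration are converted to
    equivalent-sphere diameters, and gel-like profiles can be fitted with
    the Debye-Bueche and Ornstein-Zernike correlation-length models.
    Includes reading and writing of columnar profile files, background
    subtraction, replicate averaging, Kratky transformation, a seeded
    synthetic-profile generator for validation, and a concentration-series
    pipeline producing parameter tables, equivalent-sphere diameters and
    forward-intensity ratios.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
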