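Package: aimpol
Title: Atom-in-Material Polarizabilities and Dispersion Coefficients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes atom-in-material (AIM) polarizabilities and dispersion
    coefficients from partitioned electron-density descriptors. Implements the
    MCLF method (m-scaling of isolated-atom scaling laws, a conduction-limit
    upper bound, three-part iterative dipole screening with updating Gaussian
    widths, proportional polarizability partitioning, an anisotropy
    correction, and a multibody screening function), yielding force-field,
    static, and fluctuating polarizability types plus C6, C8, C9 and C10
    dispersion coefficients via Casimir-Polder integration and quantum Drude
    oscillator parameterization. The Tkatchenko-Scheffler self-consistent
    screening (TS-SCS) baseline is included for comparison, together with
    synthetic-system generators and independent oracles for testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
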