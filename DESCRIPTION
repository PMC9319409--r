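Package: fieldqsar
Title: Field-Based 3D-QSAR Modelling and Binding-Affinity Correlation for
    Congeneric Inhibitor Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative molecular field analysis (CoMFA) and comparative
    molecular similarity indices analysis (CoMSIA) for pre-aligned congeneric
    ligand series: Lennard-Jones/Coulomb and Gaussian similarity fields on a
    lattice, partial least squares regression with leave-one-out
    cross-validation and bootstrap statistics, field-combination search, the
    full internal/external validation metric suite (r_m^2 family, Q_F^2
    variants, concordance correlation), leverage-based applicability domain
    (Williams plot), and StDev*Coeff contour extraction. A companion layer
    post-processes binding free energy tables: pIC50 to Gibbs energy
    conversion, linear interaction energy and MM-PB/GBSA term assembly, and
    experimental-versus-computed correlation with bootstrap standard errors.
    Includes a synthetic congeneric-series generator with a planted linear
    field-activity relationship for end-to-end method validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
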