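Package: duplexmelt
Title: Two-State Melting Thermodynamics and Conformational Analysis of
    Modified RNA Duplexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative characterization of short RNA
    duplexes carrying modified residues such as the N7-regioisomers of
    adenosine and LNA-adenosine. Implements two-state van't Hoff analysis
    of UV absorbance melting curves (per-curve Levenberg-Marquardt fits
    with sloping baselines, averaging of curve fits, and 1/Tm versus
    ln(CT/4) concentration plots), nearest-neighbour extinction
    coefficients, duplex stability comparisons (delta-delta-G at 37 C with
    propagated standard deviations, delta-Tm, and the 15 percent two-state
    consistency check), conformational analysis of duplex coordinate
    frames (glycosidic chi torsions and syn/anti states, middle-base-pair
    hydrogen bonds, leader-algorithm RMSD clustering with cluster-average
    structures), aggregation of per-frame molecular-mechanics energy
    components into predicted hybridization free energies, and seeded
    synthetic-data generators for every input so the whole pipeline is
    testable without instrument or trajectory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    bio3d,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
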