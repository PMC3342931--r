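Package: cnvpotts
Title: Cellular Potts Simulation of Choroidal Neovascularization in the Outer Retina
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-dimensional multi-cell (Glazier-Graner-Hogeweg / Cellular
    Potts) simulator of the choriocapillaris-Bruch's membrane-RPE-photoreceptor
    complex and of choroidal neovascularization (CNV). Cells interact through
    labile contact energies and breakable-spring plastic couplings; four
    diffusing fields (oxygen, RPE-derived VEGF-A, short-diffusing VEGF-A and
    MMP) drive chemotaxis, endothelial survival, stalk-cell growth and Bruch's
    membrane degradation. The package enumerates the 108-scenario factorial of
    graded adhesion impairments, classifies simulated CNV by a morphometric
    contact-area weight into sub-RPE (Type 1), sub-retinal (Type 2) and
    combined (Type 3) loci and their progression dynamics, manages replica
    sweeps, and fits the response-surface regressions that relate initiation
    probability and CNV locus to the adhesion parameters. A closed-form
    one-dimensional oxygen profile across the outer retina supports
    calibration of photoreceptor inner-segment oxygen consumption.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
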