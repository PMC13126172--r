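Package: lamellar
Title: Peptide-Membrane Biophysics from CD Titrations and Lamellar Diffraction
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how membrane-active peptides bind and
    reorganize lipid bilayers. Fits lipid-titration circular-dichroism binding
    isotherms with a modified Langmuir model by differential-evolution ensemble
    MCMC; reduces 1-D lamellar X-ray and neutron diffraction traces to indexed
    Bragg peaks, repeat spacings and structure factors (including two-lattice
    decompositions of phase-separated stacks); phases structure factors by
    H2O/2H2O contrast variation, reconstructs scattering-length-density
    profiles by Fourier synthesis, quantifies bound water by deuterium
    difference with d7-lipid amplitude calibration, and propagates
    uncertainties by Monte-Carlo resampling of structure factors; counts
    hydration-shell waters around a solute from XYZ coordinate frames. A
    forward simulator generates every input from planted ground truth for
    closed-loop parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
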