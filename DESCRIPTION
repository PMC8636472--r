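Package: quadstruct
Title: Topology, Stability and Dynamics of DNA G-Quadruplexes from the
    C9orf72 Repeat Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for DNA G-quadruplexes (GQs) formed by the
    (G4C2)n hexanucleotide repeat of C9orf72.  Provides constrained linear
    unmixing of circular dichroism (CD) spectra into antiparallel and
    parallel GQ fractional components, Savitzky-Golay spectral smoothing,
    topology classification from CD peak signatures, Boltzmann sigmoid
    fitting of 295 nm thermal melt curves with melting-temperature
    comparison, atomic GQ model construction and editing (residue deletion,
    base mutation, 3'-extension, strand joining, CpG 5-methylcytosine
    modification, inter-tetrad potassium placement), Hoogsteen tetrad
    detection with plane fitting, and trajectory stability statistics
    (per-tetrad buckle displacement, per-residue RMSD and RMSF after Kabsch
    superposition).  A synthetic-data module generates CD basis spectra,
    crowding titrations, melt curves and rigid-tetrad/mobile-loop toy
    trajectories with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    minpack.lm,
    bio3d,
    seqinr,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
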