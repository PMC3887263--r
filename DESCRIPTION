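Package: HostGuestMS
Title: ESI-MS Annotation and Structural Energetics of Host-Guest Inclusion Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterizing non-covalent host-guest inclusion
    complexes, built around the beta-cyclodextrin/alendronate system.
    Assigns centroided electrospray-ionization (ESI) peak lists to
    host-guest ion stoichiometries by exact monoisotopic mass and isotope
    profile, interprets MS/MS spectra as sequential neutral-loss chains,
    computes complexation energies from supermolecule total energies, and
    detects and classifies intermolecular hydrogen bonds in optimized
    complex geometries by a distance/angle criterion. Ships a synthetic-data
    generator (simulated centroid spectra with ppm jitter and decoy peaks;
    planted hydrogen-bond geometries) so every stage is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'formula.R'
    'species.R'
    'spectrum.R'
    'assign.R'
    'msms.R'
    'structure.R'
    'energetics.R'
    'synthetic.R'
    'workflows.R'
    'zzz.R'
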