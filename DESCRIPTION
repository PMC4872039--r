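Package: hydrokin
Title: Hydration-Structure Dynamics Coupled to Protein Domain Motions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of how local hydration-structure changes couple to
    collective domain motions in multi-domain proteins from molecular
    dynamics trajectories. Provides principal component analysis of
    rigid-body domain motion with separate superposition and analysis atom
    sets, screw-axis hinge extraction, per-residue packing and hydration
    change statistics (solvent-accessible surface area and hydration-water
    counts), sliding-window voxelized solvent electron-density maps in a
    locally superposed frame, region-integrated hydration charge,
    classification of wetting/drying and water adsorption/dissociation
    states, residence-time survival analysis with exponential rate fitting,
    and two-Gaussian modelling of domain height distributions. Includes
    synthetic-trajectory generators (rigid hinge motion, Markovian pocket
    hydration, bulk solvent) with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    graphics,
    utils,
    tools,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'molecular-io.R'
    'domain-pca.R'
    'height-analysis.R'
    'hydration-descriptors.R'
    'state-kinetics.R'
    'solvent-density.R'
    'synthetic-data.R'
    'pipeline.R'
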