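Package: ucspine
Title: Dynamic Upper Cervical Spine (C0-C3) Instability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Marker-based intervertebral kinematics and ligament mechanics for
    the occipito-atlanto-axial complex (C0-C3). Generates synthetic optical
    motion-capture trajectories (500 Hz, four markers per vertebra) with known
    ground truth for physiological and ligament-fatigued (unstable) flexion or
    extension, registers a rigid template to neutral-position markers by a
    triangle-matching construction with an orthogonal-Procrustes oracle,
    recovers per-joint sagittal angle series and range-of-motion summaries,
    evaluates tension-only spring-ligament stress and pressure tables, solves
    a quasi-static sagittal moment-rotation equilibrium under a compressive
    preload, classifies radiographic instability (11 degree / 3.5 mm
    criterion), and runs model-validation statistics (regression, literature
    range containment, paired agreement testing).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
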