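Package: datmotor
Title: Striatal Dopamine-Transporter Imaging and Motor Sequence Learning Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking striatal dopamine-transporter availability
    (DaT-SPECT) to motor-sequence-learning behaviour. Implements keystroke-level
    scoring of a sequential finger-tapping task (correct-sequence duration,
    accuracy, performance index, online/offline learning measures), voxelwise
    "local SBR" quantification of MNI-space DaT-SPECT volumes with
    cluster-extent permutation inference, seed-based normative resting-state
    functional connectivity, cohort statistics (mixed repeated-measures ANOVA
    with Huynh-Feldt correction, Mann-Whitney U, correlations), and seeded
    synthetic-data generators for every input kind the pipeline consumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
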