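Package: lumbomap
Title: Lumbosacral Spinal Cord Task-fMRI Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for task-based functional MRI of the human
    lumbosacral spinal cord. Implements run-level quality control (framewise
    displacement, DVARS scrubbing, temporal SNR), a block-design general linear
    model with a three-function haemodynamic basis and fixed-effects combination
    across runs and conditions, spinal-level delimitation from nerve root entry
    zones, hemicord laterality indices, size-corrected segmental activity
    distributions, and a decision-tree construction of personalized muscle
    projectomes. Ships a synthetic-data module that generates cord geometry,
    block paradigms and 4D BOLD runs with known ground truth so the whole
    pipeline can be exercised and validated without real acquisitions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
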