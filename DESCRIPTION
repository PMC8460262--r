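Package: pupilstate
Title: Brain-State Clustering and Decoding of Pupil Dynamics from
    Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Filip", "Nowak", email = "fnowak@example.org", role = c("aut", "cre"))
Description: Tools to characterize the brain state-dependent coupling between
    pupil diameter dynamics and resting-state fMRI. Per-trial voxel-wise
    pupil-fMRI correlation maps are clustered into brain states (neighbor-graph
    embedding, Gaussian mixture models, silhouette model selection, consensus
    over repeated initializations, half-split / surrogate-map reproducibility
    checks). Pupil traces are decoded from PCA-decomposed fMRI with a
    correlation-template baseline, penalized linear regression, and a gated
    recurrent unit network; decoder weights are back-projected into voxel-wise
    pupil-information maps with randomization-test significance and false
    discovery rate control. A synthetic cohort generator with known latent
    coupling makes every stage verifiable without the original recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    uwot,
    yaml
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
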