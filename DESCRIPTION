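Package: kneemorph
Title: Personalized Knee Soft-Tissue Geometry Prediction from Corresponded Bone Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts subject-specific knee soft-tissue geometry from corresponded
    bone surface meshes: cartilage layers by per-vertex thickness-map projection
    along vertex normals, menisci as offset-wrapped tubes with triangular
    cross-sections, main ligaments and the patellar tendon by elastic mesh
    wrapping with penetration resolution, and cruciate ligaments as
    variable-radius Frenet-Serret tube meshes. Includes polynomial profile
    fitting with degree selection against an over-fitted reference, indices-based
    landmark transfer across corresponded meshes, surface-distance validation
    metrics (RMSE, average surface distance, Hausdorff distance) with a
    leave-one-out experiment driver, and a deterministic synthetic knee cohort
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pracma,
    withr
Config/testthat/edition: 3
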