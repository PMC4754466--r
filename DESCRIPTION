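Package: tractmat
Title: Tract-Specific Analysis of White-Matter Maturation Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Along-tract analysis of diffusion-tensor MRI maturation on
    medial (skeleton) surfaces of white-matter fasciculi. Projects
    diffusion tensor volumes onto continuous medial representations by
    sampling along spokes with maximum-FA selection, smooths vertexwise
    FA/MD maps with a surface heat kernel, fits linear and exponential
    age trajectories per vertex and sex, corrects vertexwise F-tests with
    random field theory, selects models by AIC, and derives maturation
    maps (plateau age, yearly rate) with tract-level summaries and a
    between-sex overlap comparison. Includes a synthetic-cohort generator
    (surfaces, growth fields, subjects, measures, embedded tensor
    volumes) so the full pipeline is testable without MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    RNifti,
    xml2,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
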