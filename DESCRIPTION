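Package: bias3d
Title: Brain-Inspired Attentional Search in a 3D Cube World
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An active-vision search agent with separate "what" (object
    classification) and "where" (camera motion) processing streams. A camera
    orbits a textured cube, extracts a foveated multi-resolution glimpse from
    the centre of each view, and learns - by deep Q-learning combined with a
    classification loss - to steer itself toward the cube face carrying a
    target image and to classify that image. Includes a software pinhole
    renderer for the cube world, generators for cluttered-cube datasets
    (including a procedural glyph set so nothing needs downloading),
    recurrent network layers built on JK flip-flop neurons and Elman/Jordan
    context feedback, supervised pretraining of the classifier stream,
    end-to-end training with a target network and temporal-difference loss,
    and inference-time search evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: grDevices, graphics, stats, utils, Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
LinkingTo: Rcpp, RcppArmadillo
RoxygenNote: 7.3.3
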