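Package: echodive
Title: Detection of Air-Breathing Predator Dives in Fishing-Vessel Echosounder Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect encounters between krill fishing vessels and
    air-breathing krill predators (penguins, Antarctic fur seals, baleen
    whales) in single-beam echosounder data. Provides a synthetic acoustic
    scene generator with pixel-level ground truth; standardization of raw
    backscatter records to 600 x 1000 grayscale echograms (1 s x 0.5 m grid,
    10 min x 500 m windows, -90 to -20 dB range); pixel-wise five-class
    segmentation (background, seafloor, krill swarm, whale, bubble trail)
    with a trainable U-Net and a deterministic rule-based reference
    segmenter; extraction of dive events with duration and acoustic height;
    taxon classification of mammal dives by acoustic height; and
    normalization of detections into predator encounter rates over time,
    spatial grids, and colony buffer zones.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, grDevices, graphics, png, EBImage,
    jsonlite, tools, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), geosphere, withr, optparse, knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
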