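Package: flockmotion
Title: Calibrated Speed Estimation and Tracking Evaluation for Animal Video Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracker-agnostic toolkit for measuring real-world locomotion speed
    of animals (e.g. poultry) from pixel trajectories produced by any
    multi-object tracker. Calibrates a planar homography from four reference
    points, rectifies tracks to a metric top-down view, and converts pixel
    displacement to speed in metres per second. Implements the standard
    multi-object tracking and segmentation evaluation metrics (MOTA, IDF1,
    IDP, IDR, identity switches, throughput FPS, mean IoU, speed RMSE) with a
    CLEAR-MOT matching procedure, reads and writes MOTChallenge-format track
    files and run-length-encoded segmentation masks, and ships a synthetic
    flock simulator with known ground-truth kinematics and configurable
    observation noise for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    clue,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
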