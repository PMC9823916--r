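Package: gaze3d
Title: Calibration-Free 3D Gaze Estimation from Stereo IR/RGB Eye Cameras
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a per-user 3D eyeball model from stereo pupil detections
    taken by a head-mounted pair of eye cameras (one infrared, one RGB),
    without any user-facing calibration procedure. Pupil bounding-rectangle
    detections from the two cameras are paired by timestamp, triangulated by
    closest approach of back-projected rays, filtered by a ray-gap and a
    depth-median rule, and fed to a robust truncated M-estimator sphere fit
    at the fixed anatomical eyeball radius of 12 mm. The fitted sphere maps
    infrared pupil positions point-to-point to RGB pixels through a
    ray-sphere intersection, yields 3D gaze rays, supports online model
    validation against occasional RGB detections, and exports
    self-supervised pupil labels for detector training. A synthetic stereo
    rig simulator with full ground truth provides test data and evaluation
    metrics (IoU, angular and pixel gaze error, median-of-medians
    summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    png,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
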