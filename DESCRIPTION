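Package: seegloc
Title: Automatic Localization of SEEG Depth-Electrode Contacts in Post-Implant CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Segments the recording contacts of stereo-EEG (SEEG) depth
    electrodes from a thresholded post-implant CT volume. Starting from the
    planned entry and target point of each electrode, the algorithm locates
    the screw (head point) by iterative centre-of-mass refinement, follows
    the electrode shaft with a piecewise-linear axis to the tip, and then
    walks back along the shaft segmenting each cylindrical contact, with
    corrections for curved shafts, crossing electrodes and bilaterally
    collinear implants. Includes a synthetic CT phantom generator with
    ground truth, a target-displacement robustness experiment, and writers
    for contact coordinate tables and VTK surface meshes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
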