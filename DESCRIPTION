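Package: stimchar
Title: Characterization of Action-Observation Video Stimuli
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterizing video stimuli used in action-observation
    experiments. Detects the exact frame of motion onset by frame differencing
    against a static reference frame, trims clips so that visible motion starts
    at frame 2, locates the frame of action-category recognition with a
    between-subject up-down staircase (engine plus seeded observer simulator),
    and evaluates categorical rating data psychometrically (recognition
    accuracy, confusion matrices, Fleiss' kappa, one-sample tests against
    chance). Includes seeded synthetic generators of videos, observers and
    rating tables so the full workflow can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
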