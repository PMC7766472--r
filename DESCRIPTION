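Package: hopfall
Title: Hopfield Associative-Memory Fall Detection from 9-Axis IMU Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fall detection from wrist-worn 9-axis inertial measurement unit
    (IMU) recordings using a 25-neuron discrete Hopfield network trained by
    one-shot Hebbian learning. Gyroscope, accelerometer and magnetometer
    channels are fused into five activity features, thresholded into a bipolar
    5 x N matrix, and the most active 5 x 5 window becomes the stored activity
    template. Recall runs either as ideal digital Hopfield dynamics (with
    energy tracking) or as a behavioral simulation of an op-amp summing
    amplifier circuit in which Hebbian weights become normalized conductances.
    Recalled patterns are classified by cosine similarity against the fall
    template. Includes a seeded synthetic-IMU generator for five activity
    classes, JSON/CSV interchange, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
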