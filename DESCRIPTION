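Package: rumenbolus
Title: On-Device Signal Processing for a Lifelong Rumen Bolus Sensor
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Desk-scale implementation of the complete measurement pipeline
    of an ingestible rumen bolus sensor for dairy cattle: drinking-event
    detection from rumen temperature, motion-activity scoring and rumination
    detection from 3-axis acceleration, heart-rate estimation from short
    acceleration windows with a server-side neural classifier, hourly
    telemetry packet encoding/decoding for a 51-byte LPWAN uplink, and the
    radio duty-cycle, battery-lifetime and data-compression budget
    arithmetic. Includes a synthetic-signal generator that produces paired
    temperature/acceleration streams with ground-truth event logs so every
    detector is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
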