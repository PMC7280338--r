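Package: weargaze
Title: Parsing, Quality Assessment and Event Annotation for Wearable
    Eye-Tracker Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A headless toolkit for packet-based recordings from head-mounted
    (wearable) eye trackers. Reads gzip-compressed line-delimited JSON packet
    streams (binocular gaze direction, pupil, gyroscope, accelerometer, TTL
    and video-timestamp packets), groups packets into per-sample gaze data,
    applies per-eye validity rules, snaps samples to the nominal sampling
    grid and fills gaps with explicit missing samples, and supports
    recordings split across multiple segments. Computes Fick-angle (azimuth,
    elevation) eye orientation, Savitzky-Golay smoothed angular eye velocity,
    windowed RMS sample-to-sample precision and data loss. Provides a
    contiguous event-stream annotation model (manual edits, TTL-derived
    streams, text-file import with reset, pluggable classifiers including a
    built-in slow/fast-phase velocity classifier), a synthetic-recording
    generator for fully reproducible testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
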