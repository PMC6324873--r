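Package: xenocall
Title: Kinematic-Acoustic Analysis of Underwater Sound Production in Xenopus
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing how clawed frogs (Xenopus) produce sound
    underwater without airflow. Implements subpixel tracking of arytenoid-disc
    markers in high-speed video by normalized cross-correlation, gap-width
    kinematics (velocity and acceleration by smoothed finite differences),
    zero-phase band-pass conditioning of sound-pressure traces, per-stimulus
    sound-onset detection, amplitude-kinematics regressions with
    motion-threshold estimation, and a cavitation-consistency diagnostic.
    A second pipeline measures the two dominant frequencies (dyads) of
    advertisement-call sound pulses, their Q-values, the DF2/DF1 ratio and its
    musical-interval class, and clade-level summaries. A synthetic-data module
    generates video, audio and paired experiments with known ground truth so
    every stage is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
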