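Package: ripsync
Title: Thoraco-Abdominal Synchrony and Fatigue Biomarkers from Wearable Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies thoraco-abdominal (a)synchrony from respiratory
    inductance plethysmography (RIP) during repetitive work, together with
    surface-EMG fatigue features (%MVC amplitude, Welch median frequency),
    wrist-accelerometer task-cycle segmentation and pitch/roll kinematics,
    and a mixed-effects statistical layer relating them. Includes a
    synthetic multi-subject study generator with ground truth for
    parameter-recovery testing, a plain-text file format for multi-channel
    recordings, and tidy/ggplot2 interfaces for all result types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    data.table,
    signal,
    lme4,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
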