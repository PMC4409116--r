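Package: ermtools
Title: Event-Related Modes from Ensemble Empirical Mode Decomposition of EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes multi-trial event-related EEG into event-related
    modes (ERMs) using ensemble empirical mode decomposition (EEMD) with
    spline-envelope sifting, computes Hilbert-Huang instantaneous amplitude
    and frequency spectra, and tests condition differences in windowed mode
    amplitudes with channel-wise paired statistics. Includes a generator for
    contour-integration Gabor stimulus fields and for synthetic multi-subject
    EEG with planted condition effects, so the full pipeline can be exercised
    and validated without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
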