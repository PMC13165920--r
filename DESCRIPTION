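Package: nasometry
Title: Dual-Channel Nasalance Measurement and Nasometer Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for objective nasality assessment from dual-channel
    (nasal/oral) speech recordings. Implements the nasometric pipeline used
    by separator-plate nasometers: Butterworth bandpass filtering, frame-based
    RMS energy estimation, energy gating, nasalance trajectories and session
    summaries. Adds the electroacoustic analyses used to evaluate such
    devices (long-term average spectra in fixed-width bands, spectral mean
    absolute difference, oral-nasal intensity gap, total harmonic distortion),
    trajectory agreement measures for non-synchronous recordings (lagged
    cross-correlation and dynamic-time-warping-aligned Pearson correlation),
    a synthetic dual-channel recording generator with known ground truth, and
    a command-line interface. Reads and writes stereo PCM WAV and headerless
    raw PCM audio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
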