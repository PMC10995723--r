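Package: freevib
Title: Time-Domain Modal Analysis of Free Vibrations in Egg-Clutch Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates free-vibration frequency and decay time constant from
    short accelerometer recordings of treefrog egg clutches. A damped
    sinusoid oscillating around a quadratic trend is fitted in the time
    domain by exact linear solution of the amplitude and trend coefficients
    nested inside Nelder-Mead minimization of the normalized root mean
    square error. Includes automatic free-vibration window selection against
    the recording noise floor, fit-acceptance filters, waveform metrics
    (peak amplitude, vibration duration, spatial attenuation), Welch
    two-sample comparisons, a synthetic-recording generator with known
    ground truth for parameter-recovery studies, and a reproducible
    simulate-window-fit-summarize pipeline with WAV and CSV interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
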