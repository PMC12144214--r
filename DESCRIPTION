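Package: tdrstates
Title: Dive Reconstruction and Behavioural States from Low-Resolution
    Time-Depth Recorders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs individual dives from low-temporal-resolution
    (5-minute) time-depth-recorder transmissions on air-breathing marine
    vertebrates and infers latent behavioural states from them.  Provides
    zero-offset correction, threshold dive detection with interpolated
    boundary times, descent/bottom/ascent phase labelling, kinematic
    splitting of merged dives, a four-feature multivariate hidden Markov
    model fitted by Baum-Welch EM with AIC-based restart selection,
    Argos track filtering and move-persistence classification, a
    high- versus low-resolution validation protocol based on Fisher's
    exact test, and cyclic-spline binomial models of seasonal state
    occupancy.  A synthetic-data module generates labelled dive
    sequences, continuous depth traces and Argos-like tracks with known
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    geosphere,
    mgcv,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
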