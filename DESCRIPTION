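Package: fibroegm
Title: In Silico Intracardiac Electrograms and Machine-Learning
    Characterization of Atrial Fibrotic Substrate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates atrial tissue patches with parameterized interstitial
    fibrosis (collagen density and transmural depth), propagates excitation with
    an operator-split monodomain reaction-diffusion model and a reduced
    two-variable atrial ionic model, and synthesizes unipolar and bipolar
    intracardiac electrograms at multi-electrode catheter positions through an
    infinite-medium Green's function forward model. Provides a generalized
    autoregressive model of catheter noise fitted from activity-blanked
    segments, Hilbert-space activity detection, seven morphology and complexity
    features (active-segment duration, peak-to-peak amplitude, sample entropy,
    Shannon entropy, spectral entropy, Lempel-Ziv complexity, Higuchi fractal
    dimension), and decision-tree classifiers with greedy forward feature
    selection to characterize fibrosis presence, density, and transmurality,
    including electrode-height degradation sweeps and Sorensen-Dice comparison
    of substrate maps against voltage-cutoff maps.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rpart,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
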