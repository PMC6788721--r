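Package: corrcode
Title: Correlation Codes for Sound Recognition from Cochlear Models and
    Neural Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the short-term spectro-temporal correlation
    structure of sounds and of multichannel neural ensemble recordings, and
    for decoding sound identity and sound category from those correlations.
    Includes a gammatone filter-bank cochlear front-end, running windowed
    correlation statistics with stationarity and ensemble-diversity indices,
    trial-shuffled estimators that decompose neural correlograms into
    stimulus-driven and noise components, naive-Bayes and Gaussian-mixture
    MAP classifiers over principal-component correlation features, analog
    multiunit activity envelope extraction, 1/f spectrum equalization, and a
    synthetic-data generator with controllable correlation structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
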