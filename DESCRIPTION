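Package: rmmcircuit
Title: Recurrent Mechanistic Models of Small Neural Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Learns quantitatively predictive, interpretable models of small
    neural circuits from current-clamp recordings.  Implements recurrent
    mechanistic models (RMMs) with contracting linear internal dynamics and
    multi-layer-perceptron current maps; the unified training algorithms of
    feed-forward teacher forcing, multiple shooting and generalized teacher
    forcing (with hand-written backpropagation and Adam); a smoothed
    spike-train similarity metric for validation; a dynamic-clamp half-center
    oscillator simulator with ground-truth synaptic and H currents; and a
    frequency-domain interpretation layer (IV/GV curves, frequency-dependent
    conductances, excitability regions, fold and Neimark-Sacker bifurcation
    candidates).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    Rcpp,
    signal,
    stats,
    tools,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
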