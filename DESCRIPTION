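Package: windupasic
Title: Windup in Wide-Dynamic-Range Neurons with Proton-Gated ASIC1a Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Conductance-based simulation and analysis of windup, the
    progressive spike-count facilitation of deep dorsal-horn wide-dynamic-range
    (WDR) projection neurons under 1 Hz C-fiber stimulation.  The package
    couples a three-compartment Hodgkin-Huxley WDR neuron driven by 20
    A-delta-fiber and 20 C-fiber synapses to pH-gated ASIC1a channel models
    (native homomeric and heteromeric parameterisations) and a buffered
    synaptic-cleft acidification model, and provides the windup quantification
    pipeline (latency-window spike classification, windup curves, area under
    curve, percent inhibition), pharmacological scenario variants (ASIC block,
    MitTx-style constitutive activation, KCa block), parameter validity grid
    searches, and a generator of surrogate in vivo WDR recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
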