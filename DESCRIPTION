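Package: ngvmet
Title: Reduced Neuro-Glia-Vasculature Model of Brain Energy Metabolism and
    GLUT1 Deficiency
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reduced mechanistic model of the neuro-glia-vasculature (NGV)
    unit coupling brain energy metabolism (glycolysis, TCA cycle, oxidative
    phosphorylation, glycogen, pentose phosphate shunt, glutathione redox) to
    a Hodgkin-Huxley neuron through an ATP- and glucose-dependent Na+/K+-
    ATPase. Implements GLUT1 deficiency syndrome as transporter-parameter
    scaling, nutrient and cofactor therapy protocols, after-discharge seizure
    detection and rescue, metabolite-variability analysis under fluctuating
    blood nutrients, and redox-ratio-based therapy ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
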