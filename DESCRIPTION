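Package: echoplace
Title: Template-Based Place Recognition with Batlike Sonar
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates batlike ensonification of parametric acoustic scenes
    (hyperbolic FM call, multi-microphone panoramic sampling), converts echo
    trains into cochlear place templates via a gammatone auditory periphery
    model with dechirping, onset blanking, frequency and microphone averaging
    and temporal integration, and quantifies two properties of the templates
    that a navigating echolocator would rely on: unique classifiability under
    a calibrated Gaussian noise model (Mahalanobis nearest-template Monte
    Carlo) and spatial continuity (angular and linear catchment distances).
    Includes pre-packaged synthetic study designs contrasting open,
    semi-cluttered and cluttered habitats and corridors dominated by strong
    distant versus weak nearby reflectors.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
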