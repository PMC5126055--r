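Package: bgstim
Title: Spiking Basal Ganglia Network Simulation of Subthalamic Stimulation
    and Impulsive Decision Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a spiking network model of the basal ganglia
    (striatum, subthalamic nucleus, globus pallidus externus and internus,
    thalamus) built from two-variable Izhikevich neurons on 2D lattices, with
    dopamine-modulated temporal-difference learning of cortico-striatal
    weights driving performance on the Iowa Gambling Task. Includes a
    spatially explicit deep-brain-stimulation current model (Gaussian spread
    around an electrode centre, biphasic pulse train), population synchrony
    and spectral metrics, and an experiment harness comparing healthy,
    untreated and medically treated parkinsonian conditions with and without
    stimulation, with one-way ANOVA and Bonferroni post-hoc statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
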