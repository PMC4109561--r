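Package: meaburst
Title: Network Burst and Up-State Analysis for Multi-Electrode Array Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and statistical characterization of network bursts
    (up-states) in spike-sorted multi-electrode array (MEA) recordings of
    cultured neocortical networks. Provides a seeded synthetic MEA recording
    generator with wild-type and epileptiform (seizure-like, long up-state)
    firing modes and pharmacological perturbations; refractory-period cleaning
    and PCA/K-means waveform sorting with distance-based outlier removal;
    sliding-window up-state detection with hysteresis thresholds; per-unit
    burst metrics (burst duration, spike number, firing rates, inter-burst
    intervals, Fano factor, autocorrelogram); unsupervised excitatory versus
    inhibitory unit classification and four-way network-state sorting;
    burst-duration distributions with event- and time-based normalizations;
    nonparametric comparison utilities (Mann-Whitney, Wilcoxon, Kruskal-Wallis
    with exact small-sample enumeration, Dunn post hoc); and Hill dose-response
    fitting for antiepileptic drug block of firing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
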