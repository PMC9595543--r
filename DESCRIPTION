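Package: megspike
Title: Automated Detection of Interictal Spike Clusters and Delineation of the
    Irritative Zone in MEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Two-stage, fully automated pipeline for detecting clusters of
    interictal epileptiform spikes in magnetoencephalography (MEG) recordings
    and delineating the irritative zone on a cortical source space. Stage one
    finds candidate spikes on peaky, dipolar ICA components (kurtosis and
    MUSIC dipolarity selection, adaptive peak detection, refractory pruning);
    stage two clusters candidate epochs with rank-1 multivariate convolutional
    sparse coding and assigns events by an iterative MAD threshold. Cluster
    averages are localized by regularized minimum-norm estimation at the spike
    peak and at 50% of the ascending slope, binarized, voted and smoothed into
    a predicted irritative zone, which is validated by the signed mean distance
    to the convex hull of a resected volume. Includes a synthetic MEG simulator
    (dipolar forward models, planted rank-1 spike sources, 1/f noise) so every
    stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    e1071,
    generics,
    ggplot2,
    ica,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
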