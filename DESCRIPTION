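Package: netburst
Title: Network Burst Analysis for Multi-Well Microelectrode Array Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for spontaneous activity of neuronal cultures
    recorded on multi-well microelectrode arrays (MEAs): spike detection from
    raw extracellular traces (Butterworth high-pass, robust noise-scaled
    threshold), single-channel burst detection from the logarithmic
    inter-spike-interval histogram, network-burst detection across electrodes,
    well-level network metrics (mean firing rate, network burst rate and
    duration, inter-burst interval and its coefficient of variation,
    percentage of spikes outside network bursts), treatment normalization for
    pharmacology experiments, and canonical discriminant analysis of
    well-level phenotypes.  Companion tools quantify evoked synaptic currents
    (NMDA/AMPA ratio, decay constants), passive and active intrinsic membrane
    properties, and molecular readouts (ChIP-qPCR percent input, relative
    expression by the 2^-ddCt method).  A synthetic-data generator produces
    multi-well recordings, raw voltage traces and evoked current sweeps with
    known ground truth so that every stage of the pipeline can be validated.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    minpack.lm,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    withr
Config/testthat/edition: 3
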