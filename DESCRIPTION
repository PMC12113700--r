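Package: cerebpsd
Title: Behavior-Resolved Band-Power Analysis of Extracellular Cerebellar Recordings
Version: 0.9.0
Authors@R: person("cerebpsd", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Pipeline for behavior-resolved spectral quantification of
    extracellular multi-unit recordings from cerebellar structures (Crus II,
    inferior olive, dentate nucleus) in a lesion model of parkinsonism.
    Provides a seeded synthetic-cohort generator with 1/f-like background
    spectra, behavior schedules, mains interference and recording artifacts;
    session serialization (JSON manifest, float32 signals, CSV annotations);
    zero-phase Butterworth band-pass and harmonic notch filtering;
    behavior-aligned 5-s trace extraction with saturation and excursion
    rejection; periodogram power spectral density with band area-under-curve
    and bandwidth-normalized power; exact-null nonparametric statistics
    (Mann-Whitney U, Wilcoxon signed-rank, Friedman, Holm step-down,
    Spearman, Lilliefors, Levene); and an orchestrating analysis that
    produces intergroup, intragroup, behavior-duration and duration-power
    correlation tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
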