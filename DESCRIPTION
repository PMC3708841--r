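Package: cascadeHMM
Title: Onset of Sexually Dimorphic Expression from Fine Time-Course
    Transcriptomes via a Left-to-Right Hidden Markov Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls the developmental onset of sexually dimorphic gene
    expression from a fine time-course expression matrix. Probes are
    quantile normalized, filtered by detection p-values, screened with a
    sex-by-strain-by-stage factorial ANOVA, reduced to per-stage
    significance-gated log2 fold differences between XY and XX samples,
    quantized into a seven-symbol alphabet, and decoded with an 18-state
    left-to-right hidden Markov model (three states per time point, tied
    emissions) trained by Baum-Welch and decoded by Viterbi. Downstream
    tools classify activation versus repression mechanisms, compare onset
    cascades between inbred strains with hypergeometric overlap tests, and
    rank candidate regulatory genes in eQTL intervals. A synthetic-data
    generator with planted dimorphism cascades makes every stage testable
    without microarray downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
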