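Package: hdokin
Title: Kinetic Modelling of Hexane-2,3-diol Pathway Flux
Version: 0.1.0
Authors@R: person("hdokin", "maintainers", email = "hdokin@example.org",
    role = c("aut", "cre"))
Description: Lumped ordinary-differential-equation models of the microbial
    glucose -> butyryl-CoA -> butanal -> hexane-2,3-diol pathway, with and
    without a thioesterase drain to butyrate and with and without substrate
    inhibition of the CoA-acylating aldehyde dehydrogenase (PduP). Provides
    first-order, Michaelis-Menten and substrate-inhibition rate laws, a
    stiff-tolerant adaptive integrator with a Bateman closed-form oracle for
    the linear chain, staged nonlinear least-squares fitting of sparse
    fermentation time courses, RSS/AIC model comparison, cumulative
    butyryl-CoA flux accounting, a synthetic time-course generator with known
    ground truth for parameter-recovery studies, and fermentation performance
    metrics (titer unit conversion, substrate yield, volumetric productivity).
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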