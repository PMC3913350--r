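Package: hnmbio
Title: Hybrid Neural and Kinetic Modeling of Biofuel Bioprocesses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Grey-box modeling tools for two batch bioprocesses aimed at
    second-generation biofuels. For the lipase-catalyzed transesterification
    of triolein, a Ping-Pong Bi-Bi rate law with ethanol inhibition is
    integrated as a scalar batch ODE whose product/ethanol closures are
    supplied either by linear stoichiometric correlations or by a trained
    multilayer perceptron, yielding a parallel hybrid neural model. For the
    anaerobic codigestion of manure with orange juice waste, a pure
    feed-forward network maps feed composition, initial mixture state and
    process time to cumulative methane productivity, and a grid optimizer
    ranks piecewise feed-composition strategies. Includes a from-scratch
    Bayesian-regularized Levenberg-Marquardt trainer, gauged least-squares
    estimation of the twelve lumped kinetic constants, and seeded synthetic
    data generators emulating both experimental campaigns.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
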