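Package: swarmstall
Title: Simulation and Analysis of Temporarily Immobile Bacterial Swarmer Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying temporarily immobile cells inside bacterial
    swarms. Provides a three-state continuous-time Markov chain model of
    flagellar dynamics (run, tumble, stall) with a state-coupled swarm
    simulator; a renderer producing phase-contrast-like intensity stacks with
    exposure-time motion blur and DIC-like hue maps encoding local wetness;
    long-exposure immobile-cell detection with grid bin-occupancy statistics
    (occupation fraction, Gaussianity, inverse-square-root scaling of the
    across-bin standard deviation, temporal autocorrelation); cell tracking
    and speed/neighbour kinematics; hue-threshold classification with
    stopping/wetting event extraction; and dwell-time inference (exponential
    maximum likelihood, two-component exponential mixtures with AIC
    comparison, embedded transition matrices and a memorylessness test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    tools,
    utils,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
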