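Package: sleepswitch
Title: Sleep-State Bistability: Intermediate-State Scoring, Flip-Flop
    Circuit Simulation, and Focal Drug Diffusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the bistability of NREM/REM sleep from
    EEG band-power recordings and for simulating its presumed circuit
    substrate. Implements state-space scoring of NREM/REM intermediary
    (NRt) epochs from trajectory-intersection cluster boundaries, with
    bout statistics; leaky integrate-and-fire flip-flop network
    simulations of sleep-state switching with pool-inhibition
    experiments; a 3-D iterated-Gaussian model of muscimol spread under
    microinjection and reverse-microdialysis source schedules with a
    spike-inhibition dose-response; a labelled synthetic-recording
    generator; and paired estimation statistics (BCa bootstrap mean
    differences, Cohen's d).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    boot,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
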