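Package: aptwin
Title: Patient-Specific Digital Twin and Offline Reinforcement Learning for
    Closed-Loop Insulin Dosing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building patient-specific artificial-pancreas
    components from wearable-device records in type 1 diabetes.  Converts
    insulin-pump events (basal, temp-basal, multi-mode boluses), self-reported
    meals and heart rate into uniformly sampled forcing signals; simulates a
    modified Roy-Parker glucose-insulin ordinary differential equation model
    with exercise effects as a patient digital twin; infers time-dependent
    model parameters and hidden states from continuous glucose monitor (CGM)
    observations with a systems-biology-informed neural network (SBINN)
    trained under self-adaptive loss weights; learns insulin dosing policies
    from replay buffers with two offline reinforcement-learning algorithms
    (continuous batch-constrained Q-learning and TD3+BC); and scores glucose
    predictions and closed-loop trajectories with Clarke error grid and
    time-in-range analytics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    splines,
    stats,
    utils,
    xml2,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
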