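Package: emgforce
Title: EMG-Driven Muscle Force and Joint Torque Estimation with Hill-Type
    and Multi-Scale Cross-Bridge Muscle Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates muscle force and isometric joint torque from surface
    electromyography (EMG). Implements the standard EMG conditioning chain
    (zero-lag Butterworth filtering, rectification, envelope extraction,
    normalization to maximum voluntary contraction), second-order activation
    dynamics with electromechanical delay and optional nonlinear shaping,
    a Hill-type contractile element in series with a linear tendon, and a
    multi-scale contractile element derived from two-state cross-bridge
    kinetics whose stiffness and force obey distribution-moment ordinary
    differential equations driven by a thresholded chemical input and a
    recruitment input. A Huxley-type partial differential equation solver for
    the attached cross-bridge distribution is included as an independent
    oracle, together with a motor-unit-based surface-EMG simulator for fully
    synthetic end-to-end trials, ankle plantar-flexion torque assembly for
    gastrocnemius and soleus, error metrics, and calibration of the
    activation shape factor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
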