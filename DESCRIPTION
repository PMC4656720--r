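Package: affgrasp
Title: Reinforcement Learning of Grasp Affordances in a Simulated Primate Arm
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A neural simulator of integrated affordance and grasp learning.
    Parietal population codes over object position, orientation, surface
    normals and size feed a reinforcement-modulated self-organizing affordance
    map (area AIP), which drives premotor dynamic neural fields that select
    reach and grasp parameters (object center, reach offset, virtual-finger
    combination, maximum aperture, wrist rotation).  Decoded parameters drive
    a kinematic 22-degree-of-freedom arm/hand model via dynamic movement
    primitives, pseudo-inverse inverse kinematics and PD joint controllers,
    with a geometric opposition-axis criterion standing in for rigid-body
    grasp physics.  Connection weights are trained end-to-end by
    trial-and-error reinforcement (REINFORCE with execution-related
    eligibility traces), and the package ships the accompanying analyses:
    shape preference indices, selectivity time courses, linear feature fits
    and success-rate curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
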