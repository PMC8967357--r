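Package: garlicsim
Title: Process-Based Growth and Yield Simulation for Hardneck Garlic
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative process-based crop model for hardneck garlic
    (Allium sativum). Simulates leaf appearance through a
    storage-conditioned dynamic phyllochron, individual leaf elongation
    and senescence, recoverable cold injury and irreversible cold-damage
    mortality, canopy carbon assimilation by a coupled C3
    photosynthesis-stomatal conductance-energy balance model over sunlit
    and shaded leaf fractions, and stage-dependent carbon partitioning to
    root, leaf, sheath, scape, and bulb. Includes a stochastic weather
    synthesizer for contrasting winter climates, daily-to-hourly weather
    downscaling, and an experiment harness scanning planting dates across
    weather ensembles and CO2 scenarios to locate optimal planting dates.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
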