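Package: gaitsens
Title: Muscle-Strength Sensitivity of Knee Cartilage Stress Across Gait Modifications
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale musculoskeletal analysis pipeline for studying how reduced
    lower-limb muscle strength alters the effect of gait modifications (toe-in,
    toe-out, wide stance) on tibiofemoral cartilage stress. Provides a seeded
    synthetic stance-phase gait generator, a simplified scaled lower-limb
    musculoskeletal model with Hill-type strength muscles, quasi-static inverse
    dynamics, static-optimization muscle recruitment under a cubic polynomial
    criterion, a connector-restrained elastic-foundation tibiofemoral contact
    model with upper-quartile stress summaries, a one-dimensional biphasic
    cartilage consolidation solver, and percent-change / percentage-point
    sensitivity statistics with paired-t and repeated-measures ANOVA tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
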