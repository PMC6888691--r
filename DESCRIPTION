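Package: npdamage
Title: Nanoparticle Radio-Enhancement of Nanosize DNA Damage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for quantifying the radio-enhancing effect of
    core-shell metal nanoparticles on DNA double-strand-break (DSB) induction.
    Provides a core-shell nanoparticle water-phantom builder, a parametric
    synthetic generator of secondary-electron energy-deposition events with
    nanoparticle-proximal enhancement, SSB/DSB scoring on a procedural B-DNA
    duplex or a PDB-derived geometry, quantification of plasmid agarose-gel
    densitometry via Poisson inversion of band fractions, dose-response yield
    fitting with amplification factors and hydroxyl-radical scavenger
    decomposition, and the XPS overlayer-attenuation shell-thickness formula.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    knitr
Config/testthat/edition: 3
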