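Package: idrpep
Title: Contact-Energy-Based Design of Peptides Targeting Intrinsically
    Disordered Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing short peptide binders against intrinsically
    disordered protein regions (IDRs) from residue-residue contact energies.
    Provides loaders and transforms for 20x20 contact free-energy tables
    (including the relative-energy referencing against the average residue),
    greedy one-by-one and one-by-three minimum-energy peptide design with
    register scanning over a target IDR, an umbrella-integration estimator
    that reconstructs a potential of mean force and a pairwise binding free
    energy from harmonically biased reaction-coordinate samples, and the
    one-to-one binding model used to fit dissociation constants from
    fluorescence-anisotropy titrations.  Synthetic generators for biased
    samples and titration curves support fully reproducible testing without
    molecular dynamics or instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
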