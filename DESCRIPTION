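Package: easregio
Title: Regioselectivity Prediction for Electrophilic Aromatic Substitution
    from Semiempirical Proton Affinities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the regioselectivity of electrophilic aromatic
    substitution (EAS) reactions by ranking the proton affinities of all
    symmetry-unique aromatic C-H positions of a molecule. The sigma-complex
    (Wheland intermediate) formed by the attacking electrophile is
    approximated by protonation, so the relative stability of the protonated
    isomers predicts the preferred reaction site. The pipeline enumerates
    low-energy tautomers, runs a conformer search (3D embedding, force-field
    pre-screen, Butina RMSD clustering, energy refinement) for every neutral
    and protonated species, and marks predicted sites that fall within
    1 kcal/mol (green) and 3 kcal/mol (red) of the highest proton affinity.
    Energies come from an external GFN-xTB tight-binding engine with GBSA
    implicit solvation, or from a deterministic surrogate backend used for
    testing and method development. Includes evaluation utilities that score
    predictions against experimentally observed sites as correct,
    semi-correct or failed, with and without tautomers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    igraph,
    jsonlite,
    bio3d,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
SystemRequirements: Open Babel (>= 3.0) command line tool 'obabel' on PATH;
    Python 3 with RDKit on PATH as 'python' (3D conformer embedding);
    optionally the 'xtb' semiempirical tight-binding engine for production
    energies.
Config/testthat/edition: 3
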