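# easregio

Predicts the regioselectivity of **electrophilic aromatic substitution
(EAS)** — which C–H position of an aromatic molecule the electrophile
attacks — for medicinal and synthetic chemists who want a fast, automated
call from nothing but a SMILES string.

## The method

EAS proceeds through a positively charged σ-complex (Wheland intermediate).
The σ-complex is approximated by protonating a ring carbon, so the **proton
affinity** of each candidate site,

```
PA(c) = E(neutral) − E(protonated at c)      [kcal/mol, proton energy neglected]
```

ranks the sites: the highest-PA position is the predicted reaction site.
For each molecule the pipeline enumerates tautomers (keeping forms within
15 kcal/mol of the most stable), finds the symmetry-unique aromatic C–H
positions of every kept form, and runs an identical conformer search for
every neutral and protonated species: `min(1 + 3·n_rot, 20)` seeded
distance-geometry embeddings, a force-field pre-screen (3 kcal/mol window),
Butina clustering on heavy-atom RMSD (0.5 Å), and energy refinement guarded
by a 60,000 kcal/mol connectivity sentinel. Sites within 1 kcal/mol of the
per-tautomer PA maximum are **green** (predicted), within 3 kcal/mol
**red** (borderline); the molecule's highest PA maps to a qualitative
**low / medium / high** reactivity class via a 70–100 kcal/mol band.

Production energies use an external GFN-xTB engine (GFNFF pre-screen,
GFN1/GFN2 refinement, GBSA solvation in methanol); a deterministic
surrogate backend (`MOCK`) runs the identical pipeline without the engine
and powers the test-suite.

## Requirements

* R ≥ 4.1 with ChemmineR, igraph, jsonlite, bio3d (all on CRAN/Bioconductor)
* Open Babel ≥ 3.0 (`obabel` on PATH) — SMILES parsing/canonicalization
* Python 3 with RDKit (`python` on PATH) — 3D conformer embedding
* optional: `xtb` for production tight-binding energies

## Worked example

```r
library(easregio)
cfg <- run_config("MOCK", verbose = FALSE)     # surrogate backend; use "TB1" with xtb installed
predict_eas("Oc1ccccn1", "2-hydroxypyridine", cfg)
```

```
<prediction_report> 2-hydroxypyridine ( Oc1ccccn1 )
  reactivity: medium
  tautomer Oc1ccccn1  rel 0.0 kcal/mol  [medium]
    atom 3 (0-based 2) PA 91.79 kcal/mol  deficit 0.00  green
    atom 4 (0-based 3) PA 91.64 kcal/mol  deficit 0.16  green
    atom 5 (0-based 4) PA 90.75 kcal/mol  deficit 1.05  red
    atom 6 (0-based 5) PA 90.44 kcal/mol  deficit 1.36  red
  tautomer O=c1cccc[nH]1  rel 1.5 kcal/mol  [medium]
    atom 3 (0-based 2) PA 94.96 kcal/mol  deficit 0.00  green
    atom 4 (0-based 3) PA 92.31 kcal/mol  deficit 2.65  red
    atom 5 (0-based 4) PA 93.59 kcal/mol  deficit 1.37  red
    atom 6 (0-based 5) PA 92.60 kcal/mol  deficit 2.36  red
```

Both the hydroxy (lactim) input form and the 2-pyridone (lactam) tautomer
were found and scored; per tautomer, every symmetry-unique ring C–H is
listed with its proton affinity, its deficit from the best site, and the
resulting green/red call (atom indices are shown 1-based and 0-based). The
relative tautomer energy (here 1.5 kcal/mol) is well below the 15 kcal/mol
cutoff, so both forms count. Under the surrogate backend the PA values
cluster near 90 kcal/mol by construction ("medium" reactivity); real
site discrimination needs the tight-binding backend.

`report_to_json()` serializes a report (with full config provenance),
`render_depiction()` draws green/red-highlighted structures as SVG, and
`run_pipeline()` processes `.smi`/`.csv` batches with per-molecule failure
isolation. `evaluate_predictions()` scores runs against observed sites as
Corr / Semi / Fail, with the tautomer-aware existential rule.

A thin CLI wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","easregio.R",package="easregio"))')" \
    predict --smiles "c1ccccc1" --id benzene --method MOCK --output-dir out
```

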