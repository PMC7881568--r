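---
title: "Predicting EAS regioselectivity from proton affinities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting EAS regioselectivity from proton affinities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Electrophilic aromatic substitution (EAS) proceeds through a positively
charged sigma complex (Wheland intermediate) in which the electrophile has
added to one ring carbon. Across many electrophiles the relative stability
of the sigma complexes at different positions tracks the observed
regiochemistry, and the sigma complex itself is well approximated by simply
*protonating* the ring carbon. `easregio` therefore ranks candidate
reaction sites by their proton affinity

\[
\mathrm{PA}(c) = E(\text{neutral}) - E(\text{protonated at } c),
\]

with the solvated proton's own energy neglected on both sides — only
*differences* between sites, and comparisons against fixed empirical
cutoffs calibrated under the same convention, enter any decision.

For each molecule the pipeline:

1. parses and validates the SMILES (neutral molecules only — the PA model
   presumes a neutral substrate protonated to +1);
2. enumerates tautomers, runs a conformer search for each, and keeps the
   forms whose refined energies lie strictly within 15 kcal/mol of the most
   stable form;
3. finds the symmetry-unique aromatic C–H positions of each kept tautomer;
4. builds each arenium ion, runs the same conformer search on it, and
   computes the proton affinities;
5. marks sites within 1 kcal/mol of the per-tautomer maximum as **green**
   (predicted) and within 3 kcal/mol as **red** (borderline);
6. classifies the molecule's overall reactivity from the highest proton
   affinity of the most stable tautomer: below 70 kcal/mol *low*, 70–100
   *medium* (closed band), above 100 *high*.

The conformer search is identical for neutral and protonated species:
`min(1 + 3 n_rot, 20)` distance-geometry embeddings (ETKDG v2 at a fixed
random seed, default 90), a force-field pre-screen that keeps structures
strictly within 3 kcal/mol of the running minimum, Butina leader clustering
on pairwise heavy-atom best-fit RMSD at 0.5 Å, and a refinement of the
cluster centroids from which the lowest-energy member is taken. After every
refinement the optimized structure's distance-perceived connectivity is
compared with the input's; a species that rebonded (e.g. an intramolecular
proton transfer) has its energy replaced by a 60,000 kcal/mol sentinel so
it can never be selected.

## Energy backends

Production energies come from an external GFN-xTB engine (`FF` = GFNFF for
the pre-screen, `TB1` = GFN1 or `TB2` = GFN2 for refinement) with GBSA
implicit solvation in methanol (dielectric 33.6, echoed in every report) or
water. The adapter writes an XYZ file per call, passes charge and method
flags, converts the final total energy from Hartree with the pinned factor
627.509474 kcal/mol, and treats timeouts and non-convergence as failures
subject to the documented fallbacks (a failed force-field member passes its
unoptimized structure through to refinement rather than being dropped).

The `MOCK` backend is a deterministic surrogate used by the test-suite and
for development without an engine:

\[
E = \sum_{\text{bonds}} k\,(d_{ij} - d^0_{ij})^2 \;+\; \sum_{\text{atoms}}
\varepsilon(\mathrm{el}) \;+\; c\,q_{\mathrm{tot}},
\]

with \(k = 100\) kcal/mol/Å², \(d^0\) the covalent-radius sum,
a small fixed per-element table \(\varepsilon\) (H = 160 kcal/mol), and
\(c = -250\) kcal/mol. "Optimization" under `MOCK` is a no-op. Because the
protonated species differs from the neutral by exactly one hydrogen, the
surrogate's proton affinities land near \(-c - \varepsilon(\mathrm H) = 90\)
kcal/mol — inside the realistic 70–100 kcal/mol medium band — while
site-to-site spread comes only from embedding-geometry strain. The
surrogate emulates determinism, charge sensitivity, and rigid-motion
invariance of a real backend; it does **not** emulate electronic
substituent effects, so green/red assignments under `MOCK` exercise the
decision logic, not the chemistry. Passing tests therefore validate
plumbing, symmetry handling and thresholds; predictive accuracy on real
molecules is entirely a property of the tight-binding backend.

## Tautomer enumeration

Forms are generated by 1,3 and 1,5 hydrogen shifts along alternating
single/double bond paths, applied over *every* Kekulé resonance structure
of each form (perfect-matching enumeration over the ring double bonds) and
closed under breadth-first iteration, deduplicating by canonical SMILES.
Three restrictions keep the ruleset chemically sane:

* the donor atom must carry no double bond (this forbids cumulene-forming
  shifts);
* at least one heteroatom (N, O, S) must take part;
* the hydrogen never lands on an *aromatic carbon*, which would
  dearomatize the ring — landing on aromatic N/O/S is allowed, which is
  exactly the lactam/lactim and azole N–H chemistry the method needs.

This ruleset is deliberately permissive compared to curated transform
lists: it can emit high-energy sp³ ring forms that other toolkits suppress
by pattern design. Those forms are legitimate constitutional isomers and
the 15 kcal/mol energy filter is the intended control for them. A
configurable cap (default 32 forms) guards pathological inputs.

Stereochemistry rides on the 3D coordinates: a stereocenter remote from
all shift sites survives enumeration untouched, while a shift that touches,
creates, or sits adjacent to a stereocenter drops the stereo designations
of that output form (the whole form, not just the affected center — a
deliberately coarse reading of the ambiguity caveat, flagged per tautomer
in the report as `stereo_stripped`).

Heavy-atom indices are preserved across all tautomer forms (transforms move
hydrogens only), so experimentally observed sites given in the input
SMILES' atom order transfer to every form without graph matching.

## Symmetry-unique reaction centers

Candidate sites are aromatic carbons bearing at least one hydrogen —
aromaticity is perceived ring-by-ring by a Hückel count on the perceived
rings (heteroatom lone pairs contribute two electrons, exocyclic carbonyl
carbons zero), which handles the fused bicyclics and 2-pyridone-type rings
this method targets. Equivalence classes are automorphism orbits of the
hydrogen-suppressed coloured graph (colours: element, formal charge,
attached-H count, aromaticity; bond colours: aromatic or Kekulé order),
computed with BLISS via igraph; the tests cross-check them against a
brute-force permutation oracle. Stereo labels and isotopes are ignored —
sigma-complex energetics are insensitive to remote stereo labels, and
ignoring them avoids spurious class splitting. One representative per class
(lowest atom index) is protonated.

Because a single Lewis structure of an arenium ion is not unique, the
protonated species' canonical notation is fixed by enumerating the
allylic-shift-reachable charge placements and keeping the lexicographically
smallest canonical SMILES. Protonating two symmetry-equivalent atoms
therefore yields the identical species string, and the species' conformer
search re-embeds from that canonical SMILES — so its energy depends only on
the species' identity, never on which class member was protonated.

## Numerical choices

* **Strict vs inclusive boundaries.** The 15 kcal/mol tautomer cutoff and
  the 3 kcal/mol pre-screen window are strict (`<`); the 0.5 Å RMSD
  threshold and the 1/3 kcal/mol site windows are inclusive (`≤`); the
  70–100 reactivity band is closed on both ends. Each boundary has a
  dedicated test.
* **Butina tie-breaks.** Candidate centers are ordered by descending
  neighbour count within the threshold, ties by ascending member index;
  neighbour counts are computed once on the full matrix.
* **Embedding.** Distance-geometry embedding (ETKDG v2) at a caller-fixed
  seed, with one randomized-coordinates retry before a species is declared
  unembeddable. The upstream 3D builder in the format-conversion toolchain
  runs an unseeded stochastic rotor search and cannot provide run-to-run
  reproducibility, which byte-identical reports require.
* **Bond perception.** Bond iff distance ≤ 1.3 × (sum of covalent radii),
  with a published consensus radii table bundled as data; interatomic
  distances under 0.3 Å are a geometry error.
* **Unit conversion.** 627.509474 kcal/mol per Hartree, pinned because the
  decision windows are sensitive at the 1 kcal/mol level.
* **Indexing.** Internal indices are 1-based (R convention); every report
  prints 0-based and 1-based indices side by side, and the evaluation CSV
  contract uses 0-based indices in the input SMILES order.
* **Degenerate inputs.** A tautomer with no aromatic C–H is kept in the
  report, flagged `no_eas_sites`, and excluded from the report-level
  reactivity call; sites whose arenium ion fails valence sanitization or
  whose every conformer tripped the connectivity sentinel are listed as
  `sites_not_evaluated` rather than silently dropped.

## Evaluation labels

Against a set of experimentally observed sites, a prediction is **Corr**
when every observed site is green, **Semi** when every observed site is
green or red, and **Fail** otherwise. With tautomers the criterion is
existential — some single form must cover all observed sites. The
published rule states the green (Corr) case; extending the same existential
reading to green∪red for Semi is this package's inference and is noted
here deliberately.

## Problem sizes

The bundled fixture set holds eleven molecules from benzene to 7-azaindole
(≤ 10 heavy atoms), chosen so that every pipeline branch — symmetric rings,
directing substituents, N-heterocycles, lactam/lactim pairs, fused
bicyclics — is exercised while a full surrogate-backend batch run completes
in well under a minute; the exhaustive label truth table runs over a 4-site
universe (3^4 site states × 15 observed subsets), and clustering oracles
use ensembles of up to six members. These sizes are the package's own
test-design choice: large enough to hit every decision boundary, small
enough to keep the suite fast.

## Known limitations

* Accuracy claims require a real tight-binding backend; the surrogate
  validates mechanics only.
* The tautomer ruleset is its own (permissive) transform set, not a
  reimplementation of any specific toolkit's curated list; rare exotic
  tautomerizations (ring-chain, valence) are out of scope.
* RMSD clustering uses the identity atom mapping (no symmetry-corrected
  RMSD); two mirror-image conformers of a symmetric species may land in
  distinct clusters — harmless for energy ranking, but the cluster count
  is not symmetry-minimal.
* Ipso attack at substituted carbons and heteroatom protonation are
  excluded by design: the model targets C–H substitution; heteroatom
  basicity is a different question.
* No Boltzmann weighting over conformers or tautomers: the single lowest
  energy conformer represents each species, matching the method's design.
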