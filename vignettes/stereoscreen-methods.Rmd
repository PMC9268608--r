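---
title: "Methods: rank-and-weight target prioritisation for stereoisomeric ligands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-and-weight target prioritisation for stereoisomeric ligands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereoscreen)
```

## The problem

Chiral natural products are usually synthesised as racemic mixtures, yet
their enantiomers can bind protein targets very differently: a pocket that
forces a planar ligand arrangement (for example through a π-π stack with a
tryptophan) may accept one enantiomer and reject its mirror image.
`stereoscreen` implements the desk-side half of a stereoisomer
virtual-screening campaign: given a table of docking scores for the four
stereoisomeric forms of a ligand (*trans*-(−), *trans*-(+), *cis*-(−),
*cis*-(+)) against a panel of candidate proteins, plus a known inhibitor per
protein, it decides which proteins are plausible targets, which isomer each
protein group prefers, and — once molecular-dynamics trajectories of the
selected complexes exist — whether binding holds up dynamically and how it
deforms the receptor. Docking and MD themselves are upstream engines, out of
scope; the package consumes their outputs and emulates them with a
synthetic-data generator for testing.

## The target-selection gate

A protein is called a potential target of an isomer when two criteria hold:

1. **Energy**: the isomer's docking score is *strictly* lower (more
   negative, i.e. stronger predicted binding) than the known inhibitor's
   score. The strictness follows the ordinary reading of "lower than"; ties
   fail (`passes_energy_criterion()`).
2. **Site similarity**: the isomer binds the same pocket as the inhibitor.
   Campaigns often judge this visually from the docked poses; the package
   substitutes a reproducible, monotone proxy — the Jaccard index
   |A∩B|/|A∪B| of the interacting-residue sets of the two poses, pooled
   over the selected interaction types (`residue_overlap()`). The default
   threshold is 0.1: the printed residue sets of a pose are small (one to
   four residues), so any shared pocket residue passes, which mirrors the
   permissive visual judgement while remaining auditable. When both residue
   sets are empty the similarity is vacuously 1 and flagged as such.

When no interaction data exist for a protein, `call_targets()` degrades to
the energy criterion alone and flags the call with
`site_data_available = FALSE` rather than inventing a site judgement.

Residue identity is (three-letter code, sequence number), compared
case-insensitively on the code. Printed residue labels are taken at face
value — the packaged inhibitor profile keeps a label that disagrees with
the surrounding narrative by a digit transposition, because correcting data
at load time would hide provenance; with the packaged tables this makes the
isomer/inhibitor pocket overlap on CSF1R exactly 1/6.

## The rank-and-weight scoring system

Docking scores across a 60-protein panel cannot simply be summed: absolute
energies are not comparable between proteins. The scoring system therefore
re-expresses each protein's four isomer scores as **competition ranks** in a
4-3-2-1 manner: 4 for the best (most negative) score down to 1 for the
worst, with

rank(i) = 4 − #{isomers with a strictly better score than i},

so tied scores share the higher rank (`competition_ranks()`). This tie rule
is the one consistent with the published per-protein rank rows that contain
ties; ranks are invariant under any strictly increasing transformation of
the scores, which is the property that makes them comparable across
proteins.

Each rank is then multiplied by a **drug-accessibility weight** determined
by the protein's subcellular localization: 3 for membrane-bound proteins
(highest chance of drug exposure), 2 for cytoplasmic, 1 for nuclear
(`apply_weight()`). Within each functional group (anti-apoptosis/survival,
cell growth/proliferation, metastasis, signalling) the ranks and the
weighted ranks are summed per isomer (`summarize_group()`); the isomer with
the largest weighted sum is the group's **preferred isomer**. Ties for the
maximum are reported (`tie = TRUE`, all argmax members listed), never
silently broken.

Where a published rank table disagrees with ranks recomputed from the
published scores, recomputation from scores is authoritative throughout the
package — the score table is the primary datum, the rank table a derived
artefact. With the packaged table the preferred isomer is *trans*-(−) for
the anti-apoptosis, growth and signalling groups (growth-group weighted
sums 151 vs 55 for *trans*-(+)) and *cis*-(+) for the metastasis group.

## Isomer-score variability

Stereoselectivity of a single protein shows up as spread among its four
isomer scores. `isomer_variance()` reports the sample variance (n−1
denominator) and sample SD of the four scores; `rank_by_variability()`
orders proteins by descending variance with a deterministic name tie-break.
Published variability screens of this kind sometimes print values that are
numerically the sample *variance* under an "SD" heading; the package
exposes both statistics under unambiguous names so either can be compared.
Note that recomputing from the packaged score table ranks EGFR (variance
≈ 2.89 (kcal/mol)²) above CSF1R (≈ 1.09) among the twelve shared targets —
the published narrative claims the reverse, and that claim is not
reproducible from the printed scores; the package reports what the data
give.

`one_way_anova()` covers the replicated case (e.g. per-run scores from a
stochastic docking engine), fitting the classic one-way ANOVA via
`stats::aov` with a significance flag at p < 0.01. One score per isomer
cannot support an ANOVA, so each group must have ≥ 2 replicates; the
descriptive variance serves the 1-score case.

## Trajectory statistics

`read_trajectory()` parses multi-model PDB (via `bio3d::read.pdb`, frames
delimited by `MODEL`/`ENDMDL`) or plain xmol XYZ into a `trajectory`
container (atoms × 3 × frames, with per-atom residue index, mass and a
ligand flag). Masses come from a standard element table with a 12.011 Da
fallback (warned). On this container:

* `rmsd_series()` — RMSD of every frame to a reference frame (default
  frame 1), on protein Cα atoms by default, after optimal least-squares
  rigid-body superposition (Kabsch, via SVD with the determinant correction
  that excludes reflections). Superposition makes the series invariant to
  global rigid motion and never increases the RMSD of any frame.
* `rmsf_profile()` — per-residue Cα fluctuation about the window-mean
  structure, every frame superposed onto that mean (the mean is refined
  once: align to an initial frame, average, re-align to the average). For
  isotropic Gaussian jitter of amplitude σ the expected RMSF is σ√3.
* `com_distance_series()` — per-frame distance between the mass-weighted
  ligand and protein centres of mass (ligand excluded from the protein
  centre), with the least-squares slope in Å/ns attached as a dissociation
  indicator.
* `residue_distance_profile()` / `delta_d_profile()` — the
  conformational-shift profile Δd(n) = d(n, bound) − d(n, free), where
  d(n, state) is residue n's mean Cα distance to the protein centre of mass
  over an analysis window. Δd > 0 means the residue moved away from the
  protein centre upon ligand binding, Δd < 0 that it moved closer; |Δd|
  strictly greater than 2 Å (the default threshold) is classified
  significant (`"further"`/`"closer"`, otherwise `"unchanged"`).

Two choices here were genuinely open and are package decisions: whether
d(n) is a snapshot or a time average (we average, default window = final
third of the frames, taken as the equilibrated portion — snapshots are
noisier and no more principled), and whether the protein centre of mass is
mass-weighted (it is; that is what "centre of mass" means, and with
Cα-only models it coincides with the geometric centre anyway). Distances
to the centre of mass are rigid-motion invariant, so no superposition is
needed for Δd.

## The synthetic-data generator

The generator exists so that every pipeline stage has inputs with known
ground truth. `generate_score_table()` draws

score(protein, isomer) = base + effect(group, isomer) + N(0, noise_sd²),

with the inhibitor at `base + inhibitor_offset` and localizations sampled
from configured probabilities. Defaults model the study system at its
actual scale: 60 proteins (15 per group), base −9 kcal/mol (the centre of
the packaged score distribution), noise 0.5 kcal/mol (a typical
within-protein spread), localization probabilities 0.10/0.75/0.15
(membrane/cytoplasm/nucleus, the packaged proportions), and planted effects
that make *trans*-(−) best in three groups and *cis*-(+) best in
metastasis — the qualitative structure the scoring system is meant to
recover. With zero noise, every protein's ranks equal the planted effect
order exactly; recovery degrades gracefully with noise, which the tests
quantify (≥ 95/100 seeded replicates recover every group's winner at noise
0.1 kcal/mol with 20 proteins per group).

`generate_trajectory_pair()` builds a Cα pseudo-protein on a fixed
helix-like scaffold (radius 8 Å, 10 residues per turn, 1.5 Å rise — the
constants only need to make residue-to-centre distances non-degenerate),
jittered isotropically per residue. The bound state displaces designated
residues radially from the scaffold centre by the configured planted shift
and carries one ligand particle drifting outward at a configured Å/ns.
Defaults (60 residues, 300 frames at 1 ns/frame, 0.3 Å fluctuations) are a
desk-scale stand-in for a 300 ns kinase-domain simulation.

A single integer seed governs each generator; state-specific sub-seeds are
derived from it (seed + a small stage offset) and the caller's RNG stream
is left untouched.

What the generator does *not* emulate: force-field physics, solvent,
correlated residue motion, anisotropic fluctuations, score distributions
with heavy tails, or any coupling between docking scores and trajectory
behaviour. Passing tests therefore demonstrate that the statistics recover
planted structure under idealised Gaussian conditions, not that the
upstream engines are accurate.

## Numerical and testing choices

* Ranks and weighted sums are exact integer arithmetic; no tolerances.
* Variance agrees with a two-pass textbook computation to 1e−12 relative;
  the trajectory property tests run at sizes (5,000 frames × 40 residues
  for RMSF; 1,000 frames for Δd recovery; 100 replicate tables for
  preferred-isomer recovery) chosen so Monte-Carlo error sits well inside
  the asserted bands while the whole suite stays fast.
* Superposition is cross-checked against an independent implementation
  (`bio3d::rmsd(fit = TRUE)`) on random frames.
* Degenerate inputs fail loudly and early: non-finite scores, duplicate
  protein names, malformed PDB codes or residue labels, inconsistent frame
  atom counts (reported by frame index), empty atom selections,
  single-score variance, and under-replicated ANOVA groups are all errors,
  not warnings.
* JSON reports have recursively sorted keys, so byte-identical inputs give
  byte-identical reports; input paths and MD5 hashes and all thresholds in
  effect are echoed into the report for audit.

## Known limitations

* The site-similarity proxy uses only residue identity, not geometry; two
  poses sharing residues in different orientations score as similar.
* The 0.1 Jaccard default is calibrated to small printed residue sets;
  fingerprints from exhaustive contact detection would warrant a higher
  threshold.
* Group-level weighted sums depend on the localization annotation; a
  protein shuttling between compartments has no natural single weight.
* Δd conflates radial motion with any centre-of-mass redefinition caused
  by large conformational change; it is a screening statistic, not a free
  energy.
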