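# stereoscreen

Target prioritisation for stereoisomeric ligands from virtual-screening
output, plus trajectory statistics for the selected complexes.

Chiral compounds are usually synthesised as racemates, but a protein pocket
can strongly prefer one enantiomer. Given a docking-score table — one row
per candidate protein with the scores (kcal/mol, more negative = stronger)
of the four stereoisomeric ligand forms *trans*-(−), *trans*-(+),
*cis*-(−), *cis*-(+) and of a known inhibitor — `stereoscreen` answers, for
computational chemists running such campaigns:

* **Which proteins are plausible targets?** A two-criterion gate: the
  isomer must out-score the known inhibitor (strictly), and its pose must
  share the inhibitor's pocket, measured as the Jaccard overlap
  |A∩B|/|A∪B| of the two poses' interacting-residue sets (default
  threshold 0.1).
* **Which isomer does each protein group prefer?** Each protein's four
  scores become 4-3-2-1 competition ranks (rank = 4 − #{strictly better};
  ties share a rank), multiplied by a drug-accessibility weight from the
  protein's subcellular localization (membrane 3, cytoplasm 2, nucleus 1),
  and summed per functional group; the preferred isomer attains the
  maximal weighted sum.
* **How stereoselective is each protein?** Sample variance/SD of its four
  isomer scores, plus one-way ANOVA when replicate scores exist.
* **Does binding hold up dynamically?** From multi-model PDB or XYZ
  trajectories: RMSD to a reference frame (Kabsch-superposed), per-residue
  Cα RMSF, ligand–protein centre-of-mass distance with a dissociation
  slope, and the per-residue shift profile Δd(n) = d(n, bound) −
  d(n, free), where d is the mean Cα-to-protein-centre distance; |Δd| > 2 Å
  is significant ("further"/"closer").

A synthetic-data generator plants known isomer preferences, fluctuation
amplitudes, residue shifts and ligand drift so that every stage is testable
without docking or MD engines. A 60-protein example score table and the
matching interaction table ship with the package.

## Worked example

```r
library(stereoscreen)
tab <- example_score_table()            # 60 proteins, 4 isomer scores each

summarize_group(tab, "cell_growth_proliferation")
#> Group: cell_growth_proliferation (22 proteins)
#>              trans_minus trans_plus cis_minus cis_plus
#> sum of ranks          72         28        64       58
#> weighted sum         151         55       127      119
#> Preferred isomer: trans_minus
```

The *trans*-(−) isomer dominates the growth group (weighted sum 151 vs 55
for its mirror image): in protein after protein it holds the best rank, and
the membrane-bound kinases (weight 3) amplify the margin. Running the gate
for that isomer against the packaged interaction table:

```r
calls <- call_targets(tab, example_interaction_profiles(),
                      isomer = "trans_minus")
subset(calls, site_data_available)
#>    protein      isomer isomer_score    inhibitor inhibitor_score energy_pass
#> 16   CSF1R trans_minus       -11.84 Pexidartinib          -11.59        TRUE
#> 20    EGFR trans_minus        -9.71    Erlotinib           -8.82        TRUE
#>    site_similarity site_pass site_data_available overall_pass
#> 16       0.1666667      TRUE                TRUE         TRUE
#> 20       0.6666667      TRUE                TRUE         TRUE
```

CSF1R passes both criteria: −11.84 beats pexidartinib's −11.59, and the
poses share one of six pocket residues (the π-stacking Trp550). Proteins
without interaction data fall back to the energy criterion and are flagged.
The variability screen ranks the same panel by stereoselectivity:

```r
head(rank_by_variability(tab, restrict = c(
  "COX2", "Hsp90a", "Hsp90b", "cdc25A", "CDK2", "RagC", "CSF1R", "EGFR",
  "AKR1B1", "JAK3", "MNK2", "p38")), 4)
#>   protein n sample_variance sample_sd
#> 1    EGFR 4       2.8924250 1.7007131
#> 2   CSF1R 4       1.0899000 1.0439828
#> 3  cdc25A 4       0.8958000 0.9464671
#> 4  Hsp90b 4       0.5240917 0.7239418
```

`run_pipeline()` chains gate + ranking + variability into one
machine-readable JSON report; `inst/scripts/stereoscreen` wraps the same
functions as a shell tool (`run`, `screen`, `rank`, `variance`, `traj`,
`simulate` subcommands). For trajectories:

```r
pair <- generate_trajectory_pair(traj_sim_config(
  n_residues = 40, n_frames = 1000, fluctuation_sd = 0.2,
  planted_shift = c("15" = 3.0), seed = 17))
dd <- delta_d_profile(residue_distance_profile(pair$bound),
                      residue_distance_profile(pair$free))
dd[dd$class != "unchanged", c("residue", "delta_d", "class")]
#>    residue  delta_d   class
#> 15      15 2.936441 further
```

See `vignette("stereoscreen-methods")` for the model, its assumptions, the
defaults and their rationale, and known limitations.

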