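# lrcomm

Ligand–receptor communication scoring with feedback loops, for studying
how the tissue microenvironment shapes neuronal survival after injury.

## The problem

After an axonal injury such as optic nerve crush (ONC), retinal ganglion
cell (RGC) subclasses die at very different rates: a resilient trio
(ipRGC, αRGC, Gpr88RGC) survives while most other subclasses are lost.
Part of that difference is cell-intrinsic, but neighboring retinal cells
(Müller glia, astrocytes, amacrine cells, …) also talk to RGCs through
ligand–receptor (LR) signaling. `lrcomm` is a pipeline for asking, from
multi-timepoint single-cell expression data: **which LR interactions are
preferentially received by the subclasses that survive**, and are those
interactions in place before injury or induced by it?

## The model

For each LR pair, sender group, receiver group and timepoint the package
computes an interaction score

```
S0   = sqrt(e_L * e_R) * (alpha + (1 - alpha) * n)
S_LR = S0 + gamma * Lambda * (1 - S0)        (0 when S0 = 0)
```

where `e_L`, `e_R` are the sender's ligand and the receiver's receptor
mean expression scaled by each gene's maximum over all groups and
timepoints; `n` is network support — the fraction of the receptor's
downstream targets (≤ K signaling edges, then one regulatory edge, in a
directed gene network) detected in the receiver; and `Lambda` is the
feedback-loop bonus — the best base score of a reverse-direction pair
whose receptor, in turn, reaches this pair's ligand (a cell–cell
signaling loop). Candidate pairs are kept when ligand and receptor are
detected in ≥ 10% of sender/receiver cells and the score reaches 0.5.

Protective interactions are called with the differential statistic

```
DS_LR = mean over high-survival subclasses of max_t(S_LR)
      - mean over low-survival  subclasses of max_t(S_LR)
```

with `DS_LR > 0.25` marking a protective interaction (and `< -0.25` the
— empirically empty, but still carried — "stronger in low" class).
Protective interactions are further classified as **preset** (the
high-vs-low advantage exists at the control timepoint) or **induced**
(it appears only after injury), and as **autocrine / paracrine / both**
by where the ligand is expressed at 12 h post-injury. The package also
flags temporally variable interactions (pairwise fold change > 1.2
across timepoints) and assigns them to four dynamic archetypes, adjusts
subclass proportions by overall survival rates, and implements the two
RNAscope dot-quantification equations:

```
avg intensity / dot = (sum(dot intensities) - bg * sum(dot areas)) / n_dots
total dots          = (total intensity - bg * total area) / (avg intensity / dot)
```

Because real accessions are not required, a first-class synthetic-data
module simulates labeled negative-binomial count atlases with planted
protective interactions, decoys, and loop-closing networks, so every
stage is tested against known ground truth.

## Worked example

```r
library(lrcomm)

des <- synthetic_design(
  n_planted = 4, n_decoys = 10, prop_induced = 0.5, prop_loops = 0.5,
  n_cell_types = 5,
  rgc_subclasses = data.frame(
    name = c("ipRGC", "alphaRGC", "T-RGC", "N-RGC"),
    survival_class = c("high", "high", "low", "low")),
  cells_per_group = 200, n_genes = 150, seed = 7)
sim <- simulate_experiment(des)
net <- build_synthetic_network(sim$truth)

atlas    <- qc_filter_cells(sim$atlas, qc_preset("synthetic"))$atlas
profiles <- summarize_profiles(atlas, "both")
part     <- survival_partition(c("ipRGC", "alphaRGC"), c("T-RGC", "N-RGC"))
scores   <- score_interactions(profiles, truth_lr_pairs(sim$truth), net,
                               scoring_params(),
                               senders = unique(SummarizedExperiment::colData(atlas)$cell_type),
                               receivers = c(part$high, part$low))
retained <- filter_interactions(scores, profiles, scoring_params())
diff_tab <- differential_table(scores, part, profiles = profiles,
                               retained = retained)
head(diff_tab[diff_tab$class == "protective"][order(-ds_lr)], 5)
```

prints (seed 7):

```
  sender ligand receptor ds_lr      class  timing mode
1   CT04  g0020    g0021 0.619 protective induced both
2   CT03  g0017    g0018 0.599 protective  preset both
3   CT01  g0005    g0006 0.482 protective  preset both
4   CT02  g0011    g0012 0.418 protective induced both
5   CT04  g0005    g0006 0.336 protective  preset both
```

Each row is one (sender cell type, ligand, receptor) family: `ds_lr` is
the high-minus-low survival score difference (values above 0.25 are
protective), `timing` says whether the advantage predates the injury,
and `mode` whether the ligand comes from RGCs themselves, from other
cell types, or both. All four planted interactions are recovered (e.g.
`g0005-g0006` from `CT01`, planted preset with a feedback loop); the
extra rows are the same planted pairs seen from neighboring senders that
also express the ligand above threshold. Of the 33 scored families, 15
are protective and 18 neutral; none of the ten decoys — identical
expression levels, no subclass bias — is called in either direction.

The same run is reproducible end-to-end from a JSON config:

```sh
Rscript inst/cli/lrcomm.R run-all --config my_config.json --out results/
Rscript inst/cli/lrcomm.R fishquant --dots dots.tsv --region region.json
```

## Layout

- `R/simulate.R` — synthetic atlas / network / truth generator
- `R/atlas.R` — 10x-style I/O, per-cell QC presets and filters
- `R/profiles.R` — per-(group, timepoint) means and detection rates,
  log2FC tables, KS comparison of LR genes vs background
- `R/scoring.R` — interaction scores, network support, loop detection,
  retention filters, cell-type aggregation
- `R/differential.R` — DS_LR, protective calling, preset/induced,
  autocrine/paracrine, survival-adjusted proportions
- `R/dynamics.R` — fold-change flagging and dynamic-group templates
- `R/fish.R` — RNAscope dot-field quantification
- `R/pipeline.R` — config, orchestration, CLI
- `vignettes/methods.Rmd` — the package's account of its methods
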