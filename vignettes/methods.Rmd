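---
title: "Scoring protective cell–cell communication: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring protective cell-cell communication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lrcomm` infers which ligand–receptor (LR) interactions a tissue sends
preferentially to injury-resilient neuron subclasses. This vignette is
the package's own account of the science: the model, its assumptions,
the parameters that matter, what the synthetic world does and does not
emulate, and the choices made where the design was genuinely open. It
states no empirical result that the test suite and acceptance script do
not themselves compute.

## 1. The interaction score

For an LR pair $(\ell, r)$, sender group $s$, receiver group $v$ and
timepoint $t$:

$$S_0 = \sqrt{e_L\, e_R}\,\bigl(\alpha + (1-\alpha)\, n\bigr), \qquad
  S_{LR} = \begin{cases} S_0 + \gamma\, \Lambda\, (1 - S_0) & S_0 > 0 \\
  0 & S_0 = 0\end{cases}$$

**Expression terms.** $e_L$ is the mean CP10k-normalized ligand
expression in $s$ at $t$, divided by the ligand's maximum mean over
*all* groups and timepoints; $e_R$ analogously for the receptor in $v$.
Max-scaling makes scores comparable across pairs with very different
absolute expression, bounds them in $[0,1]$, and — importantly — makes
the downstream 0.5 retention cutoff operative on every pair. The cost is
that $e$ is a *relative* quantity: a gene uniformly expressed everywhere
scores $e \approx 1$ in all groups.

**Network support.** $n$ is the fraction of the receptor's downstream
target set detected (detection rate $\ge$ `detection_min`) in the
receiver. The target set is every gene reachable from the receptor via
at most $K$ signaling edges followed by exactly one regulatory edge;
zero signaling edges are allowed, so a receptor's direct regulatory
targets count. $n = 0$ when the target set is empty, so a receptor with
no known downstream biology falls back to the $\alpha$ floor rather
than being discarded. At $\alpha = 1$ the network is ignored entirely.

**Feedback loops.** A reverse pair $(\ell', r')$ from $v$ back to $s$
*qualifies* when $\ell'$ lies in the forward receptor's target set and
$\ell$ lies in the reverse receptor's target set — the two interactions
close a transcriptional loop in both directions. $\Lambda$ is the
maximum same-timepoint base score $S_0$ of any qualifying reverse pair;
the bonus $\gamma \Lambda (1 - S_0)$ can only lift a live score toward
1, never resurrect a dead one ($S_0 = 0 \Rightarrow S_{LR} = 0$) and
never push past 1. Qualification is symmetric, so a loop boosts both of
its arms. An autocrine interaction ($s = v$) may not partner with its
own instance.

The score is therefore bounded, monotone in each of
$e_L, e_R, n, \Lambda$, and equal to $S_0$ whenever the loop term is
silent — properties the acceptance suite verifies on $10^4$ random
parameter draws, and that the differential statistic below relies on.

**Retention.** A (sender, receiver, pair) triple is kept when (1)
ligand and receptor are detected in at least 10% of sender and receiver
cells respectively (inclusive, "at least 10%"), and (2) the score
reaches 0.5. The wording of criterion (2) in the source protocol ("no
<0.5 in any time point") is ambiguous; because the differential
statistic and the per-subclass workflow both operate on the *maximum*
over timepoints, the default reads it as "$\ge 0.5$ at one or more
timepoints". `strict_all_timepoints = TRUE` gives the literal
all-timepoints reading.

## 2. The differential protection statistic

With receiver subclasses partitioned into high- and low-survival sets,

$$DS_{LR} = \operatorname{mean}_{v \in \text{high}}
  \max_t S_{LR}(v, t) \;-\; \operatorname{mean}_{v \in \text{low}}
  \max_t S_{LR}(v, t)$$

per (sender cell type, LR pair) family. $DS_{LR} > 0.25$ calls a
protective interaction; $DS_{LR} < -0.25$ the converse class (carried
even when empty); comparisons are strict. Two subtleties:

* **Which rows enter the statistic.** Retention is decided per
  receiver, so a pair can pass toward high-survival receivers while its
  (low-scoring) low-survival rows fail. Computing $DS_{LR}$ on retained
  rows only would zero-fill the weak side and inflate the difference —
  in testing this manufactured spurious "stronger in low" calls on
  bias-free decoys. The package therefore evaluates families selected
  by retention on the **full** score table.
* **Missing groups.** A subclass absent from the scores (no surviving
  cells at any timepoint) counts as $\max_t S_{LR} = 0$ with a warning
  (`missing = "zero"`), on the reasoning that absence of a receiver is
  absence of the interaction; `missing = "skip"` drops it from its
  side's mean instead. Profile groups smaller than `min_cells`
  (default 10) are flagged in reports.

**Timing.** `delta_pre` is the high-minus-low mean at the control
timepoint; `delta_post` the same on per-subclass maxima over
post-injury timepoints. `preset` when `delta_pre >= 0.25` (the
advantage predates injury); `induced` when it appears only after
(`delta_pre < 0.25`, `delta_post >= 0.25`); else `neither`. The same
0.25 cutoff serves both axes since both measure the same score
difference.

**Mode.** At 12 h post-injury, a protective ligand detected
($\ge$ `detection_min`) in at least one RGC subclass and in no other
cell type is `autocrine`; only in other cell types, `paracrine`; in
both, `both`; nowhere, `undefined` (flagged).

**Survival-adjusted proportions.** Subclass cell counts are normalized
to within-condition shares, multiplied by the condition's overall
survival rate (e.g. 0.638 for control injury, 0.854 under rescue
overexpression), and divided by the uninjured share to estimate
per-subclass survival. By construction adjusted shares sum exactly to
the overall rate — a conservation law tested to $10^{-12}$.

## 3. Temporal dynamics

An interaction is *variable* when the largest pairwise fold change of
its trajectory, $\max_{t_1,t_2} (S_{t_1}+\epsilon)/(S_{t_2}+\epsilon)$
with the larger value on top, exceeds 1.2. $\epsilon$ (default 0.01)
guards zero scores; the protocol is silent on zero handling, and at
$\epsilon = 0$ the statistic is scale-invariant (tested). Raw scores
are used; no smoothing.

The source study grouped variable trajectories by heatmap clustering,
which is irreproducible without its exact dendrogram. For determinism
the package correlates each z-scored trajectory with four fixed
templates transcribed from the verbal archetypes — transient repressed
$(0,-1,0,0)$, transient activated $(0,1,0,0)$, rapid sustained
$(-1,1,1,1)$, slow activated $(-1,-\tfrac13,\tfrac13,1)$ — and assigns
the argmax (ties break in listed order). Pearson correlation makes the
assignment invariant to affine transforms of the trajectory. A
hierarchical mode (`cluster_dynamic_groups`, average linkage on
correlation distance, $k=4$) is available for atlas-style outputs.

## 4. The synthetic world

`simulate_experiment` draws counts
$X \sim \mathrm{NB}(\mu = b_g \cdot \text{boosts} \cdot \text{lib},\ \text{size} = \theta)$
per cell, with lognormal gene baselines
($\log\mu \sim N(0, 0.5)$ by default, giving means around 1 count —
deliberately well above droplet sparsity so detection-based logic is
exercised at small gene universes), one global dispersion $\theta = 2$
(a standard single-cell marginal; rank-based downstream logic does not
need gene-specific dispersions), per-cell lognormal library factors
(sd 0.2, exercising normalization without dominating signal) and
optional lognormal jitter (sd 0.1) on every (gene, group, timepoint)
mean.

A planted protective interaction boosts its ligand in one sender
(default $4\times$) and its receptor in the high-survival subclasses.
The per-timepoint receptor multiplier *is* the `induction_schedule`:
preset pairs are flat at `receptor_boost` (default $8\times$); induced
pairs start at 1 in the control and jump to the boost after injury.
With full network support these defaults put the design's
timepoint-maximal score gap near $1 - \sqrt{1/8} \approx 0.65$,
comfortably above the 0.5 gap the recovery criterion assumes — the
boosts are calibration choices (the study does not state real effect
sizes) fixed here once. Decoys receive identical marginal boosts but
in *all* subclasses, so they are a fair null for the differential
statistic: any systematic decoy call is an implementation error, not a
hard test case.

`build_synthetic_network` gives every planted and decoy receptor a
receptor → TF → housekeeping-target scaffold (so network support is
uninformative between planted and decoy — again, only subclass bias
separates them); looped pairs additionally wire TF → partner ligand and
partner receptor → TF′ → ligand, closing the loop in both directions.
All decoys share one TF; since it reaches only housekeeping targets,
sharing cannot create loop-closing paths. Random distractor edges are
appended on request and recorded.

What the generator does **not** emulate: realistic gene names, doublets,
ambient RNA, batch effects, gene-specific dispersion, spatial structure,
or cell-death-driven composition shifts over time. A green recovery test
therefore establishes that the pipeline's logic is faithful to its
definitions on data matching its distributional assumptions — not that
the method is robust to the full messiness of droplet data.

## 5. Numerical and I/O choices

* **Normalization** is counts-per-10k before averaging; the source
  stack normalizes inside its clustering toolchain without specifying a
  scheme for scoring, and CP10k is the minimal conventional choice.
  Log2 fold changes use pseudocount 1.0, bounding dropout-heavy genes.
* **Detection thresholds**: the LR retention filter is inclusive
  ($\ge 0.10$); the fold-change background gate is strict ($> 0.1$),
  matching each source phrasing.
* **QC boundaries** are retained (removal is stated for strict
  inequalities). `log10GenesPerUMI` is
  $\log_{10}(\text{nGene})/\log_{10}(\text{nUMI})$ — the standard
  definition behind that metric name, noted as an interpretation.
  Mitochondrial genes are identified by a configurable prefix
  (default `mt-`). Three presets ship: whole-retina (800–30,000 UMI,
  350–7,500 genes), purified-RGC (lower bounds only — the protocol
  names no upper bound for that dataset, and the preset leaves it
  $\infty$ rather than guessing), and a permissive `synthetic` preset
  scaled to the small simulated universes.
* **Network pruning** (`prune_network_by_detection`): whether the
  source pruned undetected nodes *before* path-finding is unstated; the
  default keeps the full network and applies expression only at the
  target-gene stage. The flag is honored in `network_support` only;
  loop qualification always uses the full network, because
  receiver-specific pruning would make a loop qualify in one direction
  and not the other with no stated warrant.
* **Ties and degenerate inputs**: dynamic-group ties break in template
  order; all-zero cells contribute zero profiles rather than NaN;
  empty (group, timepoint) combinations are omitted with a warning;
  pairs with genes outside the universe are skipped with a warning;
  an empty retained set yields empty, well-formed outputs.
* **Roll-ups**: the merge of per-sender protective lists into a
  non-redundant set is underspecified (pair identity vs pair+sender);
  `rollup_protective` reports both.
* **FISH quantification** operates on measurement tables (dots TSV +
  region JSON), not raw microscopy: the defined computation begins at
  the two printed equations, and segmentation upstream is out of scope.
  On noiseless uniform fields the two estimators invert each other
  exactly (tested to $10^{-9}$); when per-dot intensities vary, the
  estimate is unbiased only insofar as the calibration region's mean
  per-dot intensity matches the population mean — calibrating on an
  independent 20-dot region leaves a relative error on the order of
  $\mathrm{sd}/\sqrt{20}$, characterized in the test suite.
* **Determinism**: every stochastic stage derives a 31-bit child seed
  from the master seed and a stage tag, so stages never share an RNG
  stream and identical configs reproduce byte-identical artifacts.

## 6. Known limitations

Multi-subunit receptors are not modeled (the LR database is 1:1 by
gene). Statistical significance of $DS_{LR}$ is out of scope — the
protocol uses fixed cutoffs, not a null distribution. The scoring
closed form honors the three stated ingredients (expression, network
superimposition, loop bonus) of the source's delegated method but is
this package's own arithmetic; absolute score values are not
comparable to other implementations, though the bounded, monotone
construction keeps the differential logic faithful.
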