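---
title: "Methods: screen normalization, PCSF inference and TMA analysis in crpcnet"
author: "crpcnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screen normalization, PCSF inference and TMA analysis in crpcnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crpcnet)
```

crpcnet implements the computational chain used to nominate candidate
kinases from an arrayed kinome siRNA screen in androgen-deprived prostate
cancer cells, together with synthetic-data generators that plant a known
ground truth so that every stage can be validated end to end. This
vignette documents the statistical models, the tunable parameters, the
numerical choices, and the limits of what the synthetic validation shows.

## Robust plate normalization

Arrayed screens drift in location and scale from plate to plate
(reagent batches, incubation position, reader gain). Each 384-well plate
carries 48 non-targeting control siRNAs; a test well's readout $X_i$ is
normalized against its own plate's controls:

$$Z_i = \frac{X_i - \mathrm{median}(\text{controls})}{1.4826 \times \mathrm{MAD}(\text{controls})}$$

where MAD is the raw median absolute deviation and 1.4826 is the factor
that makes the scaled MAD a consistent estimator of the standard
deviation under normality, so $Z$ reads in standard-deviation units. The
formula is implemented as division by the product $1.4826 \times
\mathrm{MAD}$ — the standard robust-Z convention; a literal
left-to-right reading (dividing by 1.4826, then multiplying by the MAD)
would not be a normalization at all. `control_stats()` refuses plates
with fewer than two controls or zero MAD (degenerate scale), because $Z$
is undefined there.

Robust Z-scores are exactly invariant under plate-wide affine transforms
$x \mapsto ax + b$ ($a > 0$), and the Z of the control median is exactly
zero; both properties are asserted in the test suite.

### Hit calling and its error structure

Genes are primary hits when their summary Z meets the threshold
(`z_min = 1.8` by default, inclusive). Replicate screens are aggregated
by the mean of per-replicate Zs by default; `min` / `require_all`
policies implement the stricter both-replicates rule. The threshold and
policy are configurable because different screens trade sensitivity
against specificity differently.

With 48 controls the plate scale is itself an estimate, and the null
tail of $Z$ beyond 1.8 is noticeably heavier than the Gaussian
$1 - \Phi(1.8) \approx 3.6\%$ (the reciprocal of a noisy MAD is
right-skewed). With roughly 31 true hits among 704 genes, a primary
threshold of 1.8 therefore cannot by itself keep the false-discovery
proportion low: about $670 \times p_\mathrm{tail}$ null genes pass per
replicate, and even requiring both replicates leaves an expected handful
of false calls against ~30 true ones. This is exactly why such screens
run a second, deconvolved stage: in the confirmation screen each
candidate's pooled siRNAs are transfected individually (8 per gene: the
4 from the pool plus 4 additional distinct siRNAs) across two readouts,
and a gene is confirmed only when at least 3 distinct siRNAs score
(mean-across-assays $Z \ge$ 1.8 by default; a stricter both-assays mode
is available). Under a null gene the chance that 3 of 8 independent
siRNAs each clear 1.8 is of order $\binom{8}{3} p^3 \approx 10^{-4}$,
so the two-stage caller — primary screen then confirmation — is the
package's complete hit-calling procedure, and it is the procedure whose
sensitivity and false-discovery proportion the acceptance suite
measures. Knockdown itself is quantified by the standard
$\Delta\Delta$-Ct fold change, $2^{-\Delta\Delta C_t}$
(`ddct_fold_change()`).

## Prize-collecting Steiner forest

Hits rarely annotate their own pathway; mapping them onto a
confidence-weighted protein-interaction network and extracting a
parsimonious connecting subnetwork is the standard remedy. The
prize-collecting Steiner forest (PCSF) problem minimizes

$$\sum_{v \notin F} \beta\, p(v) \;+\; \sum_{e \in F} c(e)$$

over forests $F$: excluded node prizes $p(v)$ (here: screen Z-scores)
are paid as penalties, included edges cost $c(e)$. Multiple trees are
allowed through the standard artificial-root construction — a root
connected to every prized node by an edge of cost $\omega$, so each tree
of the forest pays $\omega$ once. The reported objective decomposition
excludes the root edges; the optimized ("augmented") objective, which
includes $\omega$ per tree, is exposed alongside so solver comparisons
are exact.

**Edge costs.** Interaction confidences $w \in (0, 1]$ must be turned
into positive costs. The default `one_minus_weight` ($c = 1 - w +
\varepsilon$, $\varepsilon = 10^{-6}$) makes confident interactions
cheap, which is what a confidence score semantically supports. Because
the phrase "edge weights set as edge costs" can also be read literally,
`weight_as_cost` is retained, as is `neg_log_weight`
($c = -\ln w$, floored at $\varepsilon$), which makes path costs
additive in log-confidence. The choice is surfaced as `cost_mode` and
never guessed silently.

**Solver.** For a *fixed* node set $S$ the optimal structure is exactly
the minimum spanning tree of the root-augmented subgraph induced by $S$
(each tree of the forest corresponds to one root edge). The search over
node sets exploits this:

* graphs with at most `exact_limit` nodes (default 12) are solved by
  complete enumeration of node subsets, each scored by a dense-Prim MST
  of the augmented induced subgraph — exact by construction;
* larger graphs use a deterministic heuristic: a terminal-metric MST
  (over prized nodes plus the root, using all-pairs shortest-path costs)
  expanded along shortest paths, then strong pruning (drop any subtree
  whose collectible net worth does not exceed its attaching edge), then
  a best-improvement local search whose moves add a boundary node, add
  an excluded terminal together with its shortest connecting path,
  remove a node, remove a pair of nodes adjacent in the current tree, or
  apply strong pruning. Pruning is a move among others because greedily
  pruning a whole root-subtree can mask a better removal inside it; the
  path-add and pair-remove moves cover profitable two-step changes that
  single-node moves miss.

The solver has no randomness: node order is sorted, ties in Prim and
Kruskal are broken by index, so identical inputs give identical forests.
An exhaustive oracle (`brute_force_pcsf()`, capped at 12 nodes, Kruskal
with union-find — an independent code path) certifies the solver: on
hundreds of random small instances across all three cost modes the two
agree exactly, and the forced-on heuristic stays near-optimal.

**Parameters.** `beta` (default 1) scales prizes against edge costs: as
$\beta \to \infty$ every reachable prized node is collected, as
$\beta \to 0$ the empty forest wins. `omega` (default $5 \times$ median
edge cost) is the per-tree charge; larger values favor fewer, larger
trees. Both are exposed because neither has a canonical value; the
defaults give forests that collect most strong prizes without absorbing
the whole graph on the synthetic interactomes described below. Prized
genes absent from the interactome are reported in the forest's
`unmapped` field rather than silently dropped — on real interactomes a
few screen hits always fail to map.

**Centrality.** `betweenness_report()` returns shortest-path betweenness
normalized by $(n-1)(n-2)/2$, computed on the inferred forest by default
(on a forest paths are unique, so no weighting question arises); on a
full costed graph, paths are weighted by edge cost. Whether centrality
should be read off the forest alone or a larger induced subgraph is a
genuine modeling choice, so the scope is the caller's.

## Randomization enrichment test

To ask whether a query node (the androgen receptor) is *specifically*
central to the hit network — rather than central to any network —
`randomization_test()` rebuilds the forest `n_iterations` times from
size-matched node sets drawn uniformly without replacement from a
background (the screened kinome), with the observed prize values
permuted onto the random nodes so the prize-magnitude distribution is
preserved. The statistic is the query's normalized betweenness in the
forest (default) or a 0/1 inclusion indicator; the betweenness criterion
is the default because centrality against random networks is the
sharper claim. The empirical p-value uses the add-one estimator

$$p = \frac{1 + \#\{\text{null} \ge \text{observed}\}}{N + 1},$$

which is never zero, is bounded below by $1/(N+1)$, and is
super-uniform under the null by exchangeability — a property the
acceptance suite verifies directly (200 null replicates at $N = 99$).
The same deterministic solver settings are applied to the observed and
every null network, so exchangeability cannot be broken by solver
asymmetry; by default the fast construction-plus-pruning solver is used
inside the loop to keep $N = 1000$ iterations affordable. Random sets
are sampled uniformly, not degree-matched: the comparison population is
"random kinases", and degree-matching would hold fixed exactly the
topological advantage being tested.

## IHC tissue-microarray analysis

Staining is scored on the ordinal 0–3 scale (0 no staining; 1 faint or
focal; 2 strong in a minority of cells; 3 strong in the majority).
`aggregate_by_class()` averages scores across all cores of each tumor
class and reports the standard error (sample SD, $n-1$ denominator,
divided by $\sqrt{n}$); plotted bars are $2 \times$ SE, approximately
95% confidence intervals. Missing scores are excluded pairwise.

**CI-overlap heuristic.** Group differences are triaged by the
rule-of-eye for independent 2-SE bars: with $n \ge 10$ per group,
bars overlapping by about half the average bar halfwidth correspond to
$p \approx 0.05$, and bars just touching to $p \approx 0.01$. The
overlap is measured as (sum of halfwidths − |mean difference|) divided
by the average halfwidth, so touching bars score 0, half overlap scores
0.5, and identical groups score 2. `ci_overlap_p()` labels the bands
(`<0.01`, `~0.01`, `~0.05`, `ns`, with a ±0.05 tolerance around
touching) and always computes the exact two-sided Welch t-test from the
same summaries alongside, so the heuristic can be checked: for equal
SEs and $n = 10$, touching bars give $t = 2\sqrt{2}$ at 18 df
($p = 0.011$) and half overlap gives $t = 3/\sqrt{2}$ ($p = 0.048$) —
the two calibration points the acceptance suite recomputes.

**Clustering.** Cores of one class (castration-resistant disease) are
clustered by their marker profiles with the uncentered absolute
correlation similarity $|\sum x_i y_i| / (\lVert x\rVert\,\lVert
y\rVert)$ — cosine similarity of raw scores, sign discarded, no mean
centering, because absolute staining level carries meaning on an ordinal
scale — and single-linkage agglomeration on distance $1 - s$. Cores
with incomplete profiles are dropped ("informative" cores only), cores
are ordered by id before clustering so leaf order is deterministic, and
merge heights are verified in the tests against a brute-force
agglomeration that knows nothing of `hclust`. The intensity map (scores
in leaf order) and the dendrogram (Newick) are exported as plain text.
Rows (cores) are clustered by default; marker clustering is left to the
caller.

## What the synthetic data emulates — and what it does not

The generators reproduce the study's design parameters:

* **Screen** (`simulate_screen()`): 704 library genes, 384-well plates,
  48 controls per plate in fixed leading positions, genes filled
  row-major across plates, duplicate replicate screens. Null readouts
  are Gaussian with per-plate location shifts ($\mathcal{N}(0, 10^2)$
  around a baseline of 100) and scale factors (uniform 0.7–1.3 times a
  baseline SD of 5); planted hits (31 by default) are shifted by their
  effect size times the plate's *true* control MAD, so the planted truth
  is invariant to plate effects. Default effects are uniform on 5–8
  control-MAD units — clearly separable single-gene effects, as a
  designed screen would target. The Gaussian noise form is a modeling
  choice (absorbance noise is roughly symmetric); nothing in the scoring
  chain assumes it.
* **Interactome** (`simulate_interactome()`): preferential-attachment
  growth (2 edges per node) over the hub plus the full 704-gene kinome,
  so every hit can map onto the graph — mirroring the near-complete
  kinome coverage of curated interactomes. The hub's attachment
  probability is multiplied by `hub_attachment_bias` (default 4: a
  clear hub that is not the universal router), planted hit neighbors are
  wired directly to the hub with confidence 0.9, and all other
  confidences are uniform on 0.2–0.95.
* **Confirmation** (`simulate_confirmation()`): 8 siRNAs per gene, two
  assays on plates with their own 48 controls; per-siRNA effects model
  variable knockdown efficiency (by default 5 of 8 siRNAs active for
  true hits in the pipeline).
* **TMA** (`simulate_tma()`): latent Gaussian staining intensities
  (SD 0.35) around per-(class, marker) means on the 0–3 scale,
  rounded and clipped to the ordinal scale; group sizes 30/30/42
  emulate 25–52 cores per class. Among the 42 CRPC cores a two-subclass
  structure is planted: a low-CSK subclass (CSK 0.2) with elevated
  SRC-family phospho-markers (pSRC-Y419 2.8, pFAK-Y925 2.6,
  pAR-Y534 2.4) versus a normal-CSK subclass (CSK 2.6, low
  phospho-markers) — the biology expected when the inhibitory kinase is
  lost. The contrast was fixed at design time so that the planted
  structure is recoverable by single-linkage clustering, which chains
  easily; a bridging core can otherwise collapse two genuine subclasses.

Deliberately **not** simulated: plate-edge and spatial artifacts, siRNA
off-target effects, growth kinetics, stain heterogeneity within cores,
and interactome ascertainment bias. Passing the recovery tests
therefore shows the *chain* is correct and well calibrated under its
stated noise model — it does not certify performance on real plates
with spatial gradients or on real interactomes with study bias.

## Problem sizes and numerical choices

The validation suite uses sizes chosen to exercise every code path at
full statistical fidelity: oracle comparisons on 200 random graphs of up
to 8 nodes; recovery on 20 full-size screens (704 genes, duplicates);
null calibration of the enrichment p on 200 replicates at $N = 99$ on a
60-node interactome (the calibration property is size-free); power on
the full-kinome configuration at $N = 1000$ over 10 seeds; clustering
recovery on the 42-core default TMA. Floating-point equality between
solver and oracle is asserted at $10^{-9}$ on objectives; tie-breaks
(fewer edges, then lexicographic node set) make reported forests unique.
All simulation is seeded through a save/restore wrapper so generators
never disturb the caller's RNG stream, and the pipeline derives
per-stage seeds from one global seed so stages are individually
reproducible.

## Known limitations

* The heuristic PCSF path is near-optimal but not guaranteed optimal
  above `exact_limit`; the guaranteed-improvement contract (never worse
  than the empty forest or any single-prize tree) always holds.
* The enrichment test is single-query by design; multiple queries would
  require multiplicity control.
* The CI-overlap rule is a triage heuristic; the exact Welch p computed
  alongside should be preferred whenever a number is reported.
* Ordinal scores are treated as interval-scaled by the mean/SE
  summaries and the cosine similarity, as is conventional for 0–3 IHC
  scores; an ordinal-regression treatment is out of scope.
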