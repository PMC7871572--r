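---
title: "Community prediction of hub regulators: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community prediction of hub regulators: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hub transcription factors — regulators with unusually many targets in a gene
regulatory network (GRN) — are disproportionately informative: they act as
master regulators of cell state and are frequent disease regulators and drug
targets. Individual GRN-inference methods estimate regulator→target edges
from expression data with notoriously variable accuracy across datasets, and
no single method wins everywhere. A regulator's *outdegree*, however, is a
sum over many edge calls, so its estimate is far more robust to individual
edge errors than the edges themselves, and combining several methods'
outdegree estimates averages away method-specific biases.

`grnhubs` implements this consensus strategy in three steps:

1. **Inference compendium.** A set of GRN-inference engines each produce a
   ranked edge list from the same expression matrix and candidate-regulator
   list (or the user supplies pre-computed ranked edge lists).
2. **Threshold selection.** A single edge-inclusion threshold $T$ — how many
   top-ranked edges of each prediction to count — is chosen to maximise the
   mean pairwise Pearson correlation of the regulator-outdegree vectors
   between methods. The rationale: where independent methods agree on who
   the hubs are, the edge-count regime is well posed.
3. **Averaging.** The hub score of regulator $k$ is
   $\mathrm{score}_k = \frac{1}{N}\sum_{l=1}^{N} \mathrm{outdegree}_{kl}$,
   the mean over the $N$ predictions of its outdegree among each
   prediction's top $T$ edges. Regulators are ranked by this score.

`hub_community()` is the fitting function; it returns a classed object with
`print`, `summary`, `coef` (scores in ranking order) and `plot` (the
threshold-agreement scan) methods.

## The inference engines

Six engines are bundled, spanning the main families of expression-based GRN
inference. All emit directed regulator→target edges over every
(regulator, other-gene) pair, ranked by a method-specific confidence.

| engine | confidence | key defaults |
|---|---|---|
| `pcc` | absolute Pearson correlation of the two profiles | — |
| `clr` | background-corrected mutual information: $\sqrt{z_i^2+z_j^2}$ with $z$ the non-negative row/column z-scores of the MI matrix | 10 equal-frequency bins |
| `aracne` | mutual information after data-processing-inequality pruning (the weakest edge of each fully-scored triangle is removed when strictly below $(1-\tau)$ times the next-weakest) | 10 bins, tolerance $\tau = 0$ |
| `genie3` | per-target random-forest importance (total variance reduction), normalised to sum 1 per target | 1000 trees, $\sqrt{p}$ features per split |
| `elasticnet` | fraction of bootstrap resamples in which the regulator's elastic-net coefficient is nonzero | 1000 resamples, mixing 0.5 |
| `tigress` | stability-selection area score: mean over steps $s = 1..L$ of the frequency of entering the (randomised, reweighted) lasso path within $s$ steps | 1000 resamples, $L = 5$, weights on $[0.2, 1]$ |

Engine-specific notes and numerical choices:

* **Mutual information** uses equal-frequency discretisation (ties broken by
  sample order, so bin occupancies are as equal as possible) and the
  maximum-likelihood plug-in estimator, in nats. Equal-frequency binning is
  invariant to monotone transforms of the profiles, matching the package's
  scale-agnostic treatment of expression units. `MI(x, x)` is the binned
  entropy, $\log(\text{bins})$ when the sample count divides evenly.
* **DPI pruning** judges every triangle against the original MI matrix (no
  order dependence), uses strict inequality, and interprets the tolerance
  multiplicatively; tolerance 1 disables pruning entirely.
* **The elastic-net penalty** is chosen once per target on the full data by
  BIC over the regularisation path and then held fixed across bootstrap
  resamples, so the reported confidence is a pure selection frequency, not a
  mixture of selection and tuning variability.
* **The stability-selection engine** derives each resample's forward-selection
  order from the lasso path (the first penalty at which a coefficient becomes
  nonzero); path-position ties break by final coefficient magnitude.
  Regression engines standardise profiles internally (their penalties are
  scale-sensitive); correlation and MI engines use raw profiles.
* Zero-variance profiles have undefined correlation/importance: affected
  edges get confidence 0 and a warning, never `NA`.
* Every stochastic engine takes an explicit seed, and the package-level seed
  fans out to per-engine seeds by fixed offsets, so adding an engine never
  perturbs another engine's stream. Re-running with the same seed reproduces
  confidences bitwise.

## Threshold selection in detail

At each candidate $T$, each prediction is reduced to the vector of counts of
each regulator among its top $\min(T, |\text{edges}|)$ edges (regulators
absent from a prediction count 0, so all vectors live on the same index).
The scan statistic is the mean Pearson correlation over unordered method
pairs; pairs in which either vector is constant are excluded (a constant
vector carries no ranking information), and a threshold where every pair is
excluded is skipped. The selected $T$ is the argmax, ties broken towards the
smallest threshold — the sparser, more conservative network.

The default candidate grid is $\{100, 200, 500, 1000, 2000, 5000, 10^4,
2\times 10^4, 5\times 10^4, 10^5\}$ intersected with $[1, \max |\text{edges}|]$,
and is user-overridable. Confidence ties at the cut boundary resolve by
stored list order; the file loaders sort stably, so file order is the
ultimate tie-break.

## Evaluation metrics

Against a gold standard (directed regulatory edges, or an undirected
protein-interaction proxy whose degree stands in for regulatory outdegree),
`evaluate_hubs()` reports:

* **PCC / SCC** — Pearson and Spearman correlation between predicted scores
  and gold outdegrees over the *full* regulator set, zeros included;
  dropping unscored regulators would hide false hubs.
* **Normalised absolute error** — both vectors are scaled to sum 1 (scores
  and counts are on different scales) and the mean absolute difference of
  the degree fractions is taken; it is 0 exactly on proportional pairs.
* **HITS hub scores** (`hits_hub_scores()`) — the hubs-and-authorities
  principal eigenvector on the thresholded edge list, by power iteration
  normalised to unit Euclidean norm each step, to a $10^{-10}$ componentwise
  tolerance or 1000 iterations.

`edge_rank_community()` provides the classic consensus-over-edges
comparator: each edge's confidence is the negative mean of its rank
positions across methods, with absent edges charged rank $|\text{list}|+1$
in that method — a simple, monotone, list-length-aware absence convention.

## The WGCNA-style comparator

The conventional alternative route to hubs is module connectivity:
soft-threshold adjacency $a_{ij} = |\mathrm{cor}(i,j)|^\beta$ (unsigned),
topological overlap, average-linkage clustering on $1 - \mathrm{TOM}$,
module eigengenes (first principal component of the standardised member
submatrix, sign oriented by mean member correlation), and ranking
regulators by $|kME|$ — the absolute correlation with their own module's
eigengene, falling back to the maximum over modules for unassigned
regulators so the ranking is total.

Two deliberate simplifications relative to full WGCNA practice:

* **Static cut instead of dynamic tree cut.** Candidate modules come from a
  fixed height cut at 0.99 of the maximum merge height plus a minimum-size
  filter (default 10). The comparator only needs representative module
  structure; the full dynamic algorithm adds many parameters without
  changing what is being compared.
* **Merging "similar expression"** is interpreted as eigengene correlation
  above 0.75 (merge threshold 0.25, the conventional default), iterated to
  stability with eigengenes recomputed after each merge.

The soft power is selected as the smallest candidate whose scale-free
topology fit (signed $R^2$ of the log-log connectivity regression, negative
when the slope is positive) reaches 0.8, else the best-fitting power with a
warning.

## The synthetic benchmark

`generate_grn()` plants hubs by giving the $r$-th regulator (in a random
order) sampling weight $r^{-\gamma}$ and drawing distinct edges with
weighted regulators and uniform targets; regulator→regulator edges are
restricted to a fixed topological order, so the regulator subgraph is
acyclic. `simulate_expression()` then draws source regulators standard
normal and each regulated gene as the weighted sum of its regulators'
profiles (weights $\mathcal{N}(0, \sigma_e^2)$, one per edge) plus
$\mathcal{N}(0, \sigma_n^2)$ noise, in one topological pass.

`default_fixture()` fixes the study conditions used throughout the tests:
300 genes, 20 regulators, 600 edges, exponent 2, 200 samples, effect scale
1, noise 0.5, seed 42. With 20 regulators and exponent 2 the top regulator
holds over half the edge mass, so the fixture has one dominant hub, a few
mid-sized hubs and a long tail of 1–4-target regulators — the regime the
tool is meant for. The linear-Gaussian choice (rather than kinetic
ODE-style simulation) buys exact noiseless checks — with zero noise every
regulated profile lies in the span of its regulators — while preserving the
hub-detectability structure.

What the generator does **not** emulate: saturating/combinatorial
regulation, measurement-specific noise (counts, batch effects),
feedback loops, and the scale of real compendia (thousands of genes, dozens
of methods). Passing the fixture-level tests therefore shows the machinery
is correct and the consensus logic behaves as designed under clean linear
signal; it does not certify performance on any particular real dataset.

## Known limitations

* **Agreement can outlive accuracy.** The threshold scan assumes that
  inter-method agreement decays once the edge count passes the informative
  regime. On the bundled benchmark the candidate-pair universe is small
  (about 6000 pairs) and the bundled engines all consume the same sample
  correlation structure, so they keep agreeing — on indirect and shared
  spurious edges — well past the true edge count, and the selected
  threshold tends to overshoot the performance optimum. Two mechanisms
  drive this: regulators that are themselves targets of a hub inherit the
  hub's correlations (and are credited with its "grandchildren"), and
  sample-level noise correlations are common-mode across engines fed the
  same matrix. With a large pair universe relative to the list lengths and
  a more heterogeneous method compendium — the setting the approach is
  designed for — both effects are diluted. Users combining only
  correlation-family engines on small networks should inspect the scan
  (`plot(fit)`) rather than trust the argmax blindly, and may prefer a
  domain-informed threshold.
* Spearman evaluation over few regulators is dominated by the long tail of
  1–4-target regulators, whose relative order is close to unidentifiable;
  rank-based performance numbers on small regulator sets are accordingly
  noisy.
* The elastic-net and stability-selection engines refit a generalised
  linear model per target per resample; at compendium scale they are the
  slow members, and their resample counts are the knobs to reduce first.
* The tool ranks regulators by predicted outdegree only; edge-level
  accuracy (AUPR/AUROC) and global centralities (e.g. betweenness) are out
  of scope, and individual predicted edges should not be interpreted as
  regulatory strengths.

## Problem sizes used in the test suite

The packaged tests exercise the engines and oracles on small random
instances (5–8 genes, tens of samples), the consensus core on 200 random
instances against brute-force recomputation, and the full pipeline on the
default 300-gene fixture and four same-sized re-seeded fixtures — sizes
chosen so the whole suite documents the method's behaviour at desk scale
while remaining quick to run.
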