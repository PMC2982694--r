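---
title: "cocktailnet: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cocktailnet: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A drug rarely perturbs a single gene: its targets are embedded in a
molecular interaction network, and the perturbation propagates to a
connected neighbourhood — an *affected subnetwork*.  cocktailnet screens
candidate drug pairs by comparing the subnetwork a predicted combination
would affect with the subnetworks its member drugs affect alone.  A
combination is worth pursuing when its balanced efficacy/side-effect
score beats every member's.

The pipeline has five stages, each usable on its own:

1. **Network assembly** (`build_background_network()`): protein–protein,
   protein–DNA and signaling edge lists are cleaned, merged into one
   undirected simple graph, restricted to genes observed in the
   expression data, and reduced to the largest connected component.
2. **Expression preprocessing** (`drug_profile()`): probe-level
   case/control microarray intensities become one gene-level expression
   ratio $r_i = T_i/C_i$ per gene and treatment.
3. **Combination prediction** (`predict_profile()`): a combination's
   ratio profile is predicted from its members' profiles.
4. **Subnetwork extraction** (`find_affected_subnetwork()`): a
   network-flow program selects the maximum-weight connected subnetwork
   rooted at the drug's targets.
5. **Scoring** (`rank_combinations()`): subnetworks are scored for
   efficacy against side-effect liability and combinations are ranked.

# Models and conventions

## Node weights

The differential-expression weight of gene $i$ is
$w_i = |\log_2 (T_i/C_i)|$: non-negative, zero exactly when the gene is
unchanged, and symmetric in induction and repression
($w(r) = w(1/r)$).  The log base only rescales all weights by a common
factor; every reported score is a ratio of weight sums, so the scores
are invariant to the base (and to any global rescaling).  The weight
function is pluggable (`weight_fn` argument) for users who prefer, e.g.,
squared log fold changes.

## Expression preprocessing

Probes are collapsed in two steps: probes sharing a symbol string are
averaged, then a gene's value is the mean over all symbol strings that
equal it or contain it as a `///`-separated token (pseudo-symbols such
as `HSPA1A /// HSPA1B` contribute to both genes).  Sample bookkeeping
follows the conventions of large perturbation compendia: batches `2`
and `2a` are relabelled as one batch; batches whose non-control samples
carry a single perturbagen are dropped (their contrasts are confounded
with the batch); only the configured cell line (default MCF7) is kept.
The batch rule is ambiguous in its source ("one single drug" could mean
one drug or one drug/dose pair); we implement *one distinct perturbagen
per batch*, the stricter and simpler reading.

Within a batch, each case's several controls are averaged into one
control, replicate cases are averaged, and per-batch values are averaged
across batches.  Genes whose case or control mean falls at or below a
floor $\varepsilon_C = 10^{-6}$ are dropped rather than allowed to
produce unstable ratios.  When a drug was profiled at several doses, the
representative profile is the gene-wise mean of the per-dose ratio
profiles; a single dose can be requested instead (`dose` argument).
Averaging across doses uses all available data and keeps the
representative profile well-defined for every gene that survives the
floor at one dose or more.

## Combination prediction

Writing gene $i$'s expression as a smooth function of the dose vector
and truncating the Taylor expansion at first order around zero dose
gives the *additive rule* for the combination ratio:
$$F_i = 1 + \sum_j (r_{ij} - 1),$$
the baseline plus the sum of the members' deviations.  Working with
ratios rather than absolute intensities removes the dependence on each
experiment's own control level.  Two corrections handle the rule's
failure modes:

* **Saturation** (`mode = "saturating"`): when all non-zero member
  deviations share one sign, co-directional effects are assumed to
  saturate and the combined deviation is the most extreme single
  deviation, $F_i = 1 + s\,\max_j |r_{ij} - 1|$, rather than the sum.
  Zero deviations are neutral, which keeps a do-nothing member from
  switching the rule.  This is the simplest damping that cannot drive a
  co-repressed gene negative; the rule is a pluggable convention, and
  outputs record per-gene which rule fired.
* **Clipping**: the additive sum can go below zero when several members
  strongly repress one gene; predicted ratios are floored at
  $\varepsilon_F = 0.01$ (i.e. $\log_2$ ratio $\approx -6.6$) and
  flagged `clipped`.

Predictions are defined on the intersection of the member gene sets, so
downstream weights are always available.

## Affected-subnetwork model

Given the weighted background network $G=(V,E,W)$ and the treatment's
target set $H = \{H_1,\dots,H_K\}$, a dummy drug node $S$ is connected
to every target, each interaction becomes two opposite arcs, and the
program selects the subnetwork:

$$\max \sum_i w_i x_i \quad \text{s.t.}$$

* $\sum_k Z_{S,H_k} = R$ — $R$ units of flow enter through the targets;
* $\sum_{j} Z_{ji} - \sum_{j} Z_{ij} = x_i$ for every gene — a selected
  gene absorbs one unit, so any feasible solution selects a total of
  exactly $R$;
* $Z_{ij} \le R\,x_i$, $Z_{ij} \le R\,x_j$ — flow traverses selected
  genes only ($R$ is the tightest valid capacity constant for this
  flow), which forces every selected gene to be reachable from $S$
  through selected genes;
* $x_{H_k} = 1$, $Z \ge 0$, $x_i \in \{0,1\}$.

With several targets the dummy node may split its flow, so the selected
genes form one or more connected pieces, each anchored at a target —
exactly the connectivity the dummy-rooted formulation defines.  The
exhaustive test oracle (`brute_force_oracle()`) uses this same
definition; on 200 seeded random instances per test run the exact
branch-and-bound solution matches the oracle's optimum exactly.

The binary program is NP-hard, so production solves relax
$x_i \in [0,1]$ to a linear program.  Both forms are written in CPLEX LP
format and handed to the GLPK stand-alone solver `glpsol`; the backend
is a config key, and any solver that returns optimal basic solutions
can stand behind it.  Genes with $x_i > 10^{-6}$ form the extracted
subnetwork — a fractional optimum can therefore return slightly more
genes than $R$ — and the LP optimum is always an upper bound on the
exact optimum.  Components of the extracted set that lost contact with
every target (possible only for fractional solutions) are discarded
with a message.  In practice the relaxation returns integral solutions
on the large majority of planted-module instances; the `lp_integral`
flag records it.

$R$ is scanned over $\{R_{\min}, R_{\min}+s, \dots, R_{\max}\}$:
$R_{\min}$ is the number of distinct genes on one deterministic
(lexicographic next-hop) shortest path per target pair — the smallest
size that can connect the targets — and $R_{\max}$ is 10% of the
network's genes, reflecting the assumption that one treatment affects a
limited part of the network.  Whether one or all shortest paths should
define $R_{\min}$ is a free choice; one deterministic path keeps the
bound minimal and reproducible.  Across the scan, subnetworks are
compared by the size-normalized score
$$\text{score}(M) = \frac{\sum_{i \in M} w_i}{\sqrt{|M|}},$$
a Z-score-style normalization under which a module of $k$ genes with
mean weight $\bar w$ scores $\bar w \sqrt{k}$: it rewards concentrated
high-weight modules without letting size alone win.  Ties break toward
the smaller, then lexicographically smaller, gene set so results are
deterministic.

## Efficacy, side effect and the verdict

With $SD$ the disease genes inside the treatment's subnetwork, $BD$ the
disease genes in the background network, $ED$ the *innocent* essential
genes (essential, not disease-related) inside the subnetwork and $EB$
their background counterpart:

$$S_{\text{eff}}(\lambda) \;=\; \lambda\,
\frac{\sum_{SD} w_i}{\sum_{BD} w_i} \;-\; (1-\lambda)\,
\frac{\sum_{ED} w_i}{\sum_{EB} w_i},$$

efficacy being the share of background disease-gene weight the
subnetwork captures and side effect the share of innocent
essential-gene weight.  Both terms live in $[0,1]$, so
$S_{\text{eff}} \in [-1,1]$; it is linear and non-decreasing in
$\lambda$, equals the efficacy at $\lambda = 1$ and minus the side
effect at $\lambda = 0$, and is invariant to rescaling all weights.
Each treatment is scored with its *own* profile's weights — a member
drug with its measured profile, a combination with its predicted one.
`lambda_scan()` tabulates the score over a 0.05-step grid; the default
single-number verdict uses $\lambda = 0.5$, equal weighting, since no
canonical trade-off exists.  A combination is *effective* when its
score strictly exceeds every member's.

# The synthetic-data generator

`make_scenario()` builds a complete desk-scale study: a connected
scale-free network (preferential attachment, 2 edges per node — the
degree heterogeneity of real interactomes), a drug panel with planted
affected modules, probe-level case/control data, and disease/essential
gene sets.  Defaults, chosen once to represent the screening conditions
the method assumes:

* **200 genes**, 5 drugs with 1–2 targets each.  Small enough that the
  full pipeline runs in seconds, large enough that the 10% size cap
  ($R_{\max} = 20$) leaves the module search non-trivial.
* **Module size 8** per drug, grown breadth-first from the targets: two
  member modules (16 genes) fit together under $R_{\max}$, so a
  combination's joint footprint is identifiable in principle.
* **Effect size 2** ($\log_2$ units at the target) with **decay 0.9**
  per hop — the perturbation is strongest at the targets and attenuates
  along the network, as the propagation picture suggests.
* **Noise SD 0.2** on the $\log_2$ scale, independent per probe and
  sample (log-normal intensity noise, matching the ratio-based model);
  the planted weight (>1.3 everywhere in a module) clears the mean
  noise weight (~0.16) by far more than 3 noise SDs.
* **Controls at a fixed baseline of 100 units**, so ratio recovery is
  exact at zero noise — the basis of the exactness tests.
* **20 disease genes, 30 essential genes, 3 overlapping.**  Half the
  disease genes are placed inside planted modules, spread evenly across
  the drugs so every drug has detectable efficacy; essential genes are
  placed outside the modules (toxicity-neutral drugs).
  `disease_frac_in_modules = 0` produces the negative-control scenario
  in which no drug touches the disease and no combination should be
  called effective.

Each emitted data set also contains the structures the preprocessing
rules must handle: two probes per gene plus one `A /// B` pseudo-symbol
probe, batches `2`/`2a` to exercise the merge, a decoy perturbagen so
batches survive the single-drug filter, and an off-cell-line
case/control pair the cell-line filter must remove.
`write_scenario()` additionally plants cleaning decoys in the edge
lists (self-loops, duplicates, under-supported pairs, unexpressed genes,
a detached component) such that network assembly reproduces the
scenario network *exactly*.

What the generator does **not** emulate: array-hybridisation physics,
probe-level biases, correlated noise, incomplete or wrong gene sets,
and dose–response nonlinearity.  Passing the synthetic suite shows the
machinery is correct under the method's own assumptions; it does not
show the assumptions hold for any particular real compendium.

# Numerical choices and degenerate inputs

* Control/case floor $\varepsilon_C = 10^{-6}$; prediction clip
  $\varepsilon_F = 0.01$; LP extraction threshold $10^{-6}$; integrality
  tolerance $10^{-6}$.
* Gene symbols are trimmed and upper-cased everywhere; no identifier
  translation is attempted.
* Empty networks warn rather than error in `largest_component()`;
  missing targets, infeasible flow models, empty gene intersections and
  invalid configuration values raise errors that name the offending
  entity.
* All tie-breaks (component choice, subnetwork choice, oracle optimum)
  are lexicographic, making every result reproducible bit for bit under
  a fixed seed.

# Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on generated
data: 200 random solver instances of at most 12 genes (the exhaustive
oracle's comfort zone), 200-gene scenarios for module recovery
(50 seeded replicates in the tests, 15 in the acceptance script) and
for verdict behaviour, and a 120-gene noise-free scenario for the
exactness checks.  These sizes keep a full run in the minutes range on
one CPU while leaving every moving part exercised.

# Known limitations

* The flow relaxation can return fractional solutions whose extracted
  subnetwork exceeds $R$; the normalized score then compares slightly
  different effective sizes.  All downstream logic tolerates this, but
  strongly fractional solutions (rare in our benchmarks) would blur the
  size scan.
* The saturation rule is one convention among several the additive
  model admits; both modes are first-class so either can be reproduced.
* Scores depend on the curation quality of the disease and essential
  gene sets; with sparse or biased sets the efficacy and side-effect
  normalizations degrade gracefully (empty-weight denominators score 0)
  but lose discrimination.
* Verdicts compare a *predicted* combination profile against measured
  member profiles; any systematic failure of first-order additivity in
  real data propagates into the verdict.
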