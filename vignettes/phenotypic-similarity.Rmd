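---
title: "Phenotypic drug-disease similarity: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotypic drug-disease similarity: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenosim)
library(dplyr)
```

## The model

`phenosim` quantifies how much a drug's side-effect profile resembles a
disease's symptom profile, on the premise that phenotypic resemblance
reflects shared molecular mechanism. The measure has three layers.

**Term specificity.** Phenotype terms form a rooted, acyclic, multi-parent
hierarchy (MedDRA-like: organ-system classes at the top, specific
preferred terms at the bottom; cross-hierarchy groupings are ordinary
extra parent edges, since only reachability matters). Instead of deriving
information content from annotation frequencies — which would make
specificity depend on how well-annotated a corpus happens to be — the
hierarchy itself supplies it:

$$IC(t) = 1 - \frac{\log(\mathrm{hypo}(t) + 1)}{\log N}$$

where $\mathrm{hypo}(t)$ counts *distinct* descendants (a descendant
reachable along several parent paths counts once — under multiple
inheritance, path counts are ambiguous while set semantics preserves the
boundary values) and $N$ is the ontology size. Leaves get IC 1, the root
IC 0, and IC never increases towards the root. The expression is a ratio
of logarithms, so the base is irrelevant.

**Term-pair score.** A side effect $a$ and a symptom $s$ are as similar
as their most informative common ancestor (MICA), damped by two weights
that penalize uninformative terms:

* frequency weight $f(t) = -\ln(n_t / M)$ — terms annotated to most
  entities carry little signal ($f \to 0$), rare terms much;
* co-occurrence weight $c(t)$ — the mean of $-\ln J(A_t, A_u)$ over all
  other terms $u$ whose annotated-entity sets overlap $A_t$, so bundles of
  terms that always travel together are down-weighted.

$$s_{a,s} = IC(\mathrm{MICA}(a, s)) \cdot \min\!\big(f_a c_a,\; f_s c_s\big)$$

The minimum (rather than product or mean) requires the phenotype to be
specific on *both* sides. If two terms share only the root, the score is 0
regardless of weights.

**Pair similarity.** For profiles of $n$ side effects and $m$ symptoms,
each side effect contributes its best-matching symptom score and vice
versa:

$$\mathrm{similarity} = \frac{\sum_i \mathrm{best}_{a_i} + \sum_j \mathrm{best}_{s_j}}{n + m}$$

Ties among best matches are resolved by value only; the partner's identity
is never consumed. The $n + m$ denominator removes the gross advantage
that heavily annotated entities would have under a plain sum. A mild
residual size dependence remains — maximizing over more candidate partners
inflates the bests slightly, a property of every best-match scheme rather
than of this normalization — and the test suite bounds it (rank
correlation with $n+m$ below 0.3, and less than half that of the
unnormalized sum) instead of pretending it is zero.

## Benchmarks along the ranking

**Lift.** For a labeled pair set, the lift at rate $r$ is the precision
among the top $\lceil r \cdot \text{total} \rceil$ ranked pairs (pairs tied
with the cutoff score included) divided by the prevalence of labels in the
whole list. Prevalence — positives over *all* pairs — is used as the
denominator rather than the positives-to-negatives ratio; only then does a
random ordering give lift 1 exactly, which is the property that makes the
curve readable. At rate 1 the lift is 1 by construction. At the spec-scale
calibration setting (1,000 pairs, 100 positives, rate 0.1) a single
shuffle has hypergeometric standard deviation of about 0.29 in lift units,
so calibration is asserted on the *mean* over 100 shuffles (within
$\pm 0.1$ of 1), not on individual shuffles.

**Molecular distance.** Drug targets and disease proteins are mapped onto
a protein-interaction network; a pair's distance is the minimum shortest
path over all target-protein combinations, binned into categories 0, 1,
2, 3, ">3". Unreachable pairs fall into ">3" rather than being dropped —
the five categories must partition every pair, or the lift denominators
would silently change. Proteins absent from the network are ignored;
entities with no mappable protein are excluded, as molecular benchmarks
conventionally restrict to the mappable universe.

**Threshold selection.** The phenotypic network keeps pairs above a
similarity threshold chosen by Pareto optimization over a grid of observed
scores (all distinct scores, or a 100-point quantile grid when there are
more), with two objectives evaluated on the molecularly covered universe:
the lift and the precision of distance-0/1 pairs above the threshold.
These two objectives are exactly proportional (lift is precision over a
constant prevalence), so the non-dominated front degenerates to the
precision-maximizing threshold; the implementation reports the front
faithfully, and additionally computes `recall01` (the fraction of
distance-0/1 pairs retained) which can be substituted as an objective to
obtain a genuine precision/coverage trade-off. Two selectors are provided
— `max_product` of min-max-normalized objectives (default) and the `knee`
point — because the original procedure does not determine a unique point
on the front.

## Network, communities, enrichment

Edges at or above the threshold form a bipartite drug-disease network.
Communities are found by greedy multi-level modularity optimization
implemented in the package (local moves to the neighboring community with
the highest modularity gain, then contraction, iterated), with no
constraint on community number or size. The greedy search is
order-dependent, so it restarts from `n_restarts = 5` seeded node orders
and keeps the best partition; results are deterministic given the seed.
The reported modularity is always *recomputed* from the final assignment
via $Q = \sum_c (e_c/m - (d_c/2m)^2)$, and the test suite verifies the
optimizer against exhaustive maximization over all partitions of small
graphs.

Class enrichment per community uses one-sided (greater) Fisher's exact
tests — the question is over-representation; two-sided is available via
`alternative` — on 2x2 tables of community membership versus class
membership among all network nodes of one side, unclassified nodes
counting as class-negative. Benjamini-Hochberg correction pools all
(community, class) cells of one side into a single family (disease and
drug analyses are corrected separately, never mixed), with significance at
FDR <= 0.01 by default. Disease-class x drug-class combination enrichment
compares the network's edges against the full scored universe the same
way, at FDR <= 0.05, and reports how many network edges significant
combinations cover. Entities with several classes count once per class.

**Candidate contraindications.** Pairs in the top 2% of the full ranking
(ties included; the fraction is a parameter) that carry an ADR-disease
label but no contraindication label are emitted as candidate precautions,
with the applied score cutoff attached. The top fraction is taken over all
scored pairs, not over labeled pairs only.

## The synthetic world

Licensed sources cannot ship, so `simulate_world()` generates inputs with
the statistical structure the analysis assumes. What it emulates, and
what it does not, determines what green tests mean.

* **Ontology** (`simulate_ontology`): a root, `n_subtrees = 10` level-1
  organ-system subtrees (MedDRA has 26 system organ classes; 10 keeps desk
  scale), then `depth = 4` levels with 2-4 children each (~300-500 terms).
  Terms below level 1 acquire extra parents with probability 0.1; one
  designated subtree attaches only at the root except for `cross_links =
  5` bridge edges, emulating an isolated hierarchy branch plus
  standardized-query cross-links.
* **Annotations**: each of 200 drugs and 300 diseases draws 5-15 *leaf*
  terms (profiles are annotated at the most specific level) under a Zipf
  popularity law (exponent 1), concentrated with probability
  `focus_weight = 0.8` in the entity's 1-2 focus subtrees — real
  phenotype profiles cluster in few organ systems, and this concentration
  is also what gives the class maps their signal.
* **Molecular layer**: a 400-node, 1,600-edge uniform random interaction
  graph; entities carry 1-3 proteins. Each protein gets an organ-system
  label from Voronoi cells around 3 random center proteins per subtree
  (ties jittered, cell labels independent), so label agreement decays
  with network distance and bottoms out at the 1/10 baseline. Drug focus
  subtrees are their proteins' labels; disease focus subtrees are
  protein-derived with probability `coupling = 0.8` and random otherwise.
  A molecularly related pair therefore draws annotations from shared
  subtrees with probability `coupling`, and the phenotypic signal fades
  over distance — the planted analogue of the enrichment-by-distance
  result. The focus-set size is drawn independently of the protein count;
  otherwise single-target entities would be systematically more
  phenotypically concentrated, which measurably fakes enrichment in the
  unreachable category.
* **Clinical labels**: sampled per pair and relation, with elevated rates
  at molecular distance <= 1 for ADR-disease (0.15 vs 0.01) and
  contraindication (0.08 vs 0.005) and distance-independent rates (0.01)
  for indication and clinical-trial labels — so the causative relations,
  and only they, should concentrate at the top of the ranking.

Not emulated: text-mining noise, negation, annotation specificity loss,
scale (thousands of entities, tens of thousands of terms), degree-skewed
interaction networks, and hierarchical class systems. Passing tests show
the pipeline recovers planted structure of this kind at this scale; they
do not certify effect sizes on real vocabularies.

Determinism: one seed drives every draw; identical configuration and seed
reproduce byte-identical written worlds.

## Numerical and degenerate-input choices

* IC is undefined for a single-term ontology ($\log N = 0$); rejected
  explicitly. Cycles and multiple roots are rejected at load time, naming
  an offending edge or the roots.
* Co-occurrence averages exclude self-pairs (J = 1 contributes nothing but
  shrinkage) and zero-Jaccard partners ($-\ln 0$ is infinite); a term
  overlapping no other term falls back to the maximum observed weight
  (configurable to zero), treating isolation as maximal independence.
  Natural logarithms throughout; not configurable.
* Frequency weights are computed within kind — side effects against the
  drug universe, symptoms against the disease universe.
* All-pairs scoring computes one term-by-term score matrix (weights are
  profile-independent) and reduces per-entity best-match sums to two
  matrix products; this is exactly equivalent to per-pair evaluation and
  is what makes the 60,000-pair default world score in under a second.
* Ranking ties are broken lexicographically by (drug, disease) identifier,
  so outputs are identical across runs and platforms; scores accumulate
  in double precision and export at six decimals.
* Empty networks, thresholds above the maximum score, relations without
  pairs, and classes without members are warnings or skips, never silent
  drops that would change denominators elsewhere.

## Problem sizes in the checks

The test suite and the acceptance script run the default 200 x 300 world
(60,000 pairs, scored in about a second) for planted-signal recovery,
three-seed averages for the distance-decay property (single-category lifts
at rate 0.01 carry sampling noise of 0.2-0.4, hence a 0.25 tolerance
between successive categories on the averages), a 1,000-pair world for
lift calibration, and graphs of up to 50 nodes against brute-force
oracles (exhaustive partition enumeration is feasible to 8-9 nodes).

## Known limitations

* The Pareto objectives degenerate as described; a coverage objective is
  provided but the default mirrors the original procedure.
* Best-match averages retain a mild profile-size effect; rankings between
  entities of similar profile size are unaffected, but comparisons across
  very different profile sizes inherit it.
* The community optimizer is a greedy heuristic; restarts mitigate but do
  not eliminate local optima on large graphs.
* Lift values on sparse label sets at small rates are noisy; the package
  flags categories with fewer than five labeled pairs (`low_n`) rather
  than suppressing them.
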