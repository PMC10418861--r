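---
title: "Methods: metapath-constrained HeteSim ranking and hub analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metapath-constrained HeteSim ranking and hub analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Literature-based discovery infers new hypotheses — here, drug–disease
links — from patterns in already-published relationships rather than from
new experiments. The raw material is a *predication knowledge graph*: each
node is a biomedical concept with a UMLS-style Concept Unique Identifier
(CUI) and a 4-letter semantic type (PHSU pharmacologic substance, DSYN
disease or syndrome, GNGM gene or genome, ...), and each directed edge is a
subject–predicate–object assertion extracted from text (`drug TREATS
disease`, `gene ASSOCIATED_WITH disease`), aggregated per triple with a
support count. `hetepath` implements the full inference chain used to rank
repurposed-drug candidates against a disease and its standard-of-care
therapy on such a graph: metapath enumeration, HeteSim relevance scoring
with a degree-weighted path-count correction, per-simulation ranking and
normalization, and a layered hub analysis with back- and cross-evaluation.

# The relevance model

## Metapaths

A *metapath* is a type-level template: an alternating sequence of semantic
types and (predicate, direction) steps, e.g.

```
PHSU-[AFFECTS>]-GNGM-[ASSOCIATED_WITH>]-DSYN
```

Predications are directed, but relevance is not: a drug can be the
grammatical subject or object of the assertions that link it to a disease.
Each step therefore records whether it traverses edges subject-to-object
(`>`) or object-to-subject (`<`). `enumerate_metapaths()` walks the
concrete graph backwards from the target node, so it returns exactly the
templates that have at least one concrete simple-path instance ending at
the target — never a merely type-compatible template with no instances.
Lengths are capped at 4 (default 3 for single simulations, 2 in the
pipeline presets): short metapaths dominate HeteSim semantics, and
enumeration cost grows geometrically with length.

## HeteSim

HeteSim is the canonical relevance measure on heterogeneous information
networks: split the metapath at its midpoint, push a uniform random walk
from the source forwards along the first half and from the target
backwards along the second half (each step's transition operator is the
row-normalized adjacency of that typed relation; the backward operators
are the row-normalized transposes), and score the pair by the cosine
similarity of the two midpoint reachability distributions. Odd-length
paths have no midpoint type, so every edge of the middle relation becomes
an instance point onto which both halves distribute. Scores are in
[0, 1]; a pair whose halves cannot meet scores 0 (totality is needed for
ranking), and a node is always perfectly self-relevant along any
palindromic path it instantiates.

Two implementations coexist deliberately. `hetesim_score()` (and its
vectorized form `hetesim_all_sources()`) uses sparse matrix products;
`hetesim_brute_force()` enumerates every walk explicitly, accumulating
midpoint mass walk by walk with no matrix algebra, and refuses inputs
beyond a configurable extension guard. The two must agree to 1e-9; the
test suite checks this on hundreds of seeded random graphs. The walk
(matrix) semantics, not simple-path semantics, defines the measure; the
path-counting utilities default to simple paths but expose `mode = "walk"`
so oracle comparisons are like-for-like.

Transition operators are unweighted by default — every aggregated
predication counts equally, regardless of how many sentences support it —
because the ranking treats all literature sources equally; support-count
weighting is available (`weighted = TRUE`) for sensitivity analyses.

## Degree-weighted path counts

Cosine similarity is scale-free: a promiscuous drug whose random walk
spreads over hundreds of neighbours is not penalized for its breadth, so
raw HeteSim rankings can be colonized by "popular" hub drugs. The
*degree-weighted path count* (DWPC) is the standard correction: every
concrete path instance contributes the product, over all its nodes
(endpoints included, so promiscuous sources penalize themselves), of
`degree^(-w)`. At `w = 0` it is exactly the path count; increasing `w`
increasingly discounts paths through high-degree nodes.

## Combining the two criteria in a simulation

A *simulation* ranks every node of the allowed source semantic types
against one or more targets. Per candidate, the package computes (i) the
mean HeteSim over the metapaths rooted at the candidate's own semantic
type (zero where no instance exists), averaged over targets, and (ii) the
aggregate DWPC over the same metapaths. With the correction enabled the
raw score is the **product of the two min-max-normalized criteria**:

```
raw = minmax(mean HeteSim) * minmax(aggregate DWPC)
```

The product (rather than a weighted sum) was a deliberate design choice.
Both criteria are proper relevance signals but each has a characteristic
failure: mean HeteSim rewards breadth, DWPC alone rewards sheer instance
count through quiet nodes. A sum lets a candidate compensate a near-zero
value on one criterion with a high value on the other, which in practice
left a dense mid-range of scores in which weakly-but-broadly connected
drugs cleared the downstream 0.2 threshold in nearly every hub
simulation. The product demands joint support — a candidate must look
relevant both by walk-profile similarity and by degree-corrected path
evidence — and it is monotone in each factor, so within a single
simulation it never reorders candidates relative to either criterion
alone. The pipeline presets use `w = 0.8`; smaller exponents
insufficiently separated designed high-degree decoys from specifically
wired candidates at desk scale. Raw scores are then min-max normalized
per simulation (the published convention for comparing nodes across
simulations), sorted descending, with ties broken lexicographically by
CUI for reproducibility. An all-equal score vector normalizes to all 1
rather than 0/0.

## Rank aggregation

`aggregate_ranks()` combines rankings over possibly different candidate
subsets (absent candidates are imputed rank `length + 1` so rankers are
commensurable). `mean_rank` is the transparent baseline and default;
`weighted_iterative` is an unsupervised scheme in the ULARA family:
starting from uniform ranker weights, the consensus is the weighted mean
of normalized ranks and each ranker's weight is reset to the inverse of
its mean squared deviation from the consensus, iterating to a 1e-6 fixed
point. Rankers that disagree with the emerging consensus are down-weighted
without any labelled relevance data. Consensus values are rounded to 12
digits before ordering so that exact ties break lexicographically
regardless of floating-point summation order. A simulation can rank by
aggregating its per-metapath rankings this way
(`aggregation = "rank_aggregation"`) instead of by mean HeteSim; both
compositions are recorded in the run manifest.

# The layered hub-analysis pipeline

`run_hub_pipeline()` chains the published discovery procedure:

1. **Preliminary simulations** rank drug-like sources (PHSU/CLND/TOPP)
   against the primary targets (the disease and its standard-of-care
   drug).
2. A **hub scan** ranks gene and disease sources (GNGM/DSYN) against the
   disease; `select_hubs()` keeps the top candidates with normalized
   score at or above 0.2 (the published threshold), at most 14 hubs (the
   published hub count), optionally capped per semantic type so neither
   genes nor diseases monopolize the layer.
3. **One simulation per hub** (`run_hub_layer()`), hub as target, over
   PHSU/AAPP/DSYN sources — "the hubs identified from one simulation
   become the targets for the next".
4. **Back-evaluation** checks in which hub simulations a designated
   candidate re-emerges above threshold; **cross-evaluation** tabulates
   every candidate passing in at least one hub simulation, with its
   recurrence and mean score, rendered as a candidate-by-hub matrix with
   columns in descending score order and sub-threshold cells empty.
5. The **final ranking** restricts to drug-like semantic types, excludes
   the pipeline's own targets, and sorts by total recurrence (preliminary
   plus hub layers) first and mean normalized score second — recurrence
   across independent searches is the primary published criterion, score
   the tie-breaker — with CUI as the final deterministic tie-break.

The whole pipeline is a pure function of `(graph, configuration)`:
re-running with identical inputs produces byte-identical triple files,
result tables and reports (manifests carry the only timestamps).

# The synthetic graph generator

No public fixture can stand in for a literature-scale predication
database, so `generate_kg()` builds a seeded synthetic stand-in with
planted ground truth; every synthetic CUI lives in the reserved
`C9xxxxxx` range. The default conditions are:

* **520 nodes** (PHSU 200, CLND 50, GNGM 100, AAPP 100, DSYN 40, TOPP
  30) and **2600 background predication draws** sampled under
  SemMedDB-like type-compatibility rules (TREATS goes drug-to-disease,
  ASSOCIATED_WITH gene-to-disease, and so on) with support counts mostly
  1.
* **Zipf-like endpoint popularity** with exponent 0.75, giving the
  right-skewed degree distribution of real predication graphs (the
  maximum degree is several times the median). Exponent 1.0 was rejected
  because at 520 nodes it makes a single background node adjacent to a
  large fraction of the whole graph, a pathology of small-n Zipf sampling
  rather than a feature of literature graphs.
* A designated **disease target** and **standard-of-care drug** joined by
  `TREATS`.
* **3 planted adjuvant drugs**, each with 6 concrete planted-family
  instances to the target across three families: `AFFECTS` edges to 4
  shared hub genes that carry parallel
  `ASSOCIATED_WITH`/`CAUSES`/`PREDISPOSES` predications to the target
  (the signature of heavily-studied disease genes), an `INTERACTS_WITH`
  edge to the standard drug, and a `TREATS` edge to a comorbid disease
  that `COEXISTS_WITH` the target.
* **5 popular decoy drugs** boosted to above the 95th degree percentile
  whose edges never touch the planted core — the explicit stress test
  for the DWPC correction: a raw path count would rank them highly; the
  pipeline must not.
* `planted_path_multiplicity = 0` is the negative control: nothing is
  planted, so nothing should be recovered.

What the generator does *not* emulate: extraction noise (mis-parsed
predications), polysemous concepts, semantic-type ambiguity, citation-age
effects, or the sheer scale of a real predication database. Passing the
recovery experiment therefore shows that the ranking machinery recovers a
planted relational signal against skewed-degree noise and adversarial
hubness at desk scale — not that it would reproduce any particular
full-scale published ranking.

`parameter_recovery()` is the acceptance surface: for consecutive seeds
it generates a graph, runs the two-layer pipeline with the disease and
standard drug as preliminary targets, and records the final-report ranks
of the planted drugs. Under the default conditions (20 runs), all three
planted drugs land in the top 10 in well over 90% of runs, no decoy ever
outranks all planted drugs, and the negative control recovers nothing.

# Numerical choices and degenerate inputs

* Row-stochastic operators are checked to 1e-12; matrix-vs-oracle
  agreement to 1e-9.
* Unreachable HeteSim pairs score 0 by convention (never `NaN`).
* Duplicate predications aggregate support counts; self-loops are dropped
  at load with a warning (midpoint distributions are ill-posed on loops).
* Serialization is lexicographic by `(subject, predicate, object)` so
  fixtures diff cleanly; every tie-break anywhere in the package is
  lexicographic by CUI.
* Empty hub selections, empty candidate sets and per-hub failures degrade
  gracefully (flagged, logged, other work proceeds).

# Problem sizes

The shipped tests and the acceptance script run the oracle comparison on
~200 random graphs of up to 50 nodes, the I/O round-trip on 100 random
graphs, and the recovery experiment on 20 seeded replicates of the
default 520-node configuration — sizes chosen so the whole validation
chain re-runs comfortably on a single CPU while still exercising every
code path at realistic density.

# Known limitations

* HeteSim here is exact; the approximate accelerations used by
  production literature-mining systems on million-node graphs are out of
  scope, and desk-scale graphs are the intended regime.
* The hub threshold (0.2) and hub cap (14) are published constants, not
  fitted quantities; on other graphs they are configuration, not truth.
* Aggregation across metapaths is an arithmetic mean per source semantic
  type; length- or family-weighted schemes are not implemented.
* The final report ranks candidates; it does not attach significance
  levels — the upstream procedure defines none.
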