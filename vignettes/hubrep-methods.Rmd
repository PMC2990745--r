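---
title: "Multi-level reproducibility of differential co-expression signature hubs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level reproducibility of differential co-expression signature hubs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubrep)
```

## The problem

Expression signatures for the same clinical endpoint — here, breast cancer
metastasis within five years of follow-up — tend to share almost no genes
when derived from different patient cohorts. One influential family of
network signatures consists of *signature hubs*: proteins with at least
`min_degree = 3` interaction partners in a protein–protein interaction
(PPI) network whose co-expression with those partners differs between the
metastatic and non-metastatic groups. Hub lists from different cohorts also
barely overlap, which invites the question this package is built to answer:
are the discordant lists really discordant, or do they point at the same
biology through different proteins?

hubrep quantifies agreement between two hub lists at four levels, each with
a matched randomization null:

* **protein level** — the PO score, the average of the directional overlap
  fractions;
* **topology level** — the POT score, which also credits hubs whose
  interaction neighbourhoods significantly coincide;
* **co-expression level** — the POT-e score, which additionally demands
  that correlation changes point the same way in both cohorts;
* **pathway level** — overlap of the pathway sets enriched in the hubs'
  neighbourhoods, against a degree-preserving rewiring null.

## Hub statistic and selection

For hub $h$ with partner set $P$ in an expression dataset split into groups
$A$ (metastatic) and $B$ (non-metastatic), the statistic is

$$ d(h) \;=\; \Bigl| \tfrac{1}{|P|}\textstyle\sum_{p \in P} r_A(h,p)
           \;-\; \tfrac{1}{|P|}\textstyle\sum_{p \in P} r_B(h,p) \Bigr|, $$

the absolute difference of the per-group *average* Pearson correlation
between the hub and its partners, bounded by 2. The per-group average (as
opposed to averaging per-edge absolute differences) follows the
hub-modularity construction this analysis descends from; the per-edge
variant measures edge-wise rewiring rather than a hub-level shift and is
deliberately not the default.

Significance comes from permuting the phenotype labels (group sizes
preserved) and recomputing $d(h)$; the reported p-value uses the add-one
convention $p = (1 + \#\{d_{\text{perm}} \ge d_{\text{obs}}\})/(n_{\text{perm}}+1)$,
so $p$ is never zero and the smallest attainable value is
$1/(n_{\text{perm}}+1)$. A practical corollary: the selection threshold
`alpha` must exceed that floor (with the default `alpha = 0.01` you need
`n_perm >= 100`; the package default is 1000). Hubs with $p < \alpha$ are
the signature hubs. **No multiple-testing correction is applied at this
stage** — wide, correlated expression changes in tumours sap the power of
FDR procedures here, and the downstream scores carry their own FDR control.

Two numerical details worth knowing:

* partners with zero within-group variance are skipped (with a message);
  a hub whose every partner is degenerate is left unscored with a warning;
* per-hub permutation seeds are streamed from the master seed in
  lexicographic hub order, so results are independent of traversal order.

## The reproducibility scores

Let the two lists have lengths $L_1, L_2$ and share $k$ hubs. Then
$PO_{12} = k/L_1$, $PO_{21} = k/L_2$, $PO = (PO_{12}+PO_{21})/2$.

For POT, every (hub$_1$, hub$_2$) pair across the two lists is tested for
neighbourhood coincidence: with $n$ and $m$ neighbours and $g$ shared, the
p-value is the hypergeometric upper tail $P(X \ge g)$ in a background of
$N$ proteins — those with both interaction and expression data.
Benjamini–Hochberg FDR control (threshold 0.05) is applied across all
$L_1 \times L_2$ tests of a list pair; a per-hub family is available via
the `fdr_scope` consideration but the global family is the default, since
the tests of one run are a single simultaneous inference. $T_{12}$ counts
list-1 hubs *outside* the exact overlap with at least one significant
partner in list 2 (symmetrically $T_{21}$); excluding the $k$ shared hubs
prevents double counting and keeps $POT_{12} = (k+T_{12})/L_1 \le 1$.
Neither PO nor POT is normalized for list length: the package's use case
is judging whether two *given* lists agree, not ranking list pairs of
different sizes.

POT-e adds the co-expression restriction. For a significant pair, each
shared neighbour $s$ gets a direction in each dataset:
$\mathrm{sign}\bigl(r_A(h,s) - r_B(h,s)\bigr)$, metastatic minus
non-metastatic; a zero difference counts as inconsistent. With $n$ usable
shared neighbours and $x$ consistent ones, the pair passes when the
binomial upper tail $P(X \ge x \mid n, p = 0.5)$ falls below `alpha_dir`
(default 0.05). The Bernoulli success probability 0.5 — "consistent by coin
flip" — is a parameter, not a fitted quantity. Note the discreteness: with
all neighbours consistent, $p = 2^{-n}$, so pairs with $n \le 4$ shared
neighbours can never pass at 0.05. This makes POT-e conservative on sparse
overlaps, which is faithful to the construction. Setting `alpha_dir = 1`
disables the restriction and recovers POT exactly (pairs whose direction
p-value is exactly 1 — e.g. no usable shared neighbour — are kept in that
limit, which is what "restriction disabled" should mean).

On every input $PO \le POT\text{-}e \le POT$.

## Null models

Three randomizations, each destroying one candidate explanation:

1. **Phenotype permutation** — labels reshuffled within each dataset, the
   *entire* selection pipeline re-run, the score recomputed. Kills disease
   relevance while keeping the correlation structure. The inner
   permutation count for hub selection is a parameter (`n_perm = 100` by
   default inside the null loop) because nesting the full 1000 makes the
   null quadratically expensive.
2. **Random lists** — protein lists of the same lengths drawn uniformly
   from the network (pool configurable to hubs-only), scored on the real
   network. Kills everything except topology.
3. **Rewired network** — degree-preserving double-edge-swap randomization
   (swap proposals creating self-loops or duplicate edges are rejected; 10
   attempts per edge by default), then degree-matched lists scored within
   the rewired network. Kills everything except the degree sequence.

Empirical p-values use the same add-one convention, so "no null sample
reached the observed score" reports $1/(n_{\text{rep}}+1)$, never 0. For
the pathway level, the rewiring null counts how many gold-standard
pathways a degree-matched random list recovers per replicate.

## What the synthetic generator emulates

`synthetic_scenario()` encodes the study conditions the package is
validated under:

* a preferential-attachment background interactome (seed clique plus $m=3$
  distinct attachments per node, so every node is hub-eligible and degrees
  are heavy-tailed);
* `n_planted = 10` hub *pairs* appended as new nodes of degree 6 whose
  partner sets overlap by `shared_neighbourhood_fraction = 0.8` — this
  knob directly sets the expected topology-level agreement between the two
  cohorts' planted lists;
* two cohorts of 35 metastatic / 60 non-metastatic samples — the
  imbalanced case/control split typical of metastasis follow-up cohorts,
  scaled to desk size — with planted within-group correlations
  `rho_met = +0.8`, `rho_non = -0.8`. Partners are generated as
  $\rho \cdot \text{hub} + \sqrt{1-\rho^2}\,\varepsilon$, which makes the
  population within-group correlation exactly $\rho$ and the expected hub
  statistic $|\rho_A - \rho_B| = 1.6$;
* dataset 1 carries the signal at the A-hubs, dataset 2 at the B-hubs, so
  hub identities are disjoint while neighbourhoods coincide — low PO, high
  POT by construction. The `scramble_directions` switch flips the group
  correlations in dataset 2 only, a negative control that collapses POT-e
  toward PO while leaving POT untouched.

One behaviour of the generator deserves emphasis: a planted hub's partners
are *themselves* genuinely differentially co-expressed, through their
single edge back to the hub (the statistic is symmetric in the edge).
Their effect is diluted by their remaining, unperturbed neighbours, but at
the default effect size many partners pass the permutation test
legitimately. Recovered lists are therefore larger than the planted lists
and include shared partners, so the full-pipeline PO between recovered
lists is well above zero even when planted hub identities are disjoint.
The pure "PO = 0, POT = 1" configuration is a property of the planted
*lists* at `shared_neighbourhood_fraction = 1`, and that is how it is
asserted in the test suite; on recovered lists the verified property is
the ordering PO < POT.

What the generator does **not** emulate: microarray probe effects, batch
structure, non-Gaussian marginals, correlated noise between non-planted
genes, incomplete and false-positive interaction data, or survival-time
censoring. Passing tests on these fixtures demonstrate that the
statistics, the selection procedure and the nulls behave as designed —
not that any particular biological cohort will reproduce at a given score.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in minutes on one core: networks of 100–200
background nodes, cohorts of up to 100 samples per group, 200–500
permutations per hub, and 100 null replicates. Null means and calibration
fractions at these sizes are stable to a few percentage points across
seeds, which is the resolution at which the package asserts them. Every
randomized stage takes an explicit seed; pipeline stages consume named
sub-seeds derived from one master seed, and a rerun of
`run_full_pipeline()` with the same inputs and seed is byte-identical,
including the JSON report.

## Degenerate inputs and edge policies

* Expression groups below 3 samples are rejected at construction —
  correlation is degenerate there.
* Duplicate gene rows are collapsed by maximal variance at read time.
* Edge lists are deduplicated as unordered pairs; self-loops are dropped
  with a logged count.
* Hub pairs sharing zero measured neighbours receive a direction p-value
  of 1 rather than being dropped.
* A rewiring proposal that cannot legally fire (e.g. a triangle) returns a
  degree-identical copy.
* `restrict_to_measured()` is idempotent; an empty intersection with the
  measured genes is an error, not an empty network.

## Known limitations

* The hypergeometric PO-significance test needs a background size $N$
  that is genuinely ambiguous (all hubs? all proteins with data?); the
  package exposes it as a parameter and provides no default claim.
* The pathway-level background for special-gene over-representation is
  likewise configurable and defaults, loudly, to the PPI-and-expression
  universe.
* POT-e's binomial test is two-valued on tiny overlaps (see above); scores
  on lists whose pairs share fewer than five neighbours are effectively
  POT with extra variance.
* The phenotype-permutation null re-runs hub selection with a reduced
  inner permutation count by default; for publication-grade p-values raise
  `n_perm` inside the null to the full 1000 and budget accordingly.
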