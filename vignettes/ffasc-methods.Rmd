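---
title: "Screening proteomes for free-fatty-acid production potential: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening proteomes for free-fatty-acid production potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffasc)
```

## The screening model

`ffasc` estimates, from a predicted proteome alone, how promising a
cyanobacterial strain is as a chassis for free-fatty-acid (FFA)
production. The model rests on three assumptions worth stating plainly:

1. **Orthology implies equivalent effect.** Proteins grouped into one
   orthologous group (OG) are assumed to affect FFA production the same
   way. Each OG is a single criterion.
2. **Copy number matters.** The criterion value is built from hitN, the
   number of filtered homology hits of the OG's members against the
   proteome, not mere presence/absence. Two thioesterase homologs are
   treated as better than one. Deliberately, scores are *not* normalized
   for genome size: the target quantity is the organism's natural
   capacity, and a larger genome with more favorable copies genuinely has
   more of it.
3. **Effects are additive.** A strain's score is a weighted sum of its
   criteria; interactions between OGs are not modeled.

The quantification rules encode the asymmetry between categories. An nOG
contributes $-\mathrm{hitN}$: every extra copy of, say, a cyanophycin
synthetase is a liability. A pOG contributes $+\mathrm{hitN}$ when
present, but a flat $-1$ when absent — absence of an enhancer is penalized
once, regardless of how many other enhancers exist. An rOG contributes
$+\mathrm{hitN}$ with no absence penalty; missing pathway core shows up
simply as forgone positive score. The pOG rule is discontinuous by
design: moving from one hit to none changes the criterion from $+1$ to
$-1$, a drop of $2 w_j$ in the weighted score.

## Filters on homology evidence

Raw BLASTp hits are noisy. Two filters are applied, in either order (the
result is the same):

* **E-value** $\le 10^{-4}$. The boundary is inclusive — a hit at exactly
  the threshold is kept, matching common BLAST practice.
* **Domain completeness.** A homolog is accepted only if the set of
  trusted-cutoff Pfam domains annotated on it contains *every* domain
  required for the query protein. A homolog carrying one of two required
  domains is discarded. Catalog members with no stated domain
  requirements bypass this filter (the shipped catalog distributes 81
  domain families unevenly over 64 proteins, so this case is legal and
  common).

hitN counts **distinct (query, target) pairs**: multiple HSPs between one
query and one target collapse to a single hit. The alternative unit —
distinct target proteins per OG, where two members hitting the same
target count once — is exposed as `build_hit_matrix(count_unit =
"targets")`, since homology-search conventions differ on this point.

## The shipped catalog

`default_catalog()` carries the 49 OGs (13 nOG, 24 pOG, 12 rOG) with
KEGG Orthology and eggNOG identifiers, one action label each (present /
overexpression / insert / knockout / knockdown / underexpression,
recording the engineering evidence class), and 64 member proteins. The
primary member token per OG comes from the curated feature names; the 15
additional members are alias/paralog tokens reconstructed from alternate
gene names and are flagged as such in the file header. Domain
requirements ship empty: the exact Pfam families required per member
depend on the user's Pfam release and are meant to be supplied alongside
the annotation run (`hmmsearch --domtblout --cut_tc`). Until they are,
the domain filter is vacuous and the screen reduces to e-value-filtered
hit counting — a deliberate, conservative default rather than a guess at
the original domain assignments.

## Weight optimization

With no quantitative production data to regress on, weights are anchored
to a single contrast: a strain experimentally known to be a good producer
(positive reference) versus a known poor one (negative reference). The
objective

$$\max_w \; w^\top |x_1 - x_2| \; + \; p \cdot \mathit{rank}
\qquad 0.001 \le w_j \le 1, \;\; \textstyle\sum_j w_j = 12, \;\;
w^\top |x_1 - x_2| > 0.001$$

maximizes the score separation of the references, with the rank gap
(rank of negative minus rank of positive, over *all* screened species)
rewarded at rate $p = 0.010241$. The box bounds keep every criterion
alive (no weight can vanish entirely); the fixed sum pins the overall
scale so that separation cannot be inflated by growing all weights.

The optimizer is a generalized pattern search, written here from first
principles with the following concrete semantics:

* **Feasibility by projection.** Every poll point is projected onto the
  intersection of the box and the sum hyperplane — the exact Euclidean
  projection, computed by bisection on the clip-shift multiplier. All
  evaluated points are feasible, and bound-attaining solutions (e.g.
  $w_j = 1$) are representable exactly.
* **Complete polling with sufficient decrease.** All $2m$ coordinate
  directions scaled by the mesh are evaluated and the best candidate is
  accepted if it improves the objective by more than a relative margin
  of $10^{-12}$. Greedy first-improvement acceptance was tried and
  rejected: because the projection couples all coordinates, polling an
  *irrelevant* coordinate still perturbs the relevant ones by
  $O(\Delta/m)$ and can yield a positive but negligible gain, so a
  first-improvement rule spends its entire iteration budget on
  $10^{-13}$-sized steps and never reaches the separating coordinate.
* **Mesh control.** Expansion 2 on success, contraction 0.5 on failure,
  initial mesh 0.25, and a ceiling equal to the box width: steps larger
  than the box are clipped by projection anyway, and letting the mesh
  double unboundedly destroys the floating-point precision of the
  projection (at mesh $\sim 2^{100}$ the bisection can no longer resolve
  the hyperplane). Termination at mesh $< 10^{-6}$ or 2000 iterations.
* **Strict separation constraint** enforced by candidate rejection; a
  degenerate problem ($x_1 = x_2$) bypasses it so a flat landscape
  terminates cleanly rather than erroring.
* The optimization runs on **quantified criteria rows**, not raw hit
  counts: the absence penalty and sign conventions are part of the
  scoring semantics being tuned.

The search is deterministic — no random state is consumed — so identical
inputs give identical weights.

## Cluster-based validation

Ranking quality is supported indirectly by asking whether the criteria
space has structure that separates producers from non-producers without
any ranking at all.

* `kmeans_cluster()` is best-of-25-restarts Lloyd's algorithm (squared
  Euclidean, via `stats::kmeans`), deterministic given the seed; raw
  criteria values are used, with no extra scaling.
* `average_silhouette()` and `calinski_harabasz()` are implemented
  directly because their degenerate-case conventions are pinned down
  here: singleton clusters contribute silhouette 0, the all-identical
  0/0 case is 0, and a zero within-cluster sum of squares yields the
  infinite-separation sentinel `Inf`. The test suite cross-checks the
  silhouette against `cluster::silhouette` on regular partitions.
* `select_natural_k()` encodes the outgroup heuristic: taxonomically
  alien species (diatoms among cyanobacteria) act as planted outliers.
  Scanning $k$, each partition is labeled `mixed` (outgroup shares a
  cluster with in-group species), `exclusive_together` (outgroup alone,
  in one cluster) or `split` (outgroup alone but divided). The natural
  range runs from the first `exclusive_together` through the first
  subsequent `split` (inclusive); within it, the highest average
  silhouette picks $k$, with the CH index reported as corroboration.

For heatmap display, the criteria matrix is perturbed by
$(\mathrm{unif}(-0.5, 0.5)) \cdot 10^{-10}$ — read as uniform noise scaled
to at most $5 \cdot 10^{-11}$, small enough to never alter any displayed
value yet sufficient to break exact ties that make rank-correlation
matrices singular — then z-scored by rows and columns, and both axes are
ordered by average-linkage clustering under the $1 - \rho_{Spearman}$
distance. Constant rows or columns have undefined rank correlation; their
distance falls back to the maximum (2) with a warning.

## Annotation comparison

`compare_annotations()` reconciles two binary presence/absence matrices
by label, subtracts the second from the first and classes each OG as
`identical`, `a_only` (all disagreements are presence in the first
matrix), `b_only`, or `mixed`. The sign convention is the mathematically
consistent one: positive differences mean present in the first matrix
only. `mixed` is reported as its own class rather than folded into
either side; a three-way account would silently misattribute OGs that
disagree in both directions across strains.

## The synthetic-fixture generator

All tests run offline on fixtures with known ground truth, generated by
code:

* **Hit counts** are Poisson with per-category means nOG 0.5, pOG 1.5,
  rOG 1.0 — chosen so that the pOG absence-penalty branch (hitN = 0) and
  multi-hit counting are both exercised routinely in a matrix of
  realistic sparsity.
* **Payloads** are syntactically valid BLAST outfmt-6 and HMMER
  domtblout text; about 15% of planted pairs get a second HSP line to
  exercise pair collapsing. **Decoys** are injected so that each fails
  exactly one filter: e-value decoys (e-value in $(10^{-4}, 0.3)$, fully
  domain-annotated) and domain decoys (passing e-value, one required
  domain withheld). The decoy log records which filter must remove each.
* **Reference pairs** plant an exact criteria difference between the
  designated positive and negative strains, with background strains
  scattered around their midpoint (sd 0.5).
* **Clustered layouts** mirror the 125-cyanobacteria + 3-diatom setting:
  five spherical Gaussian blobs (sd 1) with centers pairwise `separation`
  = 6 apart in 8 dimensions, and an outgroup centered one separation away
  with internal spread 2 — wider than a blob, mimicking outgroup members
  that are mutually distinct yet far closer to each other than to the
  in-group. These values were fixed once, by the following reasoning: the
  outgroup must be absorbed into in-group clusters at small $k$ (its
  isolation saves less variance than separating the big blobs), isolate
  exactly when the blobs are all separated ($k$ = blobs + 1), and split
  only later (its internal spread must cost less than splitting a
  25-point blob until the blob structure is exhausted). The scan on this
  layout reproduces the mixed → together → split sequence and selects
  $k = 6$.

What passing tests on these fixtures do **not** show: robustness to the
correlated, phylogenetically structured hit patterns of real proteomes,
to annotation pipelines that disagree with the catalog's member set, or
to reference strains whose criteria differ in many weakly informative
coordinates. The optimizer anchored to one reference pair is known to
produce skewed weights; with more experimentally characterized producers
the single contrast should be replaced by a multi-pair objective.

## Problem sizes and numerical choices

The test and acceptance runs use deliberately desk-scale instances: 6–10
OG catalogs with 4–8 species for round-trip checks (100 seeds), the full
49-criterion geometry for optimizer recovery, and 128-row matrices for
the cluster scan — matching the scale of the original 125-strain screen
while keeping any single run to seconds. Scores are reported to six
decimals in output files. Weight-vector feasibility is asserted at
$10^{-9}$ on the sum; the projection itself is accurate to machine
precision away from pathological inputs. Ties in ranking are broken by
ascending species id, making every reported ranking reproducible
byte-for-byte.
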