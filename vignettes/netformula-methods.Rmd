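---
title: "Methods and design of netformula"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of netformula}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netformula)
```

This vignette is the package's own account of the statistical models it
implements, the parameters that matter, the design decisions taken where
the methodology left room, and the limits of what the synthetic
validation can show.

## Drug-likeness screening

Each compound is described by eight descriptors: molecular weight (Da),
ALOGP, hydrogen-bond acceptors and donors, polar surface area (Å²),
rotatable bonds, aromatic rings and structural alerts. The quantitative
estimate of drug-likeness maps each descriptor through an asymmetric
double sigmoid desirability function $d_i$ (the published parameter sets
for the eight descriptors) and combines them as a weighted geometric
mean:

$$\mathrm{QED} = \exp\!\left(\frac{\sum_i w_i \ln d_i(x_i)}{\sum_i w_i}\right)$$

Design choices:

* **Weight scheme.** The mean-weight scheme is the default (`qed_weights()`),
  the variant most commonly reported alongside the descriptor-level
  parameters. Weights are user-replaceable.
* **Desirability floor.** Desirabilities are floored at $10^{-6}$ before
  the logarithm, so extreme descriptors degrade the score smoothly
  instead of collapsing it to $-\infty$.
* **Pass thresholds.** `screen_compounds()` passes a compound when
  `qed >= qed_min` (default 0.3, a conventional weak drug-likeness
  floor; platforms typically expose this as a user slider), Lipinski
  violations ≤ 1 and Veber violations ≤ 1 — the usual "no more than one
  violation" reading of both rules. All four Lipinski boundaries
  (HBD ≤ 5, HBA ≤ 10, MW ≤ 500, logP ≤ 5) are inclusive. The second
  Veber criterion is a disjunction — it is violated only when *both*
  PSA > 140 *and* HBD + HBA > 12.

Descriptors are taken from the input table as data; no structure parsing
or descriptor prediction is attempted.

## Formula–target identification

Let $n$ be the number of active formula compounds (typically the
drug-likeness pass-set) and, for each target $t$, let $k_t$ be the
number of active compounds linked to $t$ after score filtering. Links
carry a 0–1000 association confidence; the default cutoff is 400 (the
conventional medium-confidence midpoint of that scale) and the sentinel
9999 marks curated links without a score, which pass any cutoff.

The background probability $p_t$ is the fraction of distinct compounds
in the *score-filtered* association table that link to $t$. This
construction — compounds as Bernoulli trials against a table-wide
background — is the natural completion of the binomial model, which the
surrounding literature states without fixing $p$'s estimator. Under the
null, $k_t \sim \mathrm{Binomial}(n, p_t)$ and the evidence for $t$ is
the tail $P(X \ge k_t)$, computed through the survival function
(`stats::pbinom(k - 1, n, p, lower.tail = FALSE)`) rather than by
summing densities.

Significant targets ($P < P_{sig}$, default 0.05) are ranked ascending
by p-value and scored

$$\mathrm{geneScore}_t = \begin{cases}
  -\log P(X \ge k_t) \,/\, \mathrm{Rank}_t & P(X \ge k_t) < P_{sig} \\
  0 & \text{otherwise,}
\end{cases}$$

so the rank denominator attenuates all but the sharpest signals — a
deliberate alternative to multiple-testing correction, which is
therefore *not* applied on top. Each compound's chemScore is the
arithmetic mean of the geneScores of the profiled targets it hits.

Decisions taken on unstated details:

* **Logarithm base** is 10 (configurable to natural log); the score
  formula is conventionally printed without a base.
* **Ranking** is ordinal with deterministic tie-breaks: equal p-values
  order by larger $k$, then target id. Competition ranking would only
  differ on exact p-value ties, which are rare off the lattice.
* **chemScore averages over all profiled targets** of the compound,
  zeros included; compounds hitting no profiled target score 0 instead
  of being dropped, keeping the score total on the active set.
* **Degenerate backgrounds.** $p_t = 0$ with $k_t \ge 1$ is impossible
  under the null; such targets are reported with the smallest positive
  normal double as p-value and flagged (`degenerate`), never silently
  dropped.

## Enrichment and co-association curves

Enrichment of a query gene list against a gene-set collection uses the
hypergeometric upper tail with the universe defaulting to the union of
all set members. Two consequential conventions:

* The query is intersected with the universe first; dropped genes are
  reported, and $n$ counts only in-universe genes.
* Only terms overlapping the query ($k \ge 1$) are tested, and the
  Benjamini–Hochberg adjustment runs over exactly those tested terms.
  This matters: the BH multiplier $m$ counts tested terms, so adjusted
  values differ from a convention that tests empty overlaps too.

The shared-term co-association curve compares two ranked enrichment
results. With both lists sorted by p-value (ties by term id, making the
curve deterministic), $C(n)$ is the size of the intersection of the two
top-$n$ term lists, evaluated to depth $N$ (default 30, truncated to
the shorter list). Two summaries are reported:

* `similarity` $= C(N)/N \in [0,1]$ — the top-$N$ overlap fraction;
* `auc` $= \frac{1}{N}\sum_{n=1}^{N} C(n)$ — the mean shared count,
  deliberately *unnormalized*, so it ranges up to $N$.

The two scales coexist on purpose: co-association practice reports both
a bounded similarity and a curve area that can exceed 1, and emitting
the raw $C(n)$ vector alongside lets any alternative normalization be
computed downstream.

## Network proximity

Both proximity scores operate on a simple undirected PPI graph
(self-loops and duplicate edges removed at load time; gene ids absent
from the graph are dropped with a warning, never imputed).

**KATZ score.** Path counts are *walk* counts — entries of adjacency
matrix powers summed over cross-set pairs — the only construction that
the geometric $\beta^l$ weighting matches. The total is

$$\mathrm{total} = |A \cap B| + \sum_{l=1}^{3} \beta^{l}\,\mathrm{path}_l,
\qquad \beta = 0.001,$$

with the overlap entering at weight 1 ($\beta^0$): the overlap is listed
as a separate score item by convention and no other combination rule is
stated, so the natural $l = 0$ term is used.

**Closest distance.** The symmetric average-closest form from the
proximity literature:
$d(A,B) = \big(\sum_{a} \min_b d(a,b) + \sum_{b} \min_a d(a,b)\big)/(|A|+|B|)$
over unweighted shortest paths. Nodes with no finite distance to the
other set are excluded from numerator and denominator with their count
reported; if nothing is finite the sets are in different components and
an error is raised.

**Permutation nulls.** Null set pairs are drawn uniformly from the
node set (without replacement within a set), sizes matched to the
observed sets. Degree-matched sampling is intentionally not the default:
uniform draws keep the null simple, deterministic and exactly
exchangeable with uniformly drawn query sets, which is what the
calibration tests verify. P-values use the add-one estimator
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{perm})$ (≤ for the
distance test, which is one-sided toward closer-than-random), so no
p-value can be zero and the minimum attainable is $1/(n_{perm}+1)$.
The null median and mean are both reported, covering either reading of a
"random score" summary. A degenerate null (zero standard deviation)
yields `z = NA` while the empirical p-value remains valid.

**Seed subnetworks.** Without expansion, the induced subgraph on the
seeds (isolated seeds retained). With expansion, non-seed *connector*
nodes adjacent to at least two seeds are added before inducing. The
two-seed rule is the documented default for an otherwise unspecified
expansion step: one-seed neighbours would balloon the subnetwork with
degree-1 attachments, while two seed contacts make a node a genuine
bridge.

## Core-formula mining

Prescriptions are (patient, visit, herb-set) records. The herb network
has an edge for every herb pair that co-occurs, weighted by the number
of prescriptions containing both. Because clique enumeration needs an
unweighted graph, the network is binarized at a threshold (edges at or
above it survive; isolated nodes drop) and maximal cliques of the result
are the candidate core formulas, enumerated by an in-package
Bron–Kerbosch recursion with pivoting (the candidate with most
neighbours among the remaining candidates), canonically ordered.

Formula quality is measured against the prescriptions:

* **confidence** of formula $F$ in prescription $R$:
  $|F \cap R| / |F|$;
* **support** $S_\alpha$: fraction of prescriptions with confidence
  $\ge \alpha$ (default $\alpha = 0.9$, i.e. essentially intact);
* **average confidence** $\bar\alpha$: mean confidence over *all*
  prescriptions. Averaging over supporting prescriptions only is a
  defensible alternative; the all-prescription mean is used because it
  is monotone in containment and independent of the $\alpha$ cutoff.

These follow the support/confidence reading of frequent-itemset mining,
since the methodology's own definition is published elsewhere; the
definitions above are the package's documented contract.

**Adaptive binarization.** Candidate thresholds are the distinct edge
weights, scanned descending. At each, qualifying formulas are the
maximal cliques meeting the size constraint (`min_herbs`, or exactly
`desired_herbs` under `enforce_size`) with $S_\alpha \ge s_{min}$. The
chosen threshold maximizes the count of qualifying formulas, ties
resolved toward the larger threshold (the sparser, higher-evidence
network). The per-threshold counts are always returned, so an empty
result is a diagnosis, not an exception. When `enforce_size` finds
nothing, the strict reading stands unless `fallback = TRUE` relaxes to
`min_herbs` filtering.

**Merging.** Similarity between formulas is the Jaccard index of their
herb sets (the measure is otherwise unnamed; Jaccard is symmetric,
scale-free and standard). *Together* merges each connected component of
the similarity-≥-threshold graph in one pass; *Step* repeatedly merges
the single most similar qualifying pair (ties: lexicographically
smallest union) and re-evaluates, which can stop earlier than
*Together*. All metrics are recomputed on the dataset after merging;
merging is idempotent.

**Person-based statistics** credit each patient with their best visit:
the maximum confidence over that patient's prescriptions, with
person-support the fraction of patients reaching $\alpha$.

## Synthetic data: what it does and does not emulate

The generators (`fixture_spec()`, `gen_*()`) produce every input shape
the package consumes, with plantable signal:

* prescriptions with a core formula included intact at a set presence
  rate (default: 500 prescriptions, 250 patients, a 5-herb formula at
  rate 0.6, prescriptions of 8–15 herbs), noise herbs drawn from a
  disjoint pool;
* a compound–target table (default: 500 compounds at link density 0.02,
  scores uniform on 150–999) whose planted target links to the 50
  formula compounds at tenfold density with scores ≥ 400;
* gene-set collections with one planted term overrepresented in the
  emitted query;
* preferential-attachment networks standing in for PPI data.

At enrichment factor 1 the planted entities are generated exactly like
background, giving exchangeable null fixtures for calibration. All
generators are pure functions of their spec under R's Mersenne–Twister
RNG; seeded regression values in the tests (e.g. the edge count of a
generated network) are stable across platforms for that RNG.

What passing tests on these fixtures shows: the algorithms recover
planted signal at realistic effect sizes, their null distributions are
calibrated, and every reader/writer round-trips. What it does not show:
robustness to the marginal distributions of real databases (compound
score distributions, herb-name synonymy across sources, degree
distributions of curated PPI networks, annotation bias in gene-set
collections). In particular, herb-name normalization is deliberately
minimal — whitespace trimming and space-collapsing only — because
synonym resolution is data, not method.

## Numerical conventions and degenerate inputs

* All orderings that reach output files carry explicit tie-breaks
  (p-value, then larger $k$, then identifier; clique size, then member
  list), so identical inputs and seeds give byte-identical outputs.
* Duplicate scored links keep the maximum score — conservative toward
  retaining associations.
* Empty pass-sets, empty enrichment tables and empty mining results are
  valid, reported outcomes; errors are reserved for inputs that make a
  computation undefined (empty files, sets fully outside a network, no
  finite cross-set distance, thresholds that erase the data).
* Validation problem sizes: exhaustive oracles run at $n \le 12$
  (binomial outcomes, hypergeometric draws, clique subsets), network
  oracles at $\le 20$ nodes, calibration at 200 replicates × 1000
  permutations on a 500-node network, and recovery at 20–100 seeded
  replicates — sizes chosen to make the checks exact or statistically
  decisive while keeping the default suite comfortably runnable on one
  CPU.

## Known limitations

* The binomial background $p_t$ is estimated from the same table that
  supplies the observations; very small tables make $p_t$ noisy and the
  profile anti-conservative. A curated external background can be passed
  explicitly to `profile_formula()`.
* KATZ walk counting double-counts backtracking walks by construction;
  it is a relevance index, not a path census.
* The co-association AUC depends on the enrichment tie-breaking order
  exactly at ties; term-id tie-breaks make it reproducible but, like any
  convention, arbitrary at exact ties.
* Clique enumeration is exponential in the worst case; prescription
  herb networks are small and sparse after binarization in practice,
  and the adaptive scan starts from the sparsest (highest) thresholds.
* No ontology-aware propagation: gene-set inputs are flat GMT
  memberships.
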