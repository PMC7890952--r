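---
title: "Methods: building and analysing ceRNA networks with cernanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and analysing ceRNA networks with cernanet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernanet)
```

## The biological problem

Competing endogenous RNAs (ceRNAs) are transcripts — mRNAs, lncRNAs,
pseudogenes — that regulate one another indirectly by competing for a
shared pool of microRNAs. Two transcripts carrying response elements for
the same miRNAs act as mutual "sponges": when one is highly expressed it
titrates the shared miRNAs away from the other. A ceRNA *network* makes
this crosstalk explicit: nodes are candidate ceRNAs, and an edge asserts
that a pair (i) shares more targeting miRNAs than chance predicts and
(ii) is co-expressed in a way consistent with miRNA-mediated coupling.

`cernanet` builds such networks from four plain-text inputs — a
candidate-ceRNA expression matrix, a miRNA expression matrix, a
miRNA–target interaction table, and a gene annotation table — and then
analyses them (topology, modules, over-representation, survival). It is a
batch, scriptable pipeline: every interactive choice a GUI would offer is
a declarative config key, and every run writes a manifest with input
checksums and the seed, so results are reproducible.

## Symbol harmonization

Analysis is gated on three symbol sets: valid ceRNAs (present in the
ceRNA expression matrix, among interaction targets, and annotated), valid
miRNAs (present in the miRNA expression matrix and among interaction
miRNAs), and valid samples (shared by both matrices). Matching is exact,
case-sensitive string equality — the inputs are required to use one
naming standard, and silent aliasing would be worse than an honest empty
intersection, which is a hard error naming the offending set. Interaction
rows that reference symbols outside these sets are dropped with a
reported count.

## Quality filtering

Filtering operates on the *raw* (pre-transformation) values and precedes
any transform; this matches the usual single-cell workflow in which
FPKM-like values are filtered and then log-transformed.

* **Samples.** For each matrix, the *detected-RNA ratio* of a sample is
  the fraction of genes strictly above a detection threshold. Samples may
  be removed either by a minimum-ratio rule or by dropping the *k*
  lowest-ratio samples per matrix; a sample survives only if it survives
  in both matrices, so both matrices always end with the identical sample
  set.
* **Genes.** Candidate ceRNAs are first grouped by an annotation
  attribute (canonically: biotype `protein_coding` → `Coding`, everything
  else → `Noncoding`, because absolute expression levels differ so much
  between types that one threshold cannot serve both). A gene is retained
  iff its *expressing-sample ratio* at its group's minimal expression
  level is **strictly greater** than the group's fraction cutoff — the
  "expression value > 1 in > 80% of cells" style of rule, applied with
  strict inequalities at both levels, so a gene sitting exactly on a
  boundary is removed. The miRNA matrix is filtered with the same
  mechanism as a single group.

Transforms come last, in a fixed order: log first
(`log_b(x + pseudocount)`), normalization second (row-wise min–max or
z-score; z-scores use the sample standard deviation, denominator
N−1).

## The five pair measures

For a candidate pair \(R_1, R_2\) with expression vectors \(e_{R_1},
e_{R_2}\) over \(N\) samples:

**MS — shared-miRNA enrichment significance.** With \(Q\) considered
miRNAs, \(T_1\) and \(T_2\) targeting each gene and \(t\) shared,

\[ MS = 1 - \sum_{i=0}^{t-1}
   \frac{\binom{T_1}{i}\binom{Q-T_1}{T_2-i}}{\binom{Q}{T_2}}
   \;=\; P(X \ge t), \quad X \sim \mathrm{Hypergeom}(Q, T_1, T_2). \]

Small MS = more sharing than chance. \(t = 0\) gives exactly 1 (the empty
sum). The universe \(Q\) is the set of valid miRNAs that survive
preprocessing *and* appear in the interaction table — the miRNAs the
pipeline actually considers. The tail is evaluated with the
hypergeometric survival function rather than naive summation, which is
numerically safe for large counts. MS is thresholded raw by default (the
reference workflow cuts raw MS at 0.05); `adjust_measure()` adds a
Benjamini–Hochberg-adjusted column for users who prefer a corrected
cutoff.

**PCC.** The Pearson product-moment correlation; linear co-expression.

**MI / CMI.** Plug-in (conditional) mutual information on discretized
expression, natural log, \(0\log 0 \equiv 0\):

\[ MI = \sum_{r_1,r_2} p(r_1,r_2)\log\frac{p(r_1,r_2)}{p(r_1)p(r_2)},
\qquad
CMI = \sum_{r_1,r_2,z} p(r_1,r_2,z)
  \log\frac{p(z)\,p(r_1,r_2,z)}{p(r_1,z)\,p(r_2,z)}. \]

The conditioning variable \(z\) is the discretized per-sample **sum** of
the pair's shared miRNAs' expression. All three variables use the same
discretization scheme (the scheme is not separately specified for the
conditioner, and there is no principled reason to treat it differently).

**LA — liquid association.** How the shared-miRNA level modulates the
pair's co-expression:

\[ LA = \frac{1}{N}\sum_{i=1}^{N} z_i(e_{R_1})\, z_i(e_{R_2})\,
   norm_i(e_{R_{mi}}), \]

with \(z\) the per-gene z-score and \(norm\) the Van der Waerden normal
scores \(\Phi^{-1}(r_i/(N+1))\) of the summed shared-miRNA expression.
Positive LA: the pair co-varies more when the shared miRNAs are high.

### Numerical choices

* **Discretization** (for MI/CMI): equal-frequency bins by default, with
  \(k = \max(2, \lfloor\sqrt{N}\rfloor)\) bins — robust to the heavy
  right skew of expression data; equal-width is available. Ties share the
  average rank, hence the same bin. The binning is not part of the
  measure definitions, so both method and \(k\) are configurable.
* **Logarithm base** for MI/CMI: natural log (nats). Base only rescales
  values and thresholds uniformly.
* **LA z-scores** use the sample sd (N−1), the same convention as the
  z-score normalization transform, while the outer average divides by
  \(N\) exactly as the definition states. The definition fixes the
  \(1/N\) but not the z denominator; consistency across the package won.
* **VdW ties**: average ranks, which keeps scores symmetric under
  permutation of tied entries. A constant modulator has all scores
  \(\Phi^{-1}(1/2)=0\) and hence LA exactly 0.
* **Pairs sharing no miRNA** (\(t=0\)): MS is exactly 1; CMI and LA are
  reported as missing (there is no modulator to condition on); PCC and MI
  remain computable. Pairs are canonical unordered with
  `gene1 < gene2`.
* **Constant expression vectors** make PCC and LA undefined; both return
  `NA` with a warning rather than a fabricated value.

## Network construction

Candidate pairs are enumerated per selected group pair (within-group
pairs use the group label twice) in deterministic lexicographic order.
Measures are computed per pair — a pure computation, so the table is
byte-identical for any parallel worker count. Thresholds are directional
and **strict** (`MS < 0.05`, `PCC > 0.48`-style; ties excluded), may be
scoped to one group-pair label or `"all"`, and a pair becomes an edge
only if it passes *every* matching threshold; a missing value for any
thresholded measure fails. Genes that gain no edge remain in the graph as
isolated nodes; edges carry the measure values and the shared-miRNA
symbols. The network summary counts connected nodes, isolated nodes,
edges, and connected components *among connected nodes* — an isolated
node is not a singleton component, matching the way network reports
separate the two notions.

## Topology and modules

Degree, shortest-path betweenness (reported unnormalized and normalized
by \((n-1)(n-2)/2\), since no convention is universal), local clustering
coefficient (0 for degree < 2), closeness, and edge betweenness — all
unweighted and undirected. ceRNA networks are routinely disconnected, so
closeness needs a convention: the default is within-component closeness
\((|C|-1)/\sum_{u\in C} d(v,u)\); a harmonic variant (mean inverse
distance over all other nodes) is available by flag.

Module detection is Louvain (resolution parameter exposed; randomness
pinned by a seed and a canonical sorted node order). MCL, MCODE and EPCA
are registered names that raise "not implemented": their algorithms are
defined in their own papers, and re-implementing them was out of scope
behind the pluggable interface. Modularity is the Newman–Girvan
\(Q = \sum_c [e_c/m - (d_c/2m)^2]\), implemented in-package and checked
against a brute-force edge-counting oracle. The module report gives
per-module size, internal edge count, density \(e_c/\binom{s_c}{2}\)
(defined as 0 for singletons, avoiding 0/0), and the module-associated
miRNAs — the union of the shared-miRNA sets over the module's internal
edges. "Average density" is the unweighted mean over modules (weighting
by size is an equally defensible choice; unweighted is documented and
kept).

## Enrichment and survival

Over-representation of a query set against a user-supplied GMT-style
collection uses the *same* hypergeometric tail as MS — one
implementation, two call sites: `p = ms(t, |set|, |query|, |universe|)`
with BH adjustment across the collection. No term database ships with
the package; enrichment is deliberately local and offline.

Survival analysis stratifies patients by module expression: each
patient's score is the mean of the per-gene z-scores of the module genes,
split at the median (strictly below → "low"). This is a documented
default for "patient clustering by module expression" — the original
analysis does not define its rule — and a seeded 2-means alternative is
available. Groups are compared with the Kaplan–Meier product-limit
estimator \(\hat S(t)=\prod_{t_i\le t}(1-d_i/n_i)\) and the standard
log-rank test (both implemented in-package and verified against
`survival::survfit`/`survdiff`); Cox proportional hazards regression is a
thin adapter over `survival::coxph`, with convergence problems surfaced
verbatim.

## The synthetic-data generator: what a green test establishes

`generate_fixture()` emulates the *shape* of a single-cell miRNA/mRNA
co-sequencing experiment: FPKM-like non-negative ceRNA values, log-like
miRNA values, a sparse bipartite interaction table, a biotype annotation.
Its defaults are the stated world of the package's end-to-end tests: 60
samples, 30 miRNAs, 80 coding + 20 noncoding genes, 20 planted triads,
repression strength 0.8, noise sd 0.3. Each planted triad couples two
genes to one high-variance driver miRNA through shared repression
\(e_R = a - b\,e_m + \varepsilon\) — the shared repressor induces the
positive target–target correlation that the ceRNA hypothesis predicts —
and lists both genes as targets of the driver plus three decoy miRNAs, so
the pair's shared-miRNA enrichment is strong while background genes
(independent noise, two random targets each) mostly share zero or one
miRNA. Under these defaults, construction with `MS < 0.05` and
`PCC > 0.4` recovers the planted pairs essentially perfectly.

What this does **not** establish: the generator has no dropout or
zero-inflation, no compositional or batch effects, no indirect
(transitive) regulation, and its planted effect sizes are strong by
design. A green recovery test certifies that the pipeline's machinery is
correct and sensitive in a world where the ceRNA signal exists as
modelled — not that any particular biological dataset will yield a
comparable network. All generator randomness flows from one seed, and
survival fixtures follow the same pattern (exponential times with hazard
\(\propto e^{\beta\cdot score}\), administrative censoring at a fixed
horizon).

## Known limitations

* Only Louvain module detection; no overlapping or consensus clustering.
* No missing-value support in expression matrices: none of the five
  measures defines missing-data handling, so a non-numeric cell is an
  error rather than being imputed.
* Sensitivity-correlation-style partial measures and causal-effect
  estimation are other methods' contributions and are intentionally
  absent; user-defined measures can be plugged in as hook functions.
* Enrichment requires a local gene-set file; there is no online
  annotation retrieval anywhere in the package.
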