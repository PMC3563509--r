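---
title: "Topology-aware pathway enrichment: model, parameters and design"
author: "topoenrich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-aware pathway enrichment: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topoenrich)
```

## The problem and the model

Classical over-representation analysis treats a canonical pathway as a bag
of genes: count how many differentially expressed genes fall inside it and
compare against a hypergeometric null. That discards two things that
curated pathway databases actually encode. First, *within-pathway
structure*: a gene whose regulators and targets are all differentially
expressed is more interesting than one sitting in a quiet neighbourhood,
even at the same univariate p-value. Second, *between-pathway structure*:
canonical pathways share genes and interactions extensively, so treating
each pathway as an isolated entity throws away the connections that run
between them.

`topoenrich` addresses both by merging the entire pathway collection into
one **pooled pathway**: a directed graph over the union of all pathway
genes. Regulatory interactions (activation, inhibition, expression,
repression, phosphorylation, dephosphorylation, ubiquitination, indirect
effects) become directed edges; binding/association events, which have no
natural direction, contribute an edge in both orientations. The boolean
adjacency matrix $A$ has $A_{ij} = 1$ when some pathway contains an
interaction from gene $i$ to gene $j$, and a zero diagonal so
self-interactions never contribute. Because most platforms miss some
pathway genes, $A$ is first restricted to the measured genes by literally
deleting the missing rows and columns — no transitive edges are invented
through unmeasured genes.

Three layers of evidence are then computed per gene $i$:

* **Direct evidence** $p_i^D$: a two-sided two-sample t-test p-value
  comparing the gene's expression between the two groups (Welch by
  default; see below). Any per-gene p-value vector can be plugged in
  instead, e.g. from SAM, ANOVA or a moderated t.
* **Indirect evidence**: the score
  $SI_i = \sum_{j \ne i} A_{ij}\,(-\log_{10} p_j^D)$
  summarises how differentially expressed the neighbourhood of $i$ is.
  Its significance $p_i^I$ comes from a permutation null: the $p^D$
  values of *all* pooled genes are re-assigned to genes uniformly at
  random $N$ times with the topology held fixed, and $p_i^I$ is the
  fraction of shuffles whose random score strictly exceeds $SI_i$.
  Because the estimate lives on a $1/N$ grid, it is floored at $1/N$.
  This null preserves the graph exactly, so hub genes shared by many
  pathways are judged against their own, appropriately heavy, null
  distribution rather than a global one.
* **Combined evidence** $p_i^C$: Fisher's method,
  $p_i^C = P\!\left(\chi^2_4 \ge -2\ln(p_i^D\,p_i^I)\right)$.
  The independence Fisher's method assumes is plausible here because
  $SI_i$ depends only on the neighbours' expression, not on gene $i$'s
  own; the fit nevertheless reports the Pearson correlation of
  $-\log p^D$ vs $-\log p^I$ as a diagnostic (`$diagnostics$evidence_cor`)
  so a user can spot datasets where the assumption is doubtful. Genes
  with no neighbour in the chosen orientation keep $p^C = p^D$ — absence
  of connectivity information is never a penalty, and in the limiting
  case of no usable topology at all the whole procedure collapses to the
  plain hypergeometric test (a property the test suite asserts exactly).

Genes with $p^C < \alpha$ (strict, default $\alpha = 0.05$) are declared
significant, and each pathway is scored by the inclusive hypergeometric
upper tail $P(X \ge k)$ of its significant-gene count, with the measured
pooled-pathway genes as the universe. Family-wise error control is
Bonferroni by default (Holm available).

### Contextual pathway association

Beyond per-pathway enrichment, the pooled graph supports a directional
**contextual association score** between pathways $\alpha$ and $\beta$:

$$SC_{\alpha\beta} = \sum_{i \in g^\alpha} \sum_{j \in g^\beta}
  A_{ij}\,(-\log_{10} p_i^D)(-\log_{10} p_j^D),$$

the weight of differential expression carried by edges running from
$\alpha$'s genes into $\beta$'s genes. Only direct evidence enters the
weights — combined evidence already contains topology and would be counted
twice. The permutation null is the same global shuffle of $p^D$ values,
with one shared set of $N$ shuffles reused for every pair, so the two
orientations of a pair are judged against identical random draws. The
score is deliberately asymmetric ($SC_{\alpha\beta} \ne SC_{\beta\alpha}$
in general); both ordered rows are reported, with an optional
`symmetrize = "max"` or `"sum"` aggregation. The companion **static
overlap test** — a hypergeometric tail on the number of shared genes,
using the full pre-restriction pathway complement as universe — isolates
what was already knowable from the database alone. The interesting cases
are pairs with weak static overlap but strong contextual association:
two pathways sharing no gene can still be tightly coupled through
cross-edges between differentially expressed genes, and the test suite
reproduces exactly this scenario as a regression fixture.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `n_shuffles` (N) | 2000 | permutation count for both nulls; the p-value grid is $1/N = 5\times10^{-4}$. Below 1000 a warning flags the coarse grid; below 100 is refused. |
| `alpha` | 0.05 | strict gene-level threshold on $p^C$. |
| `method` | `"welch"` | t-test flavour. Welch is the safer default when group variances may differ; `"student"` gives the pooled-variance test. A plug-in `p_direct` vector bypasses both. |
| `direction` | `"out"` | neighbourhood orientation of $SI$: the literal row orientation of $A$ ($A_{ij}$ = edge from $i$ to $j$). `"in"` and `"both"` are offered because "the neighbours of a gene" is ambiguous in a directed graph; the default honours the formula as written. |
| `ties` | `"gt"` | the permutation count uses a strict inequality, as the estimator is defined; `"ge"` switches to the conservative $(c+1)/(N+1)$ convention. |
| `fwer_method` | `"bonferroni"` | the most conservative reading of family-wise error control; Holm is uniformly more powerful and available. |
| relation map | see `default_relation_map()` | which KGML subtypes become directed edges, bidirectional edges, or nothing. The mapping is a reconstruction of common curation practice and is fully overridable via a two-column TSV. |

Numerical edge cases are handled explicitly: $p^D = 0$ (possible with
plug-in tables) is clamped to $10^{-300}$ before $-\log_{10}$ with a
warning, preserving ordering without infinities; a zero-variance gene
gets $p^D = 1$ when the group means agree and the smallest positive
double when they differ; pathways left with no measured gene are retained
with $p = 1$ and an `empty` flag so the output keeps one row per input
pathway; and if no gene reaches significance every enrichment p-value is
1 with a warning rather than an error.

## What the synthetic generator emulates

Real pathway collections cannot be redistributed with the package, so all
validation runs on a seeded generator (`synthetic_spec()`,
`generate_pathways()`, `generate_expression()`,
`generate_null_labels()`). It emulates the statistical structure the
method relies on:

* pathways of equal size arranged in a **ring**, each sharing exactly
  `floor(overlap_fraction * size)` genes with the next — partial gene
  overlap is the defining feature of curated collections (a `"hub"`
  pattern, one core shared by all pathways, stresses highly shared
  genes);
* directed interactions sampled independently at `edge_density`, with a
  fraction relabelled binding/association and hence bidirectional;
* i.i.d. normal noise with equal variance in both groups, so that the
  power of the planted signal is analytically checkable from the
  noncentral t distribution;
* a planted pathway in which a `de_fraction` subset of genes receives a
  standardized mean shift `d` in the condition group, each gene shifted
  at most once however many pathways it belongs to.

The default study conditions are 12 pathways × 25 genes, ring overlap
0.2, edge density 0.05 (≈ 30 interactions per pathway, a sparsity
comparable to curated signalling maps), 10% bidirectional edges, 10
samples per group, `d = 1.5` with half of the planted pathway's genes
shifted, and unit noise. At these settings a shifted gene reaches
$p^D < 0.05$ with probability ≈ 0.89, so the planted pathway is
recoverable but not trivially so. The generator deliberately omits
array-level artefacts (probe saturation, batch effects, correlated
noise, heavy tails): passing tests demonstrate the statistical machinery
is correct under its stated assumptions, not that those assumptions hold
on any particular microarray dataset. In particular the false positive
calibration below inherits the equal-variance normal noise model.

## Validation performed by the test suite and acceptance script

All problem sizes were chosen to make a desk-scale run exhaustive or
tightly bounded:

* permutation p-values (both $p^I$ and $p_{\alpha\beta}$) are compared on
  4–5-gene graphs against **exhaustive enumeration** of all $|G|!$
  weight assignments, within three binomial standard errors at
  $N = 2000$ plus one grid step;
* the hypergeometric tail is compared against direct combinatorial
  enumeration over an exhaustive grid of universes up to $M = 25$;
* Fisher combination is compared to its two-p-value closed form
  $q(1 - \ln q)$, $q = p^D p^I$, to $10^{-10}$ relative error over 1000
  random pairs;
* under a global null the distribution of $p^I$ is checked to be
  stochastically no smaller than uniform (permutation validity);
* the pathway-level false positive rate on null data (17 replicates × 12
  pathways = 204 pathway-tests, full pipeline each time) must stay below
  0.05 plus three binomial standard errors — observed rates are far
  lower, with the large majority of $p_{FWER}$ values equal to 1,
  because Bonferroni over 12 pathways is conservative;
* the planted pathway must rank first in at least 90% of 50 seeded
  replicates at `d = 1.5`;
* a two-pathway fixture with zero shared genes and five strong cross
  edges must reach the minimal $p_{\text{context}} = 1/N$ while its
  static overlap p-value is 1.

Determinism is part of the contract: every stochastic routine takes a
seed, uses it through a scoped RNG (the caller's `.Random.seed` is
untouched), and identical seeds give bitwise-identical tables and output
files.

## Design choices where the design was open

* **Which t-test.** Only "a t-test" is specified by the enrichment
  tradition; Welch was chosen as the default because it is never much
  worse than the pooled test and substantially safer under variance
  heterogeneity. The pooled form and the plug-in bypass are one argument
  away.
* **Orientation of the indirect sum.** `"out"` implements the formula
  literally; prose descriptions of "neighbours" suggest symmetry, so
  `"both"` exists, but the default follows the formula.
* **Strict inequality in permutation counts.** The estimator is defined
  with a strict `>`; a consequence is that a pair with no possible
  positive random score (e.g. no cross edges) receives the floor $1/N$
  rather than 1. The `ties = "ge"` option gives the add-one convention
  for users who prefer it.
* **Enrichment universe.** The measured pooled-pathway genes, not the
  whole chip: significance of $p^C$ is only defined for pooled genes, so
  using the chip as universe would mix two populations. This makes the
  reported universe size explicit in every output row.
* **Static-overlap universe.** The pre-restriction pooled gene count (the
  full complement of annotated pathway genes), because static overlap is
  a database property, not a platform property; overridable.
* **FWER method.** "Family-wise error rate" without qualification is read
  as Bonferroni; Holm is offered since it dominates Bonferroni.
* **Pairs with empty memberships** keep their rows (score 0) so output
  shapes are platform-independent.

## Worked example

```{r example, fig.width = 6, fig.height = 4}
spec <- synthetic_spec(seed = 3)          # 12 pathways x 25 genes, d = 1.5
paths <- generate_pathways(spec)
ds <- generate_expression(paths, spec)

fit <- topoenrich(ds$values, ds$groups, paths, n_shuffles = 2000, seed = 11)
fit
head(fit$enrichment, 3)
plot(fit)
```

The planted pathway (`P01`) should dominate the ranking. Contextual
associations of the planted pathway with its ring neighbours:

```{r assoc}
head(associations(fit, focus = "P01", seed = 11), 4)
```

Pairs joined by cross edges between differentially expressed genes get
high scores and small `p_context`; `p_overlap` shows how much of that was
already predictable from shared membership alone.

## Known limitations

* The permutation null shuffles p-values *globally*; a gene's null
  therefore reflects the pooled weight distribution, which is the
  intended behaviour but means $p^I$ values of different genes are
  dependent (they share shuffles).
* Two-group designs only; no paired or multi-group support (plug-in
  p-values are the escape hatch).
* Compound-mediated KGML links and metabolic maps are out of scope; the
  graph is gene-only.
* $p_{\alpha\beta}$ is reported without multiple-testing correction by
  default, matching how pairwise association screens are usually read;
  correction over tested pairs is available in the run layer.
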