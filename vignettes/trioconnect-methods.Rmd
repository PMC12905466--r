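---
title: "Methods: trio filtering, expression prioritization and connectome search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio filtering, expression prioritization and connectome search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioconnect)
```

# Scope and model

`trioconnect` prioritizes candidate genes from parent–child trio exomes in
four stages: Mendelian inheritance-mode classification with annotation
filters and evidence tags; developmental brain-expression summarization
(cerebellum versus the average of all other structures); evidence-network
construction with exhaustive minimal connector-node and
transcription-factor searches plus permutation edge-enrichment; and exact
hypergeometric overlap tests against curated panels. Sequencing, alignment,
genotype calling and annotation generation are upstream of the package:
a trio VCF and a per-variant annotation table are consumed as given, and
impact severity in particular is **input data**, never recomputed from the
consequence term (annotation pipelines disagree on corner cases such as
conserved synonymous sites, and second-guessing them would silently change
results).

# Trio variant filtering

## Inheritance-mode predicates

For each biallelic record with trio genotypes, three mutually exclusive
patterns are tested:

* **de novo** — both parents homozygous reference, proband carrying exactly
  one alternate allele. Read-level manual review is replaced by a numeric
  check: the proband allele balance (alt reads / depth) must lie in a
  window, default $[0.30, 0.70]$ around the heterozygous expectation of
  0.5, at depth $\ge 10$. A hemizygous-alternate male-X proband with
  reference parents is *not* called de novo under the default (no balanced
  read support exists for a hemizygous call); a notice is emitted so such
  candidates can be reviewed separately.
* **autosomal recessive** — proband homozygous alternate, both parents
  heterozygous carriers. Only defined on autosomes; X input is a routing
  error by design rather than a silent false.
* **X-linked recessive** — male proband hemizygous alternate, mother
  heterozygous, father hemizygous reference (the female homozygous pattern
  is supported for generality). Pseudoautosomal positions follow autosomal
  rules; GRCh38 X PAR coordinates are the default and the simulator
  declares its own miniature PAR. A homozygous-alternate mother is rejected
  by default — the expected pattern is a carrier mother, and an affected
  homozygous mother usually indicates an annotation or pedigree problem —
  with an explicit override flag.

All three predicates require genotype quality $\ge$ `gq_min` (default 20,
a conventional phred-scale floor) in every sample. A record with any
missing genotype is *uncallable* (`NA`), deliberately distinct from a
negative call.

## Annotation filters

Variants are kept when CADD $> 10$ (strict, so printed scores of 10.6–10.7
survive), population allele frequency $< 0.05$ (strict), and impact
severity is not LOW. Missing values follow an asymmetric policy: a missing
frequency is treated as 0 (a novel allele is exactly what these screens
look for), while a missing CADD **retains** the variant with a warning — a
filter must not reject on absent evidence. Every rejected record is logged
with the first rule it failed, which the tests assert per decoy class.

## Evidence tags

The package implements a deliberately narrow two-tag rule rather than a
full ACMG engine: PS2 (confirmed de novo, both parents tested and
confidently reference at `gq_min`) and PM2 (population frequency missing,
zero, or below `pm2_af_max`, default $5\times10^{-3}$ — published practice
grants the rare-in-controls tag at frequencies around $10^{-3}$).
`likely_pathogenic` is assigned exactly when both tags are present;
everything else is `uncertain`. The tag set and classification are stored
per variant so downstream stages never re-derive them.

# Expression prioritization

Ages are mapped to one totally ordered axis in postnatal months: `pcw`
$\mapsto (\text{weeks} - 40)/4.345$, months directly, years $\times 12$.
Only the ordering relative to the early/late boundary matters for the
windowing, so any monotone mapping with birth at 40 pcw would give the same
windows; this one is fixed for determinism. The early window is
age $< 12$ postnatal months (the boundary is configurable; the source
material alternates between "up to 10 months" and "< 12 months", and 12 is
the boundary its printed tables use), prenatal ages always early.

Per gene, four unweighted arithmetic means are computed: early/late
$\times$ cerebellum/other. "Other" excludes cerebellar samples entirely
rather than being a grand mean — this bookkeeping reproduces the published
11-of-14 early tally. A configurable by-structure weighting is deliberately
not the default: with unbalanced structure sampling both conventions are
defensible, and the unweighted mean matches the published values.

Enrichment flags gate on the **early** other-structure mean exceeding a
1-RPKM floor (strict), in both windows: the floor expresses "expressed at
all in earliest development", so a gene below it is never flagged in either
window. Above the floor, `plus`/`minus`/`tie` compare the cerebellar mean
with the other-structure mean of that window. One published late-window
mark (MOSPD2, cerebellar 2.63 vs other 3.61) is inconsistent with its own
comparison rule; the package applies the stated rule, yielding an 8/6 late
tally rather than the printed 9/5, and the tests pin the rule-based result
as a regression guard.

# Network connectome

## Containers

An evidence network is a typed multigraph: every provenance record (edge
with its evidence channel) is preserved, while connectivity is always
evaluated on the collapsed undirected simple graph (one edge per gene
pair). TF→target edges are the only directed channel and are deliberately
treated as undirected for connectivity — a regulatory arrow is a
functional link in either direction for the purpose of joining components.
Channel confidence scores are not used: presence/absence connectivity
keeps the search exact and auditable.

## Minimal connector search

The question "which single gene connects the high-confidence set?" is
formalized as a minimum-cardinality node addition (Steiner-node) search:
enumerate candidate subsets of size $0, 1, \dots, k_{\max}$ (default 3)
and return **all** minimum-cardinality subsets $S$ such that the induced
subgraph on seeds $\cup\, S$ is connected, in lexicographic order. Because
sizes are enumerated in increasing order the result carries its own
minimality certificate. Exhaustive enumeration is feasible at the scale
this method is used (tens of candidates, $k_{\max}\le 3$:
$\sum_{k\le 3}\binom{n}{k}$ subsets); the TF search additionally offers a
greedy strategy (largest component merge first, lexicographic tie-break)
for larger TF universes, with an explicit warning that greedy solutions
are not certified minimal.

## TF augmentation and orphan rescue

Each TF is a candidate star: edges to its targets within the gene panel.
The exact strategy enumerates TF subsets by increasing size. When even the
full TF universe cannot connect the panel (the case study's own data leave
three orphans after TF addition), the exact search returns the minimal
subset achieving the best attainable component count, flagged
`status = "partial"` — this mirrors the real analysis flow, where TF
augmentation is followed by a separate rescue step. Orphans are then
rescued through a table of predicted interactions (optionally mixed with
known support edges): an orphan is rescued when a path exists from it to
the giant component through the union of network and support edges; edges
and intermediate rescue nodes along a shortest such path are added.
Unrescued orphans are always reported, never dropped.

## Edge enrichment

Observed statistic: the number of background edges with both endpoints in
the gene set. Null: `n_perm` equally sized node sets drawn uniformly
(`node_resample`) or matched to the observed set's degree-decile
composition (`degree_binned`, offered because dense hubs inflate a naive
null). The p-value uses the add-one permutation estimator
$p = (\#\{\text{null} \ge \text{obs}\} + 1)/(n_{\text{perm}} + 1)$, which
is valid (never anti-conservative) and never exactly zero. The original
study's enrichment p-value depends on a specific interaction-database
release and is not reproducible from fixtures; the package instead
validates the machinery with a property suite: a planted 6-clique in a
sparse background (200 nodes, edge probability 0.01) must reach the
permutation floor $p = 0.001$ at 999 permutations, and the empirical size
$P(p \le 0.05)$ under the null must be close to nominal. The calibration
suite draws 25-gene sets on a 0.05-density background so the count
statistic is approximately continuous (about 15 expected edges per draw);
on very sparse backgrounds small sets induce almost no edges, the null
mass concentrates at zero, and the add-one estimator is heavily — and
correctly — conservative, which would measure discreteness rather than
calibration.

# Overlap statistics

Overlap of a candidate list with a curated panel is tested exactly:
hypergeometric point masses evaluated in log space (stable at
genome-scale universes), upper tail for `greater`, and the two-sided
p-value as the sum of all achievable tables with probability at most the
observed one (with a $10^{-7}$ relative tie tolerance, the convention of
the exact conditional test). The odds ratio is the sample odds ratio of
the 2×2 table, reported as `Inf` when undefined. The background universe
is never implicit: pipeline configuration must state it, and the
documented library default of 20 000 approximates the protein-coding gene
count. Published significance bounds are checked only under this
documented universe, since the original background was not stated.

# Synthetic data

The generators define the package's reference study conditions:

* **Trios** (`generate_trio`): a miniature genome (two 1-Mb autosomes plus
  X with a declared 10-kb PAR, so PAR routing is exercised at small
  scale). Planted variants satisfy their mode's genotype pattern with
  clean values (GQ 60, de novo allele balance 0.5, depth 40) and
  annotations inside every filter bound; decoys cycle through an explicit
  taxonomy — inherited, low-GQ, common allele, low CADD, LOW impact,
  allele-balance outlier — each violating exactly one rule so per-rule
  rejection logging is assertable. Default 20 decoys per trio, male
  proband so the X-linked pattern is testable.
* **Expression** (`generate_expression_matrix`): log-normal RPKM around
  per-gene baselines (log-uniform in 2–20 RPKM, comfortably above the
  1-RPKM floor), four structures (one cerebellar) crossed with a ten-step
  age ladder from 8 pcw to 40 years, default noise SD 0.2 on the log
  scale; enriched genes have early cerebellar samples multiplied by a
  planted factor (default 4, a clearly detectable but not extreme
  enrichment).
* **Networks** (`generate_network`): an Erdős–Rényi background (default 30
  nodes, edge probability 0.08) in which the seed genes touch nothing but
  a single planted hub, making that hub the verified-unique $k=1$
  connector; the TF layer plants a known minimal TF subset bridging
  orphan genes to the seed component with single-target decoy TFs. Both
  planted guarantees are re-verified by exhaustive search before the
  generator returns — a generator that could silently emit a non-unique
  "unique" instance would invalidate recovery tests.

What the simulations do *not* emulate: read-level data, linkage and
population structure, annotation errors, batch effects in expression, and
the degree heterogeneity of real interactomes. Passing the planted-truth
suites therefore demonstrates correctness of the algorithms under clean
conditions, not robustness to real-data artifacts.

# Numerical and design choices

* Problem sizes in the test and acceptance suites — exhaustive-oracle
  agreement on 100 random graphs with ≤ 15 candidates, TF oracles at ≤ 12
  TFs, 500 calibration replicates at 499 permutations, 20-network recovery
  sweeps — are chosen so each property is exercised across many random
  instances while the whole suite completes in well under a minute per
  module.
* Tie-breaking is lexicographic on gene symbols everywhere; all co-minimal
  connector solutions are reported rather than an arbitrary first one.
* Permutation seeds are explicit arguments; generators are byte-identical
  under a fixed seed.
* Multi-allelic VCF records are decomposed per alternate allele with
  genotype recoding (target allele → 1, all others → 0), 1-based
  coordinates throughout; chromosome labels are accepted with or without
  the `chr` prefix.
* Variants lacking an annotation row are rejected with an explicit
  `unannotated` rule rather than passed through with missing-value
  semantics: an unannotated record cannot be evaluated against the
  annotation contract at all.

# Known limitations

* Compound heterozygotes are out of scope (no phasing).
* The two-tag classification is intentionally minimal; it does not
  implement the full ACMG evidence combination rules.
* The exhaustive connector search is exponential in $k_{\max}$; it is
  intended for the tens-of-nodes regime of curated candidate networks,
  with the greedy strategy as the documented non-certified fallback.
* Expression summaries take RPKM as given; no normalization or
  differential-expression testing is performed.
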