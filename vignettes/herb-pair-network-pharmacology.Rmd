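---
title: "Dissecting a two-herb formula: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting a two-herb formula: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnp)
```

## The problem

A classical antidiabetic herb pair — Huangqi (*Radix Astragali*) plus
Huanglian (*Rhizoma Coptidis*) — contains on the order of 170 distinct
compounds. Only a fraction of them are plausibly active after oral
administration, and those act on dozens of protein targets at once.
`herbnp` implements a system-pharmacology pipeline that answers three
questions: *which ingredients are credible actives*, *which targets,
pathways and organs do they jointly touch*, and *which few ingredients
carry most of the effect*.

## ADME screening

Each ingredient comes with a predicted oral bioavailability OB (percent)
and a drug-likeness score DL. The screen keeps ingredients with
OB $\ge$ 30% **and** DL $\ge$ 0.18; both comparisons are inclusive, so an
ingredient sitting exactly on both cut-offs passes. DL itself is the
continuous-vector Tanimoto similarity

$$T(A,B) = \frac{A\cdot B}{|A|^2 + |B|^2 - A\cdot B}$$

between the compound's descriptor vector $A$ and the average descriptor
vector $B$ of known drugs. The operation accepts any label-aligned
descriptor basis: the four shipped properties (MW in Da, CLogP, nHDon,
nHAcc) are the printed convention, but curated drug databases score DL on
much larger descriptor sets, so the basis is a parameter rather than a
constant. Two numerical caveats are documented rather than hidden: the
score is undefined for two all-zero vectors (an error), and with negative
components (CLogP can be negative) it can leave $[0,1]$; the bound is only
guaranteed — and only asserted in tests — for non-negative inputs. The
default reference vector is the mean of a small packaged *synthetic*
drug-like descriptor table; it stands in for a curated drug database and
callers doing real work should supply their own reference mean.

Herbal practice keeps some threshold-failing compounds anyway — major
constituents with strong pharmacology (berberine at OB 0.68%,
astragaloside IV at 2.20%, a polysaccharide mixture with no computable
descriptors at all). That judgement is not computable from the inputs, so
rescue is an explicit boolean flag on the ingredient record, never a
heuristic. The screen therefore returns a strict three-way partition —
passed / rescued / excluded — plus an audit table with per-rule outcomes.
Missing OB or DL values never pass on numbers; they are rescued if
flagged, excluded otherwise. Raising either threshold can only shrink the
passed set (tested as a property over threshold grids).

## Chemical space

The four properties live on incommensurate scales, so the PCA input is
autoscaled (column mean 0, unit sample variance); missing descriptor cells
are imputed by the column mean with a logged count, and a constant column
degrades to zeros with a warning instead of an error. Eigenvector signs
are arbitrary in exact arithmetic, so a deterministic convention (the
largest-magnitude loading of each component is positive) keeps score plots
and test expectations stable. Explained-variance fractions are reported
against the total variance, sum to one over all components, and are
non-increasing. The overlap between two score clouds (ingredients vs
reference drugs) is summarised descriptively — per-component containment
fractions and centroid distance — rather than by a formal test, because
the published claim it mirrors is itself visual.

## Bipartite networks and the contribution index

The three networks (compound–target, target–pathway, target–organ) are
plain bipartite graphs with exact integer degree bookkeeping; degree is
the only centrality used. Isolated universe members are excluded from the
built network by default — matching what a Cytoscape import of an edge
file shows — but are tracked separately, so a target in no pathway is
visible rather than lost. Rankings are always deterministic (degree
descending, id ascending). A target is *shared* when its incident
ingredients span both herbs; a compound attributed to both herbs counts
toward both, so one dual-herb compound suffices. Duplicate edges from
different prediction servers merge with their provenance tags unioned —
the sources disagree often enough that dedup-with-provenance is the only
defensible reconciliation.

For ingredient $j$ with targets $i = 1..n$ in the C-T network, network
efficacy is $NE(j) = \sum_i d_i$ with $d_i$ the degree of target $i$ in
the T-P network, and the contribution index weights it by the
disease-related literature count $c_j$:

$$CI(j) = \frac{c_j\,NE(j)}{\sum_{i=1}^m c_i\,NE(i)} \times 100\%.$$

CIs sum to 100% whenever the denominator is positive (an all-zero
denominator is a typed error pointing at the inputs). "The top $N$
ingredients whose cumulative CI is more than 85%" is read with a strict
inequality: a prefix summing to exactly 85.00 does not stop. Ties in CI
break by NE, then id. An ingredient missing from the literature table
gets weight 0 with a warning rather than an error — no literature, no
weight — and CIs are computed at full precision, rounded only for
display. Because the literature counts are the softest input (they depend
on a bibliometric snapshot), `weight_sensitivity()` reports top-set
membership frequencies under multiplicative lognormal noise on $c$.

## Profiling

Annotation-category composition counts term–gene *associations*, not
distinct terms, which is how category pie percentages are conventionally
computed. Organ distribution reports per-organ target counts as
percentages of **all** targets, reproducing arithmetic such as 30 of 50
targets = 60%. "Highly expressed in an organ" is operationalised as
expression $\ge 3\times$ the target's median across organs; no published
definition exists, so the factor is an exposed parameter, and the rule is
deliberately nested (a larger factor yields a subset of edges).
Enrichment is a generic annotation-table-driven hypergeometric upper-tail
test with Benjamini–Hochberg correction across the tested terms;
annotation snapshots are user-supplied, since shipping a frozen GO/KEGG
copy would misrepresent the package's scope.

## The synthetic generator

The generator's defaults *are* the study conditions: 112 + 64 compounds
with 5 shared (171 distinct), 50 targets, 30 pathways of 2–13 member
targets, compound-target hubs capped at degree 33, organ-specific
expression boosts, and heavy-tailed (discretised lognormal, meanlog 2,
sdlog 1.5) literature counts. Where the published study pins down no
value we fixed one realistic choice: a pass fraction of 0.25 (43 of 171 compounds
were active), a rescue fraction of 0.17 among failures (22 rescued of 128
failing), lognormal baseline expression (sdlog 0.2) with 30-fold
organ-specific boosts on 30% of targets, and five planted dominant
contributors jointly holding 87% of the $c\cdot NE$ mass, shared equally.
Equal sharing matters: it guarantees the cumulative-85% prefix is exactly
the planted set, which is what the end-to-end recovery tests assert over
20 seeded replicates.

Pass/fail at the thresholds is decided per compound by an explicit
Bernoulli draw, and OB/DL are then sampled conditionally on the correct
side of their cut-offs (right-skewed gamma tails above, scaled-beta below),
so the realised pass fraction concentrates tightly around the target
(within five percentage points at $n \ge 500$). One master seed drives
fixed per-component sub-streams (compounds, C-T, T-P, T-O, literature,
planting), so enlarging one component does not perturb the others, and a
regenerated dataset is bit-identical. The planted literature boost is
solved analytically from the realised efficacies, then rounded up to
integers, so the realised share is recorded in the ground truth rather
than assumed.

What the generator does *not* emulate: correlated prediction errors
between target servers, compound structures (descriptors are sampled, not
computed), annotation bias in literature counts, or organ expression
correlations. Passing tests on synthetic data therefore demonstrate
algorithmic correctness and recoverability of planted structure, not that
the published server-derived networks would be reproduced.

## Problem sizes and determinism

The test-suite exercises the full 171-compound study conditions for the
generator and the end-to-end recovery (20 replicates), smaller 47-compound
configurations elsewhere, 1000 random instances for CI normalisation, 100
random graphs for degree conservation, and a fixed-seed $n = 2000$
isotropic Gaussian for the PCA variance check. All randomness flows
through explicit seeds; reruns are bit-identical, including the pipeline
report.

## Known limitations

OB values are inputs, not predictions; target, pathway and organ edges are
inputs or synthetic, never fetched; the published contribution ranking
depends on a 2017 bibliometric and server snapshot and is not recomputable
from the shipped tables alone — the pipeline reproduces the printed
*counts* exactly and the *mechanics* of the ranking verifiably, which is
the part that transfers to new herb pairs.
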