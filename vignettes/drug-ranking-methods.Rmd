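---
title: "Ranking drug candidates from molecular topology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking drug candidates from molecular topology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(adrank)
library(ggplot2)
```

## The problem

Measuring the physicochemical profile of a drug candidate is expensive;
computing descriptors from its structural formula is free. Degree-based
topological indices are graph invariants of the hydrogen-suppressed
molecular skeleton that correlate, often strongly, with bulk properties
such as boiling point or molecular weight. `adrank` implements a complete
screening pipeline on this idea for a panel of Alzheimer's-disease drug
candidates: compute six standard indices per molecule, weight them
objectively with the entropy method, rank the molecules with two
multi-criteria decision-making (MCDM) methods — TOPSIS and simple additive
weighting (SAW) — and use simple-regression QSPR against measured
properties to decide which criteria should count as benefits and which as
costs.

## The molecular graph convention

All indices are computed on the *hydrogen-suppressed simple graph*: heavy
atoms are vertices, and every bonded heavy-atom pair contributes exactly
one edge, whatever the bond order or aromatic state. This bond-order-blind
convention is the one under which the classical degree-pair edge-partition
calculations for drug molecules are carried out: a carbonyl carbon bonded
to one oxygen and two carbons has degree 3, and the C=O bond is a single
edge between a degree-1 and a degree-3 vertex. Charges, isotopes and
stereochemistry are ignored. Disconnected inputs (salts) are rejected
unless `largest_fragment = TRUE`, which keeps the component with the most
atoms (lexicographically smallest label on ties). The convention is
deliberately *not* extended to organometallic or charged species, whose
skeleton conventions are less settled.

The computation substrate is the degree-pair **edge partition**: the tally
of edges by the unordered pair of endpoint degrees. For donepezil
(28 heavy atoms, 31 bonds):

```{r}
don <- graph_from_smiles("COc1cc2c(cc1OC)C(=O)C(CC3CCN(CC3)Cc4ccccc4)C2",
                         id = "donepezil")
edge_partition(don)
```

## The six indices

Each index is a sum over edges `uv` of a kernel in the endpoint degrees
`d(u)`, `d(v)`; on the partition this becomes a weighted sum over degree
pairs `(a, b)` with multiplicities:

| index | kernel |
|---|---|
| first Zagreb `M1` | `a + b` |
| second Zagreb `M2` | `a * b` |
| hyper-Zagreb `HZ` | `(a + b)^2` |
| harmonic `H` | `2 / (a + b)` |
| forgotten `F` | `a^2 + b^2` |
| sum-connectivity `SCI` | `(a + b)^(-1/2)` |

```{r}
compute_indices(don)
```

`HZ = F + 2 M2` holds identically and is asserted in the test suite on
random graphs, as is the handshake-square identity (edge-form `M1` equals
the sum of squared vertex degrees). Values are stored at full double
precision; the conventional reporting precision is 5 decimals for `H` and
4 for `SCI`. Additional indices can be added through
`register_index()` without touching the pipeline; the six above are the
built-ins.

## Entropy weighting

Given a strictly positive decision matrix `x_ij` (m drugs by n index
criteria), each column is normalized to proportions
`r_ij = x_ij / sum_i x_ij`, the per-criterion Shannon entropy is
`E_j = -(1/ln m) sum_i r_ij ln r_ij` (with `0 ln 0 = 0`), and the weights
are `w_j = (1 - E_j) / sum_j (1 - E_j)`. A criterion whose column is near
uniform carries no discriminating information and gets weight near zero; a
perfectly uniform column gets exactly zero. Weights are invariant to
positive rescaling of any column, so the very different magnitudes of,
say, `HZ` and `SCI` do not distort them.

Two normalization conventions circulate for this method (over rows or over
columns); only the column-over-alternatives form makes the entropy formula
well-defined, and that is the form implemented. Weights attach to the
index *criteria*, not to the drug alternatives. Degenerate inputs (every
column uniform) error by default; `equal_fallback = TRUE` substitutes
equal weights with a warning. Structural zeros can be shifted by
`1e-6 * max(column)` behind the explicit `shift_zeros` flag, off by
default, since the entropy formula needs strict positivity.

## TOPSIS and SAW

**TOPSIS** normalizes each column to unit Euclidean norm, multiplies by
the weights, forms the ideal point (per-criterion best: max for benefit,
min for cost) and anti-ideal point, and scores each drug by the relative
closeness `C_i = P−_i / (P+_i + P−_i)`, where `P±` are Euclidean distances
to the two points. Rank 1 is the largest closeness. The Euclidean metric
is the only one implemented; a Manhattan variant would change the
acceptance surface without changing the method's character.

**SAW** rescales each column onto `(0, 1]` — `x / max` for benefit
criteria, `min / x` for cost criteria — and scores each drug by the
weighted sum. With weights summing to 1 the total score lies in `(0, 1]`,
and a drug that is best on every criterion scores exactly 1. The linear
max-normalization is the textbook SAW scale; a vector-normalization
variant is available behind `scheme = "vector"` for sensitivity analysis,
since the literature on this pipeline does not pin the SAW scale down
numerically.

Ties: scores equal within `tie_tol` (default `1e-12`) share the minimum
rank and subsequent ranks are skipped (competition ranking); tie groups
are reported in the result object so they are never silent. Both methods
are deterministic, invariant to positive column rescaling, and
permutation-equivariant; all three properties are asserted in the suite.

## QSPR: choosing criterion directions

Whether a high index value should *help* a drug depends on what the index
tracks. The QSPR module correlates each index with each of six measured
properties (melting point °C, boiling point °C, molecular weight g/mol,
density g/cm³, flash point °C, complexity), allocates each index the
property with the largest `|r|` (ties broken in the fixed vocabulary
order just given), and lets the index criterion inherit the property's
pharmacological preference: boiling point, molecular weight and flash
point are benefits; melting point, density and complexity are costs.
Pearson correlation with pairwise-complete observations is the default,
matching standard QSPR practice; Spearman is available as a sensitivity
flag. A property constant across the panel has no defined correlation and
is reported as `NA`, never silently as 0. Simple (one-descriptor) OLS
fits back the allocation with slopes, intercepts and `R²`.

The pipeline accepts three direction sources: all-benefit (the default,
matching the plain max/min ideal definition), a hand-written direction
table, or `directions = "qspr"`. Which source was used is always recorded
in the report's assumption log, because the choice is a genuine modelling
decision, not a mathematical consequence.

## The synthetic panel generator

Real measured property tables for the 12-drug panel are not shipped;
the generator provides statistically controlled stand-ins for testing
every stage:

* **Graphs** — a degree-capped random spanning tree (cap 4 by default,
  mirroring carbon valence) plus `Binomial(n, 0.15)` extra ring-closing
  edges, sizes drawn from 10–28 vertices (drug-like heavy-atom counts,
  matching the shipped fixture's range of 11–31). This emulates
  connectivity and degree structure only — not valence rules, aromaticity
  or heteroatom chemistry — so passing tests speak to the graph-theoretic
  and statistical machinery, not to chemical validity.
* **Decision matrices** — i.i.d. log-normal entries
  (`meanlog = 1`, `sdlog = 0.5`), strictly positive by construction.
* **QSPR panels** — each property is a planted linear function of one
  designated index plus Gaussian noise, by default a bijection of the six
  indices onto the six properties with slopes, intercepts and noise SDs on
  each property's natural scale (e.g. boiling point `= 1.2·M2 + 150 ± 15`,
  density `= 0.02·H + 0.9 ± 0.05`). The design is returned as ground
  truth, so slope recovery (within 3 standard errors) and exact allocation
  recovery at small noise are testable. Graph generation and property
  noise use separate seed streams, so enlarging a panel never perturbs
  the noise draws of existing properties.

All generators take a `seed` and restore the caller's RNG state.

## Numerical and design choices

* Indices are defined on the edge partition, with graph-level entry points
  delegating; this keeps the worked-example calculations directly testable.
* Entropy/weight arithmetic and both rankings are plain double-precision
  linear algebra; the only tolerances are the tie tolerance (`1e-12`) and
  the weight-sum check (`1e-6` on user-supplied weights).
* An m = 1 decision matrix is rejected (entropy needs `ln m > 0`); an
  all-constant matrix is rejected at the closeness stage as degenerate.
* SMILES parsing is delegated to the OpenBabel-backed ChemmineR parser; a
  light token pre-scan supplies position-annotated error messages for
  invalid characters, non-organic-subset atom symbols outside brackets,
  and unbalanced brackets.
* Rank agreement between the two methods is summarized by tie-aware
  Kendall tau-b; it is diagnostic output, and no agreement threshold is
  asserted anywhere.

## Worked 12-drug example

```{r, message = FALSE}
smi <- system.file("extdata", "ad_drugs.smi", package = "adrank")
report <- run_full_ranking(smi)
tidy(report)
glance(report)
```

```{r, fig.width = 5, fig.height = 4}
autoplot(report)
```

The shipped fixture provides the 12 drug structures; their measured
property tables are figure-bound in the source literature and therefore
not shipped, so the default demonstration uses entropy weights with
all-benefit directions and reports its own agreement list. With
all-benefit directions on raw size-correlated indices, larger molecules
dominate — a known behaviour of this kind of pipeline, and precisely why
the QSPR direction stage exists.

## Limitations

* The graph model ignores bond order, so indices cannot separate, e.g.,
  cyclohexane from benzene; that is inherent to the method, not a bug.
* Entropy weights reflect dispersion, not pharmacological importance.
* SAW ignores criterion interactions; TOPSIS results depend on the
  normalization and metric conventions fixed here.
* QSPR fits are univariate screens, not validated predictive models; with
  12 molecules a single outlier moves `r` substantially.
* Synthetic panels are statistical stand-ins; conclusions about real
  property data require real property tables.

## Test problem sizes

The suite exercises: 200 random graphs for the algebraic identities, 100
random matrices for the weighting properties, 20 seeded 12×6 instances
against from-scratch scripted TOPSIS/SAW recomputations, and 200
seeded 12-molecule QSPR panels for slope-recovery coverage (40 panels in
the per-module test, 200 in the acceptance test). These sizes give stable
pass/fail behaviour at sub-minute runtimes on a laptop.
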