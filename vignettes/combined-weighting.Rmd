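---
title: "Combined subjective-objective weighting for base-hospital evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined subjective-objective weighting for base-hospital evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(screeneval)
```

## The evaluation problem

China's community stroke-screening programme is implemented by designated
tertiary "base hospitals" that screen residents aged 40 and over, identify
high-risk individuals, and run follow-up and intervention. Annual
quality-control reviews score each hospital on eleven indicators --- task
completion, risk-factor control, detection rates for stroke risk and for
hypertension, diabetes and dyslipidemia, awareness, intervention and
follow-up rates, and the demographic representativeness of the screened
population (age deviation). Each indicator converts a raw rate into points
through threshold bands, and the traditional review simply sums the points.
A plain sum weights every point equally, which over-rewards indicators that
almost every hospital saturates and under-rewards the ones that actually
separate strong from weak implementation. This package implements a
weighted re-evaluation that combines expert judgement with data-driven
weighting and quantifies how much the choice of weighting methodology
changes the resulting hospital ranking.

## The model

Let $X_{ij}$ be the points awarded to hospital $i$ ($i = 1,\dots,n$) on
indicator $j$ ($j = 1,\dots,m$), and $S_j$ the score the expert panel
assigned to indicator $j$ (the "Assigned score" column of the scheme;
$\sum_j S_j = 112$ for the default eleven-indicator scheme).

**Subjective weights** follow directly from the expert scores:
$W^s_j = S_j / \sum_{k} S_k$.

**Objective weights** come from the entropy weight method (EWM). The matrix
is first normalised per indicator according to its attribute:

* positive (higher is better): $Y_{ij} = (X_{ij} - \min_i X_{ij}) /
  (\max_i X_{ij} - \min_i X_{ij})$;
* negative (lower is better): the reflection of the positive rule;
* moderate (closest to the panel mean is best):
  $Y_{ij} = 1 - |X_{ij} - \bar X_j| / \max_i |X_{ij} - \bar X_j|$.

Every cell is then shifted by $+0.001$ so zero values cannot annihilate the
logarithms, proportions are formed per column,
$P_{ij} = Y'_{ij} / \sum_i Y'_{ij}$, the information entropy of indicator
$j$ is $E_j = -\tfrac{1}{\ln n} \sum_i P_{ij} \ln P_{ij}$, and the weight is
$W^o_j = (1 - E_j) / \sum_k (1 - E_k)$. Indicators whose columns vary more
across hospitals have lower entropy and earn larger weights; a constant
column has $E_j = 1$ and weight exactly zero.

**Combined weights** use multiplicative synthesis with normalisation (MSN):
$W^c_j = \prod_l W_{jl} / \sum_k \prod_l W_{kl}$ over the $L$ component
methodologies (here $L = 2$: subjective and objective). The product widens
the spread between indicators the two methods agree on, and the
normalisation keeps the result a weight vector. With $L = 1$ MSN is the
identity, and uniform inputs stay uniform.

**Scores and rankings.** Each methodology scales the matrix column-wise,
$X^{(w)}_{ij} = W_j X_{ij}$, totals the rows,
$\mathrm{TWS}_i = \sum_j X^{(w)}_{ij}$, and ranks hospitals by descending
total. The traditional "original" methodology is reproduced exactly by unit
weights (a plain sum), which is why its weight vector is exempt from the
sum-to-one constraint.

**Methodology agreement.** Two metrics compare methodologies:

* the *head-tail consistency rate* $S = (x + y) / (0.4 n)$, where $x$ and
  $y$ count hospitals jointly placed in both top-$k$ and both bottom-$k$
  sets with $k = \lfloor 0.2 n \rfloor$;
* the *discrimination degree* $D$, computed per methodology from scores
  standardised onto $[0, n]$ ($V_i = n (1 - |V'_i - V'_1| / (V'_1 -
  V'_n))$, best score $\mapsto n$, worst $\mapsto 0$) and the squared gaps
  between consecutive standardised scores,
  $D = (\sum_i (V_{i+1} - V_i)^2 + 1) / (2n^2 - 2n - 1)$. Methodology pairs
  are compared by $|D_a - D_b|$.

## Worked example

```{r example}
sch <- default_scheme()
m <- generate_matrix(generator_config(seed = 42))
report <- run_evaluation(m, sch)
report
```

The report bundles the four weight vectors, the four ranking tables, the
subjective-to-objective weight-change table and all pairwise comparisons;
`write_report()` serialises it as CSV files plus a JSON twin.

## Parameters that matter

* **Assigned scores** (default 35, 12, 6, 6, 3, 3, 3, 8, 12, 12, 12 for
  X1--X11, unitless points summing to 112): fixed by the expert panel of
  the national programme office; they fully determine the subjective
  weights.
* **Reference standards** (fractions, no default): several indicators score
  rates against national or provincial target values that are distributed
  to hospitals as configuration, not published with the scheme. The scoring
  engine therefore refuses to score a relative band until
  `set_reference_standards()` supplies the value; weighting and ranking of
  an already-scored point matrix need no standards.
* **Zero shift 0.001** (points on the normalised scale): the published
  procedure's guard against $0 \ln 0$; applied uniformly, it bounds shifted
  values in $[0.001, 1.001]$.
* **Discrimination-degree reading** (`"ratio"`, default, or `"sqrt"`): the
  defining formula's radical is typeset ambiguously and the two literal
  readings differ by a square root. They are monotonically related, so
  methodology orderings agree under either; the package defaults to the
  plain quotient and exposes the choice.
* **Head/tail size** $k = \lfloor 0.2 n \rfloor$ with the fractional
  denominator $0.4 n$ kept as defined: at $n = 16$ this makes the
  attainable maximum $6 / 6.4 = 0.9375$ rather than 1, which is exactly the
  value reached when two methodologies agree on both sets.

## Numerical and design choices

* **Band semantics.** Scoring bands are left-closed and right-open unless
  the published criterion states otherwise; bands are matched in listed
  order and the first match wins, which resolves the one boundary overlap
  in the published scheme (a detection rate of exactly 26% falls in the
  closed 20--26% band). The task-completion row lists both "0% &le; P <
  85%" and a dedicated "P = 0%" criterion; the 15-point band is therefore
  open at zero so that a zero rate scores zero points.
* **Relative thresholds.** Criteria of the form "standard &times; 10% &le;
  P < standard" are read as thresholds at decreasing multiples (90%, 80%,
  ...) of the reference standard; the literal reading would make the listed
  bands empty or inverted.
* **Age deviation degree** is defined per age group but enters the matrix
  as one value per hospital; the engine accepts a pre-aggregated single
  rate and leaves the aggregation to the data provider.
* **Constant columns.** Min-max and moderate normalisation divide by zero
  on a constant column; the package sets such a column to the midpoint 0.5
  with a warning. The choice is inconsequential downstream: after the
  shift, a constant column's proportions are uniform, its entropy is
  exactly 1 and its objective weight exactly 0.
* **Fully degenerate matrices.** If every column is constant the entropy
  denominator $\sum_j (1 - E_j)$ vanishes; `entropy_weights()` raises an
  error, while the pipeline wrapper `run_evaluation()` degrades to equal
  weights with a warning and omits the comparison table (all-tied scores
  have no defined discrimination degree) instead of crashing.
* **Ties.** Rankings use descending competition ranking (tied scores share
  the smallest rank) with lexicographic hospital order within ties, so
  output tables are deterministic.
* **Printed-value tolerances.** The published weight tables print 4
  decimals. Recomputations that start from printed (hence rounded) inputs
  are compared at absolute tolerance 5e-5 (half a print ULP). Input
  rounding propagates: recombining the printed subjective and objective
  vectors reproduces 7 of the 11 published combined weights within 5e-5
  and all 11 within 6e-5 --- the published combined table was evidently
  computed from full-precision objective weights, which require the
  unpublished raw matrix.

## The synthetic-data generator

The generator emulates the shape of a provincial review year: by default 16
hospitals scored on the 11-indicator scheme, every cell drawn from the
indicator's admissible band-point lattice (awarded points, not continuous
rates --- published total scores are sums of band points). Dispersion is
controlled per indicator: `"none"` pins the column at its maximum, `"low"`
is near-constant (the top band with a 10% chance of the band below,
mimicking the compliance ceiling of process-oriented indicators), `"high"`
spreads uniformly across all bands; `ceiling_fraction` additionally pins a
share of hospitals at the maximum. Each column has its own seed stream
derived from the configuration seed, so changing one indicator's dispersion
leaves the other columns' draws untouched.

Two design points deserve emphasis. First, min-max normalisation rescales
any two-valued column to $\{0, 1\}$ regardless of how close the two values
are, so a column with substantial mass on two adjacent bands does *not*
read as low-dispersion to the entropy method; that is why `"low"` is
near-constant rather than a 25/75 split. Second, the realised entropy of a
single 16-row draw is noisy, so the monotone response of the objective
weight to the dispersion level is a property of the generator's
distribution, not of every draw; the test suite asserts it on the mean over
a fixed 20-seed panel (and the exact fact that a `"none"` column always
receives the minimum, zero, weight).

What the generator does not emulate: correlation between indicators (the
real detection rates are biologically related), hospital-level quality
factors inducing row effects, and the empirical marginal distribution of
any real review year. Tests that pass on synthetic panels therefore
validate the algebra and the contracts of the pipeline, not claims about
real-world score distributions.

## Problem sizes and runtime

All tests run on panels of the published shape (16 x 11) or smaller;
property suites iterate over 20--25 seeded replicates. The whole suite
completes in well under a minute on a single CPU; the reproduction script
for the published quantities (`scripts/acceptance.R`) is millisecond-scale
since the published tables are themselves the inputs.

## Known limitations

* The EWM assumes indicator independence; the default scheme's detection
  rates are plausibly correlated, which the weighting cannot see.
* The published raw matrix is not distributed with the publication, so the
  package can reproduce every published quantity that is derivable from
  printed tables (subjective weights, combined weights, weight changes,
  head-tail rates) but cannot re-derive the objective weights from raw
  data; those enter as transcribed fixtures in `reference_tables()`.
* The published pairwise discrimination-degree values cannot be reproduced
  under either literal reading of the defining formula (the closest, the
  plain-quotient reading, is the default); the package treats the statistic
  as property-tested (affine invariance, oracle agreement,
  additive-consistent pairwise deltas) rather than value-pinned.
* Rank stability under perturbation (bootstrap or otherwise) is out of
  scope; rankings are point estimates of one review year.
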