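---
title: "Methods: risk-based tiering and tiered similarity statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: risk-based tiering and tiered similarity statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biosimtier)
```

`biosimtier` models the statistical core of a biosimilar analytical
similarity exercise: a small number of manufactured lots of a candidate
("test") and of the licensed originator ("reference") are measured on a
panel of continuous quality attributes, each attribute is assigned a
criticality-driven tier, and each tier has its own comparison rule. This
vignette records the model, every tunable constant, and the design choices
made where the conventions of the field leave the details open.

## Criticality: risk ranking and filtering

Each (attribute, assay) pair carries an ordinal *impact* score and an
ordinal *uncertainty* score; their product is the risk score. The package
defaults to the widely used ordinal scales impact $\{2, 4, 12, 16, 20\}$ and
uncertainty $\{1, 2, 3, 5, 7\}$, giving scores from 2 to 140. Scores are
ranked High ($\ge 40$), Moderate ($\ge 16$) or Low, and an attribute is a
CQA when its score reaches the cutoff (default 40) or when it is on the
mandatory-CQA list. All of these are configuration (`default_config()`),
because published panels typically print ranks, not scores: the bundled
adalimumab panel therefore stores impact/uncertainty pairs chosen to
reproduce its published ranks through the default cut-points, and should be
read as a worked configuration, not as published scoring data.

The mandatory-CQA list (defaults: residual DNA, host-cell protein,
protein A) reflects standard practice of treating process-related
impurities as critical on toxicity/immunogenicity grounds even when their
uncertainty score is low.

## Tier assignment

The rule, applied in order to each (attribute, assay) row:

1. tier 1 iff the readout directly reflects the primary mechanism of action
   (`moa_direct`) — for an anti-TNFα antibody, soluble-TNFα binding and
   neutralization;
2. an explicit (attribute, assay, tier) override, if configured;
3. tier 2 iff High/Moderate risk rank *and* a quantitative readout *and*
   neither a qualitative assay nor a trace-level analyte;
4. tier 3 otherwise, annotated `star` for qualitative assays and `hash` for
   trace analytes (these annotations mark attributes demoted to tier 3 for
   assay-nature reasons despite High/Moderate rank).

Tiers attach to (attribute, assay) pairs, not attributes: the same attribute
measured by two methods (e.g. aggregates by SEC-UV and by SEC-MALS) may
legitimately land in different tiers, and the package makes no attempt to
reconcile them — published panels do not state a reconciliation rule either.
The override table exists because published panels contain assignments the
general rule cannot produce (the bundled panel's sub-micron/sub-visible
particle rows are Moderate-risk quantitative assays placed in tier 3 with no
footnote); we carry such rows as explicit configuration rather than invent a
rule the source does not state.

## Tier-1: two one-sided tests

For test lots $x_1,\dots,x_{n_T}$ and reference lots $y_1,\dots,y_{n_R}$,
the TOST at one-sided size $\alpha$ is executed through the equivalent
two-sided $100(1-2\alpha)\%$ interval for $\mu_T-\mu_R$:

$$\bar x - \bar y \pm t_{1-\alpha,\nu}\; \mathrm{SE},$$

passing iff the interval lies strictly inside $(-k_1 s_R, +k_1 s_R)$ with
defaults $k_1 = 1.5$, $\alpha = 0.05$ (the "90% CI within $\pm 1.5$ SD"
rule). Margins are always anchored to the reference sample SD $s_R$, never
to pooled or test variability: the margin is meant to describe the
originator's own batch-to-batch process spread.

The interval construction is not fixed by convention, so both are offered:
the default is the Welch construction ($\mathrm{SE}^2 = s_T^2/n_T +
s_R^2/n_R$, Satterthwaite degrees of freedom), which protects against the
unequal variances that routinely arise between two different manufacturing
processes; `variance_mode = "pooled"` gives the classical equal-variance
interval for guideline-style comparisons. The two coincide exactly when the
arms share lot count and sample variance.

Preconditions are enforced, not patched: fewer than 3 lots per arm or
$s_R = 0$ is an error (a zero-SD reference makes the margin degenerate).

## Tier-2: quality range

The range is $\bar y \pm k_2 s_R$ (default $k_2 = 3$); membership of test
lots is counted on the *closed* interval, and the attribute passes when
`fraction_inside >= pass_fraction` with default 0.9, applied exactly: with
6 test lots, 5/6 ≈ 0.833 fails — the literal reading of the 90%-of-lots rule
at small lot counts. Impurity-style attributes bounded above only can use
`sidedness = "upper"`, i.e. $(-\infty, \bar y + k_2 s_R]$.

## Tier-3: descriptive comparison

Visual side-by-side comparison is not reproducible, so tier 3 reports a
numeric descriptor: the overlap of the observed lot ranges (intersection
length over union length, in $[0,1]$; defined as 1 when both ranges collapse
to the same point) and a categorical flag — `lower`/`higher` only when the
ranges are strictly disjoint, `similar` otherwise (touching ranges count as
overlap). Disjointness of observed ranges is a deliberately conservative
trigger: it flags exactly the situations where every lot of one product sits
outside everything observed for the other.

## Operating characteristics

`simulate_pass_rate()` draws lot sets from normal (or, for impurity-like
attributes, lognormal parameterized by natural-scale mean/SD) distributions
and applies the tier-1 or tier-2 procedure. The normal default reflects the
assumption already implicit in SD-based margins and ranges: near-normal
batch variation around a process mean.

Seed policy: replicate $i$ of a scenario with root seed $s$ draws under
`set.seed(s + i)`, test lots first, then reference. This makes pass-rate
estimates bit-reproducible, lets scenarios at a common root share replicate
streams (power curves at different shifts are positively coupled, and a
duplicated shift reproduces its row exactly), and is simple enough for an
independent implementation to reproduce the decisions. Replicates in which
the procedure is degenerate (e.g. a zero reference SD, impossible under
continuous draws but possible for user-supplied discrete-valued
distributions in future extensions) count as failures and are tallied in
`n_degenerate`.

Two properties of the tier-1 procedure, both visible through this module and
checked in the test suite, deserve emphasis:

- **Equal products often fail at realistic lot counts.** At $n_T = 6$,
  $n_R = 10$, $k_1 = 1.5$, $\alpha = 0.05$, the pass rate under *identical*
  products is only about 0.63: the 90% interval is wide relative to a margin
  of 1.5 estimated SDs. This is a property of the design, not of the
  implementation, and is the reason the package's bundled scenario rests its
  "equal products pass" expectations on tier-2/3 attributes.
- **Size at the margin.** With the margin *estimated* as $1.5 s_R$, the
  probability of passing when the true shift equals the true margin does not
  converge to $\alpha$: margin-estimation noise is of the same order as the
  mean-difference noise, and the limit is $\approx 0.09$ for equal arms at
  any $n$. The scenario option `margin_mode = "known"` fixes the margin at
  $k_1 \sigma_R$ and recovers the textbook size $\le \alpha$; the test suite
  checks this at $n = 200$ per arm.

Problem sizes used in the shipped tests and acceptance script — 100 pipeline
runs of the 6-vs-10 scenario, 1000 randomized oracle-agreement cases, 2000
replicates for coverage and size checks — were chosen to put Monte-Carlo
standard errors near or below 1 percentage point for the quantities checked.

## The synthetic generator and the bundled scenario

`generate_lots()` draws independent per-attribute lot values with
deterministic lot identifiers (`T01…`, `R01…`) shared across attributes
within a product. It emulates the first-order structure the similarity
procedures consume — per-product means and batch-to-batch SDs — and
deliberately nothing else: no between-attribute correlation (real glycan
fractions co-vary, since they share a denominator), no assay measurement
error distinct from batch variation, no drift over manufacturing campaigns.
Passing tests on this generator therefore validate the decision rules and
their operating characteristics, not the realism of any one dataset.

`glycan_scenario()` encodes the package's worked comparison: five N-glycan
relative-abundance attributes on 6 test and 10 reference lots, with the
candidate's high-mannose fraction (means 2.5% vs 8.0%) clearly below the
reference and the other attributes in agreement (afucosylation is generated
with identical means). Published lot summaries report means and min–max
ranges but not per-lot values, so generating SDs are reconstructed as
range/4 — the range of 6–10 near-normal draws spans roughly 3–4 SDs. This is
a documented approximation with a visible limitation: for the
galactosylation attribute the reference range is wide and asymmetric around
its mean (16.3–22.7 around 18.1), which no normal model with SD ≈ range/4
reproduces; regenerated test and reference ranges are then disjoint at many
seeds and the attribute is flagged `higher` even though the source ranges
overlap. We kept the simple, stated heuristic rather than tuning
per-attribute SDs: the scenario's checked claims (%HM flagged `lower`,
equal-mean attributes passing) are robust to it, and the galactosylation
behaviour is itself a useful illustration of why range-reconstructed
fixtures are never ground truth. Generated values keep full precision
internally; `write_lot_table()` can round to each attribute's reporting
precision (0.1 for the glycan percentages) on output.

## Numerical and interface conventions

- Sample SDs use the $n-1$ denominator throughout; the SD of a single lot
  is reported as 0 (a one-point sample shows no spread) — relevant only to
  display summaries, since the procedures require 3+ lots.
- Boundary conventions are fixed and tested: TOST passes on *strict*
  inclusion of the interval in the open margin interval; quality-range
  membership is *closed*; tier-3 `lower`/`higher` require *strict*
  disjointness.
- Units are opaque strings compared for equality only; each attribute must
  be reported in a single unit, and values are never converted or imputed —
  malformed rows are errors naming the row.
- The CSV report echoes the configuration in commented header lines, and
  the markdown report renders `mean (min–max)` cells; both carry identical
  decision content, which the suite verifies by parsing the CSV back.
- Configuration precedence for the command line is flags over JSON config
  over package defaults.

## Limitations

Beyond the generator simplifications above: the pipeline applies no
multiplicity adjustment across attributes (none is conventional in this
setting); tier-1 power for small lot counts is modest by construction, and
no small-sample margin correction for estimating $s_R$ from few lots is
applied — the Welch/pooled choice and the margin multiplier are exposed so
users can study these effects with the OC module rather than have a
correction imposed; and the criticality stage scores nothing itself — impact
and uncertainty are inputs, the package only ranks, filters and tiers them.
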