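---
title: "Scanning dated phylogenies for clade-wise temporal signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning dated phylogenies for clade-wise temporal signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladeclock)
```

## The model and its assumptions

Let a rooted phylogeny have branch lengths in expected substitutions per
site (e.g. a maximum-likelihood tree), and let every tip $i$ carry a
sampling date $t_i$ in decimal years. For any internal node $v$, write
$d_i(v)$ for the path length from $v$ to descendant tip $i$. Under a
strict molecular clock with rate $\beta$ inside the clade of $v$,

$$ d_i(v) = \beta\,(t_i - t_v) + \varepsilon_i
         = \beta t_i + \alpha + \varepsilon_i, \qquad \alpha = -\beta t_v ,$$

so the ordinary least-squares fit of distance on date estimates the
substitution rate as its slope, the node's own date as its x-intercept
$-\alpha/\beta$, and quantifies clock-likeness through $R^2$. `cladeclock`
fits this regression at *every* internal node (root included) and flags a
node as carrying temporal signal when the slope is positive and the slope
t-test p-value is at most $\alpha_{\text{sig}}$ (default 0.05).

Assumptions worth keeping in mind:

* branch lengths are genetic distances, **not** time — a chronogram input
  is meaningless here and is out of scope;
* the tree's rooting is taken as given; no best-fitting-root search is
  performed;
* the per-tip points share phylogenetic ancestry and are therefore not
  independent. The t-test p-value is anti-conservative, and the scan tests
  many nested nodes. This is an exploration and triage tool: confirm any
  candidate clade with a date-randomization test or Bayesian model
  comparison before tip-dating it.

## Eligibility rules

A node is only regressed when the fit can be meaningful:

1. it is the parent of at least 3 tips (`min_tips`);
2. there are at least 3 distinct (date, distance) combinations
   (`min_distinct_combos`) — duplicated points carry no extra geometry;
3. there are at least 2 different sampling dates (`min_distinct_dates`).

The conditions are checked in this order and the first failure is
reported. Distinct-pair comparison is exact float equality by default;
`combo_tolerance` merges near-duplicates for trees serialised at truncated
precision.

## The fit and its numerical conventions

The regression is computed from centred sums ($S_{xx}$, $S_{xy}$), with
$\mathrm{SSE}$ from explicit residuals, $\text{adj}\,R^2 = 1-(1-R^2)
\frac{n-1}{n-2}$, and the p-value from Student's t with $n-2$ degrees of
freedom (two-sided by default; a one-sided option exists since the
significance rule already demands a positive slope, and the two
conventions differ only by the factor 2 on p). Degenerate cases return
defined values instead of NaNs:

* perfect fit ($\mathrm{SSE}=0$): $p = 0$, $\text{adj}\,R^2 = 1$;
* constant distances ($\mathrm{SStot}=0$): slope $0$, $p = 1$,
  $\text{adj}\,R^2 = 0$, no x-intercept — this is exactly what a
  zero-rate clade produces;
* all dates equal cannot be reached past eligibility and raises a
  defensive error.

On exactly-linear data built in floating point, SSE is a rounding residue
(~$10^{-30}$) rather than literal zero; everything downstream treats such
fits as perfect where it matters (outlier flagging), and p-values underflow
to numbers like $10^{-130}$ that are zero for any practical purpose.

**Distance origin.** Distances are measured from the focal node, not the
global root. The two conventions differ by a constant per clade, which
changes nothing about slope, p, or $R^2$ (an invariance the test suite
asserts explicitly) but makes the x-intercept estimate the focal node's own
date rather than a quantity entangled with the node's depth. When comparing
x-intercepts against tools that measure from the global root, account for
this.

**Multiple testing.** None by default, matching the tool's exploratory
framing; `correction = "benjamini-hochberg"` applies BH across all
eligible nodes before flagging.

## Outlier flagging

Tips that deviate grossly from the regression line (misdated samples,
contamination, assembly problems) are conventionally identified by eye.
`residual_outliers()` operationalises this: a tip is flagged when its
*externally* studentized residual (the leave-one-out t-statistic, using
leverage $h_i = 1/n + (x_i-\bar x)^2/S_{xx}$) exceeds $k = 3$. Internally
studentized residuals are bounded by $\sqrt{n-2}$, so a fixed cutoff of 3
would be unreachable for clades of up to 11 tips — the external variant is
the one that scales to small clades. Below 4 points studentization is
meaningless and nothing is flagged.

## What the simulator emulates — and what it does not

`simulate_clock_tree()` generates the study conditions the scan is
validated against: a rooted binary topology from recursive uniform random
splits of the tip set; tip dates uniform in a sampling window (default
20 years ending 30 years after the root, with the default rate $10^{-3}$
substitutions/site/year — the regime of a fast-evolving RNA virus sampled
over decades, comparable to a hantavirus dataset spanning 1984–2016);
internal-node dates placed uniformly between parent and earliest
descendant tip; branch lengths equal to rate × elapsed time. Noise is
applied to branch lengths, either additive gaussian (clamped at zero) or
multiplicative gamma with mean one; `rate_map` assigns one rate per
root-child subtree to emulate clade-heterogeneous signal, including a
zero-rate (non-evolving) clade.

The generator deliberately does **not** emulate: rate variation *within* a
clade, coalescent or epidemic topologies, sequence-level evolution
(alignments in the tests are drawn i.i.d. per column), phylogenetic error
in branch-length estimation, or sampling biases. Passing tests therefore
demonstrate the scan's *algorithmic* correctness — exact recovery under
the model's own assumptions, graceful degradation under branch noise — not
robustness to the full messiness of empirical trees.

Problem sizes used by the suite and the acceptance script (10–200 tips,
200 noisy replicates, 1000 permutations) were chosen as the smallest sizes
at which the stochastic properties are stable; all are seeded.

## Design choices on open points

* **Date field default**: the last `"_"`-delimited token of the tip label;
  delimiter, field index (negative = from the end) and a regex capture
  are configurable, because no universal labelling convention exists.
  Calendar dates are not parsed from labels; `as_decimal_year()` converts
  `YYYY-MM-DD` to `year + (day − 0.5)/days_in_year` when needed.
* **Undated tips** abort by default, with pruning (`on_missing =
  "prune"`) as an explicit opt-in; pruning merges the parent edge so all
  remaining patristic distances are untouched.
* **Rootedness**: any root with ≥ 2 children is accepted; a basal
  polytomy draws a warning (the rooting may be arbitrary) but not an
  error, since rejecting it would refuse legitimate ML trees.
* **Zero-length branches** are legal (ML trees produce them); negative
  lengths are a hard error.
* **Variant sites**: a column counts as variant when ≥ 2 distinct
  unambiguous nucleotides (A/C/G/T after case-folding, U→T) occur among
  the clade's records; gaps and IUPAC ambiguity codes are ignored so
  missing data cannot fabricate variation, with `gap_as_state = TRUE` as
  the opt-out. Variant columns are computed *within the clade* — the only
  reading under which the extracted dataset reflects the clade's own
  polymorphism.
* **Node addressing**: node ids are deterministic preorder indices (root
  = 1, children in file order), stable across re-reads of the same file;
  the annotated Nexus additionally carries each node's lexicographically
  smallest descendant tip label as a renumbering-proof anchor.
* **Serialisation**: every float is written in shortest round-trip form,
  so re-reading any output reproduces the values bit-for-bit and repeated
  runs are byte-identical.

## Known limitations

The p-values are not calibrated for phylogenetic dependence (under
permuted-date nulls the realised false-positive rate runs slightly above
nominal — the suite bounds it at 8% for α = 5%). Nested nodes are strongly
correlated, so counts of significant nodes must not be read as independent
discoveries. X-intercept estimates for shallow nodes with short sampling
spans are extrapolations and can be wildly unstable even when the slope is
significant.
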