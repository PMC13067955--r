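---
title: "Shape-based mining of bacterial growth curves: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-based mining of bacterial growth curves: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

High-throughput microplate screens of knockout libraries produce tens of
thousands of OD600 growth curves. Classical analysis compresses each curve
into a handful of fitted parameters (lag, maximum rate, carrying capacity)
from a logistic or Gompertz model. That compression fails exactly where the
biology is most interesting: flat, delayed, multiphasic or otherwise
aberrant trajectories are not S-shaped, and rigid parametric fits either do
not converge or return misleading values that scatter non-growing strains
among normal ones. `growthshape` instead clusters curves directly on their
shape, using alignment-based time-series distances, and then asks which
gene functional categories concentrate in which shape class.

# The distance model

Two complementary distances are combined.

**DTW** on the raw OD trace. Dynamic time warping aligns two series with a
monotone warping path and scores the unnormalized sum of local costs
$|a_i - b_j|$ over the path (steps diagonal/up/right, no window, no
endpoint relaxation). It is sensitive to absolute OD levels but, when
unconstrained, invariant to pure time shifts: a many-to-one match of equal
values is free. The default DTW engine is a multiresolution approximation
in the fastdtw family (coarsen by pairwise averaging, solve, project the
path, refine within a `radius` of it; default radius 1). The approximation
is deterministic, always an upper bound on the exact distance, and equal to
it once `radius` reaches the sequence length.

**DDTW** on the slope sequence. Each curve is first mapped to approximate
derivatives
$$d_i = \frac{(x_i - x_{i-1}) + (x_{i+1} - x_{i-1})/2}{2},$$
the mean of a backward and a central difference, in OD per time step.
Interior points use the formula; endpoints replicate their neighbour
(`d_1 = d_2`, `d_n = d_{n-1}`), a convention chosen because the transform
is only defined for interior points — a `drop` alternative is exposed.
DTW on these sequences ignores absolute level entirely
(`ddtw(x, x + c) = 0`) and scores slope-profile similarity. DDTW uses the
exact full dynamic program by default: derivative sequences are small in
magnitude and the banded approximation would add error where precision
matters most.

Because DDTW magnitudes are far smaller than DTW magnitudes, the DDTW
matrix is rescaled by the ratio of off-diagonal means
(`scale = mean(DTW) / mean(DDTW)`) before mixing. The scale is a property
of each data set and is always recomputed; on smooth, low-noise data it can
reach the thousands, while noisy synthetic data give much smaller values.
The combined distance is
$$d_\alpha(X, Y) = (1-\alpha)\,\mathrm{DTW}(X,Y) +
  \alpha\,\mathrm{scale}\cdot\mathrm{DDTW}(X,Y), \qquad \alpha \in [0,1],$$
linear in $\alpha$ with the two pure matrices at the endpoints.

# Preprocessing

Curves should end at comparable growth phases. The stationary plateau is
located as the 5-point window with the highest mean OD (ties resolved to
the earliest window, so the *first* plateau of a multiphasic curve wins),
and everything more than 5 points past that window is truncated. Earlier
dynamics, including diauxic shifts, are untouched. Viability filtering
rejects curves whose plateau mean rises less than `min_rise` (default 0.1
OD) above the first three readings (`no_growth`), and curves still rising
at the end of the record — tail slope above `tail_slope_eps` (default 0.02
OD/h) with the plateau window at the very end (`no_plateau`). The two
thresholds have no canonical values in the literature; both are exposed
and logged, and every per-curve decision is kept in the report rather than
silently dropped.

# Replicate-variance cleaning

For each strain the within-replicate pairwise DTW and DDTW distances are
pooled across the whole data set, and the `q`-quantiles (default `q` =
0.25, i.e. the top quarter most similar pairs) define similarity
thresholds, using type-7 linear interpolation between order statistics and
a strict `<` comparison. A curve is retained when it belongs to at least
one pair that passes **both** thresholds simultaneously (`pair_mode =
"joint"`); the laxer reading — some pair passes DTW, some possibly
different pair passes DDTW — is implemented as `"independent"` because the
two descriptions are genuinely ambiguous in prose, and the joint rule is
the default. Because all thresholds come from one pooled pre-cleaning
distribution, retained sets are exactly nested across `q`, which the
sensitivity scan asserts and exploits.

# Clustering and model selection

Clustering is hierarchical with average linkage (UPGMA) on the combined
matrix, cut into exactly `n` flat clusters; cluster ids are renumbered by
decreasing size so cluster 0 is always the dominant (baseline) group.
UPGMA is deliberate: centroid-based methods fragment the large baseline
cluster that dominates knockout screens, while average linkage preserves
it and peels off genuine defects.

Two selection rules pick $(\alpha^\*, n^\*)$ over a grid (default
$\alpha = 0, 0.1, \dots, 1$; $n = 2 \dots 100$):

* **Reverse elbow (statistics only).** The mean silhouette (computed
  directly from the distance matrix; members of singleton clusters
  contribute 0, a convention that matters at large `n` and is therefore
  stated) declines as `n` grows; the sharpest single-step drop
  $\mathrm{SC}(\alpha, n{+}1) - \mathrm{SC}(\alpha, n)$ marks the knee and
  the `n` just before it is selected. Ties (within 1e-12, so floating-point
  dust cannot decide them) go to the smaller `n`, then the smaller
  $\alpha$; all per-$\alpha$ best drops are returned ranked because real
  grids often show two defensible optima. A medoid-based Davies–Bouldin
  index is provided as a second opinion; with only distances available the
  centroid is replaced by the medoid and scatter by the mean distance to
  it.

* **Replicate coherence.** For every grid cell the number of curves whose
  replicate group spans more than one cluster is counted (every member of
  a split group counts). The selected cell has the largest `n` among those
  at the minimum split count (within `tolerance`), with ties preferring
  $\alpha$ closest to 0.5 and then the smaller $\alpha$. Selection uses
  the raw counts: the 3-point moving average along `n` that is reported as
  the "mean frequency" would average a sharp onset into the last split-free
  `n` and systematically exclude it, so it describes but does not decide.
  Under exactly zero replicate noise every cell is split-free and the rule
  degenerates to `max(n)` by construction — the rule is informative only
  when replicates carry noise.

An external reference curve (e.g. wild type) is projected onto a finished
clustering by assigning it to the cluster with the smallest mean combined
distance to its members — the assignment consistent with average linkage —
with ties to the lower cluster id.

# Enrichment

For a selection of $n$ genes from a universe of $N$ (the genes present in
the analyzed collection, not the whole genome), a category with $K$
members in the universe and $k$ in the selection is scored by the
hypergeometric distribution
$$P(X = k) = \frac{\binom{K}{k}\binom{N-K}{n-k}}{\binom{N}{n}}.$$
Both one-sided tails are computed — over-representation $P(X \ge k)$ and
under-representation $P(X \le k)$ — and the tail matching the fold change
$(k/n)/(K/N)$ is reported with its sign (`+` iff FC > 1; exact ties count
as `-`). Benjamini–Hochberg adjustment runs across the tested categories
at FDR 0.05. Categories with at most `min_category` (default 10) genes in
the universe are excluded *before* correction; this mirrors common
screening practice but is statistically non-standard — excluding
hypotheses after seeing the data they would be tested on inflates apparent
power — so it is a documented, adjustable choice. A two-tailed Fisher
exact option covers GO-style analyses. Cleaning enrichment reuses the same
machinery with the cleaned gene set as selection and the pre-cleaning set
as universe, so preferential retention surfaces as `+` and preferential
removal as `-`.

# The parametric baseline

`parametric_baseline()` reproduces the conventional pipeline the shape
method is designed to replace: least-squares fits of the reparameterized
Gompertz ($K e^{-e^{\mu e/K(\lambda - t)+1}}$) and logistic
($K/(1+e^{-\mu(t-t_0)})$) forms with data-derived starting values, model
choice by AIC, and K-means (fixed seed, 10 restarts) on the fitted
(rate, capacity) pairs. Fits that fail to converge — the expected outcome
on flat trajectories — are flagged and fall back to their starting values,
as naive parameter pipelines effectively do. On mixtures containing flat
curves this baseline reliably misassigns some non-growers into
grower-dominated clusters, while the shape pipeline separates them
cleanly; the acceptance suite asserts exactly this contrast.

# The synthetic generator

`simulate_collection()` emulates a knockout screen at desk scale: 150
strains × 3 replicates, 0.25 h sampling over 24 h (96 points), four shape
classes with probabilities 0.70 / 0.15 / 0.10 / 0.05:

| class | lag $\lambda$ (h) | max rate $\mu$ (OD/h) | amplitude $A$ (OD) |
|---|---|---|---|
| normal | N(2, 0.5) | N(0.70, 0.08) | N(0.85, 0.05) |
| long_lag | N(15, 1.0) | N(0.70, 0.08) | N(0.70, 0.05) |
| no_growth | — | drift U(0, 0.002) OD/h | — |
| low_capacity | N(2.5, 0.5) | N(0.35, 0.05) | N(0.30, 0.04) |

Baselines are U(0.05, 0.08). Replicate noise is multiplicative (sd 0.02),
additive (sd 0.005), and a per-replicate lag jitter (sd 0.25 h); noise
touches OD only, never time, because plate readers sample on a fixed
clock. A diauxic class (two stacked Gompertz terms) exists to exercise the
truncation rule but is off by default.

Three generator choices deserve their rationale:

* **Long-lag curves have reduced within-window amplitude** (0.70 vs 0.85).
  A class differing from normal *only* by lag would be mathematically
  invisible to unconstrained DTW and DDTW — warping absorbs a pure time
  shift at zero cost — so no distance-based method could separate it and
  the classes would not be "well separated" in any operative sense.
  Biologically, severely delayed growers in minimal medium do show lower
  biomass within a fixed observation window.
* **Non-growing wells drift slightly** (up to 0.002 OD/h) instead of being
  perfectly flat: background condensation and instrument drift make real
  dead wells noisy ramps, and this is what makes parametric fits to them
  treacherous.
* **The planted enrichment factor is the realized fold change.** With
  background category rate $r_0 = 1/\#\text{categories}$ and target-class
  fraction $\pi$, genes of the target class draw the planted category at
  rate $f r_0 (1-\pi)/(1-\pi f)$, which makes the category's frequency in
  the class $f$ times its frequency in the *whole* universe (inclusive of
  the planted excess) — the same quantity the enrichment table reports as
  FC. Defining the factor on the raw draw weight instead would dilute a
  nominal 3× plant to a realized ~1.9× and silently starve power studies.

What the generator does **not** emulate: plate-edge and well-position
effects, death phases, correlated (smooth) noise, batch effects between
replicate days, OD nonlinearity at high density, and the heavy tail of
irreproducible curves seen in real screens. Passing tests on this
generator therefore demonstrate correctness of the machinery and adequate
statistical behaviour under idealized noise, not performance on any
particular laboratory data set.

# Numerical choices and degenerate inputs

* Quantiles: type 7 (linear interpolation); documented because printed
  thresholds depend on the convention.
* Strict `<` at cleaning thresholds.
* Max-OD window ties → earliest start; medoid ties → lowest replicate
  index; projection ties → lower cluster id; equal-size clusters keep
  dendrogram order when renumbered by size.
* An all-zero DDTW matrix (curves identical up to offsets) makes the scale
  undefined; the error message advises $\alpha = 0$.
* Coincident points with $a = b = 0$ contribute 0 to the silhouette.
* `dtw_fast` windows are repaired after projection to guarantee a feasible
  monotone corridor, so the approximation is defined for every input and
  never below the exact distance.
* Time grids must be uniform to 1e-6 h; wide-format files may pad shorter
  curves with trailing blanks, but interior gaps are an error.

# Problem sizes used in validation

The test and acceptance suites run entirely on the generator: 150 × 3
curves for class recovery and model selection, 600 strains for enrichment
power (the scale at which a 3× plant is comfortably detectable), 100
planted seeds and hundreds of null replicates for power and FDR
calibration, and small constructed fixtures for every hand-checkable
formula. These sizes were chosen as the smallest at which each property is
statistically meaningful.

# Interfaces

The package surface is the set of exported functions;
`run_statistical_mode()` and `run_replicate_mode()` orchestrate the full
pipelines and can serialize labels, grids, enrichment tables (TSV) and a
JSON run manifest via `out_dir`. A shell entry point is intentionally not
shipped: the intended users work in R, and the two runner functions are
the command surface.

# Known limitations

DTW-based distances are not metrics (no triangle inequality), so no
metric-tree speedups apply and the full pairwise matrix is quadratic —
the practical ceiling is a few thousand curves per run on one core.
Unconstrained alignment cannot distinguish trajectories that differ only
by timing; lag-phase structure enters through value differences and the
banded DTW engine, not through the warp itself. The reverse-elbow rule
operationalizes a qualitative knee heuristic and can legitimately surface
several candidate optima; inspect the ranked list rather than trusting the
single winner. The `min_category` pre-filter and the excluded-before-FDR
convention follow screening practice, not statistical orthodoxy.
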