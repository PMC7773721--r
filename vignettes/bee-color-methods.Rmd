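---
title: "Floral color signaling through bee eyes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Floral color signaling through bee eyes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Flower-visiting bees have phylogenetically conserved trichromatic vision,
with photoreceptors peaking in the ultraviolet, blue and green. How a flora's
color signals look *to bees* — how diverse they are, whether co-flowering
species converge or diverge in color, and how strongly color tracks the
plant phylogeny — is analyzed by mapping reflectance spectra into the
hexagon color space of hymenopteran vision and then applying community
ecology and comparative methods to the resulting loci. This package
implements that pipeline end to end, together with a synthetic-study
generator so every stage can be exercised and validated without field data.

# The color model

## From spectrum to locus

A species' stimulus is its reflectance spectrum $R(\lambda)$ on
$300\text{–}700$ nm. For each receptor $i$ with spectral sensitivity
$S_i(\lambda)$ and illuminant photon flux $I(\lambda)$, the quantum catch is

$$P_i = \int_{300}^{700} R(\lambda)\, S_i(\lambda)\, I(\lambda)\, d\lambda ,$$

evaluated by the trapezoidal rule on a common 1-nm grid (401 points; the
finest resolution typical spectrometer exports provide, making residual
quadrature error negligible). Receptors adapt to the leaf-green background
(von Kries): the relative catch is $q_i = P_i / P_i^{\mathrm{bg}}$, where
$P_i^{\mathrm{bg}}$ uses the pointwise mean of the measured leaf spectra.
The bounded excitation is

$$E_i = \frac{q_i}{q_i + 1} \in [0, 1),$$

so the background itself sits at $E_i = 1/2$ exactly. The hexagon locus is

$$x = \frac{\sqrt{3}}{2}\,(E_g - E_u), \qquad
  y = E_b - \frac{E_u + E_g}{2},$$

with hue $\theta = \operatorname{atan2}(y, x)$ mapped to $[0, 360)$ degrees
and chromatic contrast $r = \sqrt{x^2 + y^2} \le 1$. Because the $q_i$ are
ratios, multiplying the illuminant by any positive constant leaves the locus
unchanged — a property the test suite asserts directly.

## Receptors and illuminant

Bee receptor peaks default to 350, 440 and 540 nm. Only the peaks are
constrained by the bee-vision literature consumed here, so the full curves
come from the Govardovskii A1 visual-pigment nomogram (alpha plus beta
band), the standard template in bee color modeling, peak-normalized to 1.
The illuminant is the CIE D65 relative spectral power table (300–700 nm at
5 nm, linearly interpolated) multiplied by wavelength — insect
photoreceptors count photons, not energy — and normalized to a maximum of 1
(the normalization is cosmetic given scale invariance).

## Sectors and descriptors

The hexagon is tiled into six 60° wedges centered on the receptor and
blended vertices: BG at 30°, B at 90°, UB at 150°, UV at 210°, UG at 270°,
G at 330°. Wedges are half-open $[v-30, v+30)$, so a boundary hue belongs
deterministically to the higher wedge. The absolute angular origin is a
convention; this orientation puts the bee-preference window (bee-blue plus
bee-blue-green) at 30°–90° and sends UV-absorbing white flowers into BG and
UV-reflecting yellows into UG, matching the "White Arm"/"Yellow Arm"
pattern reported for island and continental floras. The achromatic point
($r = 0$) has no defined hue; it reports $\theta = 0$ by convention, an NA
sector, and is excluded from angular statistics.

Spectral **marker points** — wavelengths of steepest spectral transition,
classically compared with pollinator receptor tuning — are detected as the
steepest point of each contiguous region where the smoothed absolute slope
exceeds 20% of its maximum (centered moving average, default window 11 nm).
The region entry threshold uses hysteresis (exit at half the entry level)
so instrument noise at a region's edges cannot split one transition into
several. A constant spectrum yields an empty marker list, not an error.

# Community statistics

## Color diversity

Floral color diversity of a species set is the area of the minimum convex
polygon (convex hull) of its loci, in hexagon squared units; $n < 3$ or
collinear sets (cross-product tolerance $10^{-12}$) have area 0, and the
full hexagon bounds the value at $3\sqrt{3}/2$. Because hull area grows
with sample size, groups of unequal richness are compared by rarefaction:
`reps = 1000` subsamples of `n_sub` (default: the smallest group size)
drawn without replacement, summarized by 2.5/50/97.5% quantiles. Two groups
are declared separated when their central 95% intervals do not overlap — an
explicit rule chosen here, since interval overlap is the conventional
reading of such resampling controls.

## Assembly null models

Color assembly is tested by comparing a community's mean pairwise color
distance (MPD) with a null distribution from drawing the same number of
species uniformly without replacement from the pooled species list
("richness" randomization, no abundance weighting), 1,000 draws by default.
Phylogenetic structure applies the same machinery to cophenetic (tree-path)
distances, adding mean nearest taxon distance (MNTD), which is sensitive to
clustering near the tips. Results report the observed statistic, null mean
and SD, SES, and the lower-tail rank probability

$$p = \min\!\left(1, \frac{\#\{\text{null} \le \text{observed}\} + 1}{\text{reps} + 1}\right),$$

so small $p$ indicates clustering and large $p$ overdispersion. Ties count
fully toward the lower tail (within $10^{-12}$): this makes the degenerate
case (community = pool, all nulls equal the observed value) report $p = 1$
rather than an arbitrary mid-rank value, and add-one smoothing keeps
$p > 0$. Pollinator-class subsets are tested against the *unchanged* full
pool, which is why their null means coincide with the parent groups'.

## Phylogenetic signal

Blomberg's $K$ measures whether trait variance partitions on the tree as
Brownian motion predicts. With phylogenetic covariance $V$ (shared
root-to-MRCA path lengths) and GLS root estimate
$\hat a = (1^\top V^{-1} 1)^{-1} 1^\top V^{-1} x$:

$$K = \frac{\mathrm{MSE}_0 / \mathrm{MSE}}
           {\left[\mathrm{tr}(V) - n / (1^\top V^{-1} 1)\right] / (n - 1)},
\qquad
\mathrm{MSE}_0 = \frac{(x-\hat a)^\top (x-\hat a)}{n-1}, \quad
\mathrm{MSE} = \frac{(x-\hat a)^\top V^{-1} (x-\hat a)}{n-1}.$$

$K = 1$ on a star tree for any non-constant trait (asserted to $10^{-10}$),
and $K$ is invariant to affine trait transforms. Significance comes from
permuting trait values across tips and ranking the phylogenetically
corrected error: $p_K = (\#\{\mathrm{MSE}_{\text{perm}} \le
\mathrm{MSE}_{\text{obs}}\} + 1)/(\text{reps}+1)$, with 999 permutations by
default (the community convention; every permutation stage requires an
explicit seed). Trees with zero-length cherries make $V$ singular; an
optional ridge ($10^{-8}$ on the diagonal, off by default) handles trees
with unresolved polytomies resolved into zero-length edges.

The Mantel test correlates (Pearson) the lower triangles of the color and
cophenetic distance matrices, permuting rows and columns of the *color*
matrix jointly — the tree structure is held fixed — with a one-tailed
(positive association) add-one-smoothed p. Hue is treated as a linear
variable in degrees, as is conventional in this literature even though hue
is circular; the 2-D Mantel test on $(x, y)$ distances is free of that
artifact and is reported alongside $K$ per group. Groups with fewer than
three members yield flagged degenerate rows (NA statistics) rather than
errors, so one small group cannot abort a study-wide table.

# The synthetic-study generator

The generator exists so that every stage has inputs with known structure.
Flower spectra are logistic steps
$R(\lambda) = \text{plateau}/(1 + e^{-(\lambda - \text{mid})/\text{width}})$
plus an optional Gaussian band, plus Gaussian measurement noise
(sd 0.01), clipped to $[0, 1]$:

| archetype | plateau | mid (nm) | band | characteristic sector |
|---|---|---|---|---|
| white_uv_absorbing | 0.80 | 400 | — | BG |
| yellow_uv_absent | 0.90 | 500 | — | BG/G boundary region |
| yellow_uv_present | 0.90 | 500 | +0.35 at 350 nm | UG |
| blue | 0.06 | 660 | +0.55 at 445 nm | B |
| purple | 0.45 | 620 | +0.50 at 430 nm | B/UB |
| red_long | 0.70 | 600 | — | G |

Leaves are a 0.05 baseline with a 0.12 Gaussian peak at 550 nm. The
archetype-to-sector mapping is itself a tested property (≥ 95% of draws at
default noise).

The default study (`gen_study_config()`) is a 160-species pool with
archetype weights 0.45/0.08/0.15/0.14/0.10/0.08 (white dominant,
UV-reflecting yellow second — the composition that produces the blue-green
"White Arm" peak seen in bee-pollinated floras), a Yule phylogeny
(`ape::rphylo`, birth rate 1, death 0), ten leaf spectra, and three
altitude communities partitioning the pool: a middle group of 45 clustered
in color space around a blue-green-arm focal, a high group of 45 drawn at
random from the smallest clade that can hold it (phylogenetically clustered
toward the tips while keeping the pool's color composition — altitude
specialization of lineages, not of color), and a low group of 70, the
random remainder and the largest group, as in mountain floras. Per-species
realism comes from jittering archetype parameters (mid ± 8 nm, width ± 3,
plateau ± 0.05, band amplitude ± 0.05, band center ± 5 nm at `jitter = 1`).

Community structures are constructed, not hoped for: `clustered` takes a
focal species plus its color nearest neighbors; `overdispersed` grows a
greedy max-min spread from the most distant pair; `random` samples
uniformly. Their MPD ordering (clustered < random < overdispersed) is
verified empirically in the suite. Brownian trait evolution accumulates
independent Gaussian increments per branch (variance $\sigma^2 \times$
length); in 2-D mode the coordinates evolve independently — a deliberate
simplification of correlated color evolution.

What the generator does **not** emulate: pigment chemistry (spectra are
geometric archetypes), replicate flowers per species with biological
variance structure, abundance, spatial structure, or trait-dependent
diversification. Passing tests on synthetic data therefore demonstrate the
statistical machinery and its calibration, not field realism.

# Numerical and design choices

- **Grid**: 1 nm, 300–700 inclusive; trapezoidal quadrature; resampling is
  linear interpolation with constant extension over at most 5 nm at the
  edges (a larger gap is an error naming its size); interpolated values are
  floored at 0. Reflectance above 1 (glare) is kept with a warning;
  negative readings are clipped to 0.
- **Replicates**: spectra sharing a `species_id` are averaged after
  resampling, giving one locus per species.
- **Determinism**: every randomized routine takes an explicit integer seed;
  per-row seeds in the batch tables are derived from the master seed so a
  run is reproducible bit for bit (asserted in the suite).
- **Verdicts**: the run summary labels a group clustered at $p \le 0.05$,
  overdispersed at $p \ge 0.95$, random otherwise; the thresholds are
  arguments and the p is always printed, because borderline values (a p of
  0.93, say) are read differently by different authors.
- **Problem sizes in the suite**: calibration checks use 200 runs at 199
  permutations (type-I bands $[0.01, 0.10]$ at nominal 0.05), parameter
  recovery 200 Brownian simulations on 50-tip trees, detection power 50
  seeded constructions — sizes at which the binomial error of the checked
  proportions is well inside the asserted bands.

# Known limitations

Hue is analyzed as a linear variable; groups whose loci straddle the
$0/360$ cut would need circular statistics. The hexagon orientation is a
convention: absolute angles of other datasets may be rotated relative to
published figures even though sector membership and all distances are
unaffected. The null models are richness-based only, and the rarefaction
separation rule (non-overlapping 95% intervals) is a declared convention,
stricter than a formal two-sample test. Receptor-noise discrimination
models, alternative color spaces and tetrachromatic vision are out of
scope.
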