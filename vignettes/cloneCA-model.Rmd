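---
title: "The cloneCA model: growth modes, driver selection and spatial clonal diversification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cloneCA model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneCA)
```

## The model

cloneCA simulates clear-cell renal cell carcinoma (ccRCC) growth as a
coarse-grained cellular automaton. The agent is the *tumour voxel*, a
1 × 1 × 1 mm³ unit of tumour tissue occupying one site of a cubic lattice
(default 200³ sites). A simulation starts from a single founder voxel at
the lattice centre carrying the two truncal ccRCC events, a *VHL* mutation
and 3p loss, and runs in discrete steps until the tumour reaches a stopping
size (default 10⁶ voxels, an equivalent spherical diameter of about 12 cm).

Each step executes four phases in order:

1. **Death.** Every voxel dies independently with probability
   `pDeath = 0.05`, freeing its site.
2. **Proliferation.** Eligible voxels divide with their genotype-dependent
   growth probability (baseline `pInit = 0.25`). Under **Surface Growth**
   a voxel is eligible only if at least one of its 26 neighbouring sites is
   empty, and the child occupies a uniformly chosen empty neighbour. Under
   **Volume Growth** every voxel may divide: 10 of the 26 orientations are
   sampled without replacement, the candidate site closest to the tumour
   surface is selected (ties broken uniformly), and the occupied ray along
   that orientation is pushed one step outward until the first empty site
   absorbs the displacement.
3. **Driver acquisition.** Each daughter voxel born this step tests every
   panel event it does not already harbour: gene mutations are acquired
   with probability `pDriver`, somatic copy-number alterations (SCNAs) with
   `0.001 * pDriver`, raised to `pDriver` once the genotype carries a
   *PBRM1* or *BAP1* mutation. A second mutation of the same gene never
   occurs in the same voxel, but independent alleles of the same gene can
   arise in parallel in different voxels; every acquisition founds a new
   subclone. Acquisition rates are evaluated against the inherited
   (parental) genotype; events acquired simultaneously at one birth do not
   boost each other within that birth.
4. **Necrosis** (optional). Voxels deeper than `dNecrosis = 15` mm from
   the tumour surface die with probability `pNecrosis = 0.5`.

Voxels are eligible for proliferation as assessed at the start of the
phase and are visited in a fresh uniform random permutation, with
emptiness re-checked at placement time; sites freed by the same step's
deaths are immediately reusable. The automaton does not model calendar
time: one step is the time unit throughout.

### The depth field

Both volume-mode placement and necrosis use one *depth field* per step:
the exact Euclidean distance from each site to the tumour surface. The
surface is defined as the exterior empty region — empty sites 6-connected
to the lattice boundary. The distinction matters: at `pDeath = 0.05` the
tumour interior permanently carries a few percent of transient empty
holes, and if holes counted as surface no voxel would ever sit more than
~10–13 mm "deep", necrosis would never trigger, and volume-mode children
would be pushed towards interior cavities rather than outward. Distances
are computed with an exact 3D Euclidean distance transform after a flood
fill of the exterior.

A push that would exit the lattice aborts the simulation with an explicit
boundary diagnostic rather than clipping silently; configurations should
keep `stopSize` well below the lattice capacity.

### Driver panel and fitness models

The panel (`defaultPanel()`) holds 26 ccRCC driver events: mutations in
12 genes and 14 SCNAs. Membership of the explicitly flagged events is
fixed — *VHL* mutation and 3p loss are truncal, *PBRM1*/*BAP1* mutations
enhance the SCNA rate, and 7q gain, 20q gain, 4q loss and 8p loss are the
strongest drivers — while the remaining names are canonical ccRCC drivers
shipped as editable defaults (`loadPanel()` accepts a JSON replacement).

Two selective-advantage models map a genotype to a growth probability:

* **Saturated** (`saturatedModel(s)`): three levels
  {`pInit`, `(1+s) pInit`, `(1+s)² pInit`}, the highest tier among
  harboured drivers, capped at 1. Gene mutations and the truncal 3p loss
  sit at the initial tier (so the parental clone proliferates at exactly
  `pInit`), the four strongest SCNAs at the maximal tier, and the other
  SCNAs at the moderate tier. With `s = 1`, a maximal-tier driver
  saturates the growth probability at 1.
* **Additive** (`additiveModel(minSk, deltaSk)`): every harboured driver
  of rank *r* (1 = weakest) adds `(minSk + (r-1) deltaSk) * pInit`, with
  the total capped at 1. Because the underlying per-driver increments are
  not fixed by any biological measurement, the package ships three presets ("low",
  "mid", "high") chosen so the strongest driver adds between roughly a
  third and the whole of the baseline probability — comparable in reach
  to the saturated tiers. The default rank order places truncal events
  first, gene mutations next and SCNAs last, with the four strongest
  SCNAs at ranks 23–26.

Both models are monotone (adding a driver never lowers fitness) and
bounded in `[pInit, 1]`.

## Analyses

**Clonal accounting.** A subclone is the set of voxels sharing the driver
events accumulated in its initiating voxel; every voxel belongs to its
most-derived clone, so clone frequencies partition the scope and cancer
cell fractions (CCF) sum to 1 at whole-tumour, slice and biopsy level.
A clone is *detectable* when its CCF exceeds 0.01 (strict); inclusive
counting at other thresholds is available. The Shannon index
S = Σ −fᵢ ln fᵢ runs over all clones, parental included.

**Slices and contours.** The analysis plane is z = z₀ through the founder
voxel. The tumour centre is the centroid of occupied slice sites — not
the lattice centre — so it tracks drifting or lobed tumours. Contours are
traced by Moore boundary following on 8-connectivity, then smoothed by
replacing each contour voxel with the mean position of itself and its
adjacent contour voxels (a cyclic three-point window; the point count is
preserved). Smoothing along the traced path removes the lattice staircase
without pulling the boundary inward: a digital disc of radius 20 keeps a
perimeter within ~2% of 2πr. Circularity is the isoperimetric ratio
4π·Area/Perimeter², 1 for a circle; the squared perimeter is required for
a dimensionless measure.

**Microdiversity.** A 3 × 3 mm² window slides at 1 mm stride across the
slice; windows containing at least one voxel are scored by their count of
distinct clones, and windows with ≥ 5 clones are *microdiversity
hotspots*. Each hotspot is located by d₁ (distance to the slice centre)
and d₂ (distance to the nearest smoothed-contour point), combined into
the normalised centre distance d = d₁/(d₁+d₂) ∈ [0, 1].

**Power-law gradients.** The cumulative distribution P(D ≤ d) of hotspot
distances is fitted by dᵏ with one-parameter least squares on the
empirical CDF (plotting position i/n; `optimize()` over k ∈ [10⁻³, 50]),
with a bootstrap of 100 resamples of 400 hotspots drawn with replacement.
Uniform hotspot locations in a disc give k = 2 (the null model); k > 2
indicates enrichment towards the margin. The bootstrap median sits ~2–3%
below the planted exponent because resampling duplicates flatten the
empirical CDF; the point estimate on the full sample is unbiased, and a
log–log linear fit is provided as an independent cross-check
(`fitPowerLawLogLog()`). Samples with (near-)identical distances are
flagged degenerate. `homogenise()` permutes clone labels across occupied
sites, preserving the composition exactly while destroying spatial
structure — fitted exponents then revert towards the null value 2.

**Fitness gradients, youngest subclones, biopsies.** The central-most,
marginal-most and a random 10% of slice voxels are averaged into a
centre/margin fitness ratio (Ratio_C2M). The n youngest subclones are
taken by largest birth step (clone-id ties broken towards the later
clone) and measured from their recorded initiating position — updated if
the voxel is displaced by volume-mode pushing, frozen at death — to the
nearest contour point. Regional biopsies collect voxels within 5 mm of
candidate centres laid out at 20 mm spacing, anchored at half the spacing
from the lattice origin (a 200 mm plane yields a 10 × 10 candidate grid).

**Time courses, flow fields, replay.** Snapshot series yield per-time
slice metrics (equivalent circular diameter 2√(A/π), detectable clone
counts, mean driver burden, mean fitness, circularity). Note that while
no voxel ever loses a driver, the *slice-mean* driver burden can dip
slightly when low-burden clones dilute the average or high-burden voxels
die; it accumulates in trend only. Kernel density estimates over
(diameter, subclone count) use Gaussian kernels with Scott's-rule
bandwidths and report the density level enclosing 90% of the mass.
Evolutionary replay restores a snapshot bit-identically (positions,
clone identities, drivers, allele ids and the RNG stream) and re-runs
replicates under fresh seeds; outcomes are compared by pairwise
Jensen–Shannon divergence (natural log, maximum ln 2) between clone
frequencies keyed by driver event set, so parallel events hitting the
same genes count as equivalent outcomes.

**Cohort interface.** Patient-style multi-region tables (regions with
coordinates, clone counts, optional event labels and group labels) are
analysed with the same machinery: regions with at least one subclone act
as hotspot proxies (a stricter ≥ 2 reading is a parameter), distances use
a supplied margin polygon or the per-tumour convex hull of regions, and
group exponent comparisons reuse the bootstrap fit plus a two-sided
Wilcoxon rank test. Events restricted to a single region are mapped by
their distance to the margin with a 10 mm reference line.

## Determinism and randomness

All phases — including the compiled growth kernel — draw from R's RNG
(Mersenne–Twister by default, pinned in the configuration), and the state
stores the stream between calls. Identical configuration and seed give
byte-identical snapshot series; a snapshot's stored stream resumes the
uninterrupted run exactly. At baseline rates the founder lineage goes
extinct in roughly a fifth of seeds (death may precede the first
division); analyses condition on established tumours via
`runUntilEstablished()`, which advances the seed by a fixed offset and
reruns — itself deterministic.

## What the synthetic data emulate — and what they do not

The built-in generators (`generateNullHotspots()`,
`generateSyntheticRegionTable()`, `fixtureLattice()`) produce exact null
distributions, planted power-law spatial patterns and small deterministic
geometries. They emulate the *spatial statistics* of regional sampling,
not measurement: there is no sequencing noise, no variant-allele-fraction
deconvolution, no purity or ploidy uncertainty, and the 1 mm³ voxel is
far above cell-scale resolution. Passing tests therefore demonstrate
internal consistency of the model and estimators, and qualitative
agreement of reduced-scale simulations with the full-scale behaviour —
they do not validate the model against sequencing data.

## Reduced problem sizes used by the test suite

Full-scale simulations (200³ lattice, 10⁶ voxels, dozens of replicates)
are not desk-scale. The tests use:

* growth-law fits: L = 60, stop at 2 × 10⁴ voxels, 10 seeds per mode;
* the Surface-vs-Volume diversification comparison: L = 100, stop at 10⁵
  voxels, 20 paired seeds per mode. Below ~5 × 10⁴ voxels the comparison
  is not meaningful: a 20-run ensemble pools only a few dozen hotspot
  windows per mode, the bootstrap exponent is unstable, and the
  margin-enrichment regime of Surface Growth (which needs several
  generations of subclones stacked at the margin) has not yet emerged;
* the necrosis contrast: L = 110, stop at 1.5 × 10⁵ voxels,
  `pDriver = 10⁻³`, 10 paired seeds. This scale is the smallest at which
  the mechanism behind central fitness elevation can operate: the tumour
  radius (~33 mm) must exceed `dNecrosis` by enough that the churning
  necrotic core overlaps the central sampling region, and advantaged
  subclones must already exist when interior material becomes deep —
  at smaller sizes or lower driver rates the core is recolonised by
  parental voxels only and the contrast vanishes.

At reduced scale, microdiversity hotspots are rare (a 9-voxel window must
hold 5 distinct clones), so hotspot distances are pooled across the run
ensemble before fitting, exactly as cumulative distributions are pooled
across repeat simulations at full scale.

## Known limitations

* Lattice anisotropy: the 26-neighbourhood makes diagonal growth slightly
  favoured; contour smoothing compensates in 2D measurements.
* Boundary contact aborts rather than clips; choose `L` generously.
* The additive-model increments and the panel membership beyond the
  flagged events are package defaults, not measured constants.
* Slice-level means (fitness, driver burden) are not monotone step to
  step; only their trends are meaningful.
* No microenvironment, immune interaction, treatment, or
  environment-dependent fitness; driver advantages are fixed constants.
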