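---
title: "Quantifying airway mucus plugging in 3-D volumes: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying airway mucus plugging in 3-D volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airwayplug)
```

## The problem and the model

Muco-obstructive lung diseases produce intraluminal mucus plugs whose
burden and wall adherence vary along the airway tree.  Two voxel-level
quantities summarise a single airway cross-section:

- the **mucus area ratio** \(A = n_\mathrm{mucus} / n_\mathrm{lumen}\),
  where the lumen is the airway interior (air **plus** mucus);
- the **mucus contact ratio** \(C = n_{\mathrm{wall}\cap\mathrm{mucus}} /
  n_\mathrm{wall}\), where the wall is operationalised as the lumen voxels
  with a 6-neighbour outside the airway interior.

Both are fractions in \([0,1]\); summaries report percent.  Per-sample
means of \(A\) and \(C\) are related by simple linear regression
(\(C = \beta_1 A + \beta_0\)) and Pearson correlation; in the murine
muco-obstructive model that this package emulates the published
relationship is \(\beta_1 = 3.204\), \(\beta_0 = 7.243\) percentage points
with \(R^2 = 0.89\) and per-method \(r \ge 0.80\), with per-sample mean
area ratios spanning 0.7–15.5 % and mean contact ratios 6.4–58.1 %.  Those
coefficients are used here as *simulation defaults* of
`generate_cohort_ratio_table()`, not as assertions about new data.

### Cross-section extraction

The three methods deliberately trade accuracy against cost:

- **slice** uses the original z-planes — exact for z-aligned branches but a
  branch tilted by angle \(\alpha\) smears by \(1/\cos\alpha\) (about
  \(\sqrt 2\) at 45°; the package documents rather than corrects this);
- **skeleton** samples, at every non-junction centerline node, the plane
  orthogonal to the local tangent on a voxel-pitch grid with
  nearest-neighbour lookup (counts stay integers and oracle-checkable);
  the record's lumen set is the 4-connected in-plane region containing the
  node, which stops capture of neighbouring branches;
- **geodesic** bins mask voxels by \(\lfloor d/w \rfloor\) of the geodesic
  distance \(d\) from a seed slice, with chamfer weights
  \(1/\sqrt2/\sqrt3\) to limit metrication error (the level sets are
  non-planar, so \(A\) becomes a mucus *volume* fraction; bins partition
  the reachable mask exactly, and unreachable components are excluded and
  rendered blue in maps).

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `voxel_size_um` | explicit, no default | isotropic voxel edge; metric meaning of every count depends on it, so a missing value is an error, never a guess |
| `sigma` (segmentation) | 1 voxel | Gaussian pre-smoothing for the watershed; the original tooling names no preprocessing, so this is a package choice |
| `barrier`, `cut` | auto: background level − 2 sd, − 2.5 sd | intensity cap for the lumen flood and the raw-intensity refinement threshold; estimated per volume from marker patches and the smoothing residual |
| `mucus_params()` | Otsu threshold; opening 1, closing 2, min component 27 voxels | binarisation band and morphological cleanup for mucus; all configurable, with a fixed-band override |
| `prune_vox` | 8 | minimum terminal skeleton segment; the effective threshold adapts upward to the local radius + 3 (junction bulges shed spurs about one radius long) |
| geodesic `bin_width` | 1 voxel | level-set width |
| `mean_over` | `"stations"` | per-sample means average records; `"branches"` averages branch means first (the upstream convention is unstated, so both are provided) |
| map scales | area 0–30 %, contact 0–100 % | full-scale of the green→red ratio maps |
| score cut | 50 % inclusive → score 1 | "up to 50 %" read as inclusive |

## The synthetic world

`build_tree_volume()` digitises straight cylindrical branches by a strict
voxel-centre-inside-surface test (no anti-aliasing), so exact counting
oracles exist: a digital disc of radius ≥ 8 is within 5 % of \(\pi R^2\).
Murine airways branch monopodially — daughters bud off a continuing trunk —
and the default tree builders follow that architecture.  Deposits come in
three morphologies (plug, crescent, annulus).  A crescent takes a target
wall coverage \(c\) (angular window) and a target fill fraction \(a\):
for \(a \le c\) a radial wedge of thickness
\(t = R(1-\sqrt{1-a/c})\) suffices; for \(c < a < 1\) the wedge is extended
by a concentric core of radius \(r = R\sqrt{(a-c)/(1-c)}\) (union area
solved in closed form).  Full occlusion (\(a = 1\)) geometrically forces
\(c = 1\) — a fully plugged lumen touches the whole wall — so such
combinations are rejected; the acceptance grid uses the feasible cells.

`render_intensity()` paints air/mucus/tissue at 0.10 / 0.60 / 0.85 on a
unit gray scale plus clipped Gaussian noise.  The triple is an artifact
constant (chosen so threshold-based separation works to sd ≈ 0.1), not a
measured property of stained tissue.  What a green test therefore
establishes: the pipeline recovers known geometry under three-class
contrast with additive Gaussian noise.  What it does not establish:
robustness to reconstruction artefacts (beam hardening, rings, phase
contrast), partial-volume gradients at walls, alveolar texture, or
anisotropic resolution — none of which the generator emulates.

Every stochastic generator takes an explicit seed and is a pure function
of (specification, seed); `run_microanalysis()` derives all per-stage
seeds from the single config seed, so rerunning a config is bit-identical.

## Segmentation design

The lumen segmenter is a marked watershed in the priority-flood
formulation: user markers label lumen and background, flooding proceeds on
the smoothed intensity in increasing gray order.  Two package-specific
choices deserve note:

1. **Barrier**: the lumen label may not claim voxels brighter than an
   automatically estimated barrier (background level − 2 estimated noise
   sd).  Without it, a flood from dark seeds eventually crosses the bright
   wall wherever the background marker is far away; with a stricter
   barrier, wall-adjacent mucus (whose smoothed value is pulled towards
   tissue) is lost.  The final mask is refined on the *raw* intensity,
   hole-filled, and restricted to seed-connected components, which restores
   voxel-accurate boundaries in the phantom world.
2. **Branch decomposition**: the proprietary branch-labelling algorithm of
   the original tooling is not published, so it is approximated
   functionally: skeletonise, split at junction clusters, re-merge the
   best-aligned incident pair at each junction (a monopodial trunk
   continues straight through; merge requires direction dot < −0.5), and
   assign every mask voxel to the nearest skeleton branch by multi-source
   geodesic propagation.  Two artifact classes are pruned: terminal spurs
   shorter than the local radius + 3, and "branches" whose nodes lie ≥ 85 %
   inside other branches' tubes (junction-bulge skeleton duplicates).

Mucus is then thresholded *inside* the airway interior (whether
binarisation preceded or followed airway masking upstream is unstated;
in-lumen banding is the reasoned reconstruction), cleaned by opening,
closing and small-component removal.  The Otsu mode carries a bimodality
guard: an Otsu split of unimodal noise separates class means by only
~1.6 sd, so a separation below 4 sd returns an empty mask instead of
speckle.

## Numerical choices and degenerate inputs

- Connectivity: 26 for foreground components, 6 for walls/boundaries
  (standard complementary pair).
- Thinning: distance-ordered homotopic thinning with the
  Bertrand–Malandain simple-point test and curve-endpoint preservation;
  deterministic FIFO tie-breaking.  Blunt tube caps shed short descending
  tails; they are trimmed by walking each free end while the
  distance-to-background strictly descends.
- Tangents: central differences over a 5-node window, one-sided at ends;
  junction nodes emit no cross-section record (the conservative reading of
  the known topological unreliability there).
- A geodesic bin can, rarely, contain only interior voxels; its contact
  ratio is recorded as `NA` and excluded from means rather than dropping
  the record (which would break the partition property).
- All-tied Kruskal-Wallis input returns H = 0, p = 1 by convention; exact
  Mann-Whitney enumerates all label assignments (ties included) when both
  groups have ≤ 8 observations; two-sided p values throughout; the normal
  approximation uses continuity correction 0.5.
- Indexing is 1-based `(z, y, x)` everywhere, including CSVs — the
  package-wide convention follows R rather than mixing in a 0-based one.

## Scoring model

The ordinal score (0 = no mucus, 1 = obstruction ≤ 50 %, 2 = > 50 %) is
attached to a monopodial nomenclature catalog spanning generations 1–11 in
all five murine lobes (RUL, RML, RLL, RCL, LL); the trachea (generation 0)
is excluded by design.  The shipped catalog (170 segments; the published
study scored ≈ 185 segments/animal, the exact inventory is not printed) is
an artifact construction with trunk segments labelled by capital letters
and daughter paths by lowercase letters and Roman numerals; it is plain
CSV so users can substitute their own.  Aggregation averages over scored
segments only; a stratum with no scored segment yields `NA`, never 0.
`auto_score()` maps computed area ratios onto the same scale with the 50 %
boundary inclusive.

## Limitations

- The phantom world is geometric; no claim is made about performance on
  real SRCT reconstructions.
- The slice method's oblique smear is reported, not corrected.
- Skeleton cross-sections lose the few stations nearest branch ends (tail
  trimming) and all junction stations.
- The whole-organ scoring model treats segments as independent draws; real
  mucus distributions are spatially correlated along the tree.
- Branch decomposition is a functional stand-in for an unpublished
  algorithm; only its observable contract (branch-labelled partition with
  parent/child adjacency) is tested.
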