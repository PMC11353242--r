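---
title: "Measuring chromosomal instability: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring chromosomal instability: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinmetrics)
```

# Scope

`cinmetrics` measures chromosomal instability (CIN) along four axes:
differential copy-number distance from a control-defined baseline, karyotype
heterogeneity, mitotic-defect event rates, and microtubule growth speed.
This vignette explains the underlying models, the parameters that matter,
the numerical conventions, and the choices made where the design was
genuinely open. It states no empirical result that the test suite does not
itself compute.

# The copy-number model

## Read depth

Binned read counts are modelled as negative binomial with mean

$$\mu_b = m \cdot \frac{c_b}{p} \cdot g(\mathrm{GC}_b),$$

where $m$ is the copy-neutral mean count per bin, $c_b$ the integer copy
number, $p$ the base ploidy, and $g$ a quadratic multiplicative GC-bias
factor. The dispersion $\alpha$ enters as
$\mathrm{Var} = \mu + \alpha\mu^2$ (the standard read-count overdispersion
parameterisation); $\alpha = 0$ is defined as "return the expectation
exactly", which gives the tests a noise-free escape hatch. Note the
consequence: for $\alpha = 0.05$ the coefficient of variation is at least
$\sqrt{0.05} \approx 22\%$ *at any depth*, i.e. per-bin log2 ratios carry a
robust spread (MAD) around 0.3. Parameters: `mean_count` (default 100
reads/bin — low-coverage territory), `dispersion` (0.05), `gc_linear`/
`gc_quadratic` (0.6/−2 in the demo; moderate, smooth bias). Sequencing
depth and bin size are deliberately exposed rather than fixed: shallow WGS
protocols vary widely and nothing in the measured quantity depends on a
particular choice.

## GC correction

Expected count is fit as a quadratic in GC over *copy-neutral-candidate*
bins — those whose raw count lies within the interquartile range — so that
genuinely altered bins do not bend the curve; each bin is then rescaled by
`median(expected)/expected(bin)`. With constant GC the correction is the
identity (with a notice) since no bias is identifiable. The correction is
scale-equivariant: doubling all counts doubles corrected counts.

## Normalisation and masking

The copy-neutral reference (*MedianRatio*) is the genome-wide median of
corrected counts; ratios are counts over this median, log2-transformed.
Because the median commutes with scaling, the median of the resulting
ratios is exactly 1 whenever at least half the genome is copy-neutral.
Zero-count bins are masked, not imputed: at shallow coverage a zero carries
no usable depth information and imputation would fabricate signal at
exactly the loci (deep deletions) where honesty matters most.

## Segmentation

Each chromosome's unmasked log2 series is segmented by recursive binary
segmentation in which the candidate at every stage is the contiguous
*window* maximising the two-sample t-statistic between the window and the
rest of the segment — the circular-binary-segmentation scan. A plain
single-split scan was tried first and rejected: for an event in the middle
of a chromosome the best single split sits at one event edge and its
statistic is roughly halved, which at shallow-coverage noise leaves
mid-chromosome events systematically undetected (and asymmetrically so,
since the condition with more alterations loses more — a direct bias on
the closer/further comparison).

Acceptance of a candidate is permutation-calibrated: the observed maximal
statistic is compared with the same scan on `n_perm` within-segment
shuffles (deterministic given `seed`), and the window is accepted when
$(1 + \#\{\text{perm} \ge \text{obs}\})/(n_\text{perm}+1) \le \alpha$. The
permutation loop aborts as soon as the exceedance count proves the
candidate cannot reach $\alpha$; this changes nothing about the decision
and makes null segments cheap. Every piece a cut creates must keep
`min_bins` (default 3) bins.

**Default `alpha = 0.001`, `n_perm = 999`.** A whole-genome run spawns on
the order of one hundred segment tests (22 chromosomes, recursion); at
$\alpha = 0.01$ that is an expected false breakpoint per profile, which is
visible in the per-locus classification. $\alpha = 0.001$ is the smallest
level attainable with 999 permutations (accept only when no shuffle reaches
the observed statistic) and keeps the expected false-breakpoint count per
genome near 0.1. The level is a parameter; `segment_profile()` refuses
unattainable combinations instead of silently never splitting.

Copy-number calls round `ploidy * 2^mean_log2` half away from zero; ploidy
is a *per-cell-line preset* (e.g. 5 for a ~107-chromosome line, 2 for a
~52-chromosome line), not something a ratio profile can determine by
itself. Log ratios are log2 throughout.

# The baseline-distance classifier

Profiles are compared on the finest common tiling of their segments
(per-bin mode is available by pairing ratio profiles directly); loci masked
or uncovered in either profile are excluded from both. With
`delta = knockdown − control` per locus and $d(x) = |\text{log2 ratio}|$:

| condition | class |
|---|---|
| `abs(delta) <= half_width` | unchanged |
| `d(kd) > d(ctrl)` | further from baseline |
| `d(kd) < d(ctrl)` | closer to baseline |
| `d(kd) == d(ctrl)`, `abs(delta) > half_width` | sign-flip policy |

The **unchanged band** is `2 * ar(MedianRatio)` where `ar` is a robust
dispersion of the MedianRatio-normalised bins. The operator is not pinned
down by the source convention, so it is pluggable (`mad` about segment
means scaled by 1.4826 — the default, `sd`, or `IQR/1.349`) and the choice
is recorded in the classification's provenance. MAD is the default because
shallow-coverage log2 ratios are heavy-tailed and an outlier-inflated band
would silently re-label real change as "unchanged".

A pure **sign flip** (equal magnitude, opposite sign — a gain replaced by
an equally sized loss) is neither closer nor further by the distance rule.
The default classes it `further`, on the argument that the knock-down state
is a new alteration, not an attenuation; the policy is configurable and
recorded. Note the consequence: on sign-flip loci the closer/further swap
under condition exchange is broken by policy. The antisymmetry property is
exact on continuous data, where exact ties have measure zero.

Percentages are computed over *changed* loci only, so closer% + further% =
100 whenever anything changed (matching the convention in which the two
reported percentages are complementary); with no changed loci they are
reported as `NA`, not 0. The "affected chromosomes" list uses a
changed-fraction threshold parameter (default 0.1) because the underlying
criterion is a reporting convention, not a measurement.

# The synthetic world

The simulators produce every input the pipeline consumes. What they emulate
— and what they do not — bounds what a green test establishes.

**Genome.** 22 autosomes proportional to the human autosomes, rescaled to
720 Mbp so whole-genome runs stay desk-scale, 1 Mbp bins by default.

**Alterations.** The control carries `n_alterations` (10) events of
`alteration_length` (20 Mbp) on a non-overlapping slot grid; each doubles
or halves copy number relative to ploidy (CN 4 or CN 1 at diploid base).
Two deliberate choices:

* *Symmetric log2 ±1 effects.* At dispersion 0.05 the unchanged band is
  ≈ 0.6–0.8 log2 units, which engulfs a single-copy diploid gain
  (log2 1.5 ≈ 0.58). Events of |log2| = 1 keep the designed contrast
  visible above the stated noise floor, and neither state zeroes out read
  depth (no masking asymmetry). Single-copy events at this noise level are
  a genuinely harder world; they can be simulated by building a custom
  profile, but they are not the default because the default is the world
  the acceptance properties measure recovery in.
* *Arm-scale length.* 20 Mbp on the 720 Mbp toy corresponds to ~80 Mbp on a
  human genome — chromosome-arm territory, which is the scale of CIN
  events; it also gives the window statistic proper power at 1 Mbp bins.

The knock-down reverts a fraction `attenuation_fraction` (0.7) of altered
bp to ploidy ("toward baseline" is implemented as full reversion — the
clone carrying the alteration is lost) and gains `new_alteration_fraction`
(0.3) of altered bp as novel events. Ground-truth closer/further bp totals
are returned and equal an interval-arithmetic recomputation exactly.

**Karyotypes.** Per division, each chromosome independently missegregates
with probability `rate`; a missegregation adds or removes one copy with
equal probability. The mean stays at the base count (107 or 52 presets);
the variance grows with the rate — the simplest model with that property,
and exactly the contrast the F-test is meant to detect. Not modelled:
selection against extreme karyotypes, whole-genome doubling, death of
nullisomic cells.

**Event counts.** A single binomial draw per condition. The demo uses 100
cells/arm; at that size a 0.24 vs 0.10 contrast is not always significant,
and the demo output honestly shows whatever the draw gives.

**Comet movies.** Point emitters advance along straight headings at fixed
speeds (µm/min), rendered as Gaussian blobs (PSF sigma 1.5 px) over a
constant background with additive Gaussian noise; frame interval 2 s as in
the live-imaging protocol this emulates. Per frame an emitter moves
`speed/60 * interval / pixel_size` px — at 3 µm/min, 0.1 µm/px, 2 s this is
exactly 1 px/frame. Not modelled: photobleaching, comet shape anisotropy,
catastrophe (tracks never terminate early), crowding beyond what random
placement produces, z-drift. A tracker that passes here can still struggle
on dense, blinking real data.

# Tracking parameters

The detector has no universal settings; defaults are documented, not
claimed optimal. DoG sigmas default to `radius/sqrt(2)` and 1.6× that —
the classic blob-scale bracket. `quality_threshold` is data-dependent
(it is a DoG response); the demo uses 4 against amplitude 100 / noise 5.
`max_disp` should exceed the largest expected per-frame displacement
(1.5 px in the demo) with margin but stay below typical emitter spacing;
4 px is used. Track filters (`min_duration`, `min_spots`, both 5–10) remove
the short fragments that detection jitter produces. Sub-pixel refinement is
an independent 1-D parabola per axis over the 3×3 neighbourhood, clamped to
±0.5 px: necessary, because at 1 px/frame motion a ±0.5 px integer-grid
error is a 50% speed error on a single link. Per-cell speed is the
*unweighted* mean over track means, so long tracks do not dominate.

The linker solves, between consecutive frames, the assignment minimising
total squared displacement with per-link cap `max_disp²` and alternative
cost `max_disp²` for leaving a spot unlinked — which always prefers linking
within the cap, and among equal-cardinality matchings picks the minimum
cost. The solver is a Jonker–Volgenant-style shortest-augmenting-path LAP
(implemented in-package; no assignment solver is available in the dependency
footprint), verified against exhaustive enumeration for small frames. There
is no gap closing and no split/merge handling — the "simple" tracker
semantics — so a missed detection terminates a track; the speed estimate is
unaffected because track means are averaged unweighted.

# Statistical conventions

* **F-test:** `F = var(a)/var(b)`, `df = (n_a−1, n_b−1)`, two-sided p by
  doubling the smaller tail (capped at 1) — the direction of the reported
  heterogeneity change is not assumed. Zero denominator variance is an
  error, not an infinite statistic.
* **Event proportions:** fold change `p1/p2` (undefined with `p2 = 0`,
  reported `NA`) plus Fisher's exact test on the 2×2 table. The exact test
  is a package decision — small-sample safe for counts of tens of cells —
  not a claim about how the original figures were starred.
* **Mann–Whitney:** midrank U; exact two-sided p (via the exact U null)
  when the smaller sample has n ≤ 8 and there are no ties, else normal
  approximation with tie and continuity correction.
* **Intensity ratio:** per channel, background = median outside the mask;
  ratio of background-subtracted means within the mask. Without a mask the
  whole frame is foreground and background is 0 by definition.

# Numerical conventions and degenerate inputs

Coordinates are 0-based half-open everywhere internally; bp internally,
Mbp only in reports. Copy-number ties round half away from zero. All seeds
are explicit arguments; internal streams derive from them reproducibly and
the global RNG state is restored after every call. Empty inputs are legal
where a sensible empty output exists (empty spot sets, empty paired
profiles); impossible requests (alterations beyond genome capacity,
emitters that cannot fit, zero-variance F denominators, unattainable
permutation levels) raise errors that name the constraint. Provenance
blocks omit timestamps unless asked (`stamp = TRUE`), so identical
configuration and seeds give byte-identical outputs. Run configuration is
JSON rather than YAML — the dependency footprint has a JSON parser but no
YAML parser, and the config is a flat mirror of CLI flags either way.

# Known limitations

* The copy-number stage is desk-scale by design: no allele-specific copy
  number, purity/contamination, mappability or replication-timing effects.
* The unchanged band uses bin-level dispersion while deltas are compared on
  segment means; the band is therefore conservative (segment means are much
  less noisy than single bins). This follows the stated convention rather
  than an efficiency argument.
* At dispersion 0.05, single-copy changes on a diploid background fall
  inside the unchanged band — a resolution statement about the convention
  at that noise level, not a bug; the default synthetic world uses events
  the convention can resolve.
* The tracker is 2-D after projection; emitters crossing in z are linked by
  proximity alone.
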