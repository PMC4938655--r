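---
title: "Quantifying larval crawling and calling slow hits in thermogenetic screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying larval crawling and calling slow hits in thermogenetic screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvatrack)
```

## The assay

A thermogenetic activation screen for larval locomotion works like this: a
single newly hatched *Drosophila* larva crawls on an agar arena under a
low-magnification bright-field camera (4 Hz), first at a permissive
temperature (23&deg;C, the warmth-gated channel closed), then at a
restrictive temperature (28&deg;C, the targeted neurons firing). Control
animals speed up on the shift — per-larva mean speeds around 65 um/sec at
23&deg;C rising roughly 1.5-fold at 28&deg;C — so a genotype whose neurons
disrupt the motor program when activated shows up as a *failure to speed
up*, or as outright slowness.

`larvatrack` implements the full quantitative chain for such a screen:
per-frame single-animal detection, centroid kinematics with an artifact
exclusion rule, per-larva summaries, and the two-criterion statistical
definition of a "slow" genotype. Because screens of this kind rarely
publish raw video, the package also contains a ground-truthed simulator of
crawl videos and screen datasets, so every stage can be validated against
known kinematics. The simulator is first-class, tested code, not a test
fixture.

## Segmentation

Each frame is processed independently — there is no temporal smoothing or
Kalman linking, so a bad frame can never contaminate its neighbors:

1. Gaussian blur (`blur_sigma`, default 2 px — a mild blur that suppresses
   sensor noise without moving the centroid);
2. Otsu threshold computed on a 256-bin histogram of the *blurred* frame
   (8-bit convention);
3. binarization, with the larva side chosen by `polarity`. The default
   `auto` takes whichever side has fewer pixels, on the grounds that the
   animal is small relative to the arena;
4. morphological closing with a disc of `closing_radius` (default 2 px),
   which fuses the small holes and bridges that thresholding leaves in a
   textured body;
5. 8-connected component labeling;
6. a size gate: only components with area in
   `expected_area * [1 - tol, 1 + tol]` survive (`area_tolerance` default
   0.5). `expected_area` is deliberately a manually entered parameter — it
   encodes what the experimenter knows a larva of this stage looks like at
   this magnification.

A frame yields data only when **exactly one** component passes the gate.
Zero candidates (`no_object`) or several (`multiple_objects`) return no
centroid; there is intentionally no closest-area tie-break, because a
second gate-passing object means the scene cannot be trusted. The centroid
is the unweighted mean of member pixel coordinates (pixel centers at
integer coordinates, origin top-left, x = column, y = row); the area is the
member pixel count.

Blur, threshold and closing are delegated to EBImage. Component labeling is
implemented in the package (union-find over foreground pixels) because
EBImage's `bwlabel` uses 4-connectivity and the chain specifies
8-connectivity; the tests check it against an independent flood-fill
oracle, exactly, on random masks.

Two numerical caveats are worth knowing. A constant frame has no Otsu
threshold and is reported as `no_object` rather than an error. And
intensity inversion (swapping a dark larva on light ground for the
opposite) is only *bin-level* symmetric: Otsu's 256-bin histogram does not
invert exactly, so centroids under `polarity = "auto"` agree across an
inversion to a small fraction of a pixel, not bit-for-bit.

## Kinematics

Instantaneous speed is the Euclidean centroid displacement between
*consecutive ok frames* (frame indices differing by exactly 1) times
`pixel_scale * frame_rate`. Pairs spanning a failed detection contribute
nothing — they are dropped from numerator and denominator alike, never
imputed.

Body length uses the screen's length proxy: the mean ok-frame area is
converted as `sqrt(mean_area / 3.14) * pixel_scale`. Two deliberate oddities
are preserved. First, the constant is the literal 3.14, not `pi`, for
bit-compatibility with the original analysis scripts. Second, the formula is
geometrically the *equivalent-circle radius* of the blob rather than any
ellipse axis; since it is only used as a relative scale for the exclusion
rule, internal consistency matters more than geometric interpretation.

The exclusion rule: any frame pair whose displacement exceeds **half the
body length** is removed from speed calculations. In this assay such jumps
come from the experimenter manually re-centering the animal when it crawls
out of the field of view, and a single un-excluded jump can inflate a mean
speed severalfold (the simulator's teleports reproduce this: with three
injected jumps in a 150-frame recording the raw mean speed is wrong by
hundreds of percent; after exclusion the error is under 0.1%). The
inequality is strict — a displacement of exactly half the length is kept.

Up to three recordings of the same larva are pooled. Pooling concatenates
the individual instantaneous speeds (a pooled mean, not a mean of
per-recording means), so recordings contribute in proportion to their
usable frame pairs; one body length is computed from the pooled mean area
and applied to all recordings of the larva. The SD is the sample SD (n−1).
Bookkeeping fields (`n_speed_samples`, `n_excluded_pairs`,
`n_invalid_frames`, `n_pairs_total`) always partition the total
consecutive-pair count, which the tests assert.

## Hit calling

For one larva recorded at both temperatures, the normalized change is

$$ n = \frac{r - p}{p} $$

with \(r\) and \(p\) the mean speeds at restrictive and permissive
temperature. Per larva, fold change and normalized change are redundant
(\(r/p = n + 1\)); at the genotype level the package reports
\(\bar r / \bar p\).

A genotype is **slow** when both of these one-tailed tests reject at
`alpha` (default 0.05):

1. its per-larva restrictive-temperature mean speeds are lower than the
   control's;
2. its per-larva normalized changes \(n\) are lower than the control's.

Both use Welch's unequal-variance two-sample t statistic with
Welch–Satterthwaite degrees of freedom under the null of equal means — the
standard reading of a "t-test assuming equal means but unequal variance".
The test direction is hard-wired to *slower than control*: the assay design
can reveal slow phenotypes but has no mechanism expected to produce fast
ones, and screening both tails would double the false-positive load for no
gain. The biological replicate is the larva, so criterion 1 compares
per-larva means rather than pooled frame-level speeds. Larvae with \(p \le
0\) have no defined \(n\) and are dropped from criterion 2 with a logged
count.

No multiple-testing correction enters the verdict — the hit list is meant
as a screening funnel whose candidates get re-tested individually —
but Benjamini–Hochberg adjusted p-values are attached as informational
columns for readers who want them.

## The simulator

**Kinematics.** Behavioral modes are `run_forward`, `run_reverse`, `pause`
and `head_cast`, switched by a first-order Markov chain (the simplest
generator consistent with a run/pause-turn/head-cast ethogram; the default
`"explore"` preset is run-dominated with brief interruptions, matching the
forward bias larvae show in this assay). Heading follows a Gaussian random
walk (`heading_noise`, default 0.15 rad/frame). Head casts move the
centroid laterally at a configurable fraction of run speed, alternating
side each frame — head casting has no canonical centroid-level kinematics,
so the zigzag is a package convention. The arena boundary is
reflective (specular), like a physical agar dish wall, and reflection
preserves the distance traveled, so the true speed series integrates to the
traveled path length exactly (a tested invariant). Teleports are injected
as instantaneous jumps to a uniformly chosen distant point at uniformly
chosen frames: repositioning is modeled as displacement, not as simulated
experimenter behavior, and the true speed series is untouched by it.

**Defaults.** 800 frames at 4 Hz; `pixel_scale = 30` um/px so a ~0.6 mm
first-instar larva spans ~20 px, consistent with low-magnification
screening (published screens of this type do not state camera calibration,
so this is a documented convention); `run_speed = 100` um/s, the order of
control restrictive-temperature speeds.

**Rendering.** The larva is a filled rotated ellipse (default 3:1 aspect
from the body length) on a uniform background, plus optional static disc
distractors and additive Gaussian noise, quantized to 8-bit. The
`render_config()` validator enforces a foreground/background contrast of at
least 3 noise SDs, so rendered fixtures are segmentable by construction.
What the renderer does *not* emulate: peristaltic shape change, self-shadow
and illumination gradients, motion blur, occlusion, or posture (the ellipse
has no head). Passing end-to-end tests therefore demonstrates that the
chain recovers centroid kinematics from clean single-animal scenes — not
that it is robust to every artifact of real video.

**Screen data.** Per-larva permissive speeds are drawn from a noise model
with configurable mean and SD (defaults 65 and 47 um/s); restrictive speeds
are `permissive x genotype fold change x multiplicative mean-one lognormal
noise` (SD `restrictive_noise_sd`, default 0.1). The default marginal model
is lognormal because it is positive by construction and matches the
requested mean and SD *exactly*; the alternative zero-truncated normal
with these parameters has a realized mean of ~73 um/s, which would no
longer center control speeds on the configured 65. Note one structural
limit of the multiplicative model: with control SD 47 and fold 1.5 the
restrictive-temperature SD cannot fall below 1.5 x 47 ≈ 70 um/s, slightly
above the ~66 um/s reported for real controls; the default
`restrictive_noise_sd = 0.1` keeps the extra inflation small.

## Statistical behavior under the default conditions

Two properties of the hit caller are measured by simulation (the test suite
and `scripts/acceptance.R` recompute both; numbers below are what those
runs print, at the problem sizes they use — 8,000–20,000 null genotypes and
200 power replicates).

**Calibration.** On all-null screens (every genotype drawn as control,
n = 10 larvae per group) each single criterion rejects at close to its
nominal 5% — the restrictive-speed criterion runs slightly conservative
(~4.3–4.8%) because one-tailed t tests on strongly right-skewed lognormal
speeds (CV ≈ 0.72) lose a little tail accuracy — and the two-criterion AND
verdict's false-positive rate is far below alpha (~0.4%), since the two
criteria are only partially correlated.

**Power.** With the default variability (permissive SD 47 um/s, i.e.
CV ≈ 0.72) and n = 10 larvae per group, a planted genotype with fold change
0.8 against a control fold of 1.5 is recalled by the two-criterion verdict
in only ~55–60% of replicates. The bottleneck is criterion 1: the
normalized-change criterion pairs each larva with itself and cancels the
large between-larva speed variation (its single-criterion power is near 1),
but the raw restrictive-speed comparison faces the full between-larva SD,
giving an effect-to-SE ratio near the rejection threshold. This is a real
property of the assay design at this sample size, not of the
implementation: detecting that effect reliably (>80%) under these SDs
requires roughly 15–20 larvae per group, stronger effects (fold ≤ 0.6 is
recalled essentially always at n = 10), or a verdict that leans on the
paired criterion alone.

## Degenerate inputs and tie-breaks

* Constant frame → `no_object`; empty or non-2-D image → error.
* Fewer than two adjacent ok frames → empty speed table, not an error.
* A larva with zero usable frames → summary row with `NA` mean, not a
  crash.
* Two components passing the size gate → `multiple_objects`, never a
  closest-area tie-break.
* Welch test on two identical constant samples → t = 0, p = 0.5.
* `p <= 0` in a normalized change → `NA` plus a warning, dropped from
  criterion 2.
* Empty experimental genotype list → empty hit table with full schema;
  reports then contain the control row only.

## Validation problem sizes

The test suite renders and tracks 20 videos of 200 frames for the
end-to-end speed check (median relative error well under 5%), uses 20,000
Monte-Carlo genotypes for calibration, 200 replicates for power, and ~120
random sample pairs plus ~45 random masks for the oracle-agreement checks.
These sizes were chosen so Monte-Carlo error is small relative to the
quantities being checked while a full run stays in the minutes range on a
single core.
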