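---
title: "Methods: posture and motion detection from 8x8 thermal arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: posture and motion detection from 8x8 thermal arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermogrid)
```

## The sensing problem

An 8x8 infrared array reports 64 pixel temperatures plus a scalar
ambient (thermistor) reading `t`, at roughly 1.6 Hz (one frame every
0.625 s). A warm human body (apparent surface temperature around 30
degC) in front of the sensor raises a cluster of pixels above the
background, forming a crude silhouette. The package answers two
questions per frame, without any trained model: is the person *standing*
or *sitting*, and are they moving *toward* or *away from* the sensor?
Alongside this closed-form path it carries a conventional ML comparison
arm (k-NN, SVM, random forest, naive Bayes on the raw 64 pixel values).

## The detector

Three statistics are computed per frame:

1. `A1 = sum(pt) / px` — the mean of the `px = 64` raw pixels (degC).
2. `df = A1 / t` — the *difference factor*, dimensionless. Dividing by
   the ambient temperature makes the statistic robust to the room
   warming or cooling as a whole; what remains is the body's relative
   contribution. `df` is undefined at `t = 0` degC and the detector
   refuses to divide there (physically, the sensor class loses
   discrimination near freezing anyway).
3. `A2` — a normalized mean of the bilinearly upsampled grid. The
   canonical normalization (`a2_mode = "alg1"`) divides the grid total
   by the *row count* `side = 8*ipf` and multiplies by `df`:
   `A2 = side * mean(z) * df`.

The decision rules are

- **standing** iff `A2 > px * t * df`, ties to sitting;
- **approaching** iff `df` increased since the previous frame
  (strictly, by more than the hysteresis `epsilon`), **receding**
  otherwise, **unknown** on the first frame.

Because `df > 0` indoors, the posture rule in alg1 mode reduces
algebraically to a df-free threshold on the interpolated mean:

```
mean(z) > (px / (8 * ipf)) * t        # = 0.8 * t at ipf = 10
```

This reduction is the package's main internal consistency check: the
test suite verifies exact agreement between the composed pipeline and
the reduced inequality on 1000 random frames.

### The two A2 normalizations

The normalization is genuinely ambiguous in the method's original
statement: a closed-form definition divides the interpolated total by
`ipx = px * ipf` (640 cells at `ipf = 10`), but the interpolated grid
actually holds `(8*ipf)^2 = 6400` cells, and the reference real-time
loop divides by the row count instead. The two disagree by a factor of
`side/ipf = 8`. We take the loop's form (`"alg1"`) as canonical — it is
the executable version the original results were produced with, and it
is the only one whose standing condition is reachable for realistic
indoor temperatures — and retain `"eq6"` (`A2 = ipf * mean(z)`) as a
documented alternative for comparison. Nothing in the package's
defaults uses `"eq6"`.

### Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `ipf` | 10 | — | per-axis upsampling factor; 10 balances silhouette smoothness against cost, and is where the reduced threshold `0.8*t` separates the default scenes |
| `a2_mode` | `"alg1"` | — | A2 normalization (above) |
| `epsilon` | 0 | — | motion hysteresis on the df increase; 0 reproduces the strict comparison, under which an *unchanged* df labels as receding (a documented quirk); raise to suppress noise-driven flapping |
| `sample_period` | 0.625 | s | nominal frame interval; informational, the detector is timestamp-agnostic |

### Interpolation-factor dependence

The threshold `(px/(8*ipf)) * t` scales with `1/ipf`: at `ipf = 1` it is
`8t` (no frame can exceed it — everything labels sitting) and at
`ipf = 50` it is `0.16t` (everything labels standing). The rule is
therefore only discriminative in a band around the operating factor,
which is exactly what an accuracy-vs-factor sweep (`sweep_ipf()`)
shows and why 10 is the shipped default:

```{r sweep}
d <- generate_dataset(40, c("standing", "sitting"), noise_sd = 0, seed = 9)
frames <- dataset_to_frames(d)
sweep_ipf(frames, attr(frames, "labels"), c(1, 2, 5, 8, 10, 12, 50))
```

## Bilinear upsampling: numerical choices

- **Output size** is `side * ipf` per axis (8x8 at factor 50 gives
  400x400), matching the method's printed grid sizes, rather than the
  `(side-1)*ipf + 1` convention some image libraries use.
- **Align-corners mapping**: output index `j` (0-based, axis length `m`)
  maps to source coordinate `j*(s-1)/(m-1)`. The first and last output
  samples coincide with the first and last source pixels, all weights
  stay in [0, 1], and corner preservation is exactly testable. A mapped
  coordinate landing on the last source row/column degenerates its
  bracketing cell (`x1 = x0`, weight 0) instead of reading out of range.
- **Evaluation form**: the four-weight average is evaluated as
  `i00 + f*(i10-i00) + g*(i01-i00) + f*g*((i11-i01)-(i10-i00))`, which
  is algebraically identical but bit-exact for constant fields, at
  corners, and at `ipf = 1` (identity). Equivalence with the literal
  four-weight form is asserted to 1e-12 against a scalar-loop oracle.
- All temperatures are 64-bit floats; no rounding on output. Outputs are
  convex combinations of inputs, so `min(src) <= z <= max(src)` up to
  double-precision round-off (tests allow 1e-12).

One subtlety worth knowing: align-corners resampling gives border source
pixels roughly half the representation of interior ones, so the
*interpolated* mean of a centre-heavy silhouette runs 2–3% above the raw
frame mean. The decision statistic is the interpolated mean, and the
simulator's defaults are calibrated against it (below).

## The scene simulator

The simulator exists so that every module is testable without hardware:
it emulates, per frame, a warm axis-aligned elliptical silhouette over a
uniform background.

- **Geometry.** Pixel (0,0) is top-left; the grid spans [0,8]^2 with the
  silhouette centred at (4, 4) by default. Reference semi-axes at 0.5 m:
  standing 3.2 x 1.4 pixels (tall and narrow), sitting 1.25 x 0.8
  (compact). Both axes scale by `0.5/distance` — a pinhole-style
  apparent-size law — so silhouette area is non-increasing in distance
  and the standing area strictly exceeds the sitting area at equal
  distance.
- **Coverage.** Each pixel's body fraction is the fraction of a 15x15
  midpoint subgrid falling inside the ellipse — deterministic,
  platform-stable, and accurate to well under a percent of a pixel;
  exact ellipse–rectangle areas would add complexity without changing
  any decision. Pixels blend as
  `bg + coverage * (body - bg)`, then i.i.d. Gaussian noise (sd 0.3
  degC, inside the sensor class's 0.5–1.0 degC accuracy band) is added
  and values are clamped to the sensor range [-20, 80] degC.
- **Defaults as calibration.** Background 13 degC, body 31 degC, ambient
  18 degC, distance 0.5 m. These are documented calibration choices (the
  original recordings never report raw pixel magnitudes relative to the
  thermistor): they are set so that at `ipf = 10` the noiseless standing
  interpolated mean (≈ 18.0 degC) lies above the `0.8*t = 14.4` degC
  threshold and the sitting one (≈ 14.1 degC) below it — separation *by
  construction*, about 7 noise standard errors of margin for the sitting
  class. The sitting geometry is deliberately sized against the
  interpolated mean, not the raw mean, for the reason noted above.
- **Sway states.** The ML arm's four-state task adds `swingfb`
  (forward–backward sway: distance oscillates, `0.32 + 0.06 sin(phase)`
  m) and `swinglr` (lateral sway at 0.45 m: centroid column oscillates
  by ±1.5 pixels), both with a 16-frame period (10 s at the 0.625 s
  frame interval). The base distances of the three standing-silhouette
  states are deliberately staggered (0.5 / 0.32±0.06 / 0.45 m) so no two
  states collide in single-frame appearance — the classifiers see one
  row at a time and have no access to temporal phase.
- **Determinism.** Every generator takes an integer seed; per-state
  blocks of `generate_dataset()` use independent substreams (`seed + s`)
  and trajectories share one stream, so reruns are byte-identical.

### What the simulator does *not* model

No radiometric optics (field of view, emissivity, lens falloff), no
multi-person scenes, no clothing or partial occlusion, no pixel-to-pixel
calibration error or temporal drift, and silhouettes are perfect
ellipses. Passing tests therefore demonstrate that the *algorithms* are
implemented correctly and behave as designed under their stated
assumptions — not that the accuracy figures transfer to real recordings,
whose published values were measured on physical sensor data and are
outside what a simulation can certify.

## Dataset layout and splitting

The ML-canonical CSV has exactly 65 columns: `p00..p63` (row-major from
the 8x8 grid) and `state`. Floats are serialized with 17 significant
digits so write→read round trips are lossless; the dialect is comma,
`.` decimal, UTF-8, LF, mandatory header. The train/test split takes
`round(total / 5)` test rows — the nearest-integer rule is the one
consistent with both reference splits (752 → 602/150, 1542 → 1234/308) —
after a seeded shuffle (whether the original data were shuffled is
unstated; `shuffle = FALSE` preserves order and cuts the tail).

## ML baselines

Hyperparameters were never stated for the original comparison, so the
package ships field-standard defaults, all overridable: k-NN `k = 5`;
SVM with RBF kernel and cost 1; random forest with 100 trees; Gaussian
naive Bayes. Training consumes the raw 64-pixel rows only —
interpolation is deliberately excluded from the feature path, since the
upsampled map adds no information for a discriminative model. Per-state
accuracy is recall (correct / test rows of that state), so confusion
matrix row sums equal per-state test counts. Wall-clock train/predict
times are reported for interest and never asserted. The published
accuracy tables for these baselines came from the authors' real sensor
recordings and are not reproduction targets for the simulator.

## Problem sizes used in validation

The shipped validation uses 1000 randomized interpolation cases, 1000
random detector frames, 200 frames per state for recognition accuracy
(400 posture frames, 10+10 twenty-step trajectories, an 800-row
four-state ML dataset), sizes at which every property is measured with
comfortable margins while the whole suite runs in well under a minute.

## Known limitations

- The closed-form detector distinguishes exactly two postures and two
  motion directions; it cannot detect falls, multiple people, or the
  sway states (those are ML-only by design).
- With `epsilon = 0` the motion label flaps between
  approaching/receding for a *still* subject, since noise makes `df`
  rise or fall each frame; this mirrors the strict reference loop.
  Raise `epsilon` to bias stillness toward "receding" or filter the
  trend upstream.
- The `"eq6"` A2 mode is provided for completeness but makes the
  standing state practically unreachable; it is not wired to any
  default.
- The posture threshold presumes the ambient reading exceeds the
  background-dominated frame mean by a known margin; rooms where the
  thermistor runs cooler than the scene it watches would need the
  body/background defaults re-examined.
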