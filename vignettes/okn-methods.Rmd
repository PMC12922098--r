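---
title: "Measuring optokinetic nystagmus from eye-camera video: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring optokinetic nystagmus from eye-camera video: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Optokinetic nystagmus (OKN) is the involuntary sawtooth eye movement evoked
by a drifting visual stimulus: the eye tracks the stimulus smoothly (the
slow phase, SP) and snaps back (the quick phase, QP).  Because OKN is
reflexive, its presence or absence at decreasing stimulus visibility is an
objective proxy for visual acuity - valuable for pre-verbal children and
other patients who cannot complete a letter chart.

Commercial wearable eye trackers report a gaze signal that usually suffices
to detect OKN.  But small, fast "stare" OKN (amplitudes around a degree,
beat rates toward 2 Hz) can be under-resolved in the gaze output, producing
false negatives even though the oscillation is plainly visible in the raw
infrared eye-camera video.  This package implements and evaluates two ways
of re-extracting the displacement signal directly from that video:

* **Centroid tracking (C)** - classical dark-pupil segmentation: threshold,
  clean up, take the blob's center of mass per frame.
* **Phase-based motion microscopy (MMIC)** - an Eulerian measurement that
  never segments anything: each frame is decomposed with a complex
  steerable pyramid and tiny displacements are read out of sub-band phase.

Detection then runs on any 1-D displacement trace (gaze, centroid, or
phase), per-eye decisions are OR-combined, and a two-stage "STEP" scheme
consults a video method only when the gaze method reports absence.
Performance is scored against ground truth with confusion matrices and the
Matthews correlation coefficient (MCC).

## The phase-flow model

Each frame $I(\mathbf{x}, t)$ is multiplied in the frequency domain by a
bank of masks $B_l$, each selecting one radial octave and one orientation
window on a single half-plane:

$$\mathcal{F}\{R_l(\mathbf{x},t)\} = \mathcal{F}\{I(\mathbf{x},t)\}\, B_l .$$

Because the masks are not conjugate-symmetric, the spatial sub-bands
$R_l = A_l e^{j\phi_l}$ are complex, giving a local amplitude $A_l$ and a
local phase $\phi_l$ per level.  Motion is encoded by the iso-contours of
the temporally unwrapped phase: writing
$\Delta\phi_l(\mathbf{x},t) = \phi_l(\mathbf{x},t) - \phi_l(\mathbf{x},0)$
and linearizing,

$$\Delta\phi_l \approx -\nabla\phi_l \cdot \mathbf{d},$$

so the displacement $\mathbf{d} = (\Delta x, \Delta y)$ relative to the
first frame solves the amplitude-weighted least-squares system
$A^\top W^2 A\, \mathbf{d} = A^\top W^2 \mathbf{b}$ across levels, with one
gradient row per level and weights coupling the amplitudes at both times,
$W^2_l = A_l(\mathbf{x},t)\,A_l(\mathbf{x},0)$.  Invertibility requires at
least two levels with independent orientations; the default bank has
5 scales x 4 orientations = 20 levels.  Note the sign: content moving
toward larger $x$ lowers the phase along its own gradient, and the solver
is arranged so that positive $\Delta x$ means rightward image motion.
No temporal derivative appears anywhere - each sample is solved against the
fixed $t = 0$ reference, so a dropped frame affects only its own sample.

### Filter-bank construction

The radial windows are raised cosines in $\log_2 r$ (one octave wide,
full-octave spacing, non-decimated), the self-inverting design in which the
squared windows telescope to one.  The angular windows are
$\alpha_K \lvert\cos(\theta - \theta_k)\rvert^{K-1}$ with
$\alpha_K = 2^{K-1}(K-1)! / \sqrt{K\,(2K-2)!}$, treated with period $\pi$,
and every oriented mask is restricted to the common half-plane
$\omega_y > 0$ (plus the positive $\omega_x$ axis).  Two consequences worth
stating:

* **Tiling is exact.**  At every non-DC frequency sample of the covered
  half-plane, $\text{hi}^2 + \text{lo}^2 + \sum_l B_l^2 = 1$ to floating
  precision (`csp_tiling_deviation()` is about $10^{-15}$), so no energy is
  invented or lost at band boundaries; DC and the Nyquist ring belong
  entirely to the residual low- and high-pass masks.
* **The Parseval factor is 2.**  Real frames have Hermitian spectra, so the
  half-plane sub-bands carry exactly half of each band's energy:
  $\lVert I - \bar I\rVert^2 = \lVert\text{hi}\rVert^2 +
  \lVert\text{lo} - \bar I\rVert^2 + 2\sum_l \lVert R_l\rVert^2$.

Non-decimated storage (no down-sampling between octaves) keeps every
sub-band at frame resolution, which makes per-pixel gradients and the
least-squares solve stencil-free at the cost of memory - the right trade
for 192 px frames.

### Numerical choices

* **Phase gradients are spectral, not finite differences.**  The design
  matrix wants the local spatial frequency $\nabla\phi_l$.  Central
  differences of (wrapped) phase act as a noisy, smoothed regressor;
  because that error sits in the *design matrix*, it attenuates the
  least-squares displacement like a classical errors-in-variables bias -
  about 10% low on band-limited texture, varying with position.  We instead
  compute $\partial R_l/\partial x$ exactly in the frequency domain
  ($j\omega_x$ scaling) and use the instantaneous frequency
  $\mathrm{Im}(\bar R_l\, \partial_x R_l)/\lvert R_l\rvert^2$.  The solver
  further averages the gradient between the reference and current frames
  (a trapezoidal scheme, second-order accurate for a pure shift, since the
  true phase change is the integral of the local frequency across the
  displacement).  Together these make the recovery of a pure sub-pixel
  shift accurate to about 0.1% at 0.01 px and a few percent at 1 px, where
  curvature of the fine-scale phase is the remaining error.
* **Temporal unwrapping** adds the multiple of $2\pi$ that brings each
  consecutive phase difference into $(-\pi, \pi]$, per pixel and level; the
  first sample is untouched.
* **Median filtering** (default window 3) runs along time on the unwrapped
  phase to suppress isolated phase spikes.  The reference sample is pinned:
  otherwise a step between frames 0 and 1 would be voted away and every
  later delta measured against the wrong baseline.
* **Singular systems are refused, not regularized.**  A pixel whose
  weighted normal matrix is rank-deficient (single orientation of content,
  vanishing amplitude) yields a missing sample; `solve_displacement()`
  raises an error naming the pixel.  A silent ridge term would bias exactly
  the small amplitudes this method exists to measure.
* **The measurement point** defaults to the limbal edge nasal to the pupil
  (mean tracked pupil center minus the iris radius), and the solution is
  averaged over a 5 x 5 pixel grid around it.  Any texture-bearing point
  works; a pure isolated edge does not (its gradients span one orientation
  only), which is why the synthetic iris carries band-limited radial
  texture.

With a fixed $t=0$ reference, multi-pixel excursions stress the
linearization for the finest levels; their misfit shows up as transient
spikes around quick phases rather than as slow-phase errors, and the
detector's smoothing absorbs them.  Drift over an 8 s trial is accepted -
detection differentiates the trace anyway.

## Centroid tracking

Per frame, inside a region of interest: threshold (`intensity <
threshold`), label 8-connected dark components, close each blob with its
convex hull (which also fills holes), and filter by equivalent diameter
$\sqrt{4A/\pi}$ and circularity $4\pi A / P^2$ with the perimeter traced
along the outer contour (diagonal steps count $\sqrt 2$; a rasterized disk
scores about 0.91).  The pupil is the **largest consistent** candidate,
where consistent means within `consistency_radius` (default 15 px at
192 px frames) of the last valid center - a gating rule that rejects
eyelash and shadow blobs far from the established track.  The center is
the unweighted binary center of mass.  Frames without a consistent
candidate are missing; a video losing strictly more than 30% of frames is
"low data" and drops to the retest partition.  There is no interpolation
across gaps - the detector handles them.

## Sawtooth detection

The detector looks for the defining OKN signature in the known stimulus
direction: a slow ramp followed immediately by a fast opposite reset.
Pipeline: Savitzky-Golay smoothing and differentiation (order 2, window
scaled to the sampling rate); velocity-sign runs, with runs shorter than
`min_run_s` merged into their predecessor and trace gaps breaking runs; a
slow run in the stimulus direction paired with the immediately following
opposite run; the reset truncated at its displacement extremum (otherwise
flat noise after a sawtooth stretches the quick phase and poisons its
statistics); a consistency test (slow phase longer than quick phase, quick
phase faster than slow phase - the defining asymmetry of nystagmus); and
amplitude / duration / velocity thresholds.

A trial is positive if two sawteeth are consecutive (end-to-onset gap at
most `consecutive_gap_max` = 0.2 s) or if three or more occur anywhere.
No-stimulus trials are tested in both directions.  Eyes combine by logical
OR, one available eye decides alone, and the STEP variants are pure
multiplexers: gaze decision if positive, else the video method's decision -
which makes STEP sensitivity $\ge$ gaze sensitivity an algebraic identity,
at the cost of specificity (the standard serial-combination trade-off).

Two presets are shipped and were fixed empirically on the synthetic
generator, then frozen in the tests: `"gaze"` (degrees, 200 Hz: minimum SP
amplitude 0.3 deg, SP duration 0.15-2 s, SP speed 1-20 deg/s, QP speed
at least 2.5 deg/s after smoothing, smoothing window 0.125 s) and
`"video"` (pixels, camera rate: minimum SP amplitude 0.8 px, SP speed
1.5-60 px/s, QP speed at least 3 px/s, window 0.15 s).  The QP minima are
deliberately below the physical reset speed because Savitzky-Golay
smoothing smears a 0.15 s reset at 30 fps to roughly half its true peak
velocity.  Pixel-unit thresholds inherit the camera geometry; on real
recordings they would be retuned per setup, exactly as the region of
interest and intensity threshold of the centroid tracker are tuned per
participant.

## What the synthetic generator emulates - and what it does not

`okn_trial_set()` reproduces the study design: 8 s trials, stimulus at
logMAR 0.5 / 0.3 / 0.1 and a no-stimulus condition, three repeats each,
direction randomized left/right.  Visibility maps to the synthetic
response - full responses (3 and 2 deg, 0.8-1.5 Hz) at the two easy
levels, partial responses at 0.1 logMAR (1 deg, 1.4-1.8 Hz, present with
probability 0.6), nothing for no-stimulus trials - echoing the two observed
regimes (roughly 4 deg at 0.8 Hz when well resolved, roughly 1 deg at
1.8 Hz when not).  A configurable fraction (default 0.2) of present trials
has the *gaze rendering* attenuated (gain 0.1), emulating the
under-resolved tracker output that motivates the video methods; the videos
always show the true movement.  This mapping is synthetic by construction
and claims nothing about human psychometrics - passing tests show the
pipeline recovers what the renderer put in, not that it would score
identically on human data.

`render_eye_video()` draws a schematic eye - bright sclera, iris with
seeded band-limited radial texture (guaranteeing a non-degenerate phase
system at the limbus), dark pupil, logistic edges - and translates it by
the waveform using exact FFT sub-pixel shifts (the image is periodic, so
wrap-around is seamless; frame-to-frame registration of noiseless renders
agrees with the command to better than 0.02 px).  Occluders reproduce the
two documented failure modes of threshold segmentation: eyelash bars
covering the pupil, and a shadow channel of dark pixels connecting pupil
to background so the blob merges and fails the shape filters.  The eye
camera's frame rate is not dictated by the hardware here; the generator
defaults to 200 Hz to match gaze and is routinely run at 30 fps.
Degrees convert to pixels at `6 * size / 192` px/deg - the nominal
eye-camera geometry, scaled with the rendered frame.

## Problem sizes used by the shipped validation

The packaged test suite and `scripts/acceptance.R` run a complete
simulated study of 20 participants x 12 trials with one eye per trial
(the single-eye fallback path is then exercised throughout), 64 px
renders at 30 fps with a 3 x 4 pyramid, and shadow occluders for two
participants; these are the package's chosen validation sizes - large
enough for stable pooled metrics (216 main-partition trials), small
enough to run everywhere.  Unit tests exercise the full 192 px / 5 x 4
study geometry on shorter fixtures.  On these conditions the pooled
main-partition MCC is about 0.98-0.99 for both video methods versus about
0.8 for the attenuated gaze baseline, and the STEP variants recover every
gaze miss - the serial-combination property holds by construction.

## Known limitations

* Pixel units are never converted to degrees; camera distance and eye
  geometry therefore scale the video presets (the recordings this mirrors
  had the same property).
* The fixed reference frame accumulates linearization error for
  multi-pixel excursions at fine scales; level restriction
  (`levels =` in `extract_point_trace()`) is exposed but off by default.
* Circularity uses a chain-code perimeter and tops out near 0.91 for
  rasterized disks; thresholds are calibrated accordingly.
* The renderer is schematic: no glints, eyelid dynamics, pupillometry, or
  photometric variation; occluders are stylized versions of the real
  artifacts.
* Look-vs-stare classification, vertical/torsional components and OKN gain
  estimation are out of scope.
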