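---
title: "Probe exclusion, boundary energetics and diffusion at cell-bilayer contacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe exclusion, boundary energetics and diffusion at cell-bilayer contacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanogap)
```

# The system and the questions

When a cell settles onto a supported lipid bilayer (SLB) decorated with
adhesion "spacer" proteins, the two membranes are held at a gap set by the
spacer complex: `P = spacer length + ligand length` (nanometres). A
diffusing probe of hydrodynamic diameter `Q` anchored in the bilayer — in
the motivating experiments a streptavidin-conjugated quantum dot — then
experiences the contact as a nanoscale slot: the quantity

\[ \Delta(P, Q) = P - Q \]

predicts whether the probe fits under the cell (`gap_delta()`). Negative
\(\Delta\) means the probe is larger than the gap. Three single-particle
readouts quantify what the contact does to such probes:

1. **Exclusion** — the first-frame probe density inside the contact
   relative to outside, `relative_density()`; exclusion is
   `1 - relative density`.
2. **Boundary energetics** — tracked probes attempt to cross the contact
   border; the success fraction `p = n_success / n_attempts` converts to
   an effective energy penalty via the Boltzmann relation
   \(\varepsilon = -\ln p\) (in kT), separately for entry and exit
   (`tally_crossings()`, `energy_penalty()`).
3. **Mobility** — the distribution of jump distances (JD) between
   consecutive frames encodes the local diffusion coefficient. The
   cumulative distribution of squared jumps follows
   \(P(r^2, \Delta t) = 1 - \exp(-r^2 / r_0^2)\) with
   \(r_0^2 = 4 D \Delta t + 4\sigma^2\), where \(\sigma\) is the
   localization precision (`fit_jd_cumulative()`). JD maps
   (`jd_map()`), intensity-zone fits (`zone_diffusion()`) and the
   retention fraction (`retention_fraction()`) resolve mobility in space.

All of this is driven end-to-end by a synthetic-data generator with known
ground truth, so every estimator in the package is testable without
external recordings.

# The synthetic-data generator

`simulate_tracks()` performs Brownian dynamics on a pixel grid carrying a
binary contact mask:

- Per frame, each particle takes an isotropic Gaussian step with per-axis
  standard deviation \(\sqrt{2 D_{\mathrm{local}} \Delta t}\).
- When the continuous step segment crosses the mask boundary, the
  crossing is accepted with probability \(e^{-\varepsilon}\) for the
  corresponding direction (entry or exit); rejected steps are specularly
  reflected at the boundary, which preserves the step-length
  distribution. Crossing detection samples the step segment at a quarter
  pixel and refines the crossing point by bisection, so fast particles
  cannot tunnel through the border between samples; boundary normals for
  reflection come from the gradient of a Gaussian-smoothed mask
  indicator.
- Reported positions add independent Gaussian localization noise
  (`sigma_loc`) per axis; tracks terminate per frame with probability
  `1 - survival_prob` and are replaced by fresh particles so the density
  stays stationary; field edges reflect.

Defaults are the acquisition conditions of the motivating experiments:
1000 frames at \(\Delta t = 30\) ms, free bilayer diffusion
`d_out = 0.6` um^2/s, and `survival_prob = 0.93`, which makes track
lengths geometric with mean \(1/(1-0.93) \approx 14\) frames. The pixel
size (0.16 um/px, a typical 100x EMCCD configuration) and the
localization noise (0.03 um) are realistic choices rather than published
values. The default contact is a 6 um-radius disk — real contacts are
comparable in scale but irregular; the disk radius is configurable. The
spacer-channel image (`generate_spacer_image()`) is a uniform bilayer
background plus an elevated contact modulated by a smoothed Gaussian
random field (default relative amplitude 0.25, correlation length 4 px),
emulating spatially heterogeneous spacer density within one contact.

What the generator deliberately does **not** emulate: probe photophysics
beyond an optional two-state blinking switch (off by default), EM-gain
camera statistics, membrane topography in 3D, and protein crowding as a
mechanism — barriers and local slowdown are imposed phenomenologically.
Passing estimator-recovery tests on these synthetics therefore shows the
*estimators* are correct and unbiased under the stated noise model; it
does not by itself validate the biological interpretation of any real
recording.

# Contact masking

The contact is segmented from the spacer channel (in practice the
temporal mean image; the generator emits a single mean-equivalent frame)
by thresholding the gradient magnitude at 0.2 times its maximum (Sobel
operator after 1 px Gaussian smoothing). The thresholded gradient forms a
band straddling the true edge; morphological closing (disk, 2 px) and
hole filling convert it into a filled region whose boundary sits at the
band's *outer* rim. The filled region is therefore eroded by the closing
radius to re-centre the boundary on the edge — without this step the mask
systematically overshoots by about 2 px, which is the difference between
a Jaccard overlap of ~0.90 and ~0.97 against ground truth. Components
smaller than `min_object_area` (default 0.5 um^2) are discarded as
bilayer inhomogeneities and the largest remaining component is the
contact; one contact per field is assumed. Because the threshold is
relative to the image's own maximal gradient, the mask is invariant to
affine intensity rescaling.

Conventions: images are `[row, col]` matrices, pixel `(i, j)` covers the
half-open square `[(j-1), j) x [(i-1), i)` times `pixel_size` with the
origin at the top-left; a localization on a mask pixel (boundary pixels
included) counts as inside. `dilate_mask()` returns the annular control
region (dilated minus original) used to verify that the free bilayer
imposes no entry restriction.

# Tracking

`detect_peaks()` finds local maxima above `median + 5 * MAD` of the
frame, suppresses neighbours within `min_separation`, and refines
positions by a 5x5 background-subtracted centroid. `link_tracks()` uses
greedy mutual-nearest-neighbour frame-to-frame assignment within
`max_jump` (default 0.8 um, about four times the rms step at the default
diffusion), the simplest linker consistent with the low probe densities
used; there is no motion model, gap closing is off by default, and tracks
not longer than five frames are discarded ("longer than five" is read
strictly: at least six localizations). Mutual-NN linking slightly censors
long jumps when particles come close — on dense synthetics this biases
fitted `D` down by a few percent — which is why estimator-validation
tests that target generator physics run on the generator's own track
tables, while pipeline-level comparisons always process experiment and
null identically so the linker bias cancels.

# Boundary energetics: estimator design

The energy estimator was the one place where the obvious implementation
fails quantitatively, and the design deserves a careful record.

An *attempt* is one boundary-approach episode: it opens when a track
arrives within `touch_band` (default one pixel, 0.16 um) of the contact
border — a particle hovering at the border for several frames is one
attempt, not one per frame — and its outcome is read exactly one frame
later: success if the track is then confidently on the opposite side.
Two details make \(-\ln p\) minus the barrier-free null baseline a
consistent estimator of the generative barrier:

- **Single-frame outcome window.** If an episode is instead resolved
  whenever the particle eventually leaves the border band, its outcome
  mixes several crossing proposals and the *re*-crossing dynamics
  governed by the opposite barrier: an entry barrier makes successful
  exits "stick" and inflates the apparent exit probability, so baseline
  subtraction cannot recover either barrier (we measured corrected
  estimates of ~1.1 and ~-0.1 kT for true barriers of 1.5 and 0.3 kT).
  With a one-frame window, the probability that the opening step proposes
  a crossing at all is a purely geometric factor, identical in the
  barrier and null runs, and cancels in the subtraction; recovery on the
  same synthetics becomes 1.48 and 0.19 kT.
- **Noise-gated side assignment on a continuous distance.** The side of
  each localization is the sign of a signed distance to the boundary,
  interpolated from a distance field computed on a 4x-upsampled grid (on
  the coarse grid the interpolated zero level wanders up to half a pixel
  off the true pixel boundary on curved edges, which mislabelled up to a
  quarter of exit attempts in ground-truth audits). Localizations within
  `side_margin` (default 0.09 um, three times the default localization
  precision) of the boundary are ambiguous and inherit the last confident
  side, so single-frame apparent flips caused by localization noise are
  not scored as crossings. A track born inside the band arms only once
  its side is confident.

Tracks with fewer than five recorded localizations after first touching
the border are excluded entirely (avoiding censoring bias toward failed
crossings), attempts of one track are treated as independent Bernoulli
trials for the Clopper-Pearson intervals (a stated approximation), zero
successes are reported as a censored bound \(\varepsilon \ge \ln
n_{\mathrm{attempts}}\), and the null baseline is always reported
alongside raw values, never silently subtracted. Energies are in kT with
kT = 1.

Remaining honest limitations: at 30 ms sampling, sub-frame excursions are
invisible, the baseline itself is an episode-definition artefact (about
1 kT on the default geometry), and corrected estimates carry a residual
bias of order 0.1 kT; the package therefore always reports attempt counts
and intervals, and the null comparison is the primary inferential tool.

`breach_zones()` splits the boundary into segments of roughly
`segment_length` (ordered by angle around the contact centroid, adequate
for roughly star-convex contacts), assigns entry attempts to their
nearest segment and reports the Spearman correlation between per-segment
entry success and local spacer intensity; a negative correlation
identifies low-spacer-density breach zones.

# Diffusion analysis

Jump distances use consecutive-frame pairs only; a jump belongs to the
region (or intensity zone) of its *starting* localization — the choice is
documented rather than obvious, and keeps region assignment independent
of the crossing outcome. The cumulative fit minimizes the squared
deviation between the empirical CDF of \(r^2\) (plotting positions
\((i-1/2)/n\)) and \(1 - \exp(-r^2/r_0^2)\) over \(r_0^2\) by 1-D
optimization; \(D = (r_0^2 - 4\sigma^2)/(4\Delta t)\), floored at zero.
The localization precision \(\sigma\) is supplied (default 0.03 um), not
co-fitted: with a single lag time, \(D\) and \(\sigma\) are not jointly
identifiable. A single-population fit is used throughout. The printed
form of this CDF in the source literature omits the minus sign in the
exponent; the standard form is implemented, since without the sign the
expression is not a distribution function. Bootstrap errors resample
jumps with replacement (default 1000 iterations; tests and the pipeline
default use fewer for speed, stated per call).

Intensity zones are equal-count (quantile) bins of contact-pixel spacer
intensity (default 4 zones) — robust to skewed intensity histograms,
unlike equal-width bins. `jd_map()` grids mean jump distance and jump
count per pixel, with `NA` (never zero) for unvisited pixels, and reports
mean speed as mean JD divided by \(\Delta t\). `retention_fraction()` is
the share of inside-starting tracks that never leave during observation.

# The null model

`run_null()` is the matched control: free Brownian diffusion
(\(\varepsilon = 0\), uniform `D`) over the same mask at matched density,
repeated (default 20 seeds), with tracks rebuilt from the noisy
localizations by the same linker and filters as the experiment side so
estimator bias cancels in the comparison. `compare_to_null()` tabulates
experiment-minus-null differences and flags statistics outside the null's
central 95% repeat envelope, refusing to compare results produced with
different estimator settings. Null retention depends only on mask
geometry, \(D \cdot t\) and the start distribution; with ~14-frame tracks
on the default disk it sits near 0.85, so retention comparisons are
meaningful as orderings against the matched null, not as absolute
numbers.

# Auxiliary estimates

`collision_count()` implements the one-sided diffusive uptake of a dilute
solution onto an absorbing surface, \(N(t) = A c_0 \sqrt{D t / \pi}\),
the time integral of the absorbing-wall flux \(J(t) = \tfrac{1}{2} c_0
\sqrt{D/(\pi t)}\); the typeset form of this estimate in the source
literature is dimensionally inconsistent, so the standard closed form is
used and recorded in the output metadata. Combined with observed
temporary binding events it bounds the nonspecific binding rate from
below; the binding fraction among tracked particles bounds it from above
(`nonspecific_rate_bounds()`).

# Statistics and reproducibility

Across-condition comparisons use one-way ANOVA with Tukey honest
significant differences (the Tukey-Kramer correction applies
automatically for unequal group sizes) at \(\alpha = 0.05\); degenerate
inputs with zero within-group variance return a flagged undefined F
rather than an error. `run_pipeline()` executes mask → track → exclusion
→ energetics → diffusion → null comparison from a single validated
configuration (`pipeline_config()`, YAML round-trip, unknown keys
rejected), preserves partial results when a stage fails, and writes a
results directory with config hash, seeds and versions. All stochastic
operations take explicit seeds; the same configuration and seed give
bit-identical outputs.

Problem sizes in the shipped tests are chosen to give each assertion
clear statistical headroom while keeping the whole suite around two
minutes: estimator-recovery runs pool 3 fields of ~270 particles x 1000
frames (≥300 crossing attempts per direction, ≥10^4 jumps), the null
envelope uses the full 20 repeats, and closed-form checks run at
10^4–10^5 samples.
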