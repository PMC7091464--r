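# nanogap

Single-particle analysis of probe behavior at cell–bilayer contacts:
size-dependent exclusion, Boltzmann energy penalties for crossing the
contact border, jump-distance diffusion mapping, retention, and a matched
free-diffusion null simulation.

## The problem

When a cell adheres to a supported lipid bilayer (SLB) through "spacer"
adhesion proteins, the two membranes are held at a gap of size
`P = spacer + ligand` (nm). A bilayer-anchored probe of hydrodynamic
diameter `Q` (e.g. a quantum dot) experiences the contact as a nanoscale
slot characterized by

```
Δ(P, Q) = P − Q
```

with negative Δ meaning the probe is bigger than the gap. This package,
aimed at single-particle-tracking practitioners studying membrane
contacts (immune synapses in particular), quantifies what the contact
does to such probes:

- **Exclusion**: first-frame probe density inside vs. outside the contact
  mask; `exclusion = 1 − relative density`. With a 9.9 nm gap, a 21.2 nm
  probe shows a relative density of 29.3% → 70.7% exclusion, and a 14 nm
  probe 53.7% → 46.3% exclusion.
- **Boundary energetics**: crossing attempts at the contact border
  succeed with probability `p = n_success / n_attempts`; the Boltzmann
  relation `ε = −ln p` (kT) gives effective entry/exit energy penalties,
  always reported against a barrier-free null baseline.
- **Diffusion**: the cumulative distribution of squared jump distances
  follows `P(r², Δt) = 1 − exp(−r²/r0²)` with `r0² = 4DΔt + 4σ²`
  (σ = localization precision), yielding D per region, per pixel (JD
  maps) and per spacer-intensity zone; plus the fraction of probes
  retained inside the contact.
- **Null model**: free Brownian diffusion over the same mask at matched
  density and D, run through identical estimators with repeat envelopes.

A synthetic-data generator with barrier-crossing Brownian dynamics and
full ground truth (true positions, per-proposal accept/reject records)
drives the test suite, so every estimator is validated by parameter
recovery without any external data.

## Worked example

Simulate an acquisition at the default study conditions (1000 frames,
Δt = 30 ms, bilayer D = 0.6 µm²/s, ~14-frame tracks, 6 µm contact) with
an entry barrier of 1.0 kT and an exit barrier of 0.2 kT, then analyze it
as if it were real data:

```r
library(nanogap)

params <- sim_params(eps_enter = 1.0, eps_exit = 0.2, seed = 7)
field  <- generate_spacer_image(params)                    # spacer channel
mask   <- contact_mask(field$image, mask_params(),         # segment contact
                       pixel_size = params$pixel_size)
sim    <- simulate_tracks(params, field$mask)
tracks <- link_tracks(sim$tracks[c("frame", "x_um", "y_um", "intensity")])

track_qc(tracks)
#>   n_tracks mean_length sd_length mean_step_um
#> 1     2244    16.84447  11.72102    0.2368206

energy_penalty(tally_crossings(tracks, mask))
#> eps_enter = 2.372 kT [1.972, 2.835] (21/225)
#> eps_exit = 1.632 kT [1.342, 1.965] (35/179)

fit_jd_cumulative(jump_distances(tracks, mask, "outside"),
                  sigma = params$sigma_loc, n_bootstrap = 200)
#> <jd_fit> D = 0.5684 um^2/s [0.5600, 0.5768], r0^2 = 0.07181 um^2, n = 26576

retention_fraction(tracks, mask)$fraction
#> [1] 0.848
```

The raw penalties include an episode-definition baseline of about 1 kT;
subtracting a barrier-free null run (`run_null()`, `compare_to_null()`)
recovers the generative barriers — the enter−exit *difference* above
(≈ 0.74 kT) already reflects the imposed 1.0 − 0.2 kT asymmetry. The
bilayer-side diffusion fit recovers the input 0.6 µm²/s to within a few
percent (mutual-nearest-neighbour linking slightly censors long jumps;
fitting the generator's own tracks gives 0.595).

Geometry helpers reproduce the published gap arithmetic exactly:

```r
gap_delta(3.5, 6.4, 21.2)$delta   # -11.3 nm: large probe, small gap
exclusion_fraction(0.293)         # 0.707
```

`run_pipeline(pipeline_config(...))` chains all stages (mask → track →
exclusion → energetics → diffusion → null comparison) and writes a
results directory with provenance.

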