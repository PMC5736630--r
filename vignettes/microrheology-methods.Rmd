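---
title: "Staging interfacial film formation by passive particle-tracking microrheology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging interfacial film formation by passive particle-tracking microrheology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmr)
```

## The measurement

Micron-scale colloidal probes adsorbed at an oil–water interface are trapped
there by interfacial energies of order $10^7\,k_BT$ (`trapping_energy()`), so
their in-plane motion reports the mechanics of the interfacial layer itself.
When bacteria colonize such an interface they can assemble a film that
evolves, over hours, from an active fluid to a solid elastic skin. Passive
microrheology stages that evolution: record the probes at video rate, track
them, and summarize each recording by the ensemble mean-squared displacement

$$\langle \Delta r^2(t) \rangle \sim t^{\,n},$$

where $t$ is lag time. The exponent $n$ of a log–log fit over a fixed lag
window classifies the mechanical state:

| exponent | regime | physical reading |
|---|---|---|
| $n > 1$ | superdiffusive | probes advected by active (bacterial) motion |
| $n \approx 1$ | diffusive | random-walk motion, thermal or agitated |
| $n < 1$ | subdiffusive | viscoelastic environment |
| $n < 0.1$ | elastic | probes locked in a solid film |

Two magnitudes complete the summary: $d = \sqrt{\langle \Delta r^2(1.67\,
\mathrm{s})\rangle}$, the RMS displacement at the reference lag, and the
apparent diffusivity $D_\mathrm{app} = \langle \Delta r^2(t)\rangle / 4t$,
compared against the Stokes–Einstein value (`thermal_diffusivity()`:
$0.49\ \mu m^2/s$ for a $0.5\ \mu m$ probe in water at 298 K) to flag active
transport.

The default lag window is $1.67\times 10^{-2}$–$1.67$ s. These printed
values are the rounded grid lags 1/60 s and 100/60 s of a 60 fps recording;
`fit_power_law()` matches window endpoints with 1% relative slack so that
exactly lags 1–100 enter the fit at 60 fps. $d$ is read from the measured
MSD at the grid lag nearest 1.67 s — a property of the data, not of the
fitted line.

## Ground-truth simulators

Because the regimes, not any one dataset, are the object of interest, the
package ships exact simulators for each dynamical class
(`simulate_trajectories()`; all work in μm and seconds, with positions
sampled at `fps`):

* **Brownian** — increments i.i.d. Gaussian, per-coordinate variance
  $2D/\mathrm{fps}$; MSD $= 4Dt$. Default study condition $D = 0.15\
  \mu m^2/s$, the diffusivity scale at which $d(1.67\,\mathrm{s}) \approx
  1\ \mu m$.
* **Fractional Brownian motion** — per-coordinate fBm with Hurst exponent
  $H$ and covariance $\tfrac{\mathrm{scale}}{2}(s^{2H} + t^{2H} -
  |t-s|^{2H})$; MSD $= 2\,\mathrm{scale}\,t^{2H}$, so fitted $n = 2H$.
  Sampled exactly: the stationary increment process (fGn) is drawn by
  circulant embedding (Davies–Harte) with a Cholesky factorization fallback
  should the embedding fail to be nonnegative definite; the covariance
  matrix itself is the test surface, checked against a direct Cholesky
  oracle on a 32-step grid.
* **Persistent random walk** — Ornstein–Uhlenbeck velocity with persistence
  time $\tau_p$ and speed scale $v$ (per-coordinate stationary velocity
  variance $v^2/2$), integrated *exactly* over each frame using the joint
  Gaussian law of (velocity, displacement); MSD $= 2v^2\tau_p^2(t/\tau_p -
  1 + e^{-t/\tau_p})$, ballistic below $\tau_p$, diffusive above. This is a
  stand-in that produces superdiffusion with a controlled crossover; it is
  not a model of any particular swimming mechanics.
* **Arrested** — probes tethered to fixed anchors, OU position with
  equilibrium std `sigma_eq` and relaxation `tau_r`; with `tau_r` far below
  the frame interval, positions are i.i.d. and the MSD is flat at
  $4\sigma_{eq}^2$. Static anchors plus localization noise $\sigma$ give
  the pure noise floor $4\sigma^2$.

Localization noise is i.i.d. Gaussian per coordinate per frame, applied
after the dynamics; common-mode drift is added as a cumulative displacement
series and recorded so tests can remove it exactly (`apply_drift()` /
`remove_drift()`). One master seed is split into independent dynamics,
noise, and placement streams (drawn by `sample.int` after seeding once), so
toggling noise never changes the dynamics realization, and identical
configurations are bit-reproducible.

Trajectories evolve on the unbounded plane by default: recordings are short
relative to the field of view, and periodic wrapping would corrupt the MSD.
A reflecting box is available for rendering. Initial positions are either
uniform over the central 60% of the box or a jittered lattice
(`placement = "grid"`). The lattice exists because tracking-accuracy
statements are only meaningful without close encounters: when two spots
approach within a feature diameter, centroid estimates pull toward each
other and proximity suppression breaks tracks, which biases tracked MSD
slopes; on isolated spots the render→track→analyze round trip recovers the
MSD slope to better than 1%.

## The aging scenarios

`build_aging_scenario()` programs how dynamics evolve with surface age
(time since the interface was formed). Each stanza is an independent
recording at one age — matching per-age video acquisition — with defaults
of 40 trajectories × 240 frames at 60 fps and 0.01 μm localization noise
(a typical centroid precision). Sampled ages are 60, 300, 900, 1800, 3600,
5400, 7200, $10^4$, $2\times10^4$, $4\times10^4$, $8\times10^4$ s.

* **PAO1-like** (film-forming): persistent random walk ($v = 1\ \mu m/s$,
  $\tau_p = 2$ s, fitted $n \approx 1.8$) through 1800 s; fBm with
  $H = 0.2$ ($n \approx 0.4$) from 3600 s; arrested
  ($\sigma_{eq} = 0.03\ \mu m$, $n \approx 0$) from $10^4$ s. The exponent
  path between 1800 s and 3600 s is not observable between sampled ages;
  this package simply samples no age in that interval — a synthetic
  convention, not an interpolation claim.
* **PA14-like** (persistently active): persistent random walk through
  3600 s, then Brownian with $D = 0.3\ \mu m^2/s$ — somewhat above the
  thermal reference, as expected for an agitated interface — through
  $8\times10^4$ s. Never subdiffusive, never arrested.

`analyze_timecourse()` runs drift correction → ensemble MSD → power-law fit
→ classification per age and reports two milestones by first crossing of
the label sequence, with no smoothing (the transition being abrupt, any
smoothing convention would be invented): the **subdiffusive onset age**
(first age with $n$ below the diffusive band) and the **transition age**
(first age labelled elastic). Both are reported because "the film forms" is
used in both senses; on the PAO1-like schedule they are 3600 s and
$10^4$ s.

## Tracking

`track_stack()` implements the classical Crocker–Grier chain on rendered or
real image stacks:

1. **Bandpass** (`bandpass()`): Gaussian smoothing at the pixel-noise scale
   minus a boxcar background at the feature scale, clipped at zero,
   replicate-padded at edges. This is what makes centroids robust: on a
   synthetic spot over a strong linear background gradient the filtered
   argmax is within half a pixel of truth while the raw argmax is not.
2. **Localization** (`locate_features()`): local maxima above an intensity
   percentile, brightest-first suppression at separations below the feature
   diameter, then iterated intensity-weighted centroids within a circular
   mask of radius half the feature diameter (the mask walks one pixel when
   the centroid lands more than half a pixel off-centre). Mass, radius of
   gyration, and eccentricity $\sqrt{4m_{xy}^2 + (m_{xx} - m_{yy})^2} /
   (m_{xx} + m_{yy})$ come from second central moments within the mask.
   Coordinates are 0-based pixel indices at pixel centres, $x$ = column,
   $y$ = row.
3. **Filtering** (`filter_features()`): thresholds on mass, size and
   eccentricity, with per-criterion rejection tallies.
4. **Linking** (`link_features()`): between consecutive frames, candidate
   pairs within `max_displacement` are assigned one-to-one minimizing total
   squared displacement; an unlinked track or feature costs
   `max_displacement`². The candidate graph decomposes into connected
   subnetworks solved exactly by bounded enumeration (deterministic
   tie-break by particle id); a subnetwork exceeding the enumeration cap
   raises an error that advises lowering `max_displacement`. `memory`
   frames of gap closing are supported (default 0).

No threshold is silent: `track_stack()` echoes every effective parameter in
its `params` attribute, and the pipeline manifest repeats them. The
packaged defaults (diameter 7 px, `min_mass` 10000, size 1–4 px,
eccentricity ≤ 0.3, displacement ≤ 5 px) are calibrated to the packaged
renderer at SNR 10, where measured true-spot masses (≥ 26 000) and noise
features (≤ 6 200) separate cleanly; `track_stack()` also raises the
candidate percentile to 90, appropriate for sparse fields. On such frames
localization achieves ≈ 0.09 px RMS per coordinate on isolated spots.

The renderer itself (`render_video()`) draws each particle as a 2-D
Gaussian spot (optionally elongated, to exercise the eccentricity filter)
on a constant background with additive Gaussian noise, quantized to 16-bit
counts, and carries fps/pixel-size metadata in a JSON sidecar of the TIFF.

## Drift correction

`subtract_drift()` removes common-mode (advective) motion: for each
consecutive frame pair, the mean displacement over trajectories spanning
the pair is subtracted from every spanning trajectory's step, and positions
are rebuilt by cumulative summation from each trajectory's first frame.
Common motion of any magnitude is removed to machine precision. The cost is
a known finite-ensemble bias: the mean contains $1/N$ of each particle's
own motion, so independent motion is shrunk by $(N-1)/N$ — about 1% at
$N = 100$, negligible against the acceptance tolerances, and asserted
explicitly in the tests. Correction precedes MSD estimation everywhere; a
flag disables it for diagnostics only.

## Estimator choices and numerical conventions

* **MSD**: time-averaged with overlapping origins per trajectory; ensemble
  curves are the *unweighted* mean over per-trajectory MSDs at each lag
  (each trajectory counts once regardless of length), with the
  contributing count recorded per lag.
* **Minimum trajectory length** for ensemble inclusion: 110 frames, so the
  reference lag of 100 frames has at least 10 origins per trajectory.
* **Fit**: unweighted least squares of $\log_{10}$ MSD on $\log_{10}$ lag;
  zero-valued MSD points are excluded (and counted); fewer than 3 usable
  points is an error. The fit is exact to numerical precision on noiseless
  power laws for any $n \in [0, 2]$.
* **Diffusive band**: reference lines exist only at $n = 1$ and $n = 0.1$;
  a decidable "diffusive" label needs a finite band, set to $[0.9, 1.1]$,
  configurable and echoed with every label. Classification is a total,
  threshold-monotone function of $n$.
* **Degenerate inputs**: a single-trajectory ensemble drift-corrects to
  identically zero displacement (warned); frame pairs spanned by no
  trajectory contribute zero drift correction (messaged); candidates whose
  centroid mask would leave the image are dropped; non-convergent centroid
  refinement keeps the last estimate and flags the record.
* **Temperature** defaults to 298 K in all thermal conversions.

## Problem sizes

The study conditions used throughout the tests and the acceptance script
are: 200 trajectories × 2000 frames at 60 fps for the Brownian and fBm
calibrations (100 × 2000 for the static noise floor), 40 × 240 per stanza
across 11 ages for the aging scenarios (20 seeded replicates in the
transition-rate check), and 36–50 rendered spots per frame at SNR 10 for
tracking accuracy. Closed-form MSD checks are asserted within 3 standard
errors at every fitted lag, with the SE taken across per-trajectory MSDs.

## What passing tests do and do not show

The synthetic generators emulate the *statistical* regimes of probe motion
and the camera's localization noise. They do not emulate: hydrodynamic or
steric coupling between probes, probe–bacterium collisions, heterogeneous
films (all probes in a stanza share one dynamical law), illumination drift
or photobleaching, out-of-plane motion, or the pixel-level artifacts of
real cameras beyond additive Gaussian noise. Passing acceptance therefore
demonstrates that the *analysis chain* — tracking, drift correction, MSD
estimation, exponent fitting, classification, transition detection — is
correct and well-calibrated on data whose truth is known, not that any
particular biological interface behaves as programmed. On real data the
defaults most likely to need adjustment are the tracking thresholds (set
them from a mass histogram of the actual footage) and the minimum
trajectory length.

## Known limitations

* The linker's exact enumeration is intended for the sparse fields this
  package targets; extremely dense fields with large search radii hit the
  subnetwork cap by design rather than silently degrading.
* Mean-displacement drift correction cannot distinguish genuine collective
  flow from a shared dynamical mode; with few trajectories the $(N-1)/N$
  shrinkage grows, and a single trajectory is zeroed entirely.
* $d$ at the reference lag requires trajectories spanning 100 frames; very
  fragmented tracking output can leave no qualifying trajectory, which is
  raised as an error naming the threshold.
* Exponents are summaries of one fixed lag window; crossover dynamics (as
  in the persistent random walk) produce window-dependent intermediate
  values by construction.
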