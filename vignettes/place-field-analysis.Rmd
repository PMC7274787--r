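---
title: "Place-field and hippocampo-septal coupling analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Place-field and hippocampo-septal coupling analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mazefields)
```

## What this package computes

`mazefields` analyzes simultaneous tetrode recordings from hippocampal CA1 and
the caudodorsal lateral septum (LS) made while a rat runs a rewarded
double-sided T-maze task: the animal is forced into one side arm, runs a
central stem, and must choose the matching arm at the far T to receive reward
at the arm's end. The scientific questions the pipeline addresses are (i) how
much spatial information single units carry, (ii) where place fields sit on
the maze relative to reward, (iii) how field shape (skew, firing-rate
asymmetry) depends on travel direction relative to reward, and (iv) whether
HPC and LS units with nearby fields fire in a temporally coupled way.

Because the original recordings require a gated download, the package ships a
synthetic session generator with planted ground truth. Every analysis stage is
validated against those planted parameters; the generator is first-class,
tested code, not a fixture.

## Track representation

The maze is quasi-one-dimensional, so all maps live on the linearized track.
`build_maze()` models the maze as a tree with two junctions (forced point F,
choice point C), five arms (two forced, stem, two choice), and reward sites at
the distal ends of the choice arms. Every tracked point is projected onto its
nearest arm (`linearize()`, off-track tolerance 10 cm) and addressed by a
global linearized coordinate obtained by concatenating the arms in a fixed
order. Two consequences of this representation are handled explicitly:

* **Adjacency** between track bins follows the maze graph, not the
  concatenated coordinate: consecutive bins within an arm are neighbours, and
  the bins meeting at a junction are linked across arms. Connected-component
  field detection therefore behaves like 4-connectivity does on a 2-D grid of
  a quasi-1-D track, and fields may span a junction.
* **Distances** (field-center separation, distance to reward, smoothing
  distances) are geodesic along the maze, never Euclidean through the air and
  never naive differences of the concatenated coordinate.

Rate-map smoothing uses a Gaussian kernel over geodesic bin distance with
visited-mask normalization: unvisited bins are excluded from the kernel
support, and the kernel never bleeds between arms that are adjacent only in
the concatenated coordinate.

## Kinematics and speed filtering

Per-sample speed is the hypotenuse distance between the positions immediately
before and after each time point divided by their time gap (one-sided at the
ends), smoothed with a 1 s SD Gaussian kernel over time, and converted from
pixels to cm/s. The camera runs at a nominal 30 Hz with occlusion dropouts to
roughly 15 Hz; smoothing interpolates onto a regular grid, convolves, and
interpolates back, which tolerates gaps at linear cost. Acceleration is the
central difference of the smoothed speed.

All occupancy and spiking enters the maps only when the animal moves at or
above 12 cm/s; spike speeds are linearly interpolated at spike times. Each
position sample contributes a dwell time equal to half the gap to its
neighbours, capped at 1 s — the cap prevents tracking dropouts from inflating
occupancy. The capped half-gap rule is this package's choice; sampling-rate
variation makes some such rule necessary and the cap only engages at gaps a
camera dropout would produce.

## Spatial information

Information maps use 1 cm bins smoothed with a 10 cm SD kernel. With
occupancy probabilities $P_i$, per-bin rates $R_i$, and overall mean rate
$\bar R = \sum_i P_i R_i$:

$$\mathrm{bits/spike} = \sum_i P_i \frac{R_i}{\bar R} \log_2 \frac{R_i}{\bar R},
\qquad
\mathrm{bits/s} = \sum_i P_i R_i \log_2 \frac{R_i}{\bar R},$$

with $0 \log 0 := 0$ and unvisited bins excluded. The two measures satisfy
bits/s $= \bar R \times$ bits/spike exactly; the unit table reports $\bar R$
(the occupancy-weighted map rate) as the mean rate so the identity holds to
machine precision in the output. Units are excluded when their speed-filtered
mean rate falls below 0.05 Hz, or when the session lacks full track coverage
at running speed; a unit counts as spatially informative when its bits/spike
meets or exceeds 0.8 ("met or exceeded", so the comparison is `>=`).

The surrogate control regenerates each unit as a homogeneous Poisson train
over the whole session timeline at a matched mean rate and pushes it through
the identical speed-filter/occupancy/rate/information pipeline. Homogeneity is
the simplest model consistent with "Poisson firing at the matched mean rate";
the speed filter is applied to surrogates exactly as to real units.

A plug-in mutual-information estimate between one-sample-window spike counts
(clipped at 3) and the occupied 1 cm bin is reported as a supplementary
column. The literature source for the original MI computation is not
specified beyond "mutual information", so this standard discretized estimator
is a documented stand-in and is not used for any classification.

## Place-field detection and shape

Field maps use 2 cm bins with the same 10 cm smoothing. Let $\mu$ and
$\sigma$ be the mean and SD of the unit's smoothed map values over visited
bins. A place field is a connected set of bins with rate $\ge \mu + \sigma$,
containing at least one bin $\ge \mu + 2\sigma$, with linearized extent of at
least 15 cm. Two interpretation points are deliberate:

* The boundary rule is stated once as "equal to or less than one standard
  deviation greater than the mean" and once as firing dropping *below* one SD
  above the mean; the two are contradictory and the second is adopted
  ($R_i \ge \mu + \sigma$ keeps a bin in the field).
* Whether $\sigma$ is a spatial-map SD or a temporal firing-rate SD is not
  specified; the spatial-bin SD is adopted because the thresholds gate a
  spatial map. The field stage also applies its rate floor to the unit's
  maximum map rate, while the information stage applies it to the mean rate —
  both floors are recorded per unit.

Field analysis is gated on the information criterion: only units at or above
0.8 bits/spike reach the detector, as in the original selection. This gate is
what makes the false-positive control meaningful — smoothed noise maps of
homogeneous units can contain above-threshold excursions, but such units do
not pass the information screen.

The field center is the bin of maximum smoothed rate (ties broken toward the
lower linearized coordinate, deterministically). Directionality is determined
by building separate toward-reward and away-from-reward maps from the trial
phases (trial start to choice-arm arrival = toward; arrival to next trial
start = away); fields present in both directions with centers separated by
strictly less than 20 cm are merged as bidirectional.

**Skew** is the third standardized moment of the within-field rate profile,
taken along the linearized track in the direction of travel (the track maps
are one-dimensional, so width-averaging across the track's physical width is
implicit): with in-field profile $w(x)$ normalized to unit mass,
$\mathrm{skew} = \sum w (x-\mu_w)^3 / [\sum w (x-\mu_w)^2]^{3/2}$. Positive
skew means firing mass late in the pass. Two properties matter when
interpreting magnitudes: the 10 cm smoothing inflates the profile variance,
and the $\mu+\sigma$ boundary truncates the asymmetric tail, so in-field skew
magnitudes are small (noise-free planted fields with strong asymmetry yield
$|\mathrm{skew}| \approx 0.05$–$0.15$). Sign-recovery checks therefore plant
strongly skewed, wide fields centered mid-arm, where the field fits entirely
inside one arm; fields abutting junctions or arm ends acquire
geometry-induced asymmetry that masks the planted sign.

**FRAI** (firing-rate asymmetry index): per pass through the field, the
in-field spikes are split in half by count; $F_1$ and $F_2$ are the mean
rates over the entry-to-split and split-to-exit intervals and the index is
$(F_1 - F_2)/(F_1 + F_2)$, averaged over passes. The printed form of the
index in the source material lacks an operator between $F_1$ and $F_2$; the
difference form is adopted because it is the asymmetry index of the cited
literature and is dimensionless in $[-1, 1]$. The count split (rather than a
time split) follows the "first half of spikes" wording.

**Lap stability**: passes are contiguous runs of at-speed in-field samples
(at least 2 samples); for each pass, the in-field bin of maximum spiking is
located and its geodesic distance from the mean per-pass peak is reported.
Fields passed fewer than 15 times are excluded.

**Kinematic control**: per-bin firing rate is regressed (OLS, with intercept)
on the bin's dwell-weighted mean speed and acceleration; the $r^2$ is
reported per unit. Degenerate designs drop the collinear column.

## Reward geometry

Field centers are labeled by maze region. Centers within 10 cm (along the
track) of a junction are labeled as forced/choice *points* and excluded from
the three-region tallies, since junction fields cannot be assigned to one
arm; 10 cm is this package's choice of junction half-width, as the exclusion
rule is stated without one. Distance to reward is geodesic. The
field-probability histogram over reward distance carries a track-exposure
column (how many 2 cm track bins map into each distance bin) because the maze
geometry folds two arms onto equal reward distances; both the raw fraction
and the exposure-normalized density are emitted, since it is not stated
whether the original histograms are geometry-normalized.

## HPC–LS coupling

Pairs are formed per HPC field (multi-field cells contribute each field): LS
fields whose centers lie within 20 cm (inclusive) are candidates, and among
candidates the LS unit with the most similar mean firing rate wins, with
distance as the tie-break. Cross-correlograms bin both trains at 10 ms and
evaluate lags from −100 to +100 ms; positive lag means LS activity follows
HPC (HPC leads), and this convention is stated in every output header.
Values are cross-products per bin by default ("counts" normalization); rate
and Pearson normalizations are available because the original normalization
is unstated.

The shuffle control circularly time-shifts the LS train by a uniform offset
of at least 1 s — preserving its ISI structure and rate — computes the
control correlogram, and subtracts the scalar mean of the control over lags
and shuffles from every lag bin. The number of shuffles defaults to 100 for a
low-variance control and is configurable down to 1 for literal replication of
a single-shuffle control. Group summaries report per-pair mean corrected
correlation over the lag window and peak lags by arm group (forced / middle /
choice), with pooled-variance t-tests between groups; the session-thirds
analysis repeats the correlogram pipeline inside each temporal third
(half-open partition), dropping a pair in any third where either train has
fewer than 2 spikes.

## Statistics

Group comparisons use the pooled-variance (Student) two-sample t-test, not
Welch, so reported degrees of freedom follow the $n_1 + n_2 - 2$ convention
of the original analyses; one-sample, paired, two-sample Kolmogorov–Smirnov,
and Pearson chi-square tests are provided behind the same interface. No
multiple-testing correction is applied anywhere; all raw p-values are
reported with their test, df, and input table.

## The synthetic generator

`simulate_trajectory()` emulates the task at 30 Hz: forced side drawn
uniformly but never repeated more than three consecutive times, correct
(rewarded) choice with probability 0.75 (the training criterion), per-leg
running speeds from a truncated normal (mean 35 cm/s, CV 0.15, floor
1 cm/s), ~5 s pauses at the visited reward site that sit below the speed
filter, small tracking noise (0.25 cm SD), and independent deletion of half
the samples to emulate occlusion (30 → ~15 Hz). Forty trials give roughly 15
minutes of behavior — about two-thirds running — which covers every 2 cm
track bin at speed; an 80-trial session approximates the 30-minute daily
recording.

Place cells are inhomogeneous Poisson (thinning against the peak rate) with
rate $\lambda(t) = b + (p - b)\,g(d(t))$, where $d(t)$ is the signed
geodesic distance of the animal from the field center oriented along the
travel direction and $g$ is a unit-peak skew-normal bump: one shape knob
controls the sign and magnitude of the planted third-moment asymmetry.
Direction-gated specs silence the bump when travel direction does not match.
Coupled pairs relay each HPC spike into the LS train at a configurable lag
with Gaussian jitter and a transmission probability, on top of an independent
Poisson background; kinematic (non-place) units fire as a rectified linear
function of speed and acceleration. Default planted populations
(`synthetic_spec()`) bias LS field centers 2:1 toward the choice arms,
mirroring the reward-biased septal field distribution the pipeline is built
to measure.

What the generator does **not** emulate — and what passing tests therefore do
not establish about real data: theta rhythmicity and phase precession,
experience-dependent field drift within a session, 2-D field structure
transverse to the track, behavioral variability beyond speed jitter and
forced-side sequencing, error-trial cognition, and non-Poisson spiking
statistics (bursting, refractoriness).

## Numerical choices and problem sizes

Spatial bins are half-open `[lo, hi)` indexed from 0 within each arm; arm-end
coordinates are kept strictly inside their arm so the concatenated coordinate
stays unambiguous at arm boundaries. Time is seconds (double); pixels are
converted to cm exactly once at load. Session bounds are the first and last
position timestamps and spikes outside them are dropped with a logged count.
On-disk numbers are printed with 17 significant digits, so a
write/read/write cycle is byte-identical and sessions regenerate exactly
under a fixed seed. Argmax ties (field centers, correlogram peaks) break
toward the lower coordinate/lag deterministically.

The validation suite sizes its simulations to run in minutes on one CPU while
keeping sampling error far from the decision boundaries: 1000 random maps for
the information identities, 100 surrogate units on a 30-minute trajectory for
the information control, 50 planted cells (widths 5–15 cm SD, peaks 5–15 Hz)
for field recovery against a noise-free oracle (the planted profile pushed
through the same detector), 20 seeds per sign for skew recovery, 50 coupled
pairs (20 ms lag, 30% transmission, 2 ms jitter) with a 20-shuffle control
for lag recovery, and 1000 null repeats for the type-I error of the pooled
t-test.

## Known limitations

* The linearized (1-D) track representation cannot express fields offset
  transverse to the track; on this maze that information is negligible, but
  the code is not applicable to open-field data.
* The plug-in MI estimator is biased upward at low spike counts and is
  reported for reference only.
* In-field skew magnitudes are strongly attenuated by smoothing and boundary
  truncation (see above); comparisons of skew across conditions are
  meaningful, absolute magnitudes are not.
* The shuffle control assumes stationarity of the LS train at the session
  scale; slow rate drifts inflate the corrected correlogram variance.
* Junction-spanning fields get a path-length extent from their bin count,
  which can differ slightly from the extent of a within-arm run.
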