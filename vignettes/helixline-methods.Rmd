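---
title: "helixline: models, measurements and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{helixline: models, measurements and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixline)
```

`helixline` analyses helical filaments in tomographic-style density
volumes: it measures their helical symmetry from layer lines, rebuilds them
by real-space symmetry averaging, docks atomic models into the result, and
quantifies how much of a microtubule population's lumen they occupy. This
vignette explains the underlying models, every tunable that matters, the
numerical decisions taken where the design was genuinely open, and what the
synthetic data used in the test suite can and cannot establish.

## The helical model

A filament is modelled by its 1-start ("genetic") helix: subunit $k$ sits at

$$\mathbf{r}_k = \big(r\cos k t,\; r\sin k t,\; k h\big),$$

with rise $h$ (Å per subunit), signed twist $t$ (degrees per subunit,
negative = left-handed) and subunit radius $r$ (Å). Because actin-like
twists are close to $180^\circ$, consecutive subunits land on nearly
opposite sides of the axis, and the projection shows the familiar two
long-pitch strands whose apparent crossings repeat every

$$C = \frac{180\,h}{180 - |t|} \quad (\text{the crossover spacing}).$$

Three periodicities are measurable from the power spectrum of a projection:
the crossover $C$ (lowest layer line), the genetic pitch $360h/|t|$ (the
strong line near 60 Å) and the rise $h$ (the meridional line). They give two
independent routes to the twist,

$$|t| = 180\,(1 - h/C) \qquad \text{and} \qquad |t| = 360\,h / \text{pitch},$$

and `derive_helical_parameters()` cross-checks one against the other,
flagging disagreements of 2° or more.

Two presets encode the morphologies of interest. The short-crossover
(cofilin-decorated-like) preset uses $h = 27.5$ Å, $t = -162^\circ$
($C = 275$ Å = 27.5 nm) with subunit radius 32 Å, reflecting the thicker,
smoother outline of a decorated filament. The canonical F-actin preset uses
$h = 27.5$ Å and $t = -166.6^\circ$; only the canonical *crossover band*
(35–37 nm) is well established, so the twist value is a package choice that
places $C = 369.4$ Å = 36.9 nm inside it. Handedness cannot be determined
from a single projection, so all reported twists are magnitudes; the
generators use left-handed helices throughout.

Both presets default to 120 subunits (330 nm of filament, twelve and about
nine crossovers respectively). This matches the scale of lumenal filaments
traced in cells — population totals of tens of micrometres over tens of
filaments imply mean lengths of a few hundred nanometres — and it matters
for measurement: the power of the crossover layer line grows linearly with
filament length, and much shorter filaments (2–4 crossovers) leave the
low-frequency line too weak to detect reliably below SNR ≈ 1.

## Rendering and noise

`render_density()` places one isotropic Gaussian per atom with
$\sigma = \text{resolution}/(\pi\sqrt{2})$, each normalized to integrate to
its mass weight; at the 20 Å working resolution a single pseudo-atom per
actin subunit is sufficient, since no sub-subunit feature survives the
kernel. Rendering is deterministic.

`add_noise_and_wedge()` adds white Gaussian noise scaled so that
`snr` equals the ratio of signal variance inside the object support (voxels
above 10% of maximum) to noise variance, then optionally zeroes the missing
wedge: with the tilt axis along $y$ and the beam along $z$, Fourier
components whose $(k_x, k_z)$ direction lies within
$90^\circ - \text{wedge\_half\_angle}$ of the $k_z$ axis are unmeasured.
There is no CTF and no dose model: every measurement the package makes is a
*spacing* or a *symmetry*, not an amplitude, so white noise is the honest
minimal degradation. Each noise model carries its own seed and leaves the
session RNG untouched.

## Layer-line detection

`compute_power_spectrum()` mean-subtracts the projection, applies a
split-cosine (Tukey) taper over `taper_fraction = 0.2` of each edge, pads by
`pad_factor = 4` and takes the FFT modulus. The taper fraction was chosen
for peak-position accuracy: with a 10% taper, leakage from the window edge
biases the lowest layer line by ~0.3%, which is material when 27.5 nm must
be distinguished from 27.66 nm; at 20% the bias drops by an order of
magnitude. Padding oversamples the spectrum so that the 3-point parabolic
interpolation of log-power locates peaks to a small fraction of a
frequency step.

`detect_layer_lines()` collapses the mean spectral *power* over a
transverse band $|R| \le$ `r_max` $= 0.025$ Å⁻¹ (wide enough to cover the
$J_2$ lobe of both presets) and keeps local maxima above
median + `noise_k`·MAD of the collapsed profile (`noise_k = 5`). Power
rather than amplitude is averaged because a layer line concentrated in a
few transverse cells then stands further above the flat noise background.
Two guards handle the extremes: the two pre-padding frequency rows next to
the equator are excluded (the filament envelope dominates there), and peaks
below 5% of the strongest in-band power are ignored, which keeps window
sidelobes from registering as lines in noise-free spectra where the MAD is
vanishingly small.

The crossover is read as the **dominant low-frequency line**: among detected
lines with spacing above 150 Å, the strongest. A literal "lowest-frequency
detected line" rule is fragile in noise — a marginal peak that barely clears
the threshold, or the genuine but weak $n=\pm4$ line at $C/2$, can sit below
the true crossover line in frequency while being many times weaker. On
noiseless renders the two rules agree exactly. Classification bands are
24–31 nm (short crossover) and 33–41 nm (canonical), both overridable.

As an independent, non-spectral oracle, `measure_crossover_realspace()`
measures the period of the intensity-weighted transverse width of the
projection: the filament is narrow at strand crossings and wide between
them. The image is first blurred axially (σ = 12 Å) so the subunit repeat
does not punch holes in the width profile, the profile is smoothed (σ =
25 Å), and the first autocorrelation maximum above 0.15 gives the period.
The test suite requires the two routes to agree within 3%.

## Reconstruction

`straighten()` fits natural cubic splines through the trace, transports a
minimally rotating normal frame along the curve, and resamples plane by
plane with trilinear interpolation; output slices beyond the traced length
are zero with a recorded usable mask, and the default segment length is 512
pixels. `helical_average()` then averages the volume over $j(h, t)$
operations with $j$ centred on zero, excluding out-of-volume samples with
per-voxel weight normalization (no wraparound). Its `self_consistency` — the
correlation of the averaged map with itself after one further symmetry
operation — is the reported quality metric; no Fourier shell correlation is
attempted at these sizes.

`symmetry_refine()` is a two-level deterministic grid search (coarse 0.5 Å
/ 1°, then a local pass at a quarter step) over a window around the initial
estimate, with ties broken toward the smaller twist magnitude. Its
objective is **not** the self-consistency of the average: an $n$-unit
average of pure noise correlates with its own symmetry operation at roughly
$(n-1)/n$ simply because the overlapping terms share noise, so that surface
is nearly flat. Instead the objective is a split-half coherence — the
correlation between the averages over even- and odd-indexed operations,
which share no input voxels and hence sit near zero for noise. The
objective is evaluated on a fixed, stride-2 subsample of voxels inside a
cylindrical mask, making the search cheap and exactly reproducible; a best
coherence below 0.15 raises a refinement-failure error, and window-edge
optima are flagged `boundary_hit`.

## Fitting and scoring

`rigid_body_fit()` searches a uniform z-y-z Euler grid (default 15°;
$\alpha$ fixed to 0 where $\beta \in \{0^\circ, 180^\circ\}$ makes it
redundant). At each orientation the translation is solved globally by the
cross-correlation theorem, and orientations are ranked by the whole-volume
correlation at that optimum — the matched-filter statistic, which varies
smoothly with pose. The best `n_starts = 3` candidates are polished by
Nelder-Mead (with one restart from the optimum to re-expand the collapsed
simplex); the polish also optimizes the whole-volume correlation, because
the masked score changes discontinuously as voxels enter and leave the mask
and stalls simplex methods.

The *reported* score is a Pearson correlation over a mask, and the mask is
the scientifically loaded choice. With `mask_ref = "probe"` (default) the
mask is where the simulated model map exceeds half its robust maximum: the
score asks *is the model in density?* and is the natural headline number
for a dock. With `mask_ref = "target"` the mask covers the experimental
map's own support: the score asks *does the model explain all the density?*
— this is the criterion that separates an under-filling bare-actin model
from a decorated (cofilactin-like) one, and the package's under-fit
ordering property uses it. `lowpass = TRUE` filters the target to the fit
resolution first; since the probe is band-limited by construction,
everything the target carries beyond that band is noise as far as the score
is concerned, and on noisy synthetic reconstructions the option typically
moves scores from ~0.6 into the 0.9s without changing their ordering.

## Microtubules and statistics

`count_protofilaments()` scores each candidate fold $n \in \{12,\dots,16\}$
by the correlation between the volume and its $360^\circ/n$ rotation over
an annular wall mask (wall radius located from the radial density profile,
±30 Å), so lumenal content cannot bias the count; margins below 0.02 are
flagged ambiguous. The candidate set brackets the 13–15 range reported for
platelet microtubules on both sides to guard against edge bias.

`occupancy_stats()` is deliberately plain arithmetic —
$100 \cdot \sum \text{filament length} / \sum \text{microtubule length}$
with a per-class breakdown, rounding only at presentation.
`compare_incidence()` is a two-sided Fisher exact test computed by full
enumeration of the hypergeometric support, summing the probabilities of all
tables no more probable than the observed one (with a $1+10^{-7}$ relative
tolerance for floating-point ties); the test suite checks exact agreement
with `stats::fisher.test` across random tables with group sizes up to 30.
Fisher's exact test is used because incidence counts at these scales are
small; the choice is recorded in the function's output metadata.

## Degenerate inputs and edge behaviour

Twist magnitudes of 0° or 180° are rejected at construction (the crossover
is undefined); filament specs must cover at least two crossovers; volumes
thinner than 3 voxels cannot be projected; images shorter than 64 axial
pixels have no usable spectrum; flat spectra return an empty line table
rather than an error, while deriving parameters from an empty table is an
error; a constant-width projection has no crossover period; maps on
different grids must be resampled (`resample_volume()`) before scoring; and
an all-negative target cannot be fitted. MRC reading accepts modes 0/1/2/6
and rejects anisotropic voxels and malformed headers by field name; writing
is always mode 2, which round-trips bit-exactly once values are
single-precision.

## Problem sizes, and what the tests do and do not show

The suite runs on volumes of roughly $26 \times 26 \times 680$ voxels at
5 Å (filaments) and $64^2 \times 80$ (microtubules), with 10–20 noise seeds
per property and a 65-filament population for the classification check;
these sizes keep the full suite in the minutes range on one CPU. Passing
tests establish that the *measurement chain is correct and unbiased on its
own forward model*: spacings are recovered to sub-percent accuracy, twist
to better than a degree, protofilament counts exactly, and classification
is stable down to SNR 0.5 under a 60° missing wedge. They do not establish
performance on real tomograms, whose contrast is CTF-modulated, whose noise
is structured (crowding, membranes, gold fiducials), whose filaments bend
and stretch locally, and whose per-filament twist varies around the mean.
The white-noise SNR used here is also not directly comparable to
conventional tomographic SNR figures. The deposited-map docking check is
the one place the package touches real data, and it requires a manual
download (see `tests/testthat/test-acceptance.R`).

## Known limitations

Handedness is not determined; Bessel orders are not assigned beyond the
three diagnostic lines; no multi-filament class averaging or iterative
(IHRSR-style) refinement is attempted — per-filament averaging with a
deterministic local grid search is the scope; self-consistency, not FSC, is
the reconstruction quality metric; and the incidence comparison reports a
p-value, not an effect-size model. Filaments whose crossover falls outside
both classification bands are deliberately left `UNCLASSIFIED` rather than
forced into a class; morphologies with a prominent meridional line relative
to their off-meridional lines can be screened with
`meridional_prominence()`, but no further class label is assigned because
no symmetry parameters exist to generate or test them.
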