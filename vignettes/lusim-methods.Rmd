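---
title: "Simulating A-line and B-line artifacts in lung ultrasonography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating A-line and B-line artifacts in lung ultrasonography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lusim)
```

## The physical picture

A healthy, aerated lung is acoustically invisible: its impedance (~0.17
MRayl) is so far below that of the chest wall (~1.7 MRayl) that nearly all
of the incident pulse reflects at the pleura. A B-mode image of such a lung
shows the pleural line and then *A-lines* — equally spaced horizontal bands
that are pure reverberation artifacts, echoes of the pulse bouncing between
the transducer face and the pleura. When the subpleural lung is infiltrated
by fluid, the pulse can enter that region, scatter repeatedly among the
water/air microstructure, and trickle energy back to the probe over a long
time. The image then shows *B-lines*: vertical, laser-like streaks running
from the pleural line to the bottom of the image.

lusim reproduces both mechanisms with a 2D acoustic model:

* a **muscle slab** (50 mm x 10 mm in the reference geometry) with the
  probe on one face;
* a **pressure-release boundary** (p = 0) on the far face, standing in for
  the near-total reflection at the muscle/aerated-lung interface;
* an elliptical **lung disease zone (LDZ)** of fluid-infiltrated lung
  tissue embedded in the upper band of the slab, touching the pleural
  boundary (10 mm long in domain variant A, 4 mm in variant B, 1 mm in the
  4 MHz "narrow" variant; 5 mm high in A/B);
* **absorbing strips** (split-field PML) on the lateral sides, so the slab
  behaves as a section of a laterally extended medium.

## Randomized inhomogeneous materials

Each tissue gets independently randomized sound speed and density built
from a bounded texture field: a sum of `n_modes` (default 400) cosine plane
waves with wavenumber magnitudes uniform on a band, directions uniform on
the circle, amplitudes uniform on (0, 1] and phases uniform on [0, 2*pi*),
normalized so the maximum absolute value is exactly 1. Given a texture
`f(x, y)` in [-1, 1], the LDZ material is the affine map

    v(x,y) = 1070 + 430 f(x,y)   [m/s]
    d(x,y) =  715 + 285 f(x,y)   [kg/m^3]

so `f = +1` is pure water (1500 m/s, 1000 kg/m^3) and `f = -1` is lung with
roughly 60% air content (640 m/s, 430 kg/m^3) — a strongly scattering
mixture. One field drives both velocity and density, which keeps the
impedance contrast (hence scattering strength) high. The muscle texture
`g(x, y)` is drawn with an independent seed and enters as

    v(x,y) = 1570 + G g(x,y),    d(x,y) = 1090 + G g(x,y)

with the inhomogeneity level `G` in {0, 5, 10} in the reference
experiments. The muscle field uses a 4:1 horizontal anisotropy
(x-wavenumbers divided by 4) to imitate the elongated fiber texture of
muscle; any non-symmetric band serves that purpose.

Two spectral choices are genuinely open and exposed as configuration:

* **Wavenumber band.** Default `[0, 2 f0 / 1500]` cycles/m, i.e. a texture
  correlation length of about half a wavelength at the center frequency in
  water-like tissue — scatterer sizes near lambda/2 scatter most
  effectively, which is the regime the LDZ needs.
* **Mode count.** 400 modes make the field effectively Gaussian with a
  smooth spectrum; fewer modes produce visibly periodic textures.

`generate_random_field()` rejects spectra beyond the grid Nyquist limit,
and regenerating with the same seed is bit-identical, which the test suite
asserts for every stage downstream.

## The probe model

The 32-element linear array spans the slab (pitch 50/32 mm = 1.5625 mm);
pitch and element width are not published for the original setup, so the
package derives the pitch from the slab width and takes the element width
as 80% of the pitch. The excitation is a Gaussian-windowed tone burst
`sin(2 pi f0 (t - tc)) exp(-(t - tc)^2 / 2 sigma^2)` with `sigma = 1.5/f0`
(about three cycles), peak-normalized.

Acquisition sweeps a 5-element subaperture one element at a time: 32
elements give 28 sweep positions, hence 28 RF lines. Within a subaperture,
element `i` is gated on and delayed by the transmit focal law

    B_i = (max_j path_j - path_i) / c_ref,
    path_i = sqrt(focus^2 + (x_i - x_c)^2)

with the focus at 10 mm depth and `c_ref = 1570` m/s (nominal muscle, since
focusing happens inside the muscle layer). The edge elements fire first and
all five pulses arrive at the focus simultaneously. Every element records
at each sweep — the trace is the spatial mean of pressure over the
element's width at the array face — so a full acquisition yields 28 x 32 =
896 traces of 2500 samples (50 us at 0.02 us).

## The wave solver

The solver integrates the first-order variable-density acoustic system

    dp/dt = -rho c^2 div(u),     du/dt = -(1/rho) grad(p)

on a staggered grid (pressure at cell centers, velocity on faces), 2nd
order in time and 4th order in space away from boundaries. The 4th-order
stencil is not a luxury: at the working resolution of 8–10 points per
wavelength, a 2nd-order stencil's group-velocity deficit of several percent
visibly stretches the reverberation round-trip time, while the 4th-order
stencil keeps arrival-time errors near 1%. Cells adjacent to a boundary
drop to 2nd order, which keeps the boundary conditions simple without
measurable effect on the validation oracles.

Numerical choices, all testable and tested:

* **Time stepping.** The internal step is CFL-limited
  (`c_max dt sqrt(1/dx^2 + 1/dy^2) <= cfl`, default 0.5; the scheme's
  stability limit is 6/7) and sub-divides the 0.02 us output interval
  exactly, so recording needs no interpolation. The tests bracket the
  stability limit empirically: 0.95x the limit runs clean, 1.05x produces a
  non-finite field which the solver reports with the offending step index.
* **Boundaries.** "Sound hard" walls (array face, outer side walls) are
  zero normal velocity — the natural condition on the staggered grid;
  the pleural face is p = 0 via an odd-mirror ghost row. The oracle suite
  verifies a +1 reflection off the face and a -1 (inverted) reflection off
  the pleural boundary by signed cross-correlation.
* **Absorbing strips.** Split-field PML in the lateral direction with
  cubic grading and a 60 dB target attenuation over the 5 mm strip; the
  measured spurious return in a plane-wave experiment is about -62 dB
  (a hard wall in the same harness returns ~0 dB).
* **Sources.** Additive ("soft") pressure injection at the element cells
  with unit amplitude — the physical drive pressure is unpublished and
  irrelevant in a linear, lossless model, which the linearity test
  (trace scales exactly with source amplitude) confirms.
* **Heterogeneity.** Density is averaged onto faces (harmonic-mean-free
  arithmetic averaging of 1/rho is adequate at these contrasts); the
  two-layer oracle reproduces the analytic normal-incidence reflection
  coefficient (Z2 - Z1)/(Z2 + Z1) to about 1%.

## Image formation

Each of the 28 lines is built from the 5 traces of its transmitting
subaperture. The default chain (`order = "log_first"`) applies a
sign-preserving logarithmic amplifier `sign(x) log10(1 + |x|/x_ref)` to
each RF trace, then Hilbert-envelope detection, then receive delay-and-sum
focusing. Applying the logarithm before envelope detection is unusual —
most systems detect the envelope first — so the conventional order
(beamform the RF coherently, detect, then compress) is available as
`order = "conventional"`; both orders must and do satisfy the same artifact
properties. The receive focal geometry mirrors transmit (fixed focus at
10 mm, not dynamic focusing). An echo from the focus reaches element *i* at
a time offset `-B_i`, so the aligning receive advance is `max(B) - B_i`.

Lines are interpolated laterally (endpoint-preserving linear interpolation,
factor 4: 28 lines become 109 columns), normalized to 0 dB at the image
peak and clipped at a 50 dB dynamic range. The depth axis is `c_ref (t -
tc)/2` with `tc` the pulse-center time; time-gain compensation is not
applied. Dynamic range, grayscale export and the interpolation factor are
display conventions, exposed as configuration.

## Quantifying the artifacts

The reference results are images, so the package defines two scores that
turn the artifact patterns into testable numbers.

**Echo train.** `detect_echoes()` finds envelope maxima above a threshold
(default 10% of the global peak) with a minimum separation. In a healthy
run the train is the transmit pulse plus reverberation echoes spaced by the
round trip `2L/c_ref` = 12.74 us for the 10 mm slab; the measured desk-scale
spacing is within 1%, and at least three echoes fit the 50 us window.

**B-line score.** `bline_score()` compares the mean linear image intensity
below the pleural line between columns above the LDZ and columns away from
it. Two design details matter. First, the face/pleura cavity of this model
is almost lossless, so A-line bands recur at every round-trip multiple in
*all* columns and would dominate a plain below-pleura average; the score
therefore excludes rows within 2 mm (half the pulse's depth footprint) of
each horizontal band detected in the reference columns, measuring the
inter-band region where a vertical streak is unambiguous. Second, the
vertical artifact bleeds laterally past the LDZ edge by roughly the receive
subaperture half-width, so a 3 mm guard band around the LDZ extent is
excluded from the reference columns. Both constants follow from the pulse
and aperture geometry and are fixed defaults, not fitted values.
`bline_width()` reports the lateral width of the columns brighter than the
midpoint between the inside and outside means.

With these definitions the desk-scale experiments give B-line ratios of
about 1.9 (variant A), 1.7 (variant B) and 1.0 (healthy control), with the
variant-A artifact wider than variant B's, mirroring the correlation
between LDZ length and B-line width in the reference images. The contrast
declines mildly as the muscle inhomogeneity G grows (speckle raises the
reference-column background); at G = 10 the variant-B ratio sits near 1.5.

## Problem scales

Two bundled configurations differ only in declared scale keys, never in
equations, material ranges or boundary conditions:

| | paper | desk |
|---|---|---|
| slab | 50 x 10 mm | 25 x 10 mm |
| elements / sweeps | 32 / 28 | 16 / 12 |
| window | 50 us | 30 us |
| points per wavelength | 10 | 8 |

The desk scale exists so that a full phantom-to-metrics experiment runs in
about a minute on one CPU; it is the scale used by the test suite and the
acceptance script. The A-line experiment overrides the window back to 50 us
(a single sweep suffices) so that three round trips fit, as in the
reference echo train. Grid spacing always resolves the slowest medium the
scenario can produce (640 m/s inside an LDZ), which is why healthy-control
runs are much cheaper than LDZ runs.

## What the generator does and does not emulate

The phantom reproduces the features the artifact mechanisms need: a
strongly reflecting pleural interface, sub-wavelength random scatterers
with water/air-scale impedance contrast below it, and weak fiber-like
muscle texture. It does **not** include ribs and their shadows, frequency-
dependent absorption, nonlinear propagation, elastic shear waves, 3D
geometry, or transducer bandwidth/directivity beyond a finite element
width. Passing tests therefore demonstrate that the *mechanisms* —
reverberation A-lines and scattering-trap B-lines — are reproduced, not
that the images are clinically realistic in texture or gain; the reference
study's own images share most of these simplifications.

## Known limitations

* Lossless media: with no absorption and perfectly reflecting face and
  pleura, the A-line train decays only through lateral spreading into the
  absorbing strips, more slowly than in tissue.
* The B-line/A-line contrast is scored on the compressed image; the
  default log-first processing chain halves the apparent dynamic range
  relative to conventional processing, so scores should be compared within
  one processing order.
* 2D propagation overstates late-time reverberation relative to 3D
  (cylindrical versus spherical spreading).
* The sub-sample part of receive delays is rounded to whole samples
  (0.02 us at 2 MHz is 1/25 of a period; negligible here).
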