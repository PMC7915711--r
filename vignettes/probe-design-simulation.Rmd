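---
title: "Models and methods behind the TRUS-PA probe simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the TRUS-PA probe simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patrus)
```

`patrus` is a desk-scale simulation of the computational design content of a
combined transrectal ultrasound and photoacoustic (TRUS-PA) probe: the
illumination lens that spreads and steers the excitation light, the optical
fluence it produces in a turbid medium, the 128-element convex receive array,
and the photoacoustic / pulse-echo image formation chain evaluated on a
radial tungsten-wire phantom.  Everything is generated in code; there are no
external data dependencies.

## The illumination lens

A TRUS probe images a sector of about 134 degrees, but a fiber bundle emits
a narrow quasi-collimated beam.  The probe's lens solves this with two
independent 2D profiles, designed in decoupled planes the way anamorphic
optics usually are:

* **Lateral-axial (imaging) plane** — a concave-convex pair of circular
  arcs, radii 8 and 11.5 mm in epoxy of refractive index 1.519, fans a
  13 mm collimated beam into a wide divergent sector.
* **Elevation-axial plane** — a planar-oblique (thin prism) profile with an
  80 degree oblique face deflects the beam toward the imaging plane so the
  beam axis crosses it at the 25 mm design depth.

### Resolving the lateral arc arrangement

The printed design parameters (radii, index, beam width) do not by
themselves fix how the two arcs face each other, and the choice matters
enormously.  We traced every axis-symmetric two-arc arrangement of the
printed radii:

* **Concentric annular meniscus** (shared arc center): the two refractions
  nearly cancel; the exact fan is 18.9 degrees (paraxially the lens has
  focal length about -51 mm).  Far too weak for the design target.
* **Crossed arcs** (entry 11.5 mm arc concave toward the source, center
  behind the lens; exit 8 mm arc concave toward the tissue, center ahead):
  rays refracted at the entry arc meet the steep exit arc at growing
  incidence; rays beyond a critical height are lost to total internal
  reflection, and the surviving fan is capped just below the grazing exit.
  This arrangement yields a 103-111 degree full fan for any center
  thickness between 0.5 and 5 mm — the designed ~105 degree field of view
  emerges from the printed radii without tuning.

`lens_design()` therefore defaults to the crossed arrangement
(`geometry = "crossed"`), with the concentric variant retained as an option
because its exact conservation law (Bouguer's invariant, `n r sin(phi)`
constant about the shared center) makes it a sharp independent check of the
ray tracer.  The center thickness of the lateral profile is not a printed
value; it is fixed once at 2 mm, the quoted lens thickness of the elevation
profile, and the result is insensitive to it.

```{r}
lens <- lens_design()
tr <- trace_lateral(lens, n_rays = 1001)
tr$fov_full_angle_deg
c(tir = tr$n_tir, vignetted = tr$n_vignetted)
```

Rays lost to total internal reflection, and rays that pass the flank of the
8 mm exit arc without striking it, are flagged and excluded from the
field-of-view measurement but retain their weight, so energy bookkeeping
stays exact.  In the physical lens these rays leave through the flank and
do not join the design fan.

### Elevation profile

The elevation profile is a thin prism with apex angle
`90 - oblique_inclination_deg = 10` degrees: normal entry through the
planar face, one refraction at the oblique exit face.  The closed form
`deviation = asin(n sin A) - A` gives 5.29 degrees, and a beam axis offset
of 2.316 mm from the imaging plane then crosses it at 25.0 mm — the design
depth.  The offset is not printed; its default is back-computed from the
25 mm crossing and is a configuration parameter.

```{r}
trace_elevation(lens)
```

## Monte Carlo photon transport

`simulate_fluence()` implements weighted-packet transport in a homogeneous
turbid medium in compiled code: exponential free paths with
`mu_t = mu_a + mu_s`, a deposit of `w mu_a / mu_t` per interaction into the
voxel where it occurs, Henyey-Greenstein direction updates (`E[cos] = g`),
and Russian roulette below weight 1e-4 with survival factor 10.  Boundaries
are index-matched; a packet leaving the grid box is tallied as transmitted,
reflected, or side loss by the face it crosses.  Roulette uses net-weight
bookkeeping (killed weight minus survival boosts), so

> absorbed + transmitted + reflected + side + roulette_net = launched

holds to machine precision on every run, not only in expectation.  All
randomness flows through R's RNG, so a seed fixes the run bit-for-bit.

Three source models feed the transport:

* `"collimated"` — the 13 x 2 mm rectangular bundle aperture, straight rays;
* `"bare"` — two bundles at `+/- 2.316` mm in elevation with a Gaussian
  far field whose numerical-aperture half-angle (default `asin(0.66)`) sits
  at the 2-sigma level, the usual approximation for a fiber bundle;
* `"lens"` — exit rays resampled from the traced lateral fan, deflected
  toward the imaging plane by the elevation prism.

The `"milk3"` preset (reduced scattering 1.0/mm via `mu_s = 10`, `g = 0.9`,
`mu_a = 0.002/mm`) stands in for the 3% milk bath of the wire-phantom tank;
it is a configuration default representative of diluted milk, not a
measured value.  At that scattering level transport becomes diffusive
within a few millimetres, so source geometry is largely erased at depth:
lens and bare illumination deliver similar fluence to the 25 mm wire ring,
and the package's detection comparison (lens at least as many detectable
wires as bare) typically holds with equality there.  The cleaner way to see
the lens act is a weakly absorbing, non-scattering medium
(`optical_medium(mu_a = 0.05, mu_s = 0)`), which behaves as a volumetric
screen: deposited fluence maps the ballistic beam, the lateral fan broadens
with depth, and the in-plane intensity near the 25 mm crossing depth is
several-fold higher with the lens than with bare bundles — the qualitative
behaviour the lens was designed for.  The measured intensity ratios and
beam-width tables from the physical screen experiments are air-path CCD
measurements and are not asserted by any test here.

## Convex array and acquisition pulse

`convex_array()` places 128 element centers on an arc whose radius follows
from the printed footprint: `11.4 mm / 134.5 degrees = 4.856 mm`, pitch
`1.059` degrees, with the angular span read as the first-to-last element
separation and the footprint read as arc length (at this curvature the
chord differs by under 2%).  Coordinates put the origin at the probe face
with depth along +z.

The acquisition pulse is a Gaussian-enveloped cosine whose amplitude
spectrum has a -6 dB (half-amplitude, the transducer-datasheet convention)
full width equal to `fractional_bandwidth x center frequency`; the default
parameters are the measured 6.75 MHz and 66%.  `characterize_pulse()`
recovers both from the zero-padded amplitude spectrum by interpolated
-6 dB band-edge crossings; synthesis and characterization are separate code
paths, so their round trip is a real check, and it recovers both printed
values within 1%.

```{r}
p <- synthesize_pulse()
unlist(characterize_pulse(p$waveform, p$sampling_rate_mhz))
```

## Wire phantom, RF synthesis, beamforming

The imaging-performance phantom is one 100 um wire per node of a polar grid
about the probe face: -75 to 75 degrees in 15 degree steps and 5 to 55 mm
in 10 mm steps, inclusive — 66 wires, of which 54 lie inside the 134.5
degree sector.  Wires are treated as point targets (100 um is far below
the 228 um acoustic wavelength).

Photoacoustic RF is one-way: each illuminated target emits at t = 0 and
channel `e` records the pulse at `|p - x_e| / c` with `1/r` spreading and
an illumination weight sampled from a fluence grid (the imaging-plane slab,
averaged over the voxel layers nearest y = 0 to tame Monte Carlo variance).
Pulse-echo RF is two-way with one transmit per scanline.  Fractional delays
use linear interpolation in both synthesis and beamforming.

Delay-and-sum reconstruction walks a 64-element aperture across the 128
radial scanlines (co-located with the elements, which makes the printed
32/64 active-channel counts exact at the edge and center).  Apodization is
rectangular; coherence-factor weighting `|sum|^2 / (N sum^2)` is available
as an explicitly labelled stand-in for the adaptive beamformer used with
the physical probe, which is out of scope.  Envelope detection is the
analytic-signal magnitude (an FFT construction), log compression maps a
`DR` dB range onto [0, 1] (35 dB for the standalone PA wire images, 55/45
and 25 dB for combined displays), and scan conversion inverts the convex
geometry (range measured from the element arc) with bilinear interpolation,
flagging pixels outside the sector.

Point-target localization uses `locate_peak()`: the discrete envelope
maximum near the expected position refined by a three-point parabolic fit
in beam angle and range.  On the noise-free 66-wire phantom with uniform
illumination, every in-sector wire localizes within 1 mm of its true
position; without the sub-sample refinement the extreme corner wires
(60 degrees, 55 mm) can land one scanline off (~1.3 mm) because their
point-spread function is broad and asymmetric where the walking aperture
clips — the same edge-of-sector degradation the physical probe shows.

## Numerical choices and degenerate inputs

* Angles are degrees at every API boundary, radians internally; lengths mm,
  times us, frequencies MHz.
* Unit-vector inputs are validated to 1e-8 (1e-9 for `ray2d`); zero-length
  normals are rejected.
* FWHM uses the outermost half-maximum crossings after a moving average
  (default length 30 samples, edge windows renormalized), which keeps the
  measure defined for the bimodal profiles of a bare two-bundle source;
  `smooth = FALSE` gives the raw crossings.
* An inclination of exactly 90 degrees gives zero deviation and an
  infinite crossing depth sentinel.
* All-zero RF beamforms to all-zero scanlines and log-compresses without
  division errors; focal points beyond the recorded window contribute zero
  and are counted in `n_outside`.
* Equal-amplitude ties in peak searches resolve to the first index
  (`which.max`); the parabolic refinement is clamped to half a sample.

## Problem sizes

The shipped tests run the full chain at deliberately modest sizes: 1001
design rays, 2e4-1e5 Monte Carlo packets on 1-2 mm voxel grids, 40 MHz RF
sampling, 0.1 mm beamforming range steps.  These sizes hold every
statistical assertion at 3 Monte Carlo standard errors while keeping the
whole suite around two minutes; all of them scale up linearly through the
public APIs.

## Known limitations

* Geometric optics only: no diffraction, polarization, or chromatic
  dispersion; the design tracer treats the source as collimated (the 0.22
  NA of the design bundle is carried for divergent-source studies).
* The exact surface prescription of the physical lens is not published;
  the crossed-arc reading is the only arrangement of the printed radii
  that reproduces the designed field of view, but its center thickness and
  flank shape remain assumptions.
* Transport is single-medium and index-matched; no Fresnel boundaries,
  time resolution, or heterogeneous voxels.
* The acoustic chain is linear single-scattering with ideal point
  elements; no full-wave propagation, element directivity is off by
  default, and tissue attenuation is omitted (the wire tank is milk).
* The intestinal-wall transmission preset interpolates a synthetic table
  anchored at two published summary values (0.263 at 780 nm; mean 0.219
  over 650-975 nm); its shape between anchors is a stand-in.
* The adaptive beamformer used with the physical system is not
  reproduced; the coherence factor is a labelled substitute.
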