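# patrus

Desk-scale simulation of a combined transrectal ultrasound–photoacoustic
(TRUS–PA) imaging probe, for engineers and imaging scientists who want to
study the probe's computational design without hardware: the dual-geometry
illumination lens, the optical fluence it delivers into a turbid medium, the
miniaturized convex receive array, and photoacoustic / pulse-echo image
formation on a radial wire phantom. All inputs are generated in code.

## What it computes

**Illumination lens.** In the lateral-axial (imaging) plane the lens is a
concave–convex pair of circular arcs (radii 8 / 11.5 mm, n = 1.519) that
fans a 13 mm collimated beam into a wide sector; in the elevation-axial
plane it is a planar–oblique (thin prism) profile (80° oblique face) that
deflects the beam toward the imaging plane. `trace_lateral()` measures the
fan's field of view as the full angle between the extreme surviving exit
rays; `trace_elevation()` applies the exact prism deviation
δ = asin(n sin A) − A with apex A = 10°, giving a 25 mm crossing depth for
a 2.316 mm beam offset.

**Photon transport.** MCML-style weighted packets: exponential free paths
with μt = μa + μs, per-interaction deposits w·μa/μt, Henyey–Greenstein
scattering (E[cos θ] = g), Russian roulette, exact weight bookkeeping.
`simulate_fluence()` compares lens-shaped against bare fiber-bundle
illumination; `slab_transmission()` recovers Beer–Lambert exp(−μa L) in the
ballistic limit.

**Array and pulse.** `convex_array()` builds the 128-element, 134.5°,
11.4 mm-footprint receive arc (radius 4.856 mm); `synthesize_pulse()` /
`characterize_pulse()` round-trip the measured 6.75 MHz / 66% −6 dB
fractional bandwidth through a Gaussian pulse model and its spectral
estimator.

**Image formation.** `simulate_pa_rf()` (one-way) and `simulate_us_rf()`
(two-way) synthesize channel data for point-target phantoms;
`das_beamform()` applies walking-aperture delay-and-sum on 128 radial
scanlines (32 active channels at the edge, 64 at the center, matching the
probe's channel arithmetic), with optional coherence-factor weighting;
`envelope_logcompress()` and `scan_convert()` produce sector B-mode images;
`overlay()` fuses PA onto US.

## Worked example

```r
library(patrus)

lens <- lens_design()                 # printed design values as defaults
tr <- trace_lateral(lens, n_rays = 1001)
tr$fov_full_angle_deg
#> [1] 102.6574                        # designed lateral field of view (~105)
trace_elevation(lens)
#> $deviation_angle_deg
#> [1] 5.293973
#> $crossing_depth_mm
#> [1] 24.99431                        # the 25 mm design depth

p <- synthesize_pulse(6.75, 0.66, 100)
unlist(characterize_pulse(p$waveform, 100))
#> center_frequency_mhz fractional_bandwidth
#>            6.7500913            0.6600106

active_channels(1, 128, 64)$count     # outermost scanline
#> [1] 32
active_channels(65, 128, 64)$count    # center scanline
#> [1] 64

# wire phantom -> PA channel data -> sector image
ph  <- make_wire_phantom()            # 66 wires, -75..75 deg x 5..55 mm
rf  <- simulate_pa_rf(ph, convex_array(), synthesize_pulse(6.75, 0.66, 40))
sl  <- envelope_logcompress(das_beamform(rf, convex_array()), 35)
img <- scan_convert(sl, convex_array())
save_bmode_pgm(img, "wires.pgm")
```

The FOV number is the full divergence angle of the surviving exit fan; the
pulse numbers show the synthesis/characterization round trip recovering the
transducer's printed values; the channel counts are the walking-aperture
clipping at the sector edge and center.

A thin CLI over the same functions ships in `inst/cli/patrus.R`
(subcommands `design-lens`, `fluence`, `simulate`, `beamform`, `fixtures`,
`run`). The methods vignette
(`vignettes/probe-design-simulation.Rmd`) documents the models, parameter
choices, and limitations.

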