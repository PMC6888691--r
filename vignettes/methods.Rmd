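---
title: "Methods: quantifying nanoparticle radio-enhancement of DNA double-strand breaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying nanoparticle radio-enhancement of DNA double-strand breaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npdamage)
```

## The problem

Metal nanoparticles taken up near DNA amplify the biological effect of
ionizing radiation. The endpoint used throughout this package is the DNA
double-strand break (DSB), the "nanosize" lesion hardest to repair, measured
two ways: *in silico*, by scoring energy deposits from secondary-electron
cascades against a DNA geometry; and in a gel-electrophoresis assay, by
quantifying the conversion of supercoiled plasmid to its linear form. The
headline statistic in both arms is the amplification factor

$$\mathrm{AF} = 100 \times \frac{Y_{\mathrm{NP}} - Y_{\mathrm{control}}}{Y_{\mathrm{control}}}\ (\%),$$

the percentage increase of the DSB yield in the presence of nanoparticles.
Because the AF is a ratio, it is invariant to the absolute normalization of
either yield; this is what makes it comparable between a simulation and a wet
assay, and it is the only simulation-arm quantity this package treats as
reproducible (absolute DSB rates are transport-code outputs outside our
scope).

## Simulation arm

### Phantom

`build_phantom()` places non-overlapping core-shell particles (default: 3 nm
Au core, 2 nm shell, Pt or Au) uniformly in a water sphere, by default 191
particles in 50 µm³ (radius 2.285 µm). Placement is rejection sampling of
centres uniform in the sphere interior shrunk by the particle outer radius,
with up to 10⁵ retries per particle; at this dilution (volume fraction
~10⁻⁶) rejections are vanishingly rare, and the centre distribution is
indistinguishable from uniform (Kolmogorov–Smirnov statistic below 0.02 at
10⁴ particles in the test suite).

The particle count is a configuration input, not derived from concentration.
The nominal experimental metal concentration (4.23×10⁻⁵ mol L⁻¹), the
atoms-per-particle estimate from bulk density
(`atoms_per_particle(3, 59)` = 834) and the phantom volume together imply on
the order of 1.5×10³ particles — an order of magnitude above the 191 we use
as the default. The conversion assumptions behind the smaller count are not
reconstructible, so the package honours the configured 191 and exposes
`particles_from_concentration()` for the bookkeeping; no result in this
package depends on the choice, since all damage statistics are ratios or
per-dose rates.

### Synthetic phase space

`sample_events()` is a *parametric* stand-in for a two-stage Monte Carlo
transport calculation. It does not transport photons or electrons. It
produces what the downstream scoring actually consumes: a spatially
structured set of point energy deposits with process labels, namely

- a uniform background of events in the water sphere,
- an *enhancement annulus* around every particle surface
  (`enhancement_radius`, default 10 nm in the generic configuration) with
  additional events at `enhancement_factor` times the background density,
  keyed by shell material — the parametric expression of the locally
  increased secondary-electron fluence around a metal particle,
- per-event process labels drawn from configurable relative frequencies
  over {elastic, electronic excitation, vibrational excitation, ionization,
  molecular attachment}, and
- per-event energies drawn from an exponential distribution with a
  per-process mean (elastic events deposit exactly zero).

Default process weights use the track-averaged counts characteristic of a
Co-60 secondary-electron cascade around a nanoparticle (ionization 5.37×10⁴,
vibrational excitation 1.61×10⁵, attachment 467) with order-of-magnitude
elastic (10⁶) and electronic-excitation (2.1×10⁴) weights; the per-process
mean energies (ionization 25 eV, electronic excitation 10 eV, vibrational
0.5 eV, attachment 5 eV) are placeholders at the right scale. None of the
package's comparative statistics depend on these defaults: everything
downstream is normalized per dose, and the AF is additionally a ratio.

The event count is set so the expected deposited energy matches the target
water dose, and the sampled energies are then rescaled by one global factor
so the realized water-sphere dose equals the prescription exactly
(phase-space dose calibration — the standard practice of normalizing a
recorded phase space to a prescribed dose). Supplying an explicit
`background_event_density` bypasses the calibration. The spatial form of the
near-particle enhancement (uniform annulus) is a declared modelling choice;
nothing in the sources prescribes one.

What the generator deliberately does not emulate: correlated track
structure (deposits along an electron path), Auger cascades, the
photoelectric/Compton energy dependence of the metals, and any chemistry.
Passing tests therefore demonstrate that the scoring chain is correct and
that a locally enhanced deposit density produces a positive AF — not that
any particular AF magnitude is physical.

### DNA geometry and damage scoring

`build_bdna()` generates an ideal B-form duplex: one sugar-phosphate
sensitive site per strand per base pair, on a 0.94 nm-radius helix with
0.34 nm rise and 36° twist, capture radius 0.35 nm by default (the scale of
the sugar-phosphate moiety). `load_pdb()` provides the alternative of a real
structure, collapsing each residue of the first two chains to its backbone
centroid; chains are paired positionally, which makes strand semantics a
convention when the structure is a protein surrogate rather than a true
duplex. The procedural duplex is the default precisely because SSB/DSB
semantics require well-defined strands.

Scoring follows three rules:

1. **Accumulation** — each deposit is assigned to the nearest site if within
   that site's capture radius, else discarded; site energy is the sum of its
   deposits (`accumulate()`).
2. **SSB** — a site is broken when its accumulated energy *strictly exceeds*
   8.22 eV (the ionization-energy scale of DNA). The comparison is strict:
   exactly 8.22 eV is not a break.
3. **DSB** — SSBs sorted by base-pair index are swept left to right; an SSB
   joins the open cluster when its gap to the cluster's *last* member is at
   most 10 bp (chain rule, inclusive; equal indices on opposite strands are
   gap 0). A cluster is one DSB iff it spans both strands, however many SSBs
   it contains.

The inclusive-gap convention (a 10 bp separation qualifies, 11 does not) is
a choice the sources leave open; both thresholds are exposed in
`damage_config()`. The sweep is verified in the test suite against an
independent brute-force oracle (connected components of the
within-threshold graph) over a thousand random break configurations — the
two constructions coincide exactly for points on a line.

Rates are reported as DSB Gy⁻¹ Gbp⁻¹: count / dose / (length in Gbp).

### The two-arm demonstration and its scale

`run_simulation_arm()` compares a control (particles present but
radiologically inert: enhancement forced to zero) against a nanoparticle arm
(configured enhancement) on one phantom. A genuine plasmid-scale
configuration — micrometre sphere, sub-nanometre capture radii, doses of a
few gray — puts the probability of any deposit landing in a sensitive site
around 10⁻³ per 10⁵ events, so DSB counts would be identically zero at any
event count a laptop-scale run can afford; that regime is exactly why
production transport codes run 10⁸-step simulations. The default
`simulation_config()` therefore defines a deliberately scaled-down study:

- 0.05 µm³ sphere, 4 particles, 300 bp duplex with 2 nm capture radius,
- the duplex placed 5 nm from the first particle's surface, fully inside its
  60 nm enhancement annulus,
- process weights tilted toward energy-depositing events, and a 20 kGy dose
  chosen so the nanoparticle arm sits near the DSB-count optimum of the
  clustering rule (about one SSB per 10 bp) while the control stays well
  below it. Beyond that optimum, chain clustering *merges* breaks into few
  giant clusters and the DSB count falls — an intrinsic, and physically
  meaningful, saturation of the 10 bp rule.

Per-seed DSB counts are small (a handful), so `analysis/03_score_damage.R`
and the tests pool counts over seeds before forming the AF. The pooled
comparison shows the expected behaviour: enhancement strictly increases
scored damage, identical arms give an AF compatible with zero, and the whole
run is bit-reproducible from its seed manifest.

## Experimental arm

### Quantification chain

Gel densitometry gives per-lane band intensities for the supercoiled (S),
relaxed (R) and linear (L) plasmid conformations. The chain implemented in
`normalize_lane()` and `fit_dose_response()` is:

1. staining correction: total = 1.47·S + R + L (supercoiled DNA intercalates
   ethidium bromide less efficiently; the 1.47 factor is the assay's
   calibration constant, overridable),
2. linear fraction: L′ = L / total,
3. Poisson inversion: DSB per plasmid = L′ / (1 − L′). Under a Poisson break
   count with mean µ, the linear band collects plasmids with at least one
   DSB in the low-probability regime, and this inversion recovers µ exactly
   from the forward map l = µ/(1+µ),
4. dose response: unweighted least squares of DSB/plasmid against dose,
   pooling replicates. The slope is the yield m_DSB
   (breaks plasmid⁻¹ Gy⁻¹); the intercept is left free because native
   plasmid preparations carry background damage. The slope standard error is
   the classical formula √(RSS/(n−2)/Sₓₓ).

`amplification()` forms the AF between two fitted slopes and `oh_effect()`
the scavenger decomposition 100·(m − m_DMSO)/m — the fraction of damage
suppressed when DMSO quenches hydroxyl radicals, i.e. the indirect,
water-radiolysis-mediated share. Uncertainties are first-order propagation
of the slope SEs. Both statistics are invariant under a common rescaling of
all slopes. One published cell is knowingly non-reproducing: the bimetallic
scavenged OH effect computes to 87.5% from its own printed slopes while the
table prints 86 ± 1 (plausibly a mean of per-replicate values); the test
suite documents the discrepancy rather than matching it.

### Forward gel generator

`synth_gel()` inverts the chain exactly: µ = m_DSB·D, l = µ/(1+µ),
supercoiled fraction s = (1−l)·exp(−m_SSB·D) (exponential single-strand-break
conversion of the surviving supercoiled pool), r = 1 − l − s; measured
intensities are (s/1.47, r, l) plus independent Gaussian noise of SD
`noise_sd` on each band, truncated at zero. Noise is applied to intensities,
before normalization, because that is where densitometry noise lives. The
default SSB:DSB yield ratio of 20 is a typical value for sparsely ionizing
radiation and only shapes the S/R bands; SSB yields are never an output
statistic.

With zero noise the fit recovers the generating slope to 10⁻¹⁰ relative, and
the staining factor cancels whenever generation and analysis use the same
value — both are property tests. With noise SD 0.01 and triplicate lanes at
doses 0–500 Gy, the recovered slope is consistent with the truth (within 3 SE
in well over 95% of seeds). One known small bias: zero-truncation of the
noise inflates the linear band at dose 0 by the half-normal mean (≈0.004),
which the free intercept mostly — not entirely — absorbs; the residual effect
lowers the fitted slope by a few percent of its value at the default noise
level. It is a faithful consequence of non-negative densitometry readings,
not an estimator defect, and it is small against the seed-to-seed spread.

## XPS shell thickness

`shell_thickness()` implements the overlayer-attenuation estimate
T = L_film · cos θ · ln(1 + R): photoelectrons from the core are attenuated
exponentially in the shell, and the intensity ratio folds into the single
overlayer parameter R. At normal emission (θ = 0) with R = 3 (the value used
for these particles, numerically the mean core diameter) and the Au-4f
attenuation length L_film = 1.02 nm, T = 1.414 → 1.4 nm at one decimal. Two
attenuation lengths are tabulated for this system (Au 1.02 nm, Pt 1.05 nm)
without a stated choice; only 1.02 reproduces the published 1.4 nm after
rounding, so it is the default, with 1.05 available by argument (it gives
1.456 nm — the same 1.4–1.5 nm answer within the method's ~4% uncertainty).

## Numerical and interface choices

- All lengths are nanometres internally; the phantom volume is accepted in
  µm³ and converted once. Doses are Gy; energies eV
  (1 eV = 1.602176634×10⁻¹⁹ J).
- Every sampling routine runs under a private RNG stream seeded explicitly,
  so package calls never disturb the caller's `.Random.seed`, and identical
  (inputs, seed) give bit-identical outputs — phantom, phase space, gels and
  the full two-arm pipeline all carry determinism tests.
- Phase spaces, phantoms and gel lanes serialize to headered columnar text
  (TSV/CSV) with lossless round trips; malformed rows are reported with
  line numbers.
- Deposit-to-site assignment uses a bounding-box prefilter followed by
  chunked exact nearest-site search, keeping memory bounded at ~10⁵ deposits
  against ~10⁴ sites.
- Degenerate inputs fail loudly: all-linear lanes (L′ = 1) are out of the
  Poisson inversion's domain, fits require three distinct doses, AFs require
  a positive control, overcrowded phantoms error after the retry budget.

## Known limitations

- The event generator is parametric; absolute simulated DSB rates have no
  physical calibration and are never reported as such — only ratios are.
- The two-arm demonstration runs at deliberately scaled conditions (small
  phantom, enlarged capture radius, kGy doses); it demonstrates ordering and
  reproducibility, not magnitudes.
- PDB-derived geometries pair chains positionally; for non-duplex
  structures the strand assignment is a convention.
- The chemical stage (radical diffusion and reaction) is absent entirely;
  the scavenger decomposition exists only in the experimental arm.
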