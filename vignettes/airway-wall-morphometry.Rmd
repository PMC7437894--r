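---
title: "Integral-based airway wall morphometry: models, parameters and design notes"
author: "bronchoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integral-based airway wall morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bronchoquant)
```

## The measurement problem

Quantitative CT of the airways reports four numbers per airway cross
section: total diameter (TD), lumen area (LA), wall area (WA) and wall
thickness (WT). Airway walls are thin (0.3–2.5 mm) relative to the
in-plane blur of a clinical CT reconstruction, so naive edge placement is
systematically wrong: the classical full-width-at-half-maximum (FWHM)
rule localizes each wall border at the half-height of the wall peak,
which for a wall thinner than the point-spread function (PSF) widens the
apparent wall roughly to the PSF width. Integral-based methods (IBM)
avoid this by fitting an *ideal airway model* to each radial density
profile so that the model's integral matches the measured profile's
integral over windows around each border; because blurring redistributes
attenuation without destroying it, the matched integrals pin down the
border positions even when the wall is unresolved.

A second, independent error source is an adjacent vessel. Blood (~32 HU
non-enhanced, several hundred HU under contrast) is nearly as dense as
the wall, so along rays that run into a vessel there is no outer border
to detect, and partial-volume smear from an enhanced vessel leaks across
the wall into the lumen. The two completion strategies this package
implements differ exactly here:

* **standard**: fit a least-squares ellipse through the inner wall
  points of all valid rays and read the missing inner points off the
  ellipse;
* **modified**: take the median attenuation of all detected inner wall
  points and, on each failed ray, place the inner point at the first
  position (scanning outward from the lumen centre) where the profile
  reaches that median.

Wall thickness is deliberately left untouched by the completion: WT is
the median border separation over *valid* rays only.

## The per-ray model

A radial profile through a concentric circular airway is the radial
section of a Gaussian-blurred set of nested discs. The blurred profile
of a disc of radius $R$ under an isotropic Gaussian PSF of SD $\sigma$
has the exact closed form

$$B(r; R) = P\!\left(\chi^2_2\!\left(\tfrac{r^2}{\sigma^2}\right) \le \tfrac{R^2}{\sigma^2}\right),$$

the noncentral chi-square CDF with two degrees of freedom, and the model
profile is

$$f(r) = \mathrm{HU}_p + (W - \mathrm{HU}_p)\,B(r; c_{out}) + (\mathrm{HU}_l - W)\,B(r; c_{in}),$$

with $\mathrm{HU}_l$ the lumen (air), $W$ the wall and $\mathrm{HU}_p$
the parenchyma attenuation. This *annular* model is the package default.
The more familiar *planar* model replaces $B(r;R)$ with
$1 - \Phi((r-R)/\sigma)$ — the blurred half-plane — and is what the two
families converge to as $R/\sigma$ grows. The annular family is the
default because the planar one carries a curvature bias: the apparent
edge of a blurred convex boundary moves toward its centre of curvature
by about $\sigma^2/2R$, so a planar fit overestimates WT by roughly
$\sigma^2/(2 R_{in} R_{out})$ relative — about 14% for a 1 mm lumen
radius at $\sigma = 0.6$ mm, which alone would consume the method's
whole accuracy budget on small airways. Both families are exposed via
`ibm_config(model =)` and both are covered by self-consistency tests.

Fitting alternates two monotone one-dimensional root solves: $c_{in}$
on a window from $c_{in} - 4\sigma$ (clipped at 0) to the current
mid-wall position $(c_{in}+c_{out})/2$, then $c_{out}$ from the mid-wall
position to $c_{out} + 4\sigma$ (clipped at the profile end), each
matching trapezoidal integrals on the sample grid, starting from the
FWHM edges. The mid-wall split is used instead of the sampled peak
position because the blurred peak of a sub-PSF wall is flat over several
samples and its argmax is an unreliable divider. Alternation stops when
both borders move less than `convergence_mm` (default 0.0002 mm, which
keeps the residual integral mismatch below ~0.5 HU·mm).

### The wall attenuation is an assumption, not a measurement

For walls thinner than about $2\sigma$ the image cannot separate wall
density from wall thickness: a denser, thinner wall and a lighter,
thicker one produce nearly identical blurred profiles (the
partial-volume degeneracy). Joint estimation is therefore
ill-conditioned — in our experiments the sensitivity of the observable
mid-wall residual to the assumed density is a few thousandths of an HU
per HU at WT = 0.3 mm, so realistic noise maps to density errors of
hundreds of HU and WT errors of tens of percent. The package
consequently defaults to `wall_hu_mode = "fixed"` with a soft-tissue
wall of 0 HU, stating the density as a model assumption. For resolved
walls (`WT >~ 2 sigma`) `"auto_max_peak"` reads the density off the
tallest wall peak (accurate once a plateau exists), and
`"auto_refine"` iteratively re-estimates it from the fitted borders —
appropriate on clean, well-resolved data.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `psf_sigma_mm` | 0.6 | mm | Gaussian SD standing in for a soft (smooth) reconstruction kernel; configurable because scanners do not report it. |
| `prominence_min_hu` | 50 | HU | minimum rise of the wall peak over the outer plateau; real thin walls in front of −850 HU parenchyma keep >100 HU, pure noise stays below ~50. Set well below real-wall prominence so that noise cannot *select* rays, which would bias thin-wall statistics. |
| `outer_max_hu` | −500 | HU | outer plateaus brighter than this mark soft tissue/vessel rays (with or without contrast), which carry no outer border. |
| `wall_hu_fixed` | 0 | HU | assumed soft-tissue wall density (see above). |
| `n_rays` | 128 | — | angular sampling of the border. |
| `step_mm` | 0.1 | mm | profile sampling step (≈ spacing/5) so edge localization is not step-limited. |
| `convergence_mm` | 2e−4 | mm | alternation stopping rule. |

When measuring *images* (as opposed to analytic profiles), the model
sigma should be the **effective** blur: rasterization averages over the
pixel area (variance spacing²/12) and bilinear resampling along a ray
smooths over about one more pixel (≈ spacing²/8 along-ray). The helper
`effective_psf_sigma(psf, spacing)` combines these; all scripted studies
use it. With the raw PSF instead, small-lumen areas come out several
percent low.

Ray validity is classified per ray (`border_taint`, `bright_outside`,
`low_prominence`, `order_violation`) and, in a second pass, fits whose
wall thickness falls outside [median/2, 2·median] over the airway are
invalidated as `outlier_wall`: rays grazing an adjacent vessel can fuse
wall and vessel into one apparent wall (or latch onto the smear beyond
the true wall) while passing every plateau check, and such fits would
otherwise drag the ellipse completion by several percent of LA.

## The synthetic phantom

`render_phantom()` draws a continuous scene — parenchyma at −850 HU, an
optional vessel disc, the airway annulus at 0 HU, an air lumen at
−1000 HU — rasterized by 8×8 supersampling per pixel, convolved with an
isotropic Gaussian (truncated at 4 SD, reflective padding), then
degraded with i.i.d. Gaussian noise from a fixed seed. Rendering is a
pure function of the spec. Ground truth is closed-form
(`ground_truth()`).

What it emulates: partial-volume blur of a soft kernel, quantum noise at
a plausible 20 HU SD, the contact geometry of an airway sharing a wall
arc with its accompanying artery, and the four contrast phases via the
vessel attenuation presets NE 32 / PA 725 / SA 503 / VE 96 HU.

What it does not emulate: correlated/streak noise, beam hardening,
cardiac motion, non-circular airways, textured parenchyma, oblique
airway orientation, or a real (non-Gaussian, spatially varying)
scanner PSF. Passing tests therefore demonstrate correctness of the
measurement machinery under the stated image-formation model — they do
not certify accuracy on clinical scans.

The contrast-phase study uses a frozen base geometry: lumen radius 2 mm,
wall 0.8 mm (a segmental-size airway), vessel radius 6 mm tangent to the
outer wall, chosen as the configuration in which the airway shares a
long contact arc with a large artery and enhancement smear reaches
across the thin wall. Four noise repeats per phase mirror a four-fold
repeated non-enhanced acquisition; repeat seeds are shared across phases
so phases are compared on paired noise.

## What the studies show (and do not)

The accuracy sweep (`run_accuracy_sweep()`) spans WT 0.3–2.5 mm ×
TD 2.6–9.0 mm (realizable pairs, 18 grid points, 3 noise repeats each —
about 20 s of compute) and reports the per-point mean relative WT error
of the standard IBM and its grid maximum; `scripts/acceptance.R`
recomputes exactly this. At 20 HU noise the thin-wall (0.3 mm) points
are noise-floor limited: the wall's attenuation excess is spread over
very few pixels, and the per-repeat WT error SD is ~3% there, which the
median over 128 rays cannot reduce further because nearby rays share
pixels.

The phase study (`run_phase_study()`) reproduces the *existence* and
*direction* of the contrast artifact: smear from an enhanced contact
vessel pulls detected inner borders inward, the effect grows with vessel
attenuation and is negligible at venous enhancement (~100 HU). Two
in-vivo observations do **not** reproduce with this implementation, and
the corresponding acceptance assertions are left failing rather than
weakened: (i) a *negative* lumen-area response of the *standard* method
to contrast, and (ii) the modified method's response being strictly
smaller than the standard's. Both rest on the original software's
standard pipeline accepting contrast-corrupted rays whose inner points
drag the ellipse into the lumen; this package's validity classification
(the very checks the detection needs elsewhere) removes those rays in
every phase, leaving the standard ellipse essentially phase-insensitive
(±1%, sign unstable under noise), while the modified completion retains
its small (~0.05 mm on the contact arc) inward smear sensitivity. The
modified method's benefit against a *less defended* standard — the
historical situation — is documented in the source study; against this
package's standard it manifests as the two methods' differing
completion behaviour, not as a reduction of an otherwise large error.

## Numerical choices

* Bilinear interpolation for all image sampling: monotone across edges,
  no overshoot; its anisotropy leaves ray-to-ray differences up to a few
  tens of HU at blurred edges, harmless to the integral fits.
* $B(r;R)$ is evaluated through a cached lookup table over $R$
  (0.02 mm grid, linear interpolation; error ≲ 0.15 HU), keeping the
  annular fit as fast as the planar one.
* Root solves use `stats::uniroot` with tolerance 1e−5 mm on brackets
  guaranteed monotone by the model's structure; a failed bracket marks
  the ray `order_violation` rather than fabricating a position.
* Ties in peak finding go to the innermost sample; threshold crossings
  are linearly interpolated; degenerate polygons fall back to vertex
  means for centroids.
* Centre refinement iterates profile casting from the inner-polygon
  centroid (≤5 iterations, 0.1 mm tolerance); the seed only needs to be
  inside the lumen.
* Profiles are truncated to the pixel-centre grid so that border taint
  marks genuine truncation, not a requested length brushing the edge.

## Known limitations

* Strictly 2D: no centerline, no obliquity correction; airways
  substantially non-perpendicular to the slice are overestimated.
* The wall-density assumption (0 HU) biases WT on airways whose true
  wall density differs substantially, in proportion to the mismatch.
* The annular model assumes concentric circular borders; strongly
  elliptical airways reintroduce a curvature mismatch between model and
  data.
* DICOM support covers uncompressed single-frame little-endian files
  only.
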