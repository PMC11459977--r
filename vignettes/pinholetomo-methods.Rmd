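---
title: "Pinhole SPECT system-matrix modelling and reconstruction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pinhole SPECT system-matrix modelling and reconstruction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A pinhole SPECT camera images a radiotracer distribution through a small
aperture: each image voxel illuminates a magnified, inverted patch of the
detector, and the pattern of scintillation events over a circular orbit of
view angles encodes the 3D distribution. Reconstruction needs a *system
matrix* $A$ whose entry $a_{bj}$ is the probability that a photon emitted in
voxel $j$ is detected in bin $b$. This package models that matrix for single-
and multi-pinhole collimators and reconstructs images from (simulated)
projection data with Poisson-likelihood algorithms.

# Coordinate conventions

* Image arrays are `[z, y, x]` with z axial; the volume centre sits on the
  axis of rotation. All lengths are mm, angles degrees, attenuation mm$^{-1}$.
* The rotating detector/collimator frame $(x', y', z')$ coincides with the
  fixed frame at view angle 0, with $y'$ pointing from the collimator toward
  the detector — the detector sits on $+y$ at 0 degrees and positive angular
  increments rotate counterclockwise seen from $+z$. (The camera emulated here
  acquires 270 degrees counterclockwise from 180 degrees in 3 degree steps.)
* Detector bins are square; the transaxial bin axis lies along $x'$ and the
  axial one along $z'$, offset by the orbit's axial position.

# System matrix

## Geometric footprint

For voxel centre $v$ and a hole at $h$ with aperture area $A$, the total
geometric weight is the solid-angle sensitivity
$$w = \frac{A \cos\theta}{4\pi r^2}, \qquad r = \lVert h - v \rVert,$$
with $\theta$ measured to the (possibly tilted) hole axis. Voxels outside the
hole's acceptance cone, or on the wrong side of the aperture plane, get no
weight. The aperture boundary (24-gon for round holes, corners for
rectangular ones) is centrally projected through the voxel onto the detection
plane — each boundary point by similar triangles — and the weight is spread
over bins by the fractional overlap of the projected polygon. Overlap is
rasterized by analytic scanlines: exact interval coverage along $x'$, four
subsample rows per fine pixel along $z'$. On the hole axis this reduces to
the textbook magnification: a round hole of diameter $a$ at distance $d$ from
the source and $f$ from the detection plane projects to a disc of diameter
$a\,(d+f)/d$.

*Tilt* is a single rotation of the hole axis about $z'$ (the axis the
literature leaves ambiguous; documented here as the package's convention).

## PSF correction

The camera's intrinsic blur is modelled as an isotropic Gaussian with
$\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$, built on a subsampled detector
grid (`bin_size / psf_subsampling`), truncated at `psf_n_sigma` standard
deviations, integrated over pixels, renormalized to unit sum, and convolved
with the footprint in detector space before downsampling to the bin size.
A unit-sum kernel conserves each voxel's total weight except where the
footprint spills off the detector edge (physically lost counts).

## DOI correction

With depth-of-interaction enabled, the crystal is subdivided into fixed
intervals of `sampling_interval` mm measured normal to the face. Interval
$k$ spanning depths $[t_k, t_{k+1}]$ receives the interaction probability
$$w_k = e^{-\mu_c t_k/\cos\phi} - e^{-\mu_c t_{k+1}/\cos\phi},$$
where $\mu_c$ is the crystal's linear attenuation and $\phi$ the angle of the
LOR to the detector normal, and the footprint is re-projected to that
interval's mid-depth plane, which carries the parallax drift of oblique rays.
The total deposited weight is the absolute detection probability
$1 - e^{-\mu_c \ell_{\mathrm{tot}}}$ (not renormalized per LOR; the
alternative convention would hide the crystal's finite stopping power).
Degenerate cases are explicit: zero thickness falls back to the face plane
with unit weight (so the $T \to 0$ limit equals the DOI-off result at the
face), and zero crystal attenuation falls back to mid-depth with unit weight
and a warning. With DOI *disabled*, interactions are assumed at half the
crystal depth: the detection plane is the face radius plus $T/2$.

## Attenuation correction

`simple` applies one factor $e^{-\int \mu\, dl}$ along the voxel-to-hole ray
to the whole footprint; `full` computes a separate factor along each
voxel-to-bin LOR. Line integrals use an incremental Siddon-style traversal
with exact per-voxel chord lengths (the crystal subdivision above uses
fixed-step sampling instead — attenuation needs exact lengths, DOI needs
uniform depth samples). The attenuation endpoint for `full` is the bin centre
on the mid-crystal plane; since the attenuation map only covers the object,
the exact detector-side endpoint is immaterial.

## Masking and storage

Weights are computed only for voxels inside the mask: the default cylinder of
`object_radius` about the rotation axis, the strictly positive voxels of an
attenuation map, or a mask file. If a map/file mask is combined with an
object radius it must fit inside the cylinder, otherwise an error is raised.
Per-view matrices are sparse (bins x voxels, compressed columns built
directly from the projector's voxel-major output). `keep_in_memory` caches
all views; the per-angle mode rebuilds each view on use and releases it —
both modes execute the identical code path and give bit-identical results.

# Reconstruction

All algorithms process angularly interleaved subsets (view $k$ to subset $k
\bmod N$) sequentially; MLEM is the one-subset case and matches OSEM(1)
bit-for-bit. Iterates stay non-negative; `0/0` ratios are treated as 0 and
voxels with zero subset sensitivity are left untouched.

* **OSEM/MLEM**: $x \leftarrow \dfrac{x}{s_S}\, A_S^T\!\left(\dfrac{m_S}{A_S x}\right)$
  with $s_S = A_S^T 1$.
* **OS-OSL-MRP**: one-step-late with the median root prior. The denominator
  is $s_S\,(1 + \mathrm{PF}\,(x - \mathrm{med}(x))/\mathrm{med}(x))$ over a
  3x3x3 neighbourhood. Note the deliberate scaling: the median-root gradient
  is dimensionless while sensitivities carry absolute detection
  probabilities ($\sim 10^{-4}$), so adding the raw gradient would let any
  PF of order 1 drown the likelihood term at realistic count levels; scaling
  by $s_S$ makes PF a scale-free prior weight with the documented behaviour
  (PF = 0 is OSEM exactly; flat neighbourhoods receive no penalty; a
  neighbourhood median of 0 disables the penalty at that voxel; non-positive
  denominators are clamped with a counted warning attribute).
* **OS-SPS-QP**: relaxed separable paraboloidal surrogates with a quadratic
  prior over the 26-neighbourhood (weights $1/\mathrm{distance}$),
  $$x \leftarrow \Big[x + \lambda_n \frac{N\,A_S^T(m_S/\hat y - 1) - \mathrm{PF}\,\nabla R(x)}{D + \mathrm{PF}\,c_R}\Big]_+,$$
  with precomputed data curvature $D = A^T(c \odot A1)$, $c_i = 1/m_i$ for
  $m_i > 0$ (the optimal precomputed curvature of the Poisson surrogate at
  the data) and relaxation $\lambda_n = \alpha/(1 + \gamma n)$. The counter
  $n$ advances per completed *full* iteration (a genuinely open choice; the
  package exposes `relax_per = "subiteration"` as the alternative).

The Poisson log-likelihood $\sum_b (m_b \log \hat y_b - \hat y_b)$ can be
traced per subiteration (`track_objective`), at the cost of a full forward
projection when subsets are used.

# Synthetic data

The generator replaces Monte Carlo/scanner data with three digital
technetium-99m phantoms: a micro image-quality phantom (33.5 mm outer
diameter, 63 mm long; five hot rods of 1-5 mm diameter and 20 mm length on a
7 mm pitch circle; a 30 mm x 15 mm uniform section; water and air spillover
chambers of 8 mm inner diameter placed per the NEMA NU-4 convention, since
the stated phantom dimensions leave the chamber geometry open), a mouse-sized triple
line source phantom (25.4 mm acrylic body; 0.4 mm line sources at the centre
and at 10 mm offsets separated by 90 degrees), and a uniform cylinder
(28 mm body; 26 mm x 21 mm active core). Cylinders are voxelized with 3x3
in-plane subsampling of boundary voxels and exact axial overlap; generation
is deterministic.

Acquisitions forward-project the activity, scale to a requested total count,
and draw independent Poisson counts per bin under a fixed seed. The stated
acquisition world, chosen once: aperture 1 mm at a 30 mm radius of rotation,
crystal face at 55 mm, 4 mm crystal with $\mu_c = 0.30$ mm$^{-1}$ and 1 mm
intrinsic FWHM (a CsI/SiPM-class preclinical head at 140 keV), 91 views of
3 degrees from 180 degrees; attenuation defaults at 140 keV are water
0.0153 mm$^{-1}$, acrylic 0.0173 mm$^{-1}$, air 0. Total counts per
acquisition are derived, not chosen: the emulated protocol's activities and durations
(cylinder 20 MBq x 910 s, IQ 50 MBq x 3600 s, line sources 30 MBq x 5460 s)
times the 140 keV emission probability (0.885) and the stated-world camera's
computed mean per-decay detection probability ($7.0\times10^{-5}$ for the
cylinder geometry) give $1.1\times10^6$, $1.1\times10^7$ and
$1.0\times10^7$ detected counts respectively, and the tests use those
levels. Tests state explicitly where they run reduced matrices or view
counts for runtime.

What the generator does **not** emulate: scatter (in the object or camera),
septal/knife-edge penetration, energy response and calibration effects,
detector dead time and decay, non-circular orbits. A green test therefore
establishes the internal consistency, adjoint correctness, analytic limits
and trend behaviour of the modelling and reconstruction — not agreement with
a physical camera.

# Numerical choices

* Footprint rasterization: analytic scanline coverage (exact in $x'$, four
  rows per fine pixel in $z'$); footprints thinner than the row spacing
  deposit at their centroid pixel. Second moments of the discrete footprint
  agree with a brute-force pixel-overlap oracle to well under a tenth of a
  bin.
* Ray tracing nudges the entry parameter by $10^{-12}$ of the clipped range
  to avoid boundary ties; chord-length conservation holds to $10^{-9}$
  relative.
* `min_weight` truncation defaults to 0 (keep every weight).
* `number of orbits` > 1 means repeated identical orbits, summed.
* Masked-out voxels keep value 0 through every algorithm; EM updates leave
  zero-sensitivity voxels unchanged.
* Interfile payloads default to little-endian 32-bit float (64-bit double
  available); integer-valued count data round-trips exactly.

# Known limitations

* Hole tilt is a single angle about $z'$; general two-axis tilts and
  keel/lofthole aperture profiles are out of scope, as is edge penetration.
* The intrinsic PSF is stationary in detector space; distance-dependent
  aperture blur beyond the geometric footprint is not modelled.
* OS-SPS-QP keeps the absolute prior formulation; its PF trades off against
  the data scale and was validated here only through its structural
  properties (PF = 0 monotonicity, uniform-image identities).
* The per-bin (`full`) attenuation mode prices one ray per footprint bin and
  is accordingly slower; `simple` is the practical default for preclinical
  geometries where attenuation is nearly footprint-constant.
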