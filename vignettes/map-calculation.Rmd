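---
title: "Statistical map calculation for cryo-EM single-particle analysis"
author: "cryodiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical map calculation for cryo-EM single-particle analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryodiff)
```

## The observation model

A single-particle reconstruction is treated, coefficient by Fourier
coefficient, as a blurred and noisy view of an unknown true map:

$$F_o(\mathbf{s}) = k(s)\,F_T(\mathbf{s}) + F_n(\mathbf{s}),$$

where $k(s)$ is a position-independent, resolution-dependent blurring
profile and $F_n$ is zero-mean complex Gaussian noise with variance
$\sigma_n^2(s)$. Because the two half maps are reconstructed from
independent particle half-sets, their difference is pure noise and

$$\sigma_n^2(i) = \tfrac14\,\langle |F_{o1}-F_{o2}|^2\rangle_i$$

estimates, per resolution bin $i$, the noise variance of the averaged
full map $F_o=(F_{o1}+F_{o2})/2$. The half-map and full-map Fourier
shell correlations are related by $\mathrm{FSC}_{full} =
2\,\mathrm{FSC}_{half}/(1+\mathrm{FSC}_{half})$.

The unknown blur $k$ cannot be separated from the signal variance using
the data alone. Assuming the structure is, on average, a collection of
atoms sharing a common $\langle B\rangle$, the product

$$k\sigma_T(i) = \left[\max\!\big(0,\ \langle|F_o|^2\rangle_i -
\sigma_n^2(i)\big)\right]^{1/2}$$

serves as a proxy for $k$: dividing coefficients by $k\sigma_T$ both
sharpens (undoes the average blur) and places every bin on a unit-signal
scale. Bins where the subtraction clips at zero contain no detectable
signal; their output coefficients are set to zero rather than left
unsharpened, which would only amplify noise. The clip is flagged in the
statistics table so users can see where signal ends.

## Likelihood and scale estimation

Model errors follow the classical Gaussian (Luzzati) picture: given
calculated coefficients $F_c$, the observation is complex-Gaussian with
mean $D F_c$ and total variance $S = \sigma_f^2 + \sigma_n^2$, giving the
per-bin log-likelihood

$$\log L_i = -\sum_{\mathbf{s}\in i}\left[\ln(\pi S_i) +
|F_o - D_i F_c|^2/S_i\right].$$

Its joint maximizers have closed form, and these are what
`estimateScales()` returns:

$$D_i = \frac{\sum \mathrm{Re}(F_o \bar F_c)}{\sum |F_c|^2},\qquad
S_i = \langle |F_o - D_i F_c|^2\rangle_i ,$$

with $\sigma_f^2 = \max(0, S_i - \sigma_n^2)$ recovered for map
weighting. The test suite verifies the maximizer property directly
against a dense grid search over $(D, S)$ built from the same sufficient
statistics. $D$ is real per bin; a complex or anisotropic $D$ is outside
this package's scope.

The overall sharpening $B$ used in preprocessing is *not* taken from a
Wilson-plot fit (unstable at modest resolution); it is the least-squares
slope of $\ln(\langle|F_o|\rangle_i/\langle|F_c|\rangle_i)$ against
$-s^2/4$, where $F_c$ comes from a copy of the model with all ADPs set to
zero, so the slope captures the full average blurring of the observation.

## The difference map and the expected map

The posterior of the blurred signal $kF_T$ given observation and model is
Gaussian with precision-weighted mean
$m = (\sigma_f^2 F_o + \sigma_n^2 D F_c)/(\sigma_f^2+\sigma_n^2)$.
Subtracting the model contribution and dividing by the $k\sigma_T$ proxy
gives the weighted, sharpened difference coefficients

$$\Delta F = \frac{\sigma_f^2}{\sigma_f^2+\sigma_n^2}\,
\frac{F_o - D F_c}{k\sigma_T},$$

computed by `fofcCoeffs()`. Two limits matter and are asserted in tests:
a perfect noiseless model gives $\Delta F \equiv 0$, and a bin whose
signal is fully explained ($\sigma_f^2=0$) contributes nothing. With no
model at all ($D=0$) the posterior expectation reduces to the normalized
expected map of `expectedMapCoeffs()`,

$$\mathrm{FSC}_{full}\,\frac{F_o}{k\sigma_T}
 = \mathrm{FSC}_{full}^{1/2}\,E,$$

which is what should be inspected when model bias must be excluded.
Interference terms between atoms in the derivation of the signal
variance are ignored, and $k$ is global: strongly heterogeneous $B$
regions will be under- or over-sharpened, a known limitation (a local
$k$ is a separate problem not attempted here).

The difference map is only meaningful when the ADPs of the input model
have been refined against the *unsharpened* map, so that the same
sharpening applies consistently to $F_o$ and $F_c$; the pipeline
therefore expects an externally refined model and performs no refinement
itself.

## Masking, trimming and sigma scaling

SPA box sizes are arbitrary, and empty voxels shrink the whole-map
standard deviation, inflating apparent sigma levels. With $f = m/n$ the
in-mask fraction of voxels and zeros outside the mask,

$$\mu_{mask} = \mu_{total}/f,\qquad
\mathrm{var}_{mask} = (\mathrm{var}_{total}+\mu_{total}^2)/f
 - \mu_{total}^2/f^2 .$$

`maskedMoments()` computes both this correction route and the direct
in-mask moments and requires them to agree (population variances make the
identities exact). Output maps are divided by
$\mathrm{var}_{mask}^{1/2}$, which makes contour levels independent of
the box: the same signal embedded in a 32^3 or a 96^3 box yields
identical sigma-scaled in-mask values. When no mask is supplied, a
binary model mask of radius 3 Å around the (symmetry-expanded) atoms is
built; a raised-cosine soft edge is available but the default edge is
hard, since the choice only perturbs the normalization constant.

Preprocessing follows sharpen–mask–unsharpen: each half map is sharpened
by $\exp(+Bs^2/4)$, masked, and blurred back. Sharpening first
concentrates each atom's spread-out tails inside the mask, so the
processed map retains essentially the atom's full integrated density,
whereas plain masking deletes the outside tails irreversibly. Note a
subtlety verified in development: the *in-mask* integral is not the
quantity improved — for a nonnegative sharpened field it can be shown
never to exceed that of plain masking — the gain is in total retained
signal and in fidelity to the unmasked map, and that is what the test
suite asserts. Trimming cuts the mask's padded bounding box (snapped to
FFT-friendly sizes with prime factors ≤ 7, a performance choice only)
and records the voxel shift so absolute coordinates and symmetry
translations ($t_j' = t_j + (R_j - I)\,\mathrm{shift}$) are restored
exactly on output.

## Symmetry

Operators are generated from point-group symbols with the conventions:
$C_n$ about $+z$; $D_n$ adds a 2-fold along $+x$; $T$ with 2-folds on the
coordinate axes and 3-folds on the body diagonals; $O$ with 4-folds on
the coordinate axes; $I$ with a 5-fold on $z$ and an adjacent 5-fold at
$\arccos(1/\sqrt5)$ in the $xz$-plane. Cubic and icosahedral groups are
produced by closure from generators and every generated set is verified
closed (tolerance $10^{-8}$) with the expected orders (12/24/60). The
exact orientation convention for $T$ varies between reconstruction
packages; the one here is fixed and test-locked rather than claimed to
match any particular package. The symmetry origin is the box centre,
$t_j = (I-R_j)c$.

An atom within $\varepsilon$ (default 0.25 Å) of one of its symmetry
images sits on a special position. Its stabilizer must form a subgroup
(checked; a non-closed stabilizer is a geometry error), the atom is
projected onto the exact invariant locus by averaging over the
stabilizer — a projection that is idempotent by construction — its
anisotropic tensor is symmetrized the same way
($B \leftarrow |G|^{-1}\sum_j R_j B R_j^T$), and its occupancy is divided
by the stabilizer order so the expanded model double-counts correctly
(an annotation-only mode is available). Quadratic restraint residuals in
$1/\sigma_x^2$ and $1/\sigma_B^2$ (Frobenius distance for tensors)
quantify any remaining violation; both vanish after projection.

## Electron scattering factors

$F_c$ uses the Mott–Bethe conversion of standard 4-Gaussian X-ray form
factors, $f_e(s) = C\,(Z e^{2\pi i \mathbf{s}\cdot\Delta x} - f_x(s))/s^2$
with $C = 1/(2\pi^2 a_0) = 0.0957346$. Two numerical choices matter:
$f_x$ is evaluated so that $f_x(0)=Z$ exactly (the tabulated constants
miss $Z$ by $<0.01\,e$, which the $1/s^2$ would otherwise amplify near
the origin), and the $s\to 0$ coefficient uses the series limit
$C\sum a_i b_i/4$. The nucleus offset $\Delta x$ (hydrogen's electron
cloud is pulled 0.1–0.2 Å towards the parent atom) is carried per atom
with the phase on the $Z$ (nucleus) term; its sign follows the package's
$\exp(+2\pi i\,\mathbf{s}\cdot\mathbf{x})$ transform convention, and the
resulting real-space peak falls beyond the proton, as it should. By
default the offset is zero — positions in the input model are taken as
given — and `setHNucleusOffset()` applies a chosen magnitude along each
parent→H bond. Direct summation is used up to $10^4$ atom-copies (exact
within the tables); beyond that a 5-Gaussian electron-factor density is
sampled on the grid and transformed, and the two routes are held to
$<1\%$ bin-averaged agreement in tests (on a common element, since the
X-ray and electron tabulations themselves differ by up to $\sim$2% for
N).

## The synthetic generator

Every statistical claim in the package is testable without external data
because the generator realizes the observation model exactly: toy models
with a minimum separation (3 Å between heavy atoms, hydrogens riding at
1.0 Å), $B \sim U[10, 40]$ Å² by default, $F_T$ from the structure-factor
machinery, $k(s) = \exp(-B_{blur} s^2/4)$ with $B_{blur} = 60$ Å² by
default, and independent complex Gaussian noise per Hermitian-unique
coefficient (real noise on self-conjugate coefficients). The default
noise level is chosen so the half-map FSC is $\approx 0.143$ in the
highest-resolution bin — the gold-standard convention for data processed
at the resolution they support. The recorded ground truth contains the
per-bin noise variance (half-map variance / 2), the blurred signal
amplitudes and the seed; everything regenerates byte-identically from
that seed.

What the generator does *not* emulate: CTF and particle-alignment error
structure, position-dependent blurring, conformational heterogeneity,
solvent contribution, or correlations between the half sets. Passing
recovery tests on this generator demonstrates that the estimators are
correct under the stated model, not that the model captures every
property of real reconstructions.

## Problem sizes, defaults and degenerate inputs

Simulated grids in the tests range from 16³ to 48³ with 3–11 resolution
bins, sizes at which every estimator's bin counts reach the few-thousand
range where 5–10% recovery tolerances are meaningful. Bins are equal
width in $|s|$; sparse bins (fewer than 50 coefficients) are merged into
a neighbour, and bins with fewer than 10 coefficients report missing
statistics rather than estimates. A coefficient exactly on a bin edge
belongs to the lower-$|s|$ bin. Zero-power bins yield missing FSC (never
0); bins with zero model power have undefined $D$ and are excluded from
map coefficients with a warning. For omit maps the scales are estimated
against the omitted model by default: estimating them from the full model
can clip $\sigma_f^2$ to zero everywhere (model explains everything) and
annihilate the difference map — an instructive degeneracy the pipeline
guards against. Peak positions are refined by a three-point quadratic
per axis, peaks within half a voxel of the border are discarded, and
hydrogens with several potential minima (hydroxyl, sulfhydryl, carboxyl)
are excluded from both numerator and denominator of the primary
detection ratio, with the all-hydrogen convention reported alongside.

## Known limitations

Orthogonal boxes only (SPA practice); no crystallographic space groups;
no helical symmetry; no solvent model; no local (position-dependent)
sharpening; mask-bias-corrected FSC and local resolution are out of
scope. The MRC reader assumes little-endian files (universal on current
hardware) and modes 0/1/2.
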