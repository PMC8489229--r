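# cryodiff

Weighted, sharpened difference maps and half-map statistics for cryo-EM
single-particle analysis (SPA), in R.

## The problem

After an atomic model has been refined against a cryo-EM SPA
reconstruction, the questions that matter are *what did the model miss*
and *where is it wrong*. In crystallography these are answered with the
Fo−Fc difference map; in SPA the analogous map must be built differently,
because phases are observed for both the map and the model, and because
the reconstruction carries resolution-dependent blurring and noise that
must be estimated and weighted out. `cryodiff` implements that machinery
for structural biologists working from two *unsharpened, unweighted half
maps* (the reconstructions from the two independent particle half-sets)
and a refined atomic model.

## The model at the core

Per Fourier coefficient the observation is

    F_o = k(s) F_T + F_n,      F_o = (F_o1 + F_o2)/2,

with `F_T` the true coefficients, `k(s)` an isotropic blurring profile and
`F_n` zero-mean complex Gaussian noise. In resolution bins the package
estimates

* the noise variance `sigma_n^2 = <|F_o1 − F_o2|^2>/4`,
* the blurred signal amplitude `k sigma_T = (<|F_o|^2> − sigma_n^2)^{1/2}`
  (the sharpening proxy for the unknown `k`),
* half- and full-map Fourier shell correlations, with
  `FSC_full = 2 FSC_half/(1 + FSC_half)`,
* maximum-likelihood scales between the observation and the model
  transform: `D = Σ Re(F_o F̄_c)/Σ|F_c|^2` and the total residual variance
  `S = <|F_o − D F_c|^2>`, whence the model-error (Luzzati) variance
  `sigma_f^2 = max(0, S − sigma_n^2)`.

The weighted, sharpened difference coefficients are then

    dF = [sigma_f^2/(sigma_f^2 + sigma_n^2)] (F_o − D F_c) / (k sigma_T),

and the model-free normalized expected map uses `FSC_full · F_o/(k
sigma_T)`. Model transforms `F_c` come from the Mott–Bethe conversion of
X-ray form factors, `f_e ∝ (Z e^{2πi s·Δx} − f_x(s))/|s|^2`, which also
handles the shifted hydrogen nucleus (`Δx`) — the reason hydrogen
difference peaks appear *beyond* the proton position. Point-group
symmetry (Cn, Dn, T, O, I) is supported throughout: operator generation,
asymmetric-unit expansion, special-position detection/projection, and
anisotropic-ADP symmetrization. Output maps are normalized by the
standard deviation *inside a mask*, which removes the dependence of sigma
levels on the arbitrary SPA box size.

## Worked example: an omit map

Simulate half maps from a 6-atom toy model at 1.5 Å, omit the first atom
from `F_c`, and look for the difference peak:

```r
library(cryodiff)
model <- makeToyModel(6, box = 14, seed = 2)
sim   <- simulateHalfMaps(model, bBlur = 20, dMin = 1.5, seed = 11)
res   <- runFoFc(sim$half1, sim$half2, model, resolution = 1.5, omit = 1)
round(res$stats[, c("bin","d","n","sigmaN2","kSigmaT","fscHalf","fscFull","D")], 3)
#>   bin     d   n sigmaN2 kSigmaT fscHalf fscFull     D
#> 1   1 7.500 102   0.009   3.444   0.998   0.999 0.868
#> 2   2 3.333 117   0.006   1.724   0.996   0.998 0.641
#> 3   3 2.727 151   0.005   0.984   0.991   0.995 0.518
#> 4   4 2.308 225   0.003   0.493   0.973   0.987 0.383
#> 5   5 2.000 277   0.003   0.249   0.916   0.956 0.293
#> 6   6 1.765 387   0.002   0.121   0.810   0.895 0.202
#> 7   7 1.579 445   0.001   0.040   0.488   0.656 0.103
res$bOverall
#> [1] 30.5
peaks <- findPeaks(res$fofc, 3, sign = "positive")
round(peaks[1, c("x","y","z","height")], 2)
#>      x    y    z height
#> 1 4.39 8.69 7.62  20.24
round(unlist(model@atoms[1, c("x","y","z")]), 2)
#>    x    y    z
#> 4.35 8.70 7.62
```

The per-bin table shows the noise variance falling with resolution while
the FSC decays towards the cutoff; `D` tracks the blurring profile `k(s)`
because the model was built without the blur. The strongest positive
peak in the sigma-scaled Fo−Fc map stands at 20σ, 0.04 Å from the
omitted atom.

A thin command-line wrapper is installed as `exec/cryodiff` inside the
package (subcommands `simulate`, `stats`, `fofc`, `expand`,
`check-special`, `peaks`, `trim`).

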