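# dectdecomp

Image-domain basis-material decomposition for dual-energy CT (DECT), in R.

Dual-energy CT scans an object with two tube spectra (80 kVp and
140 kVp here).  Because attenuation is material- and energy-dependent,
each pixel of the co-registered reconstructed pair (μ_L, μ_H) can be
written as a mix of two basis materials — soft tissue and bone — with
coefficients (x₁, x₂):

    | μ_H |   | μ̄₁H  μ̄₂H | | x₁ |
    | μ_L | = | μ̄₁L  μ̄₂L | | x₂ |

The classical decomposer inverts this 2×2 system per pixel,

    x₁ = (μ̄₂L μ_H − μ̄₂H μ_L) / Δ,   x₂ = (−μ̄₁L μ_H + μ̄₁H μ_L) / Δ,
    Δ  = μ̄₁H μ̄₂L − μ̄₂H μ̄₁L,

which is exact on model-consistent images but divides by the small
determinant Δ, so it strongly amplifies measurement noise.  The package
implements, end to end and fully seeded:

* **`phantom_forge`**: synthetic 2D phantoms with disjoint tissue/bone
  partitions (`generate_phantom()`, `make_dataset()`), including the
  linear value transform x_t = λ_t x̃_t, x_b = λ_b x̃_b (λ_t = 50,
  λ_b = 15 by default);
* **acquisition physics**: parametric bremsstrahlung spectra
  (`make_spectrum()`), embedded water/cortical-bone attenuation tables,
  parallel-beam forward projection, polyenergetic Beer–Lambert log
  projections with beam hardening, and the Poisson photon-noise model
  p̃ = ln I − ln g(I e^{−p}) with defaults I_L = 5×10⁵, I_H = 1×10⁶
  (`forward_project()`, `polyenergetic_projection()`,
  `add_photon_noise()`);
* **reconstruction**: ramp-filtered backprojection (`fbp()`) and the
  convenience pipeline `simulate_dect()`;
* **decomposers**: direct matrix inversion (`invert_decompose()`), a
  penalized least-squares iterative comparator
  (`iterative_decompose()`), and a learned decomposer: a two-branch
  convolutional network (one branch per energy channel; 5×5 stride-2
  convolutions ×3 then an unpadded 9×9, rectified-linear activations,
  concatenated features, linear head) that maps a 65×65 patch pair to
  the coefficients at the patch center (`fcn_train()`,
  `decompose_image()`), with backprop and the Adam optimizer
  implemented in the package (R + Rcpp/BLAS);
* **evaluation**: ROI bias (mean absolute deviation) and SD
  (`decomp_bias()`, `decomp_sd()`), difference images, and a seeded
  experiment harness comparing all methods with and without photon
  noise (`run_experiment()`).

## Worked example

```r
library(dectdecomp)

ph  <- generate_phantom(128, 128, n_bone = 2, n_tissue = 1, seed = 7)
img <- simulate_dect(ph, noise = default_photon_noise(seed = 7))

basis <- calibrate_basis(ph, img = simulate_dect(ph))
basis
#> <basis2x2> H: (0.3162, 0.7138)  L: (0.4046, 1.144)  delta = 0.07306

sc <- score_decomposition(invert_decompose(img, basis), ph)
as.data.frame(sc)
#>   material       bias         sd    n
#> 1   tissue 0.06974963 0.08754964 3218
#> 2     bone 0.04696696 0.22779161  142
```

The basis entries are effective attenuations (1/cm per unit material
coefficient) under the 80/140 kVp spectra; Δ ≈ 0.073 is the determinant
the inversion divides by.  `bias` is the mean absolute deviation of the
decomposed coefficients from the ground truth inside each (eroded)
material partition, and `sd` their dispersion about the ROI mean — both
in coefficient units, where 1 ≈ pure soft tissue / compact bone.  Under
photon noise the inversion's tissue bias here is about 2.6× its
noiseless value of 0.027 (re-run with `noise = NULL` to see); the large
bone SD comes from reconstruction ringing on this phantom's few-pixel
rib inserts, which the eroded ROI cannot fully avoid.

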