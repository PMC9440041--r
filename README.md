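# spfcontour

Self-initialized active-contour segmentation of single-channel grayscale
images under intensity inhomogeneity — an R implementation of a hybrid
local–global region-based level-set model with signed-pressure-force (SPF)
regularization and automatic contour initialization, exercised end-to-end
on synthetic phantoms with known ground truth.

## The problem and the model

Microscopy and medical images are frequently corrupted by a slowly varying
multiplicative **bias field**: one object's intensities drift across the
image, so neither a global threshold nor a purely global region model
(Chan–Vese style) can separate object from background. The package models
an observed image as

```
I(x) = b(x) J(x) + n(x)
```

where `J` is a piecewise-constant true image, `b` a smooth positive bias
field and `n` additive noise. A level-set field `φ` partitions the domain
(inside ⇔ `φ > 0`); smoothed region indicators come from the regularized
Heaviside `H_ε(φ) = ½(1 + (2/π) arctan(φ/ε))` and its derivative
`δ_ε(φ) = ε / (π(φ² + ε²))`.

Two data models are fitted at each iteration:

* **global fit** — inside/outside means `c1, c2`, giving the global fitted
  image `I_GFI = c1·M1 + c2·M2`;
* **bias-corrected local fit** — a bias field
  `b = K_σ∗(I(m1M1 + m2M2)) / K_σ∗(m1²M1 + m2²M2)` and local means
  `m1, m2`, giving `I_bLFI = b·(m1M1 + m2M2)`,

with `M1 = H_ε(φ)`, `M2 = 1 − M1` and `K_σ` a Gaussian window. The
**signed pressure force** `spf = (I − I_GFI) / max|I − I_GFI| ∈ [−1, 1]`
drives SPF-weighted length and area terms. The contour evolves by

```
∂φ/∂t = δ_ε(φ)(I − I_bLFI)(c1 − c2) + δ_ε(φ)(I − I_GFI)(m1 − m2)
      + μ div(spf · ∇φ/|∇φ|) δ_ε(φ) + ν spf δ_ε(φ)
```

until the binary mask stops changing. Initial contours are found
automatically: a **circular projection** operator scores, at every pixel,
how strongly the image's gradient field converges toward (or diverges
from) a window center; the strongest responses mark object interiors and
are dilated into seed regions.

Evaluation uses pixel accuracy, Dice, Jaccard (= JSI) and the boundary-F1
contour matching score.

## Worked example

```r
library(spfcontour)

# a 128x128 disk phantom under a strong left-to-right bias ramp
ph  <- generate_phantom(phantom_spec("disk", bias = "linear_ramp",
                                     bias_amplitude = 0.5))
res <- segment_image(ph$image)   # fully automatic: no seed given
res
#> spf_segmentation: 128 x 128 | foreground 3286 px | iterations 58 | converged TRUE

unlist(metrics_report(res$mask, ph$truth_mask))
#>  accuracy      dice   jaccard  bf_score
#> 0.9964600 0.9910961 0.9823494 1.0000000

cor(as.vector(res$bias_final), as.vector(ph$truth_bias))
#> [1] 0.9082094
```

Despite the foreground on the dim side being darker than the background on
the bright side, the recovered mask overlaps the truth at Dice 0.991 and
the estimated bias field tracks the ramp.

### Command line

```sh
spfcontour phantom --shape disk --bias linear_ramp --amplitude 0.5 \
    --seed 7 --output-dir ph/
spfcontour segment --input ph/image.png --output-dir seg/ \
    --eval-against ph/truth_mask.png --save-bias
spfcontour evaluate --mask seg/mask.png --truth ph/truth_mask.png
```

(the `spfcontour` script is installed under the package's `exec/`
directory; `Rscript -e 'spfcontour::run_cli(...)'` is equivalent.)

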