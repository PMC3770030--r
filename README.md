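# pancseg

Semi-automatic extraction of a soft-tissue organ — typically the pancreas —
from a single 2-D CT slice, for the common and difficult case where the organ
touches a neighbor of nearly identical intensity across a weak, partially
fractured boundary. Plain edge- or region-driven contours leak through such
boundaries; `pancseg` implements a hybrid level-set pipeline built to stop
exactly that leakage, plus the standard overlap metrics and a synthetic
two-organ phantom so the whole method can be exercised and tested without
clinical data.

The intended users are medical-image-analysis researchers and developers who
need a scriptable, fully deterministic reference implementation of this
family of methods.

## Method

Given a denoised slice *I* (modified-curvature-diffusion, an anisotropic
filter whose flux acts only along level lines), its Gaussian-derivative
gradient magnitude *g<sub>m</sub>* feeds two per-pixel feature maps:

* a **speed map** for front propagation,
  *I(x, y) = (Max − Min) / (1 + e^−((g_m − β)/α)) + Min* with α = −0.5,
  β = 3 — near 1 in homogeneous tissue, near 0 at edges;
* an **edge indicator** *g = 1 / (1 + g<sub>m</sub>²)* for the level-set
  stage.

The pipeline then runs in two stages:

1. **Multi-seed fast marching.** The eikonal equation |∇T|·E = 1 is solved
   from operator-placed seeds by a first-order Godunov upwind scheme with a
   binary heap. When the operator has drawn a **standard line** separating
   the organ from its neighbor, an **energy-decrement** rule first floors the
   speed to its map minimum within 1.5 px of the line, so the front cannot
   cross it anywhere. Thresholding the arrival time (*T ≤ t\**) yields the
   initial organ region R₀.
2. **Modified distance-regularized level-set evolution (DRLSE).** R₀
   initializes a binary-step level-set function φ₀ = ∓c (c = 2), evolved by
   ∂φ/∂t = μ div(d_p(|∇φ|)∇φ) + λ δ_ε(φ) div(E_t ∇φ/|∇φ|) + α E_t δ_ε(φ)
   with μ = 0.2, λ = 5, ε = 1.5, a double-well potential p(s) keeping φ a
   signed distance near the contour without reinitialization, and a
   two-phase schedule: 40 steps with expansion (α = −1), then 15 refinement
   steps without the area term (α = 0). The map E_t is the edge indicator
   re-weighted by an **energy-tune** rule: treating R₀ as an energy source
   radiating E(i,j) = Σ exp(−D/σ)·g over its pixels, edge energy is enhanced
   inside R₀ and decayed in the coupling area near the standard line (or,
   without a line, beyond a distance threshold from R₀) — this is what stops
   the contour from leaking through a fractured boundary.

The final mask is {φ < 0} after morphological opening/closing, hole filling
and small-component removal. Evaluation uses FPE (false-positive error,
extracted pixels outside the reference, normalized by reference size; may
exceed 1), FNE (missed reference fraction) and SI (Dice similarity).

## Worked example

```r
library(pancseg)

# a 256x256 phantom: two adjacent organs (means 120 / 110 on background 40,
# noise sd 5) whose shared boundary is fractured along 30% of its length
ph <- generate_phantom(phantom_spec())

res <- segment_slice(ph$image, ph$seeds, ph$line)
compute_metrics(res$mask, ph$truth)[, c("fpe", "fne", "si")]
#>   fpe        fne        si
#> 1   0 0.04643425 0.97623103

# without the standard line and with the energy tune disabled, the contour
# leaks through the fractured boundary into the neighbor organ:
leak <- segment_slice(ph$image, ph$seeds, NULL,
                      pipeline_config(fm.t_star = 60), energy_tune = FALSE)
compute_metrics(leak$mask, ph$truth)[, c("fpe", "fne", "si")]
#>         fpe        fne         si
#> 1 0.4153045 0.06176768 0.79729564
```

An SI of 0.976 means near-perfect recovery of the target organ; the second
run shows the failure mode the method exists to prevent — FPE 0.42 means
42% of the organ's area was spuriously annexed from its neighbor.

A thin command-line wrapper ships in `inst/cli/pancseg`
(`segment`, `phantom`, `evaluate` subcommands; PNG/NIfTI/CSV images in,
PNG masks and JSON/CSV metrics out).

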