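# adaptivetrack

Contour-based object tracking for 2D and 3D image sequences on adaptive
Quadtree/Octree grids.

## The problem

Tracking a deforming object through an image sequence — a vessel
cross-section through a slice stack, a beating-heart chamber through a 3D
time series — can be posed as *simultaneous registration and segmentation*:
for every frame, jointly estimate

* a dense displacement field **u** between consecutive frames,
* a sparse corruption field *G* absorbing occlusions, shading and
  illumination changes, and
* a relaxed segmentation indicator φ⁰ ∈ [0, 1] whose ½-level set is the
  object contour,

by minimizing, per frame,

```
E(u, G)  = ∫ ρ(|I(x+u, t) − I(x, t−1) − G|²) + α_u ρ(|∇u|²+|∇v|²)
           + α_g1 ρ(|G|²) + α_g2 ρ(|∇G|²) dx ,     ρ(s²) = √(s² + ε²)
E(φ⁰)    = TV_w(φ⁰) + α_s1 ∫ η(x) φ⁰ dx ,          w = g + dp² + dc²
```

where η = ln p(I|θ₂) − ln p(I|θ₁) is the background/foreground
log-likelihood ratio, g = 1/(1 + γ|∇I_σ|²) the edge-stopping function, and
dp², dc² squared-distance weights built from the previous frame's shape
(warped through the current flow) that register the shape isocontours
across frames. The shape itself is carried as a signed-distance level-set
function, so topology changes (merging vessels, splitting blobs) come for
free.

All of this is expensive on a uniform pixel grid, yet the information that
matters lives in a narrow band around the moving front. Every field here
therefore lives on an adaptive Quadtree (2D) / Octree (3D): cells are
Whitney-refined so the finest cells straddle the zero level set and coarsen
geometrically away from it (typically 5–15 % of the uniform cell count).
Derivatives at hanging nodes use third-order ghost-node interpolation, so
the finite-difference stencils are exact on quadratics everywhere, and the
level set is advected semi-Lagrangianly and reinitialized with a
Godunov/minmod scheme on the same tree.

## Worked example

Track the classic two-disk vortex benchmark: two textured disks
(radii 0.15 and 0.1 on the unit square, interior intensities 200–255,
exterior 50–155) deformed by the divergence-free field
u = −sin²(πx) sin(2πy), v = sin²(πy) sin(2πx).

```r
library(adaptivetrack)

spec <- vortex_spec(n_frames = 10, size = 100, dt = 0.002, seed = 1)
seq  <- make_vortex_sequence(spec)       # frames + RK4-traced truth masks

out <- track_sequence(seq$frames, seq$masks[[1]], run_config(),
                      truth = seq$masks)
head(out$diagnostics, 4)
#>   frame leaf_count registration_energy segmentation_energy      dice
#> 1     1       1330                  NA                  NA 1.0000000
#> 2     2       1357            26.81636           -403.6365 0.9970646
#> 3     3       1390            27.78760           -421.4442 0.9975526
#> 4     4       1390            27.45948           -426.6827 0.9965737
```

Each tracked frame reports the number of tree leaves actually processed
(~1350 of the 10,000 uniform cells), the registration and segmentation
energies, and — because ground truth is available here — the Dice overlap
with the analytic mask (≥ 0.99 throughout this run).

The same engine is scriptable from the shell:

```sh
./exec/adaptivetrack synth   --frames 10 --size 100 --seed 0 --out data/
./exec/adaptivetrack track2d --frames data/frames \
                             --mask data/truth/mask_0001.png --out run/
./exec/adaptivetrack eval    --pred run --truth data/truth
```

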