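# stereoloc

Geometry and noise-propagation analysis of stereotactic fiducial
localizers.

Image-guided stereotactic neurosurgery (deep brain stimulation, functional
neurosurgery, radiosurgery) relies on a fiducial localizer attached to the
stereotactic frame to map the two-dimensional (u, v) coordinates of a CT or
MRI slice into the three-dimensional (x, y, z) frame coordinate system.
`stereoloc` models the z-reconstruction of two such devices and quantifies,
by seeded Monte Carlo simulation, how image noise in the detected fiducial
centers propagates into the reconstructed section height. It is intended
for medical physicists and engineers evaluating localizer designs.

## The two reconstructions

**N-localizer** — two vertical rods (A, C) and one diagonal rod (B) form an
"N". The section height where the diagonal crosses the slice follows by
linear interpolation,

    z = z_C + (d_BC / d_AC) (z_A − z_C),

where d_BC and d_AC are inter-fiducial distances measured in the image.
The ratio is dimensionless, so the result never depends on the image pixel
size.

**Sturm-Pastyr localizer** — two diagonal rods (A, C) meet a vertical rod
(B) at the apex of a "V", with rod angle υ = arctan(1/2). The height is
recovered non-linearly from the two distances,

    z = 4 d_AB d_BC / sqrt((d_BC + d_AB)² + 4 (d_BC − d_AB)²),

which is homogeneous of degree one in the distances: the pixel size enters
the result, and a mis-calibrated pixel size propagates directly into z.
For a section parallel to the frame base this reduces to
z = d_AB + d_BC = 2 d_AB.

**Forward models** place the fiducials for a section at height z tilted by
β degrees: the N-localizer fiducials sit at C = (0,0), B = (z/cos β, 0),
A = (140/cos β, 0) (140 mm rod spacing and height by default), and the
Sturm-Pastyr distances are d_AB = z sin υ / sin(π/2 + β − υ),
d_BC = z sin υ / sin(π/2 − β − υ), the latter diverging at
β = 90° − υ = 63.435°.

**Monte Carlo engine** — for each cell (localizer, z, β, ε) the six
fiducial coordinates are perturbed by i.i.d. uniform noise on [−ε, +ε] mm
(ε = 1 mm ≈ a two-pixel detection error at typical stereotactic imaging
resolution), distances are recomputed, z is reconstructed, and the RMS and
maximum absolute errors over n draws (default n = 2²⁵) are accumulated in
blocks with compensated summation. Per-cell seeds derive deterministically
from a master seed and the cell parameters, so sweeps are reproducible
cell-by-cell and block-size invariant.

## Worked example

```r
library(stereoloc)

# forward distances for a section at z = 20 mm tilted 5 degrees,
# then the exact round trip back to z
d <- sp_forward_distances(z = 20, beta = 5)
unlist(d)
#>      d_ab      d_bc
#>  9.617488 10.497400
sturm_pastyr_z(d$d_ab, d$d_bc)
#> [1] 20

# noise propagation at that pose, 1 mm uniform noise
simulate_cell("n",  z = 20, beta = 5, epsilon = 1, n = 2^20, seed = 1)
#> N localizer, z = 20 mm, beta = 5 deg, epsilon = 1 mm (n = 1,048,576, seed 1)
#>   RMS error 0.761768 mm, max error 2.02486 mm
simulate_cell("sp", z = 20, beta = 5, epsilon = 1, n = 2^20, seed = 1)
#> SturmPastyr localizer, z = 20 mm, beta = 5 deg, epsilon = 1 mm (n = 1,048,576, seed 1)
#>   RMS error 0.977653 mm, max error 3.1244 mm

# error scaling with noise amplitude for the N-localizer
tab <- sweep_error_vs_epsilon(z = 20, beta = 5, n = 2^20, seed = 1,
                              localizers = list("n"))
linear_fit(tab$epsilon_mm, tab$rms_mm)
#> linear fit: slope 0.759583, intercept 0.00175939, Pearson r 0.999999
```

The N-localizer's RMS error at this pose is ~0.76 mm per mm of noise
half-width and scales linearly (first-order propagation predicts 0.762);
the Sturm-Pastyr error is ~28% larger at the same pose and grows
super-linearly, because its fiducial distances shrink toward the apex of
the V and its reconstruction is non-linear in them.

## Command line

A thin wrapper script is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "stereoloc", package = "stereoloc"))')
Rscript "$CLI" zcalc --localizer sp --dab 10 --dbc 10
# 20
Rscript "$CLI" sweep-beta --localizer sp --z 20 --epsilon 1 \
  --n 1048576 --seed 1 --out sweep.csv
```

Subcommands: `zcalc`, `forward`, `simulate`, `sweep-z`, `sweep-beta`,
`sweep-epsilon`, `fit`; see `--help`. Identical arguments and seed give
byte-identical output.

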