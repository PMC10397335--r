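# pivalign

Ground-truth validation of particle image velocimetry (PIV) for collectively
moving, self-propelled particles.

PIV is the workhorse for quantifying collective cell migration when
individual cells cannot be tracked: it divides each image into interrogation
grids and reports, per grid, the displacement that maximizes the normalized
cross-correlation with the next frame. That vector is an aggregate. Whether
it represents the motion of the *individual* agents around it — especially
when the agents move like coupled stochastic particles rather than a viscous
flow — is exactly what this package measures, for people who use PIV on
cell-migration imagery and need to know which grid sizes and evaluation
radii to trust.

The pipeline is fully synthetic and end-to-end:

1. **Simulate** a Vicsek model: `N` agents at constant speed `v0` in a
   periodic box of side `L`; each step every agent adopts the circular mean
   heading `atan2(Σ sin θ_j, Σ cos θ_j)` of its neighbors within radius `r`
   (self included) plus uniform noise in `[-η₀/2, η₀/2]`.
2. **Render** each state as an 8-bit image: black 8×6-px ovals, oriented
   along the headings, on a white background (615-px images by default).
3. **PIV** the image pairs: 64-px grids, 96-px search zones, normalized
   cross-correlation, optional Gaussian subpixel peak fit and
   normalized-median vector validation.
4. **Score** the field against the hidden trajectories with the alignment
   score

   A^R = (1/M) Σ_j (1/N_j^R) Σ_{i: |x_j − x_i| ≤ R} cos∠(v_j, w_i),

   the mean cosine between each PIV vector `v_j` and the velocities `w_i` of
   agents within radius `R` of its anchor, plus the global/local order
   parameters `v_a`, `v_a^R` and the coherence difference
   `D^R = |v_a^{R,SPP} − v_a^{R,PIV}|`.

Two analytic scales organize the results: `γ₀(N) = Γ/√N`, the grid side
containing one agent on average in a `Γ×Γ` image, and `R₀(N) = γ₀/√π`, the
analogous circle radius. At high noise, PIV tracks individual motion
precisely when grid and radius sit near these scales.

## Worked example

```r
library(pivalign)

p <- vicsek_params()        # L = 5 units (615 px), N = 300, v0 = 0.03 (3.7 px/frame),
                            # r = 0.5 units (61.5 px), eta0 = pi/6 (low noise)
traj <- simulate_vicsek(p, steps = 300, seed = 1)
order_parameter(traj$states[[301]])
#> [1] 0.9867784               # strongly ordered after 300 steps at low noise

f0 <- render_frame(traj$states[[300]], p)
f1 <- render_frame(traj$states[[301]], p)
fld <- piv_field(f0, f1)    # 64-px grids, gaussian3 subpixel, median validation
fld
#> PIV field: 10 x 10 grids of 64 px (t = 299), 60/100 valid vectors
#>   mean |v| = 3.62 px, mean peak corr = 0.897

st <- traj$states[[300]]
alignment_score(fld, st, p, R_px = 30)
#> [1] 0.991403                # PIV vectors nearly parallel to nearby agents
coherence_difference(st, fld, p, R_px = 30)
#> [1] 0.007271747
```

The 40 missing vectors are real: at low noise the agents condense into
traveling clusters, leaving grids with no particle at `t` or `t+1`, and such
grids produce no vector (they are never counted as zeros). The mean vector
magnitude of 3.62 px recovers the true 3.7 px/frame displacement to within
a few percent; `A^R ≈ 0.99` says the directions agree almost perfectly at
`R = 30` px.

Characteristic scales:

```r
c(gamma0(100, 615), r0(100, 615), gamma0(300, 615), r0(300, 615))
#> [1] 61.50000 34.69766 35.50704 20.03270
```

And the order–disorder transition, from a 5-trial sweep of 7 noise levels
(stationary `v_a` averaged over t ∈ [200, 300]):

```r
cfg <- experiment_config(noise_levels = seq(pi/2, 3*pi/2, length.out = 7),
                         trials = 5, steps = 300, stationary = c(200, 300),
                         seed = 1)
find_transition(cfg)
#> Order-disorder transition estimate: eta_c = 3.014 rad (0.959 pi)
```

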