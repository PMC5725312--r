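# anatomeg

Estimating cortical anatomy from MEG sensor data.

MEG source analysis normally takes brain structure as given (from MRI)
and estimates function. `anatomeg` inverts the question: over a family
of candidate cortical surfaces, it asks which anatomy makes the measured
sensor data most probable. It is aimed at MEG/EEG methods researchers
who want to score anatomical models by Bayesian model evidence, and at
anyone needing a fully synthetic, self-contained test bed for
evidence-based source inversion.

## The model

A brain is two hemisphere meshes deformed from one shared unit sphere,
encoded as a weighted Fourier (real spherical-harmonic) series per
hemisphere and coordinate axis — `6(c+1)^2` coefficients at degree `c`
(2646 at the default `c = 20`). For each harmonic order `j` the library
coefficient block `G ∈ R^{Nb×6(2j−1)}` is mean-corrected,
`Ĝ = G − Ḡ`, and its leading right singular vector `u₁` of `ĜᵀĜ`
gives the axis of normal shape variation; candidate brains are
`X = δ·s·u₁ + Ḡ` with `s` the between-subject SD along the mode,
stepped over a 2-D grid for two orders (defaults 6 and 9).

For sensor data `Y ∈ R^{Nc×Nt}` and candidate lead field `L_a`
(single-sphere Sarvas forward model, dipoles normal to the surface), the
generative model is `Y = L_a J + ε` with the Empirical Bayes Beamformer
source prior `Q = diag(1/(l_iᵀ C⁻¹ l_i))` (unit trace), sensor
covariance `Σ_a = e^{λ₁} I + e^{λ₂} L_a Q L_aᵀ`, and log-hyperparameters
optimised by ReML. Each candidate's score is the negative variational
free energy

    F_a = −Nt/2·tr(Σ_Y Σ_a⁻¹) − Nt/2·log|Σ_a| − Nt·Nc/2·log 2π
          − ½(λ̂−υ)ᵀΠ(λ̂−υ) + ½ log|Σ_λ Π|  ≈  log p(Y | a)

and the posterior over anatomy is `p(a|Y) ∝ exp(F_a)` under a uniform
model prior, summarised by its peak and 95% credible region.

## Worked example

```r
library(anatomeg)

lib  <- generate_library(Nb = 27, degree = 20, seed = 1)  # synthetic library
grid <- build_grid(lib, orders = c(6, 9))                 # coarse 5 x 5 grid
sens <- default_sensor_array(100)                         # radial helmet
lfs  <- grid_leadfields(grid, sens)

truth <- grid$surfaces[[3, 3]]        # simulate on the grid-origin brain
ds <- simulate_dataset(truth, sens,
                       sim_config(n_sources = 2, correlated = FALSE,
                                  snr_db = 0, seed = 42),
                       leadfield = lfs[[3, 3]])

map <- score_grid(ds$Y, grid, sens, leadfields = lfs)
print(map)
#> anatomy_score_map: 5 x 5 cells, F in [-1404.95, -1248.81]
#>   peak at delta = (0, 0)

p <- model_posterior(map)
credible_region(p, 0.95)
#>   ia ib         p
#> 1  3  3 0.9998567

cmp <- compare_to_truth(map, truth)
sprintf("distance at peak: %.2f mm (grid range %.2f-%.2f mm)",
        cmp$distance_at_peak, min(cmp$distance), max(cmp$distance))
#> "distance at peak: 0.00 mm (grid range 0.00-1.92 mm)"
```

The free-energy peak lands on the generating anatomy: the origin cell
carries essentially all posterior mass, and its surface is 0 mm from the
truth while the worst candidates are ~2 mm away. With *correlated*
source pairs — violating the beamformer prior — the peak wanders, which
is the package's core demonstration that anatomical accuracy is
contingent on congruent functional priors.

A YAML-driven pipeline and CLI wrap the same steps
(`run_pipeline("config.yaml")`; `inst/cli/anatomeg run --config
config.yaml`), with a toy configuration in
`inst/extdata/default_config.yaml`.

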