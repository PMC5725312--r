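---
title: "Estimating cortical anatomy from MEG data: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cortical anatomy from MEG data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(anatomeg)
```

## The problem

MEG source reconstruction is usually conditioned on anatomy: a cortical
mesh from structural MRI fixes where current can flow, and functional
priors select among the many current distributions that explain the
sensor data. `anatomeg` turns the question around: given MEG sensor data
and a *family* of candidate cortical surfaces, which anatomy makes the
data most probable? The Bayesian machinery is the same as in
evidence-based comparison of source models — each candidate surface `a`
defines a gain (lead-field) matrix `L_a`, each inversion returns a
negative variational free energy `F_a` approximating `log p(Y | a)`, and
a softmax over `F_a` gives a posterior over anatomy.

## The shape space

Each brain is two hemisphere meshes obtained by deforming one shared
unit sphere, so every surface in a library is indexed by the same
vertices. A surface is encoded by a weighted Fourier series: per
hemisphere and per coordinate axis, the coordinate function on the
sphere is expanded in real spherical harmonics up to degree `c`
(`(c+1)^2` coefficients per axis per hemisphere, `6(c+1)^2` in total;
2646 at the default `c = 20`). The heat-kernel weight
`exp(-l(l+1)*sigma)` is applied at reconstruction; fitting minimises the
reconstruction error, so `sigma = 0` gives plain least squares and exact
round trips on band-limited surfaces. `sigma` is not identified by any
quantity we reproduce, so the synthetic library uses `sigma = 0` and the
fitting default is a conventional mild `1e-4`.

Harmonic *order* `j` refers to the block of coefficients at
spherical-harmonic degree `l = j - 1`, which has `6(2j - 1)` entries per
subject — order 1 is the hemisphere centres, order 2 the best-fitting
ellipsoids. This off-by-one convention is the only one under which the
block sizes, the "mean location" and "ellipsoid" interpretations, and
the degree-wise coefficient counts are simultaneously consistent; the
alternative (`l = j`) remains available via `convention = "degree"`.

Within one order, the library's coefficient block `G` (subjects x
coefficients) is mean-corrected and its first right singular direction
`u1` taken as the axis of normal shape variation; stepping
`X = delta * s * u1 + Gbar` with all other orders held at the library
mean defines one grid axis, and two orders (defaults 6 and 9) span a 2-D
family of candidate brains whose origin cell is exactly the mean brain.
The step unit `s` is the between-subject standard deviation along `u1`
(`sqrt(S11 / (Nb - 1))`); `step_mode = "literal"` instead uses the raw
eigenvalue `S11`, which appears in the printed form of the deformation
equation but is a squared quantity and makes grids incomparable across
libraries.

## Forward model

The single-sphere (Sarvas) conductor is used throughout: closed form,
and its only anatomical input is the sphere centre, which removes any
possibility that the forward model leaks shape information beyond
source positions and orientations. The centre is fitted once to the
origin-cell surface and shared by all candidates (fitting per candidate
was tested and changes nothing measurably). Sources are point dipoles at
mesh vertices, oriented along the outward surface normal; radial dipoles
are silent, which the tests use as a built-in oracle, together with the
identity that the radial field component equals that of the primary
current alone and a finite-difference check against the magnetic scalar
potential. The synthetic helmet is 274 (or `n`) radial point
magnetometers quasi-uniformly covering the upper hemisphere of a 12 cm
sphere; gradiometers are not modelled.

## Inversion and scoring

The sensor-level model covariance is
`Sigma_a = exp(lambda_1) I + exp(lambda_2) L Q L'`, with `Q` the
Empirical Bayes Beamformer prior: per-vertex variance
`1 / (l_i' C^-1 l_i)` from the (regularised) data covariance `C`,
normalised to unit trace — the empirical prior that is exact when
sources are uncorrelated. Log-hyperparameters are optimised by
Fisher-scoring ReML with Gaussian hyperpriors (mean -32, precision
1e-10: effectively flat with a floor), with step-halving against the
five-term free energy so the `F` sequence is non-decreasing; convergence
is `dF < 1e-2` nat or 128 iterations, deterministic given the data. The
data and each cell's prior component are internally rescaled to unit
mean eigenvalue, so reported hyperparameters live on that scale; scale
changes of `Y` or `L` shift `F` by a constant common to all cells and
never move the peak.

Before scoring, the data are projected onto their dominant temporal SVD
modes (default 16). This mirrors standard practice in evoked-response
source inversion and matters greatly here: the beamformer prior is
estimated from the data, and at 0 dB the raw-covariance prior is too
noisy to discriminate candidate anatomies (an oracle-prior control
recovers the generating cell in 10/10 runs where the raw-data EBB prior
manages 6/10; after projection the EBB prior also reaches 10/10). The
projection is identical for every cell, so free energies remain
comparable across the grid.

The posterior over cells is computed in log space with max subtraction;
failed cells are excluded and the rest renormalised, never imputed. The
95% credible region is the smallest set of cells reaching 0.95 mass,
ties broken by grid index.

## What the synthetic world emulates — and what it does not

`generate_library()` builds a template brain (two offset ellipsoids,
fixed pseudo-sulcal components at degrees 3..c with `1/l^2` amplitude
decay, base 20 mm) and perturbs every coefficient per subject. The
between-subject SD is 0.15 x the template amplitude at the
position/size degrees (`l <= 2`) but 2.5 x at the folding degrees
(`l >= 3`). The folding figure deserves justification: cortical folding
patterns at mid harmonic degrees are largely idiosyncratic, so their
between-subject variation is comparable to or larger than their mean
amplitude — this is why average brains are famously smooth. It is also
the only regime consistent with the behaviour this method is known to
show on real libraries: visibly distorted ("caricature") brains at two
standard deviations of normal variation, and an index-matched distance
range of a few millimetres across the deformation grid. A uniform 0.15
relative SD concentrates essentially all shape variance in position and
size, produces grid steps of ~0.1 mm, and makes anatomy discrimination
from MEG impossible in principle at any SNR.

Simulated datasets are single evoked windows (420 samples at 600 Hz,
sources band-limited to 0-48 Hz), two point sources at random vertices
at least 40 mm apart, with white sensor noise scaled so the Frobenius
SNR is met exactly; paired correlated/uncorrelated datasets share
vertices, SNR and the noise realisation. Not emulated: realistic brain
noise spectra and artefacts, trial structure, gradiometer geometry,
patch (extended) sources, and real cortical geometry at degrees above
20. A green recovery test therefore establishes internal consistency of
the machinery under congruent priors, not performance on empirical
recordings.

## Numerical choices

* WFS fitting uses pivoted QR with a condition-number warning above 1e8.
* The data covariance gets a relative ridge `1e-8 tr(C)/Nc` when rank
  deficient (always the case after temporal projection of short
  windows).
* Vertices within 1 mm of the sensor sphere are shrunk radially by 1 mm
  with a warning; vertices outside it are an error.
* Eigenvector signs are fixed (largest-magnitude entry positive) so SVD
  reductions are reproducible across platforms.
* Mesh validity for synthetic brains is a star-shapedness check per
  hemisphere — cheap and sufficient for surfaces built as perturbed
  ellipsoids; it is not a general self-intersection test.

## Known limitations

* Only two harmonic orders are searched, as a proof of principle; the
  posterior is over a 2-D slice of shape space, not over anatomy at
  large.
* The index-matched distance is topology-bound: it requires the shared
  sphere parameterisation and is sensitive to folding differences;
  nearest-neighbour and Hausdorff metrics are provided for
  cross-topology comparisons.
* On a self-consistent grid (truth = origin cell) the distance map is
  exactly symmetric about the origin while the physics is not, so the
  rank correlation between free energy and distance saturates around
  -0.5 even at high SNR; with an off-grid truth this ceiling does not
  apply. The free-energy peak, not the global monotonicity, is the
  quantity this package relies on.

## Reproducing the headline numbers

The acceptance report regenerates everything from scratch:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It simulates 60 correlated/uncorrelated source pairs at 0 dB on the
grid-origin brain, scores each dataset over the coarse 5 x 5 grid, and
reports the percentage of pairs in which the uncorrelated
(prior-congruent) condition failed to improve the anatomical error.
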