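Package: anatomeg
Title: Estimating Cortical Anatomy from MEG Sensor Data
Version: 0.1.0
Authors@R: person("anatomeg", "developers", role = c("aut", "cre"),
    email = "anatomeg@example.org")
Description: Tools to estimate cortical anatomy from magnetoencephalography
    (MEG) sensor data. Cortical surfaces are parameterised by weighted
    Fourier (spherical-harmonic) series over a shared unit-sphere topology;
    a library of brains is reduced per harmonic order by SVD to principal
    shape eigenmodes; stepping two eigenmodes yields a two-dimensional grid
    of candidate deformed brains. Each candidate is scored by inverting the
    MEG data with Empirical Bayes Beamformer priors under a single-sphere
    forward model, using the negative variational free energy as an
    approximation to the log model evidence. The package includes mesh
    distance metrics, a posterior over anatomy with credible regions, and a
    fully synthetic MEG simulation harness (brain library, source time
    courses, sensor arrays, controlled SNR) for validation without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
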