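# Synthetic validation harness: brain library, source time courses,
# sensor data at controlled SNR, and noise-only controls. Everything is
# generated in code; no external data are needed.

# Deterministic sub-seed so that paired datasets can share some random
# streams (vertices, noise) while varying others (time courses).
derive_seed <- function(seed, tag) {
  s <- (abs(as.numeric(seed)) * 48271 + as.numeric(tag) * 997) %% 2147483629
  as.integer(s) + 1L
}

#' Generate a synthetic library of WFS-parameterised brains
#'
#' The template brain is a pair of offset hemisphere ellipsoids (degrees
#' 0-1: centres at x = -/+ 33 mm, semi-axes 32 x 72 x 52 mm) plus fixed
#' pseudo-sulcal harmonic components at degrees 3..`degree` whose
#' per-coefficient amplitude decays as `1 / l^2`. Each subject perturbs
#' every coefficient with Gaussian noise whose standard deviation is a
#' multiple of the template RMS amplitude at that degree: `position_sd`
#' (default 0.15) at the positional/size degrees `l <= 2`, and
#' `folding_sd` (default 2.5) at the folding degrees `l >= 3` — folding
#' patterns vary across subjects by more than their mean amplitude, which
#' is also why an average brain is smoother than any individual. The
#' folding default is calibrated so that stepping a principal shape mode
#' by one between-subject standard deviation displaces the surface by
#' roughly a millimetre of mean vertex distance, giving a coarse `-2..2`
#' deformation grid a distance range of a few millimetres. The same seed
#' always reproduces the same library.
#'
#' @param Nb number of subjects (default 27).
#' @param degree harmonic degree `c` (default 20).
#' @param seed RNG seed.
#' @param param shared [sphere_param] (default 642-vertex icosphere per
#'   hemisphere).
#' @param position_sd relative between-subject SD at degrees `l <= 2`.
#' @param folding_sd relative between-subject SD at degrees `l >= 3`.
#' @param sulcal_amplitude base amplitude (mm) of the `1/l^2` decay
#'   (default 20; chosen so the mean library brain passes the star-shape
#'   validity check with margin at the default mesh resolution).
#' @return a [brain_library].
#' @export
generate_library <- function(Nb = 27, degree = 20, seed = 1,
                             param = icosphere_param(3), position_sd = 0.15,
                             folding_sd = 2.5, sulcal_amplitude = 20) {
  if (Nb < 2) stop("Nb >= 2 required", call. = FALSE)
  degree <- as.integer(degree)
  k <- (degree + 1L)^2
  template <- array(0, c(2, 3, k), dimnames = list(c("L", "R"), c("x", "y", "z"), NULL))
  a1 <- sqrt(4 * pi / 3)                 # coordinate <-> degree-1 coefficient
  ctr <- c(-33, 33)                      # hemisphere centres on the x axis, mm
  semi <- c(32, 72, 52)                  # hemisphere semi-axes, mm
  for (h in 1:2) {
    template[h, 1, lm_index(0L, 0L)] <- ctr[h] * 2 * sqrt(pi)
    template[h, 1, lm_index(1L, 1L)] <- semi[1] * a1
    template[h, 2, lm_index(1L, -1L)] <- semi[2] * a1
    template[h, 3, lm_index(1L, 0L)] <- semi[3] * a1
  }
  set.seed(derive_seed(seed, 11))
  if (degree >= 3) {
    for (l in 3:degree) {
      cols <- lm_index(l, -l:l)
      template[, , cols] <- stats::rnorm(2 * 3 * length(cols),
                                         sd = sulcal_amplitude / l^2)
    }
  }
  l_of <- degree_of_column(degree)
  t_amp <- vapply(0:degree, function(l) {
    sqrt(mean(template[, , l_of == l, drop = FALSE]^2))
  }, numeric(1))
  rel_sd <- ifelse(0:degree <= 2, position_sd, folding_sd)
  sd_col <- (rel_sd * t_amp)[l_of + 1L]
  set.seed(derive_seed(seed, 13))
  coeffs <- lapply(seq_len(Nb), function(i) {
    noise <- array(stats::rnorm(length(template)), dim(template))
    noise <- sweep(noise, 3, sd_col, `*`)
    wfs_coefficients(template + noise, degree, sigma = 0)
  })
  brain_library(coeffs, param)
}

#' Simulation configuration
#'
#' @param n_sources 1 or 2.
#' @param correlated logical; with two sources, `TRUE` puts the identical
#'   waveform on both (maximally correlated), `FALSE` uses independent
#'   waveforms orthogonalised to sample correlation below 0.01.
#' @param snr_db signal-to-noise ratio in dB, defined on Frobenius power
#'   of the noiseless sensor signal versus the noise.
#' @param Nt,fs samples and sampling rate (defaults 420 at 600 Hz, a
#'   700 ms evoked window).
#' @param band passband of the source processes, Hz (default `c(0, 48)`).
#' @param seed RNG seed; identical config + seed gives identical data.
#' @param vertices optional explicit source vertex indices; otherwise
#'   sampled at random with minimum separation `min_separation` mm.
#' @param min_separation minimum source separation, mm (default 40).
#' @param amplitude dipole moment scale, A*m (default 10 nA*m; arbitrary,
#'   since SNR is the controlled quantity).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_sources = 2, correlated = FALSE, snr_db = 0,
                       Nt = 420, fs = 600, band = c(0, 48), seed = 1,
                       vertices = NULL, min_separation = 40,
                       amplitude = 1e-8) {
  if (!n_sources %in% 1:2) stop("n_sources must be 1 or 2", call. = FALSE)
  structure(list(n_sources = as.integer(n_sources), correlated = isTRUE(correlated),
                 snr_db = snr_db, Nt = as.integer(Nt), fs = fs, band = band,
                 seed = as.integer(seed), vertices = vertices,
                 min_separation = min_separation, amplitude = amplitude),
            class = "sim_config")
}

#' Band-limited source time courses
#'
#' Gaussian processes band-limited by hard FFT truncation to `band`,
#' standardised to unit variance. A correlated pair carries the identical
#' waveform (Pearson r = 1); an uncorrelated pair is orthogonalised so
#' the sample correlation is exactly zero.
#'
#' @param n number of sources (1 or 2).
#' @param correlated logical.
#' @param Nt,fs samples and sampling rate.
#' @param seed RNG seed.
#' @param band passband, Hz.
#' @return `n x Nt` matrix.
#' @export
simulate_timecourses <- function(n, correlated = FALSE, Nt = 420, fs = 600,
                                 seed = 1, band = c(0, 48)) {
  if (!n %in% 1:2) stop("n must be 1 or 2", call. = FALSE)
  set.seed(derive_seed(seed, 17))
  bandlimit <- function(x) {
    f <- stats::fft(x)
    freq <- (seq_along(x) - 1) * fs / length(x)
    freq <- pmin(freq, fs - freq)       # two-sided
    f[freq < band[1] | freq > band[2]] <- 0
    Re(stats::fft(f, inverse = TRUE)) / length(x)
  }
  std <- function(x) (x - mean(x)) / stats::sd(x)
  s1 <- std(bandlimit(stats::rnorm(Nt)))
  if (n == 1) return(matrix(s1, 1))
  if (correlated) return(rbind(s1, s1))
  s2 <- std(bandlimit(stats::rnorm(Nt)))
  s2 <- std(s2 - mean(s2) - stats::cov(s1, s2) / stats::var(s1) * (s1 - mean(s1)))
  rbind(s1, s2)
}

# Random source vertices with a minimum pairwise separation (mm).
sample_source_vertices <- function(surface, n, min_sep, seed) {
  set.seed(derive_seed(seed, 19))
  nd <- nrow(surface$vertices)
  for (try in seq_len(1000)) {
    idx <- sample.int(nd, n)
    if (n == 1) return(idx)
    d <- sqrt(sum((surface$vertices[idx[1], ] - surface$vertices[idx[2], ])^2))
    if (d >= min_sep) return(idx)
  }
  stop("could not find source vertices with the requested separation", call. = FALSE)
}

#' Simulate an evoked MEG dataset from point sources on a surface
#'
#' Builds `Y = L J + eps`: point dipole sources at surface vertices with
#' band-limited time courses, plus white Gaussian sensor noise scaled so
#' that `10 log10(||L J||_F^2 / ||eps||_F^2)` equals `snr_db` exactly.
#' Datasets that share `cfg$seed` also share source vertices and the
#' noise realisation, so a correlated / uncorrelated pair differs only in
#' the source waveforms.
#'
#' @param surface the generating [cortical_surface].
#' @param sensors a [sensor_array].
#' @param cfg a [sim_config].
#' @param leadfield optional pre-computed [lead_field] of `surface`.
#' @return object of class `simulated_dataset`: `Y` ([meg_data]),
#'   `vertices`, `J_true` (`n x Nt`, A*m), `snr_db`,
#'   `snr_achieved_db`, `seed`, `cfg`.
#' @export
simulate_dataset <- function(surface, sensors, cfg, leadfield = NULL) {
  stopifnot(inherits(surface, "cortical_surface"), inherits(cfg, "sim_config"))
  if (is.null(leadfield)) leadfield <- surface_leadfield(surface, sensors)
  idx <- cfg$vertices
  if (is.null(idx)) {
    idx <- sample_source_vertices(surface, cfg$n_sources, cfg$min_separation,
                                  cfg$seed)
  }
  S <- simulate_timecourses(cfg$n_sources, cfg$correlated, cfg$Nt, cfg$fs,
                            cfg$seed, cfg$band)
  J <- cfg$amplitude * S
  Y0 <- leadfield$L[, idx, drop = FALSE] %*% J
  p_sig <- sum(Y0^2)
  if (p_sig <= 0) stop("zero sensor signal: cannot realise the requested SNR", call. = FALSE)
  set.seed(derive_seed(cfg$seed, 23))
  eps <- matrix(stats::rnorm(length(Y0)), nrow(Y0))
  eps <- eps * sqrt(p_sig / (sum(eps^2) * 10^(cfg$snr_db / 10)))
  structure(list(Y = meg_data(Y0 + eps, cfg$fs), vertices = idx, J_true = J,
                 snr_db = cfg$snr_db,
                 snr_achieved_db = 10 * log10(p_sig / sum(eps^2)),
                 seed = cfg$seed, cfg = cfg),
            class = "simulated_dataset")
}

#' White-noise control dataset (no source contribution)
#'
#' A surrogate for empirical recordings filtered into a band with little
#' physiological signal: pure white Gaussian sensor noise.
#'
#' @param sensors a [sensor_array].
#' @param Nt,fs samples and sampling rate.
#' @param seed RNG seed.
#' @param sd channel noise standard deviation.
#' @return a [meg_data].
#' @export
noise_only_dataset <- function(sensors, Nt = 420, fs = 600, seed = 1, sd = 1) {
  stopifnot(inherits(sensors, "sensor_array"))
  set.seed(derive_seed(seed, 29))
  meg_data(matrix(stats::rnorm(sensors$count * Nt, sd = sd), sensors$count), fs)
}
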