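#' Acquisition configuration for the scan simulator
#'
#' Collects the parameters of the mechatronic acquisition that the simulator
#' reproduces: constant-speed indentation (0.5 mm/s) stopped at a low force
#' trigger (0.2 N, protecting the sample), a 16 MHz pulse-echo transducer
#' with fractional bandwidth 0.25 at -6 dB sampled at 1.6 GHz, and a 2 mm
#' indentation-grid step.
#'
#' @param indentation_speed Indentation speed along z in mm/s.
#' @param force_trigger Force threshold (N) that ends the indentation and
#'   triggers the ultrasound acquisition.
#' @param force_sample_rate Load-cell sampling rate in Hz. At the defaults
#'   this gives one force sample per micrometre of travel.
#' @param us_sample_rate Ultrasound digitiser rate in Hz.
#' @param pulse_center_frequency Transducer centre frequency in MHz.
#' @param fractional_bandwidth Fractional bandwidth at -6 dB (dimensionless).
#' @param grid_step Indentation-grid step in mm.
#' @param force_noise_sd Additive force noise SD in N (default 0.004 N, the
#'   load-cell resolution).
#' @param us_noise_sd Additive waveform noise SD, relative to the nominal
#'   transmit amplitude.
#' @param inclusion_echo_drop Fraction in \[0, 1) by which the bottom-plate
#'   echo peak drops when the beam crosses a full inclusion diameter; the
#'   drop scales linearly with chord/diameter for partial crossings.
#' @param us_window_us Recorded A-scan window length in microseconds.
#' @param echo_amplitude Nominal (unattenuated) echo amplitude.
#' @param probe_diameter Probe face diameter in mm (stiffness and acoustic
#'   footprint).
#' @param seed Master seed; per-point noise substreams are derived from it
#'   by stable hashing of (seed, point index, channel) so reordering the grid
#'   does not change any point's noise.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(indentation_speed = 0.5,
                               force_trigger = 0.2,
                               force_sample_rate = 500,
                               us_sample_rate = 1.6e9,
                               pulse_center_frequency = 16,
                               fractional_bandwidth = 0.25,
                               grid_step = 2,
                               force_noise_sd = 0.004,
                               us_noise_sd = 0.01,
                               inclusion_echo_drop = 0.5,
                               us_window_us = 30,
                               echo_amplitude = 1,
                               probe_diameter = 3,
                               seed = 0) {
  pos <- c(indentation_speed = indentation_speed,
           force_trigger = force_trigger,
           force_sample_rate = force_sample_rate,
           us_sample_rate = us_sample_rate,
           pulse_center_frequency = pulse_center_frequency,
           fractional_bandwidth = fractional_bandwidth,
           grid_step = grid_step, us_window_us = us_window_us,
           echo_amplitude = echo_amplitude, probe_diameter = probe_diameter)
  if (!all(is.finite(pos)) || any(pos <= 0))
    stop("speeds, rates, trigger and geometry parameters must be positive",
         call. = FALSE)
  if (force_noise_sd < 0 || us_noise_sd < 0)
    stop("noise standard deviations must be non-negative", call. = FALSE)
  if (inclusion_echo_drop < 0 || inclusion_echo_drop >= 1)
    stop("inclusion_echo_drop must lie in [0, 1)", call. = FALSE)
  structure(list(indentation_speed = indentation_speed,
                 force_trigger = force_trigger,
                 force_sample_rate = force_sample_rate,
                 us_sample_rate = us_sample_rate,
                 pulse_center_frequency = pulse_center_frequency,
                 fractional_bandwidth = fractional_bandwidth,
                 grid_step = grid_step,
                 force_noise_sd = force_noise_sd,
                 us_noise_sd = us_noise_sd,
                 inclusion_echo_drop = inclusion_echo_drop,
                 us_window_us = us_window_us,
                 echo_amplitude = echo_amplitude,
                 probe_diameter = probe_diameter,
                 seed = as.integer(seed)),
            class = "acquisition_config")
}

#' Disable all sensor noise in a configuration
#'
#' @param config An `acquisition_config`.
#' @return The configuration with both noise SDs set to zero.
#' @export
no_noise <- function(config) {
  config$force_noise_sd <- 0
  config$us_noise_sd <- 0
  config
}

# Stable substream seed from (seed, index, channel): two minstd
# (Lehmer, modulus 2^31 - 1) multiplicative steps with additive mixing.
# All intermediates stay below 2^53, results below 2^31.
derive_seed <- function(seed, index, channel = 0L) {
  m <- 2147483647
  x <- (abs(as.numeric(seed)) %% m)
  x <- (x * 48271) %% m
  x <- (x + as.numeric(index) * 2246822519 %% m + as.numeric(channel) * 3266489917 %% m) %% m
  x <- (x * 48271) %% m
  as.integer((x %% (m - 1)) + 1)
}

#' Simulate one force-controlled indentation
#'
#' The probe approaches at `indentation_speed`; force is zero (noise only)
#' before a contact offset, then rises linearly as
#' `Fz = k_true * (Z - Z_contact)` with additive Gaussian noise. The trace
#' ends at the first sample reaching `force_trigger`.
#'
#' @param k_true True local stiffness in N/mm.
#' @param config An `acquisition_config`.
#' @param rng_state Integer seed for this record's noise and contact offset.
#' @param grid_point Optional (x, y) recorded with the trace.
#' @return An `indentation_record` with fields `grid_point`, `force_trace`,
#'   `z_trace` (mm, monotone non-decreasing) and `trigger_index`.
#' @export
#' @examples
#' r <- simulate_indentation(0.33, no_noise(acquisition_config()), 1)
#' estimate_stiffness(r)$k
simulate_indentation <- function(k_true, config, rng_state = config$seed,
                                 grid_point = c(NA_real_, NA_real_)) {
  if (!is.finite(k_true) || k_true <= 0)
    stop("k_true must be a positive stiffness in N/mm", call. = FALSE)
  dz <- config$indentation_speed / config$force_sample_rate
  with_preserved_rng({
    set.seed(derive_seed(rng_state, 0L, 0L))
    z_contact <- stats::runif(1, 0.5, 1.5)      # approach travel before touch
    n_pre <- ceiling(z_contact / dz)
    n_post <- ceiling(config$force_trigger / k_true / dz) + 16L
    repeat {
      n <- n_pre + n_post
      z <- dz * (seq_len(n) - 1)
      f_clean <- pmax(0, k_true * (z - z_contact))
      f <- f_clean + if (config$force_noise_sd > 0)
        stats::rnorm(n, 0, config$force_noise_sd) else 0
      hit <- which(f >= config$force_trigger)
      hit <- hit[hit > n_pre]   # trigger only once in contact
      if (length(hit) > 0L) break
      n_post <- n_post * 2L     # noise kept us below threshold: extend
    }
    ti <- hit[1]
    structure(list(grid_point = as.numeric(grid_point),
                   force_trace = f[seq_len(ti)],
                   z_trace = z[seq_len(ti)],
                   trigger_index = ti),
              class = "indentation_record")
  })
}

# -6 dB fractional-bandwidth Gaussian envelope: the amplitude spectrum of
# exp(-t^2 / (2 sigma^2)) falls to one half over a full width
# 2 sqrt(2 log 2) / (2 pi sigma), hence sigma = sqrt(2 log 2) / (pi df).
pulse_sigma <- function(config) {
  df <- config$fractional_bandwidth * config$pulse_center_frequency * 1e6
  sqrt(2 * log(2)) / (pi * df)
}

# Two-way time of flight and echo peak amplitude of the bottom-plate echo
# for the column under (x, y). Returns list(t0 [s], amplitude).
echo_model <- function(phantom, x, y, config) {
  Tz <- phantom$thickness_mm
  hit <- footprint_max_chord(phantom, x, y, config$probe_diameter)
  t_i <- hit$chord
  cm <- phantom$matrix_material$speed_of_sound
  am <- phantom$matrix_material$attenuation
  if (t_i > 0) {
    inc <- phantom$inclusions[[hit$inclusion]]
    ci <- inc$material$speed_of_sound
    ai <- inc$material$attenuation
  } else {
    ci <- cm; ai <- am
  }
  t0 <- 2 * ((Tz - t_i) / cm + t_i / ci) * 1e-3  # mm / (m/s) -> s
  db <- 2 * ((Tz - t_i) * am + t_i * ai) / 10    # two-way path loss, mm * dB/cm
  a <- config$echo_amplitude * 10^(-db / 20)
  a_ref <- config$echo_amplitude * 10^(-(2 * Tz * am / 10) / 20)
  if (t_i > 0) {
    drop <- config$inclusion_echo_drop * t_i / phantom$inclusions[[hit$inclusion]]$diameter
    a_incl <- a * (1 - drop)
    if (phantom$inclusions[[hit$inclusion]]$has_air_bubble) {
      bf <- phantom$inclusions[[hit$inclusion]]$bubble_fraction
      a_incl <- a_incl + bf * (a_ref - a_incl)
    }
    a <- a_incl
  }
  list(t0 = t0, amplitude = a)
}

#' Simulate one pulse-echo A-scan
#'
#' Synthesises the echo reflected at the phantom-bottom/steel-plate
#' interface under `(x, y)`: a Gaussian-envelope tone burst at the
#' transducer centre frequency, centred at the two-way time of flight
#' through the layered column (matrix plus inclusion chord at their own
#' speeds of sound), with peak amplitude attenuated by the two-way path
#' loss and further reduced - in proportion to chord/diameter - when the
#' beam crosses an inclusion (air bubbles restore part of the amplitude).
#'
#' @param phantom A `phantom`.
#' @param x,y Probe position in mm, inside the footprint.
#' @param config An `acquisition_config`.
#' @param rng_state Integer seed for this waveform's additive noise.
#' @return An `ascan` with fields `grid_point`, `waveform`, `sample_rate`.
#' @export
simulate_ascan <- function(phantom, x, y, config, rng_state = config$seed) {
  check_in_footprint(phantom, x, y)
  em <- echo_model(phantom, x, y, config)
  fs <- config$us_sample_rate
  n <- ceiling(config$us_window_us * 1e-6 * fs)
  sigma <- pulse_sigma(config)
  f0 <- config$pulse_center_frequency * 1e6
  w <- numeric(n)
  # burst support limited to +/- 6 sigma of the envelope
  i0 <- max(1L, floor((em$t0 - 6 * sigma) * fs) + 1L)
  i1 <- min(n, ceiling((em$t0 + 6 * sigma) * fs) + 1L)
  if (i0 <= i1) {
    u <- (seq(i0, i1) - 1) / fs - em$t0
    w[i0:i1] <- em$amplitude * exp(-u^2 / (2 * sigma^2)) * cos(2 * pi * f0 * u)
  }
  if (config$us_noise_sd > 0) {
    w <- w + with_preserved_rng({
      set.seed(derive_seed(rng_state, 0L, 1L))
      stats::rnorm(n, 0, config$us_noise_sd * config$echo_amplitude)
    })
  }
  structure(list(grid_point = c(x, y), waveform = w, sample_rate = fs),
            class = "ascan")
}

#' Simulate a full indentation-matrix scan
#'
#' Runs one indentation (at the homogenised local stiffness) and one
#' pulse-echo acquisition per grid point, in grid order. Fully
#' deterministic given `config$seed`; per-point noise substreams are tied
#' to the point index.
#'
#' @param phantom A `phantom`.
#' @param grid Two-column matrix or data frame of (x, y) points in mm, or an
#'   `indentation_grid`.
#' @param config An `acquisition_config`.
#' @return A `scan_dataset` with aligned `grid`, `records` and `ascans`,
#'   carrying `phantom` and `config` for downstream evaluation.
#' @export
simulate_scan <- function(phantom, grid, config = acquisition_config()) {
  pts <- as_grid_matrix(grid)
  n <- nrow(pts)
  if (n == 0L) stop("grid contains no points", call. = FALSE)
  records <- vector("list", n)
  ascans <- vector("list", n)
  for (i in seq_len(n)) {
    x <- pts[i, 1]; y <- pts[i, 2]
    res <- tryCatch({
      k <- local_stiffness(phantom, x, y, config$probe_diameter)
      rec <- simulate_indentation(k, config,
                                  rng_state = derive_seed(config$seed, i, 10L),
                                  grid_point = c(x, y))
      asc <- simulate_ascan(phantom, x, y, config,
                            rng_state = derive_seed(config$seed, i, 20L))
      list(rec = rec, asc = asc)
    }, error = function(e) {
      stop(sprintf("scan failed at point %d (%.3g, %.3g): %s",
                   i, x, y, conditionMessage(e)), call. = FALSE)
    })
    records[[i]] <- res$rec
    ascans[[i]] <- res$asc
  }
  structure(list(phantom = phantom, config = config, grid = pts,
                 records = records, ascans = ascans),
            class = "scan_dataset")
}

as_grid_matrix <- function(grid) {
  if (inherits(grid, "indentation_grid")) {
    pts <- cbind(grid$points$x, grid$points$y)
  } else {
    pts <- as.matrix(grid)
  }
  if (ncol(pts) != 2L) stop("grid must have two columns (x, y)", call. = FALSE)
  storage.mode(pts) <- "double"
  colnames(pts) <- c("x", "y")
  pts
}

#' @export
print.scan_dataset <- function(x, ...) {
  cat(sprintf("scan_dataset: %d grid points, %s waveform samples/point, seed %d\n",
              nrow(x$grid),
              if (length(x$ascans)) length(x$ascans[[1]]$waveform) else 0,
              x$config$seed))
  invisible(x)
}
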