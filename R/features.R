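#' Estimate stiffness from an indentation record
#'
#' The stiffness is the secant slope of force versus vertical position
#' between first contact and the force trigger:
#' `k = (Fzmax - Fz0) / (Z_Fzmax - Z_Fz0)`,
#' where `Fzmax` is the force at the trigger sample and `Fz0` the force at
#' the contact sample. Contact is located as the first sample at or above
#' `contact_threshold` when scanning back from the trigger (identical to a
#' forward scan on clean traces, robust to isolated pre-contact noise
#' excursions).
#'
#' @param record An `indentation_record`.
#' @param contact_threshold Contact force threshold in N. The default,
#'   `max(0.02, 5 * force_noise_sd)`, stays well below the 0.2 N trigger
#'   while clearing load-cell noise; `force_noise_sd` is read from
#'   `config` when given, else 0.004 N is assumed.
#' @param config Optional `acquisition_config` supplying the noise level
#'   for the default threshold.
#' @return A `stiffness_estimate`: `k` (N/mm), `Fz0`, `Fzmax`, `Z_at_Fz0`,
#'   `Z_at_Fzmax`.
#' @export
#' @examples
#' cfg <- no_noise(acquisition_config())
#' estimate_stiffness(simulate_indentation(4.6, cfg, 1))$k
estimate_stiffness <- function(record, contact_threshold = NULL, config = NULL) {
  stopifnot(inherits(record, "indentation_record"))
  if (is.null(contact_threshold)) {
    nsd <- if (!is.null(config)) config$force_noise_sd else 0.004
    contact_threshold <- max(0.02, 5 * nsd)
  }
  f <- record$force_trace; z <- record$z_trace
  ti <- record$trigger_index
  if (contact_threshold >= f[ti])
    stop("contact_threshold must lie below the trigger force", call. = FALSE)
  below <- which(f[seq_len(ti - 1L)] < contact_threshold)
  if (length(below) == 0L || f[1] >= contact_threshold)
    stop("unusable record: contact never detected below the trigger",
         call. = FALSE)
  i0 <- max(below) + 1L
  if (z[ti] == z[i0])
    stop("unusable record: no travel between contact and trigger",
         call. = FALSE)
  k <- (f[ti] - f[i0]) / (z[ti] - z[i0])
  structure(list(k = k, Fz0 = f[i0], Fzmax = f[ti],
                 Z_at_Fz0 = z[i0], Z_at_Fzmax = z[ti]),
            class = "stiffness_estimate")
}

#' Correlation Index Amplitude between two A-scans
#'
#' Energy-ratio dissimilarity between a test waveform and a reference
#' waveform: `CIA = 1 - min(E_ref, E_sig) / max(E_ref, E_sig)` with
#' `E = sum(S^2)`. CIA is 0 for signals of identical energy, approaches 1
#' for very different amplitudes, is symmetric in its arguments and always
#' lies in \[0, 1\].
#'
#' @param signal,reference `ascan` objects or bare numeric waveforms.
#' @return A `cia_estimate`: `cia`, `energy_signal`, `energy_reference`.
#' @export
#' @examples
#' compute_cia(c(0.5, 0.5), c(1, 1))$cia   # 1 - 0.25 = 0.75
compute_cia <- function(signal, reference) {
  ws <- if (inherits(signal, "ascan")) signal$waveform else as.numeric(signal)
  wr <- if (inherits(reference, "ascan")) reference$waveform else as.numeric(reference)
  if (length(ws) == 0L || length(wr) == 0L)
    stop("waveforms must be non-empty", call. = FALSE)
  es <- sum(ws^2); er <- sum(wr^2)
  if (es == 0 && er == 0)
    stop("CIA undefined: both waveforms have zero energy", call. = FALSE)
  structure(list(cia = 1 - min(es, er) / max(es, er),
                 energy_signal = es, energy_reference = er),
            class = "cia_estimate")
}

#' Select the reference A-scan of a dataset
#'
#' The reference should come from a position free of inclusions, where the
#' bottom-plate echo is only attenuated by the two-way path. Without ground
#' truth the strongest echo is the best proxy, so the maximum-energy A-scan
#' is chosen (ties broken by lowest index). An explicit index can be forced
#' downstream via [build_feature_maps()].
#'
#' @param ascans List of `ascan` objects (or numeric waveforms).
#' @return Integer index of the reference A-scan.
#' @export
select_reference <- function(ascans) {
  if (length(ascans) == 0L) stop("empty A-scan list", call. = FALSE)
  e <- vapply(ascans, function(a) {
    w <- if (inherits(a, "ascan")) a$waveform else as.numeric(a)
    sum(w^2)
  }, numeric(1))
  if (all(e == 0)) stop("no usable reference: all A-scans are zero", call. = FALSE)
  which.max(e)   # which.max already breaks ties by lowest index
}

#' Compute the stiffness and CIA feature maps of a scan
#'
#' Applies [estimate_stiffness()] to every indentation record and
#' [compute_cia()] to every A-scan against the selected reference, yielding
#' the two per-point feature maps that drive classification.
#'
#' @param dataset A `scan_dataset`.
#' @param contact_threshold Passed to [estimate_stiffness()]; defaults from
#'   the dataset's acquisition config.
#' @param reference_index Optional explicit reference A-scan index; default
#'   [select_reference()].
#' @return A `feature_maps` object: `grid`, `k_values`, `cia_values`,
#'   `reference_point_index`.
#' @export
build_feature_maps <- function(dataset, contact_threshold = NULL,
                               reference_index = NULL) {
  stopifnot(inherits(dataset, "scan_dataset"))
  n <- nrow(dataset$grid)
  if (is.null(reference_index)) reference_index <- select_reference(dataset$ascans)
  ref <- dataset$ascans[[reference_index]]
  k <- cia <- numeric(n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      list(k = estimate_stiffness(dataset$records[[i]], contact_threshold,
                                  config = dataset$config)$k,
           cia = compute_cia(dataset$ascans[[i]], ref)$cia)
    }, error = function(e) {
      stop(sprintf("feature extraction failed at point %d (%.3g, %.3g): %s",
                   i, dataset$grid[i, 1], dataset$grid[i, 2],
                   conditionMessage(e)), call. = FALSE)
    })
    k[i] <- res$k; cia[i] <- res$cia
  }
  structure(list(grid = dataset$grid, k_values = k, cia_values = cia,
                 reference_point_index = as.integer(reference_index)),
            class = "feature_maps")
}

#' @export
print.feature_maps <- function(x, ...) {
  cat(sprintf(
    "feature_maps: %d points; k in [%.3g, %.3g] N/mm; CIA in [%.3g, %.3g]; ref point %d\n",
    nrow(x$grid), min(x$k_values), max(x$k_values),
    min(x$cia_values), max(x$cia_values), x$reference_point_index))
  invisible(x)
}
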