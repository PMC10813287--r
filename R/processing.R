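# Raw tensile-record processing: polynomial smoothing of the load signal,
# low-pass filtering of its slope, detection of the post-conditioning
# loading onset, and normalisation to an engineering stress-strain curve.

as_load_record <- function(record) {
  req <- c("time_s", "force_n", "displacement_mm")
  if (!is.data.frame(record) || !all(req %in% names(record))) {
    abort(
      "a load record needs columns time_s, force_n, displacement_mm"
    )
  }
  if (nrow(record) == 0) abort("load record is empty")
  record
}

record_rate <- function(record) {
  sr <- attr(record, "sample_rate_hz")
  if (is.null(sr)) {
    if (nrow(record) < 2) abort("cannot infer sample rate from one sample")
    sr <- 1 / stats::median(diff(record$time_s))
  }
  sr
}

#' Smooth a load signal with a local polynomial
#'
#' Applies a sliding-window local least-squares polynomial fit of order 4
#' (Savitzky-Golay) to the force channel, removing stepper-motor ripple
#' while leaving any polynomial trend of degree four or less untouched.
#'
#' @param record A load record (tibble with `time_s`, `force_n`,
#'   `displacement_mm`), e.g. from [generate_load_history()] or
#'   [read_load_record()].
#' @param window Window length in samples: odd, greater than 5, at most the
#'   record length.
#' @param order Polynomial order of the local fit.
#' @return The record with `force_n` smoothed; attributes preserved.
#' @export
smooth_load <- function(record, window = 31, order = 4) {
  record <- as_load_record(record)
  if (window %% 2 == 0 || window <= 5 || window > nrow(record)) {
    abort("`window` must be odd, > 5, and no longer than the record")
  }
  if (order >= window) abort("`order` must be smaller than `window`")
  record$force_n <- signal::sgolayfilt(record$force_n, p = order, n = window)
  record
}

#' Low-pass filtered slope of the load signal
#'
#' Differentiates the force channel numerically (central differences) and
#' smooths the derivative with a zero-phase (forward-backward) low-pass
#' Butterworth filter. Zero-phase filtering leaves event timing unshifted,
#' which matters because the slope is used to locate the loading onset. The
#' DC gain is exactly one, so a linear ramp passes through unchanged.
#'
#' @param record A load record.
#' @param cutoff Cutoff as a fraction of the Nyquist frequency, in (0, 1).
#'   The default 0.5 suits load signals sampled at tens of hertz.
#' @param order Butterworth filter order.
#' @return Numeric vector of filtered slopes, N/s, one per sample.
#' @export
slope_filter <- function(record, cutoff = 0.5, order = 5) {
  record <- as_load_record(record)
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0 ||
      cutoff >= 1) {
    abort("`cutoff` must lie strictly between 0 and 1 (fraction of Nyquist)")
  }
  f <- record$force_n
  n <- length(f)
  if (n < 7) abort("record too short to differentiate and filter")
  dt <- 1 / record_rate(record)
  slope <- numeric(n)
  slope[2:(n - 1)] <- (f[3:n] - f[1:(n - 2)]) / (2 * dt)
  slope[1] <- (f[2] - f[1]) / dt
  slope[n] <- (f[n] - f[n - 1]) / dt
  bf <- signal::butter(order, cutoff, type = "low")
  as.numeric(signal::filtfilt(bf, slope))
}

#' Detect the post-conditioning loading onset
#'
#' Finds the first sample after the final preconditioning unloading at which
#' the filtered load slope stays above `slope_threshold` for `hold`
#' consecutive samples: the start of the sustained monotone pull. Time and
#' load are zeroed at this index by [engineering_curve()].
#'
#' @param record A load record (ideally already passed through
#'   [smooth_load()]).
#' @param protocol A [test_protocol()]; with `cycles = 0` the search starts
#'   at the first sample.
#' @param slope_threshold Slope threshold, N/s. Default: 5% of the maximum
#'   filtered slope.
#' @param hold Number of consecutive samples the slope must stay above the
#'   threshold.
#' @param cutoff,order Passed to [slope_filter()].
#' @return The onset sample index (1-based integer).
#' @export
detect_onset <- function(record, protocol = test_protocol(),
                         slope_threshold = NULL, hold = 5,
                         cutoff = 0.5, order = 5) {
  record <- as_load_record(record)
  slope <- slope_filter(record, cutoff = cutoff, order = order)
  thr <- slope_threshold %||% (0.05 * max(slope))
  if (!is.finite(thr) || thr <= 0) {
    abort("no positive load slope found; onset not detectable")
  }
  start <- 1L
  if (protocol$cycles > 0) {
    neg <- which(slope < -thr)
    if (length(neg) > 0) start <- max(neg) + 1L
  }
  above <- slope > thr
  run <- as.numeric(stats::filter(as.numeric(above), rep(1, hold),
    sides = 1
  ))
  cand <- which(run == hold) - hold + 1L
  cand <- cand[cand >= start]
  if (length(cand) == 0) {
    abort("onset not found: slope never stays above the threshold")
  }
  as.integer(cand[1])
}

#' Convert a load record to an engineering stress-strain curve
#'
#' Zeroes displacement and force at the detected onset of the
#' post-conditioning pull, then normalises: strain by the post-conditioning
#' specimen length, stress by the reference width (by default the
#' post-conditioning width, in practice the minimum width tracked at the
#' onset) times the thickness. The curve is truncated at 20% engineering
#' strain by default, the range over which colorectal tissue deforms
#' without damage.
#'
#' @param record A load record.
#' @param geometry A one-row geometry tibble ([specimen_geometry()]).
#' @param reference_width_mm Width used for the cross-section, mm; defaults
#'   to the geometry's post-conditioning width.
#' @param onset Onset sample index; defaults to the record's `onset_index`
#'   attribute (the generator's ground truth) if present. Supply the result
#'   of [detect_onset()] when processing measured data.
#' @param strain_max Truncation strain (use `Inf` to keep everything).
#' @return A tibble of class `processed_curve` with columns `strain`,
#'   `stress_pa`, `orientation`, carrying provenance attributes `onset`,
#'   `reference_width_mm`.
#' @export
engineering_curve <- function(record, geometry, reference_width_mm = NULL,
                              onset = NULL, strain_max = 0.2) {
  record <- as_load_record(record)
  g <- as.list(geometry)
  onset <- onset %||% attr(record, "onset_index")
  if (is.null(onset)) {
    abort("no onset available: run detect_onset() or supply `onset`")
  }
  if (onset < 1 || onset > nrow(record)) abort("`onset` is out of range")
  ref_w <- reference_width_mm %||% g$post_width_mm
  if (ref_w <= 0 || g$thickness_mm <= 0) {
    abort("reference width and thickness must be positive")
  }
  idx <- onset:nrow(record)
  strain <- (record$displacement_mm[idx] - record$displacement_mm[onset]) /
    g$post_length_mm
  stress <- (record$force_n[idx] - record$force_n[onset]) /
    (ref_w * g$thickness_mm * 1e-6)
  keep <- strain <= strain_max
  structure(
    tibble(
      strain = strain[keep], stress_pa = stress[keep],
      orientation = g$orientation
    ),
    onset = as.integer(onset),
    reference_width_mm = ref_w,
    class = c("processed_curve", class(tibble()))
  )
}

#' Process a raw load record end to end
#'
#' Convenience pipeline: polynomial smoothing, slope filtering, onset
#' detection, and stress-strain normalisation in one call.
#'
#' @inheritParams smooth_load
#' @inheritParams detect_onset
#' @inheritParams engineering_curve
#' @return A `processed_curve` tibble (see [engineering_curve()]).
#' @examples
#' rec <- generate_load_history(
#'   specimen_geometry("circ"), test_protocol(), colorectal_params()
#' )
#' curve <- process_record(rec, specimen_geometry("circ"))
#' head(curve)
#' @export
process_record <- function(record, geometry, window = 31,
                           protocol = test_protocol(),
                           slope_threshold = NULL, hold = 5, cutoff = 0.5,
                           reference_width_mm = NULL, strain_max = 0.2) {
  smoothed <- smooth_load(record, window = window)
  onset <- detect_onset(smoothed, protocol,
    slope_threshold = slope_threshold, hold = hold, cutoff = cutoff
  )
  engineering_curve(smoothed, geometry,
    reference_width_mm = reference_width_mm,
    onset = onset, strain_max = strain_max
  )
}
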