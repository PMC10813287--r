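# Published specimen geometry statistics (mm): pre-conditioning width and
# thickness, die-cut gauge length, and post-conditioning length and width,
# per orientation (mean, sd).
geometry_stats <- list(
  circumferential = list(
    gauge = 20,
    width = c(10.1, 1.7), thickness = c(1.0, 0.2),
    post_length = c(29.0, 2.6), post_width = c(8.9, 2.0)
  ),
  longitudinal = list(
    gauge = 20,
    width = c(8.6, 1.6), thickness = c(1.1, 0.3),
    post_length = c(29.8, 2.2), post_width = c(8.0, 2.1)
  )
)

# Normal draws truncated at +/- 3 sd and at a hard lower bound (> 0, and
# > gauge length for post-conditioning lengths), by rejection.
rtrunc_norm <- function(n, mean, sd, lower = 0) {
  lo <- max(mean - 3 * sd, lower)
  hi <- mean + 3 * sd
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x > lo & x < hi])
  }
  out[seq_len(n)]
}

#' Sample synthetic specimen geometries
#'
#' Draws specimen dimensions from truncated normal distributions matching
#' the reported per-orientation means and standard deviations of fresh
#' porcine colorectal specimens (die-cut to a 20 mm gauge length; specimens
#' lengthen and narrow during preconditioning, so post-conditioning length
#' and width are sampled separately). Truncation at three standard
#' deviations keeps all dimensions physical.
#'
#' @param orientation `"circumferential"` or `"longitudinal"` (abbreviations
#'   accepted).
#' @param n Number of specimens.
#' @param seed Integer seed.
#' @return A tibble with one row per specimen: `orientation`,
#'   `gauge_length_mm`, `width_mm`, `thickness_mm`, `post_length_mm`,
#'   `post_width_mm`.
#' @examples
#' sample_geometry("circ", 3, seed = 1)
#' @export
sample_geometry <- function(orientation, n, seed = 1) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort("`n` must be a positive count")
  }
  axis <- match_axis(orientation)
  st <- geometry_stats[[axis_label(axis)]]
  withr::with_seed(as.integer(seed), {
    tibble(
      orientation = axis_label(axis),
      gauge_length_mm = rep(st$gauge, n),
      width_mm = rtrunc_norm(n, st$width[1], st$width[2]),
      thickness_mm = rtrunc_norm(n, st$thickness[1], st$thickness[2]),
      post_length_mm = rtrunc_norm(n, st$post_length[1], st$post_length[2],
        lower = st$gauge
      ),
      post_width_mm = rtrunc_norm(n, st$post_width[1], st$post_width[2])
    )
  })
}

#' A nominal specimen geometry
#'
#' Builds a single specimen geometry, defaulting to the per-orientation mean
#' dimensions. Useful as input to [generate_load_history()] and
#' [render_frame()].
#'
#' @inheritParams sample_geometry
#' @param gauge_length_mm,width_mm,thickness_mm,post_length_mm,post_width_mm
#'   Override individual dimensions (mm).
#' @return A one-row geometry tibble.
#' @examples
#' specimen_geometry("circ")
#' @export
specimen_geometry <- function(orientation = "circumferential",
                              gauge_length_mm = NULL, width_mm = NULL,
                              thickness_mm = NULL, post_length_mm = NULL,
                              post_width_mm = NULL) {
  axis <- match_axis(orientation)
  st <- geometry_stats[[axis_label(axis)]]
  g <- tibble(
    orientation = axis_label(axis),
    gauge_length_mm = gauge_length_mm %||% st$gauge,
    width_mm = width_mm %||% st$width[1],
    thickness_mm = thickness_mm %||% st$thickness[1],
    post_length_mm = post_length_mm %||% st$post_length[1],
    post_width_mm = post_width_mm %||% st$post_width[1]
  )
  if (any(unlist(g[-1]) <= 0)) abort("all dimensions must be positive")
  if (g$post_length_mm <= g$gauge_length_mm) {
    abort("post-conditioning length must exceed the gauge length")
  }
  g
}

#' Test protocol settings
#'
#' The uniaxial protocol: four preconditioning cycles to 7% strain at a
#' displacement rate of 0.05 mm/s, load sampled at 30 Hz and video at 60 Hz.
#'
#' @param cycles Number of preconditioning cycles.
#' @param precondition_strain Peak preconditioning engineering strain
#'   (relative to the gauge length).
#' @param displacement_rate_mm_s Crosshead speed, mm/s.
#' @param load_sample_rate_hz Load-cell sampling rate, Hz.
#' @param frame_rate_hz Camera frame rate, Hz.
#' @return A list of class `test_protocol`.
#' @export
test_protocol <- function(cycles = 4, precondition_strain = 0.07,
                          displacement_rate_mm_s = 0.05,
                          load_sample_rate_hz = 30, frame_rate_hz = 60) {
  vals <- c(
    cycles, precondition_strain, displacement_rate_mm_s,
    load_sample_rate_hz, frame_rate_hz
  )
  if (any(!is.finite(vals)) || any(vals[-1] <= 0) || cycles < 0) {
    abort("protocol values must be positive (cycles may be 0)")
  }
  structure(
    list(
      cycles = as.integer(cycles),
      precondition_strain = precondition_strain,
      displacement_rate_mm_s = displacement_rate_mm_s,
      load_sample_rate_hz = load_sample_rate_hz,
      frame_rate_hz = frame_rate_hz
    ),
    class = "test_protocol"
  )
}

#' Generate synthetic stress-strain curves
#'
#' Produces per-specimen engineering stress-strain curves from the forward
#' model with multiplicative Gaussian noise: each sampled stress is the
#' model prediction times `(1 + e)`, `e ~ N(0, noise_cv)` independently per
#' point, clipped at zero. Multiplicative noise mirrors the observation that
#' inter-specimen scatter grows roughly in proportion to the stress level.
#'
#' @param params A [material_parameters()] object.
#' @param orientation Loading direction.
#' @param n_specimens Number of curves.
#' @param strain_max Maximum engineering strain (default 0.2, the range over
#'   which colorectal tissue deforms without damage).
#' @param n_points Samples per curve, evenly spaced on `[0, strain_max]`.
#' @param noise_cv Coefficient of variation of the multiplicative noise;
#'   0 returns exact model curves.
#' @param seed Integer seed.
#' @param stress Stress measure to generate, `"engineering"` or `"true"`.
#' @return A tibble with columns `strain`, `stress_pa`, `orientation`,
#'   `specimen`.
#' @examples
#' generate_curves(colorectal_params(), "circ", 2, noise_cv = 0.05, seed = 1)
#' @export
generate_curves <- function(params, orientation, n_specimens,
                            strain_max = 0.2, n_points = 50,
                            noise_cv = 0.05, seed = 1,
                            stress = c("engineering", "true")) {
  stress <- match.arg(stress)
  if (strain_max <= 0) abort("`strain_max` must be positive")
  if (noise_cv < 0) abort("`noise_cv` must be non-negative")
  if (n_specimens < 1) abort("`n_specimens` must be at least 1")
  grid <- seq(0, strain_max, length.out = n_points)
  base <- predict_curve(params, grid, orientation, stress = stress)
  withr::with_seed(as.integer(seed), {
    purrr::map_dfr(seq_len(n_specimens), function(s) {
      eps <- if (noise_cv > 0) stats::rnorm(n_points, 0, noise_cv) else 0
      dplyr::mutate(base,
        stress_pa = pmax(.data$stress_pa * (1 + eps), 0),
        specimen = s
      )
    })
  })
}

#' Generate a synthetic load-displacement time history
#'
#' Emulates the tensile rig output for one specimen: `cycles` triangular
#' preconditioning excursions to `precondition_strain` times the gauge
#' length, followed by a monotone ramp, all at the protocol displacement
#' rate and sampled at the load rate. Force is the model engineering stress
#' at the current stretch (strain taken relative to the post-conditioning
#' length, which is also the normalisation the processing pipeline applies)
#' times the specimen cross-section. The true onset of the final loading
#' ramp is stored as the `onset_index` attribute so detection algorithms can
#' be scored against ground truth.
#'
#' @param geometry A one-row geometry tibble ([specimen_geometry()]).
#' @param protocol A [test_protocol()].
#' @param params A [material_parameters()] object.
#' @param strain_max Engineering strain at which the ramp stops (relative to
#'   post-conditioning length).
#' @param noise_sd_n Standard deviation of additive force noise, N.
#' @param seed Seed for the noise.
#' @return A tibble of class `load_record` with columns `time_s`, `force_n`,
#'   `displacement_mm` and attributes `sample_rate_hz`, `onset_index`,
#'   `geometry`.
#' @examples
#' rec <- generate_load_history(
#'   specimen_geometry("circ"), test_protocol(), colorectal_params()
#' )
#' attr(rec, "onset_index")
#' @export
generate_load_history <- function(geometry, protocol, params,
                                  strain_max = 0.22, noise_sd_n = 0,
                                  seed = 1) {
  stopifnot(inherits(protocol, "test_protocol"))
  g <- as.list(geometry)
  amp <- protocol$precondition_strain * g$gauge_length_mm
  rate <- protocol$displacement_rate_mm_s
  dt <- 1 / protocol$load_sample_rate_hz
  t_pre <- protocol$cycles * 2 * amp / rate
  d_max <- strain_max * g$post_length_mm
  t_total <- t_pre + d_max / rate
  time <- seq(0, t_total, by = dt)

  disp <- vapply(time, function(t) {
    if (t < t_pre) {
      phase <- (t %% (2 * amp / rate)) * rate
      if (phase <= amp) phase else 2 * amp - phase
    } else {
      (t - t_pre) * rate
    }
  }, numeric(1))
  if (protocol$cycles == 0) disp <- time * rate

  strain <- disp / g$post_length_mm
  area_m2 <- g$post_width_mm * g$thickness_mm * 1e-6
  stress <- uniaxial_stress(params, 1 + strain, g$orientation)$p_eng_pa
  force <- stress * area_m2
  if (noise_sd_n > 0) {
    force <- withr::with_seed(
      as.integer(seed),
      force + stats::rnorm(length(force), 0, noise_sd_n)
    )
  }
  onset <- if (protocol$cycles == 0) 1L else min(which(time >= t_pre))

  structure(
    tibble(time_s = time, force_n = force, displacement_mm = disp),
    sample_rate_hz = protocol$load_sample_rate_hz,
    onset_index = onset,
    geometry = geometry,
    class = c("load_record", class(tibble()))
  )
}
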