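ref <- colorectal_params()

make_record <- function(force, rate = 30) {
  n <- length(force)
  structure(
    tibble::tibble(
      time_s = (seq_len(n) - 1) / rate,
      force_n = force,
      displacement_mm = (seq_len(n) - 1) * 0.05 / rate
    ),
    sample_rate_hz = rate,
    class = c("load_record", class(tibble::tibble()))
  )
}

test_that("local quartic smoothing preserves low-order polynomial signals", {
  t <- seq(0, 10, by = 1 / 30)
  const <- make_record(rep(2, length(t)))
  expect_equal(smooth_load(const, 31)$force_n, rep(2, length(t)),
    tolerance = 1e-12
  )
  cubic <- 0.5 + 0.3 * t - 0.07 * t^2 + 0.011 * t^3
  rec <- make_record(cubic)
  expect_equal(smooth_load(rec, 31)$force_n, cubic, tolerance = 1e-10)
})

test_that("smoothing attenuates white noise on a cubic trend", {
  t <- seq(0, 20, by = 1 / 30)
  clean <- 0.2 + 0.1 * t - 0.01 * t^2 + 0.002 * t^3
  noisy <- withr::with_seed(42, clean + rnorm(length(t), 0, 0.05))
  sm <- smooth_load(make_record(noisy), 31)$force_n
  rms_before <- sqrt(mean((noisy - clean)^2))
  rms_after <- sqrt(mean((sm - clean)^2))
  expect_lt(rms_after, 0.5 * rms_before)
})

test_that("smoothing window constraints are enforced", {
  rec <- make_record(rep(1, 100))
  expect_error(smooth_load(rec, 30), "odd")
  expect_error(smooth_load(rec, 5), "odd|> 5")
  expect_error(smooth_load(rec, 101), "record")
})

test_that("the filtered slope passes DC exactly and attenuates high frequency", {
  rate <- 30
  t <- seq(0, 30, by = 1 / rate)
  k <- 0.37
  ramp <- make_record(k * t, rate)
  slope <- slope_filter(ramp, cutoff = 0.5)
  mid <- 100:(length(t) - 100)
  expect_equal(slope[mid], rep(k, length(mid)), tolerance = 1e-6)

  # sinusoid at 5x the cutoff: zero-phase 5th-order Butterworth must
  # attenuate by at least the single-pass analytic magnitude 1/sqrt(1+5^10)
  cutoff <- 0.1 # of Nyquist -> 1.5 Hz; signal at 7.5 Hz
  f_sig <- 5 * cutoff * rate / 2
  sig <- make_record(sin(2 * pi * f_sig * t), rate)
  slope_sig <- slope_filter(sig, cutoff = cutoff)
  amp_in <- 2 * pi * f_sig # derivative amplitude before filtering
  amp_out <- max(abs(slope_sig[mid]))
  expect_lt(amp_out / amp_in, 1 / sqrt(1 + 5^10))

  expect_error(slope_filter(make_record(numeric(0))), "empty")
  expect_error(slope_filter(make_record(rep(1, 3))), "short")
  expect_error(slope_filter(ramp, cutoff = 0), "between 0 and 1")
  expect_error(slope_filter(ramp, cutoff = 1), "between 0 and 1")
})

test_that("onset detection lands on the generator's ground truth", {
  g <- specimen_geometry("circ")
  prot <- test_protocol()
  rec <- generate_load_history(g, prot, ref)
  truth <- attr(rec, "onset_index")
  hold <- 5
  got <- detect_onset(smooth_load(rec, 31), prot, hold = hold)
  expect_lte(abs(got - truth), hold + 2)
})

test_that("onset detection handles edge cases", {
  # pure monotone ramp with no preconditioning configured: onset at sample 1
  t <- seq(0, 10, by = 1 / 30)
  ramp <- make_record(2 * t)
  expect_equal(detect_onset(ramp, test_protocol(cycles = 0)), 1L)
  # constant force: nothing to detect
  flat <- make_record(rep(1, 200))
  expect_error(detect_onset(flat, test_protocol()), "onset not")
})

test_that("stress-strain normalisation applies the documented conventions", {
  # 1 N above the onset force over 10 mm x 1 mm is 1e5 Pa
  g <- specimen_geometry("circ",
    post_width_mm = 10, thickness_mm = 1,
    post_length_mm = 25
  )
  rec <- make_record(c(rep(0, 10), seq(0, 1, length.out = 91)))
  curve <- engineering_curve(rec, g, onset = 10, strain_max = Inf)
  expect_equal(curve$strain[1], 0)
  expect_equal(curve$stress_pa[1], 0)
  expect_equal(max(curve$stress_pa), 1e5, tolerance = 1e-9)
  # strain normalised by the post-conditioning length
  expect_equal(
    curve$strain[2] - curve$strain[1],
    (rec$displacement_mm[11] - rec$displacement_mm[10]) / 25
  )
  expect_error(engineering_curve(rec, g), "onset")
  expect_error(engineering_curve(rec, g, onset = 500), "range")
})

test_that("synthetic records round-trip to the generating model curve", {
  for (dir in c("circ", "long")) {
    g <- specimen_geometry(dir)
    rec <- generate_load_history(g, test_protocol(), ref)
    curve <- process_record(rec, g)
    expect_lte(max(curve$strain), 0.2)
    model <- predict_curve(ref, curve$strain, dir)
    rel_rms <- sqrt(mean((curve$stress_pa - model$stress_pa)^2)) /
      sqrt(mean(model$stress_pa^2))
    expect_lt(rel_rms, 0.02)
    # zeroing contract: the processed curve passes through the origin
    expect_equal(curve$strain[1], 0)
    expect_equal(curve$stress_pa[1], 0)
  }
})
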