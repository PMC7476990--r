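sine_rec <- function(freq_hz, amp = 1, dur_s = 10, fs = 1000) {
  tt <- seq(0, dur_s, by = 1 / fs)
  egm_recording(
    samples = matrix(rep(amp * sin(2 * pi * freq_hz * tt), each = 16),
                     nrow = 16, byrow = FALSE),
    fs = fs, pacing = pacing_protocol(cycle_length = 1000, n_beats = 2)
  )
}

test_that("preprocessing removes DC and honours the acquisition band", {
  rec <- sine_rec(5)
  rec$samples <- rec$samples + 5  # DC offset
  out <- preprocess(rec)
  expect_lt(abs(mean(out$samples[1, ])), 1e-3)
  # 5 Hz passes with < 1% attenuation (measured mid-signal, away from edges)
  mid <- 2000:8000
  a_in <- diff(range(rec$samples[1, mid]))
  a_out <- diff(range(out$samples[1, mid]))
  expect_gt(a_out / a_in, 0.99)
  # 0.05 Hz is attenuated by > 90%
  slow <- preprocess(sine_rec(0.05, dur_s = 60))
  expect_lt(diff(range(slow$samples[1, 20000:40000])) / 2, 0.1)
  # idempotent on already-filtered in-band signals (30 Hz probe: the 0.3 Hz
  # corner changes such content by < 1e-8 relative per pass)
  inband <- preprocess(sine_rec(30))
  again <- preprocess(inband)
  centre <- 4500:5500  # away from the slow corner's edge transients
  expect_lt(max(abs(again$samples[1, centre] - inband$samples[1, centre])), 1e-6)
  # cannot honour the band below 600 Hz
  bad <- sine_rec(5, fs = 500)
  expect_error(preprocess(bad), "sampling error")
})

test_that("stimulus detection returns metadata verbatim and finds artefacts", {
  cfg <- tiny_config(cycle_length = 750, n_beats = 4)
  study <- simulate_paired_study(cfg, n_sites = 1)
  rec <- preprocess(study$recordings[[1]])
  expect_identical(detect_stimuli(rec), rec$pacing$stimulus_times)

  truth <- rec$pacing$stimulus_times
  found <- detect_stimuli(rec, use_metadata = FALSE)
  expect_length(found, 4)
  expect_true(all(abs(found - truth) <= 1))
  expect_true(all(abs(diff(found) - 750) <= 1))

  # no artefact, no detection
  cfg0 <- tiny_config(stim_amp_mV = 0, noise_sd_mV = 0, wander_amp_mV = 0)
  study0 <- simulate_paired_study(cfg0, n_sites = 1)
  flat <- study0$recordings[[1]]
  flat$samples[] <- 0
  expect_error(detect_stimuli(flat, use_metadata = FALSE), "detection error")
})

test_that("beat segmentation tiles the recording channel by channel", {
  cfg <- tiny_config(cycle_length = 500, n_beats = 4)
  study <- simulate_paired_study(cfg, n_sites = 1)
  rec <- preprocess(study$recordings[[1]])
  beats <- segment_beats(rec, rec$pacing$stimulus_times)
  expect_length(beats, 4 * 16)
  b1 <- beats[vapply(beats, function(b) b$channel == 1, logical(1))]
  lens <- vapply(b1, function(b) length(b$samples), numeric(1))
  # consecutive windows abut: each spans one cycle length of samples
  expect_true(all(abs(lens - 500) <= 1))
  expect_identical(vapply(b1, function(b) b$beat_index, numeric(1)), 1:4 * 1)
})

test_that("landmarks recover a constructed piecewise-linear beat", {
  px <- make_pwl_beat()
  lm <- locate_landmarks(px$beat)
  expect_within(lm$r_t, 40, 1)
  expect_within(lm$r_amp, 3, 1e-9)
  expect_within(lm$s_t, 60, 1)
  expect_within(lm$s_amp, -4, 1e-9)
  expect_gt(lm$act_t, 40); expect_lt(lm$act_t, 60)
  expect_within(lm$onset_t, 30, 1)
  expect_within(lm$q_t, 30, 1)   # monotone rise: Q at onset
  expect_within(lm$end_t, px$end_true, 1)

  f <- extract_features(px$beat)
  expect_within(f$qr_interval, 10, 1)
  expect_within(f$rs_interval, 20, 1e-9)
  expect_within(f$amplitude, 7, 1e-9)
  expect_within(f$rs_gradient, (-4 - 3) / 20, 1e-6)
  expect_identical(f$qs_interval - (f$qr_interval + f$rs_interval), 0)
})

test_that("monophasic and flat beats follow the conventions", {
  # pure negative deflection: R collapses onto onset with near-zero amplitude
  inv <- make_pwl_beat(t_on = 30, t_r = 31, t_s = 60, t_end = 100,
                       r_amp = 0.001, s_amp = -4)
  lm <- locate_landmarks(inv$beat)
  expect_lt(lm$r_amp, 0.1)
  expect_equal(lm$s_amp, -4, tolerance = 1e-9)
  f <- extract_features(inv$beat)
  expect_true(all(is.finite(unlist(f[c("rs_interval", "s_point", "amplitude")]))))

  flat <- make_pwl_beat(r_amp = 0.02, s_amp = -0.03)
  expect_null(locate_landmarks(flat$beat))
  expect_null(extract_features(flat$beat))
})

test_that("downstroke rate and latency are exact on analytic beats", {
  mk <- function(v) structure(
    list(samples = v, fs = 1000, stimulus_ms = 0, channel = 1L,
         beat_index = 1L, heart_id = "T", condition = "BL", site_index = 1L,
         cycle_length = 500), class = "beat_complex")
  # V = -2t mV: constant slope -2 mV/ms
  ramp <- mk(-2 * (0:200))
  lm <- locate_landmarks(ramp)
  expect_equal(dvdt_and_latency(ramp, lm)$dvdt_max, 2, tolerance = 1e-9)
  # 5 Hz unit sine: max -dV/dt = 2*pi*5/1000
  sine <- mk(sin(2 * pi * 5 * (0:400) / 1000))
  lm <- locate_landmarks(sine)
  expect_within(dvdt_and_latency(sine, lm)$dvdt_max, 2 * pi * 5 / 1000, 1e-5)
  # beat constructed with its steepest downstroke 114.8 ms post-stimulus:
  # the fall is steepest on the 114-116 ms segment
  tt <- 0:400
  v <- approx(c(0, 95, 110, 114, 116, 119, 160, 400),
              c(0, 0, 2, 1.2, -2.8, -3.5, 0, 0), xout = tt)$y
  late <- mk(v)
  lmx <- locate_landmarks(late)
  lat <- dvdt_and_latency(late, lmx)$stim_to_dvdt_latency
  expect_within(lat, 114.8, 1)
})

test_that("fractionation counts distinct downstrokes", {
  clean <- make_pwl_beat()
  lm <- locate_landmarks(clean$beat)
  expect_identical(fractionation_index(clean$beat, lm), 1L)

  # one complex descending from R to S in five sharp steps separated by
  # short plateaus: five distinct downstrokes past the 10% threshold
  tt <- 0:200
  v <- approx(c(0, 30, 40, 42, 45, 47, 50, 52, 55, 57, 60, 62, 100, 200),
              c(0, 0, 3, 1.6, 1.6, 0.2, 0.2, -1.2, -1.2, -2.6, -2.6, -4, 0, 0),
              xout = tt)$y
  beat <- structure(
    list(samples = v, fs = 1000, stimulus_ms = 0, channel = 1L,
         beat_index = 1L, heart_id = "T", condition = "BL", site_index = 1L,
         cycle_length = 500), class = "beat_complex")
  lm5 <- locate_landmarks(beat)
  expect_identical(fractionation_index(beat, lm5), 5L)
})

test_that("feature identities and translation equivariance hold", {
  set.seed(31)
  time_feats <- c("onset_t", "q_t", "r_t", "s_t", "end_t", "act_t")
  for (i in 1:25) {
    t_on <- sample(20:40, 1)
    t_r <- t_on + sample(5:20, 1)
    t_s <- t_r + sample(10:30, 1)
    t_end <- t_s + sample(20:50, 1)
    px <- make_pwl_beat(t_on, t_r, t_s, t_end,
                        r_amp = runif(1, 1, 5), s_amp = runif(1, -6, -1),
                        total_ms = t_end + 60)
    f <- extract_features(px$beat)
    expect_identical(f$qs_interval, f$qr_interval + f$rs_interval)
    expect_identical(f$amplitude, f$r_point - f$s_point)
    expect_gte(f$egm_duration, f$qs_interval)
    expect_gte(f$fractionation_index, 1)

    lm <- locate_landmarks(px$beat)
    expect_gte(lm$act_t, lm$r_t); expect_lte(lm$act_t, lm$s_t)

    # rotate the content right by k samples (the tail is resting baseline,
    # so the sample multiset and hence the adaptive thresholds are
    # unchanged): time landmarks shift by k ms, amplitudes do not
    k <- 15
    n <- length(px$beat$samples)
    shifted <- px$beat
    shifted$samples <- c(px$beat$samples[(n - k + 1):n],
                         px$beat$samples[1:(n - k)])
    lm2 <- locate_landmarks(shifted)
    for (nm in time_feats) expect_equal(lm2[[nm]], lm[[nm]] + k)
    f2 <- extract_features(shifted)
    for (nm in c("r_point", "s_point", "amplitude", "rs_gradient",
                 "rs_interval", "qr_interval", "r_width", "s_width")) {
      expect_equal(f2[[nm]], f[[nm]], tolerance = 1e-9)
    }
    expect_equal(f2$stim_to_dvdt_latency, f$stim_to_dvdt_latency + k)
  }
})

test_that("study-level extraction produces the bookkeeping total", {
  cfg <- tiny_config(cycle_length = 500, n_beats = 2)
  study <- simulate_paired_study(cfg, n_sites = 2)
  tbl <- extract_study_features(study)
  # sites x conditions x channels x stimuli, minus any no-complex beats
  expect_lte(nrow(tbl), 2 * 2 * 16 * 2)
  expect_gte(nrow(tbl), 0.9 * 2 * 2 * 16 * 2)
  expect_identical(names(tbl), c(
    "heart_id", "condition", "site_index", "channel", "beat_index",
    "cycle_length", feature_names()))
  # identity suite on every extracted beat
  expect_equal(tbl$qs_interval, tbl$qr_interval + tbl$rs_interval)
  expect_equal(tbl$amplitude, tbl$r_point - tbl$s_point)
  expect_true(all(tbl$egm_duration >= tbl$qs_interval - 1e-9))
  expect_true(all(tbl$fractionation_index >= 1))
  expect_true(all(tbl$dvdt_max >= 0))
})
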