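test_that("velocity field follows the sqrt-coupling law and block floor", {
  cfg <- simulation_config(grid_n = 10, heterogeneity_sd = 0,
                           patch_block_prob = 0)
  f1 <- with_seed_test(1, build_velocity_field(cfg, c = 1))
  expect_true(all(f1 == cfg$base_cv))
  f2 <- with_seed_test(1, build_velocity_field(cfg, c = 0.25))
  expect_true(all(abs(f2 - 0.5 * cfg$base_cv) < 1e-12))

  # seeded generator contract: sqrt(c)-scaled log-normal field with block
  # patches drawn from the same stream, reproduced independently
  cfg2 <- simulation_config(grid_n = 12, heterogeneity_sd = 0.3,
                            patch_block_prob = 0.1, patch_radius_mm = 0)
  got <- with_seed_test(99, build_velocity_field(cfg2, c = 0.5))
  set.seed(99)
  g <- matrix(rnorm(144), 12, 12); u <- matrix(runif(144), 12, 12)
  want <- cfg2$base_cv * sqrt(0.5) * exp(0.3 * g)
  want[u < 0.1] <- cfg2$cv_floor
  expect_equal(unclass(got), want, ignore_attr = TRUE)
  expect_true(all(got > 0))
})

test_that("activation map is exact on analytic cases", {
  uni <- matrix(1, 3, 3)
  act <- compute_activation_map(uni, pacing_node = c(1, 1), dx = 1)
  expect_identical(act$times[1, 1], 0)
  expect_equal(act$times[3, 3], 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(act$times[1, 3], 2, tolerance = 1e-12)
  # halving velocity doubles every activation time
  act2 <- compute_activation_map(uni / 2, pacing_node = c(1, 1), dx = 1)
  expect_equal(act2$times, 2 * act$times, tolerance = 1e-12)
  expect_error(compute_activation_map(uni, pacing_node = c(4, 1), dx = 1),
               "index error")
})

test_that("activation map equals the brute-force relaxation oracle", {
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    field <- matrix(exp(rnorm(n * n, sd = 0.5)), n, n) * 0.6
    field[sample(n * n, 2)] <- 1e-3
    pace <- c(sample(n, 1), sample(n, 1))
    got <- compute_activation_map(field, pacing_node = pace, dx = 0.5)
    want <- bf_activation_times(field, pace, dx = 0.5)
    expect_equal(got$times, want, tolerance = 1e-10)
  }
})

test_that("action-potential template rests, rises, and repolarizes", {
  expect_identical(ap_waveform(-5), -80)
  expect_identical(ap_waveform(0), -80)
  expect_equal(ap_waveform(250 + 100), -80)
  # plateau near rest + amplitude
  expect_gt(ap_waveform(50), 15)
  # maximal upstroke rate lies in the upstroke window and scales as 1/tau
  tt <- seq(0, 30, by = 0.01)
  for (tau in c(2, 5, 10)) {
    d <- ap_dvdt(tt, upstroke_tau = tau)
    expect_lt(tt[which.max(d)], tau)
    expect_gt(tt[which.max(d)], 0)
  }
  r5 <- max(ap_dvdt(tt, upstroke_tau = 5))
  r10 <- max(ap_dvdt(tt, upstroke_tau = 10))
  expect_equal(r5 / r10, 2, tolerance = 1e-6)
  # analytic derivative matches numeric differentiation of the waveform
  h <- 1e-4
  ts <- c(1, 3, 7, 120, 160, 200, 240)
  num <- (ap_waveform(ts + h) - ap_waveform(ts - h)) / (2 * h)
  expect_equal(ap_dvdt(ts), num, tolerance = 1e-5)
})

test_that("forward model cancels synchronous activation and is monotone in height", {
  cfg <- tiny_config()
  sync <- structure(list(times = matrix(5, cfg$grid_n, cfg$grid_n),
                         pacing_node = c(1L, 1L)), class = "activation_map")
  sync$times[1, 1] <- 5  # truly simultaneous everywhere
  grid <- electrode_grid(origin = c(4, 4), height = 0.5)
  rec <- forward_egm(sync, grid, cfg)
  expect_lt(max(abs(rec$samples)), 1e-9)

  uni <- matrix(cfg$base_cv, cfg$grid_n, cfg$grid_n)
  act <- compute_activation_map(uni, c(1L, 1L), cfg$dx)
  rec1 <- forward_egm(act, grid, cfg)
  p2p1 <- mean(apply(rec1$samples, 1, function(x) diff(range(x))))
  grid2 <- electrode_grid(origin = c(4, 4), height = 1)
  rec2 <- forward_egm(act, grid2, cfg)
  p2p2 <- mean(apply(rec2$samples, 1, function(x) diff(range(x))))
  expect_lt(p2p2, p2p1)
  expect_error(forward_egm(act, electrode_grid(origin = c(4, 4), height = 0),
                           cfg), "singularity")
})

test_that("a passing plane wave yields an R deflection before the S deflection", {
  cfg <- tiny_config()
  n <- cfg$grid_n
  # plane wave along x: activation time depends on column only
  times <- matrix(rep((seq_len(n) - 1) * cfg$dx / cfg$base_cv, each = n), n, n)
  act <- structure(list(times = times, pacing_node = c(1L, 1L)),
                   class = "activation_map")
  centre <- (n - 1) * cfg$dx / 2
  grid <- electrode_grid(rows = 1, cols = 1, origin = c(centre, centre),
                         height = 0.5)
  rec <- forward_egm(act, grid, cfg)
  v <- rec$samples[1, 1:(cfg$cycle_length - 1)]
  r_i <- which.max(v); s_i <- which.min(v)
  expect_gt(max(v), 0)
  expect_lt(min(v), 0)
  expect_lt(r_i, s_i)  # positive deflection precedes the negative one
})

test_that("latency orders with electrode distance and coupling factor", {
  cfg <- tiny_config(noise_sd_mV = 0, wander_amp_mV = 0, stim_amp_mV = 0)
  uni <- matrix(cfg$base_cv, cfg$grid_n, cfg$grid_n)
  act <- compute_activation_map(uni, c(1L, 1L), cfg$dx)
  grid <- electrode_grid(origin = c(2, 2), height = 0.5)
  rec <- forward_egm(act, grid, cfg)
  tbl <- extract_study_features(list(rec))
  lat <- tapply(tbl$stim_to_dvdt_latency, tbl$channel, mean)
  # channel 1 is the origin corner (nearest the pacing node), channel 16 the
  # farthest electrode
  expect_lt(lat["1"], lat["16"])

  lat_c <- vapply(c(0.3, 0.6, 1), function(cc) {
    a <- compute_activation_map(uni * sqrt(cc) / 1, c(1L, 1L), cfg$dx)
    r <- forward_egm(a, grid, cfg, upstroke_tau = cfg$upstroke_tau / sqrt(cc),
                     coupling = cc)
    t <- extract_study_features(list(r))
    mean(t$stim_to_dvdt_latency)
  }, numeric(1))
  expect_true(all(diff(lat_c) <= 0))  # latency non-increasing in coupling
})

test_that("artifacts and noise match their construction", {
  cfg <- tiny_config(noise_sd_mV = 0, wander_amp_mV = 0, stim_amp_mV = 0)
  uni <- matrix(cfg$base_cv, cfg$grid_n, cfg$grid_n)
  act <- compute_activation_map(uni, c(1L, 1L), cfg$dx)
  grid <- electrode_grid(origin = c(2, 2), height = 0.5)
  rec <- forward_egm(act, grid, cfg)
  same <- with_seed_test(1, add_artifacts_and_noise(rec, cfg))
  expect_identical(same$samples, rec$samples)

  cfg10 <- tiny_config(noise_sd_mV = 0, wander_amp_mV = 0, stim_amp_mV = 10)
  spiked <- with_seed_test(1, add_artifacts_and_noise(rec, cfg10))
  i0 <- round(rec$pacing$stimulus_times[1] * rec$fs / 1000) + 1L
  expect_equal(spiked$samples[, i0] - rec$samples[, i0], rep(10, 16))
  expect_equal(spiked$samples[, i0 + 1] - rec$samples[, i0 + 1], rep(-10, 16))

  cfgn <- tiny_config(noise_sd_mV = 0.05, wander_amp_mV = 0, stim_amp_mV = 0)
  big <- rec
  big$samples <- matrix(0, 16, 62500)  # 1e6 samples
  noisy <- with_seed_test(2, add_artifacts_and_noise(big, cfgn))
  expect_equal(sd(noisy$samples - big$samples), 0.05, tolerance = 0.01)
})

test_that("dose-to-coupling mapping has Hill-curve anchors", {
  expect_identical(dose_to_coupling(0), 1)
  expect_equal(dose_to_coupling(25, c_drug = 0.35, d50_ml = 25),
               1 - (1 - 0.35) / 2)
  cc <- dose_to_coupling(seq(0, 50, 5))
  expect_true(all(diff(cc) <= 0))
  expect_error(dose_to_coupling(-1), "dose_ml")
})

test_that("paired study has the 16 x 2 layout with region-dependent APD", {
  cfg <- tiny_config()
  study <- simulate_paired_study(cfg, n_sites = 16)
  expect_length(study$recordings, 32)
  conds <- vapply(study$recordings, function(r) r$condition, character(1))
  expect_identical(sum(conds == "BL"), 16L)
  expect_identical(sum(conds == "CBX"), 16L)
  regions <- vapply(study$recordings, function(r) r$region, character(1))
  sites <- vapply(study$recordings, function(r) r$site_index, integer(1))
  expect_true(all(regions[sites <= 12] == "LV"))
  expect_true(all(regions[sites >= 13] == "LA"))
  for (r in study$recordings) expect_silent(validate_recording(r))
  # identical electrode placement within a site pair
  for (s in c(1, 13)) {
    pair <- study$recordings[sites == s]
    expect_identical(pair[[1]]$grid, pair[[2]]$grid)
    expect_identical(pair[[1]]$pacing, pair[[2]]$pacing)
  }
})

test_that("identical seeds reproduce a study byte for byte", {
  cfg <- tiny_config()
  s1 <- simulate_paired_study(cfg, seed = 7, n_sites = 2)
  s2 <- simulate_paired_study(cfg, seed = 7, n_sites = 2)
  d <- withr::local_tempdir()
  write_recording(s1$recordings[[4]], file.path(d, "a.csv"))
  write_recording(s2$recordings[[4]], file.path(d, "b.csv"))
  expect_same_file(file.path(d, "a.csv"), file.path(d, "b.csv"))
})

test_that("a conduction-block patch splits the complex recorded above it", {
  cfg <- simulation_config(grid_n = 60, noise_sd_mV = 0, wander_amp_mV = 0,
                           stim_amp_mV = 0, cycle_length = 500, n_beats = 1)
  n <- cfg$grid_n
  uni <- matrix(cfg$base_cv, n, n)
  blocked <- uni
  for (i in 1:n) {
    for (j in 1:n) {
      if ((i - 30)^2 + (j - 30)^2 <= 16) blocked[i, j] <- cfg$cv_floor
    }
  }
  # single electrode directly over the disc; wave paced from the corner
  grid1 <- electrode_grid(rows = 1, cols = 1, origin = c(14.5, 14.5),
                          height = 0.5)
  frac <- vapply(list(uni, blocked), function(f) {
    act <- compute_activation_map(f, c(1L, 1L), cfg$dx)
    tbl <- extract_study_features(list(forward_egm(act, grid1, cfg)))
    tbl$fractionation_index
  }, numeric(1))
  expect_identical(frac[1], 1)  # smooth passage: one downstroke
  expect_gte(frac[2], 2)        # split around the obstacle: several
})

test_that("structured tissue raises seed-averaged fractionation over homogeneous", {
  frac_for <- function(sd, pblk) {
    mean(vapply(1:3, function(s) {
      cfg <- tiny_config(grid_n = 40L, noise_sd_mV = 0, wander_amp_mV = 0,
                         heterogeneity_sd = sd, patch_block_prob = pblk)
      st <- simulate_paired_study(cfg, seed = s, n_sites = 2)
      tbl <- extract_study_features(st)
      mean(tbl$fractionation_index[tbl$condition == "CBX"])
    }, numeric(1)))
  }
  f0 <- frac_for(0, 0)
  expect_gt(frac_for(0.3, 0.04), f0)
  expect_gt(frac_for(0.6, 0.08), f0)
})

test_that("dose series is one recording per dose on frozen tissue", {
  cfg <- tiny_config(noise_sd_mV = 0, wander_amp_mV = 0)
  doses <- seq(0, 50, by = 10)
  ser <- simulate_dose_response(cfg, doses_ml = doses, seed = 3)
  expect_length(ser$recordings, length(doses))
  expect_equal(ser$coupling, dose_to_coupling(doses, cfg$c_drug,
                                              cfg$d50_ml, cfg$hill))
  expect_identical(ser$recordings[[1]]$condition, "BL")
  expect_identical(ser$recordings[[3]]$dose_ml, 20)
  # same catheter placement at every dose
  grids <- lapply(ser$recordings, function(r) r$grid)
  for (g in grids[-1]) expect_identical(g, grids[[1]])
  # noise-free latency is non-decreasing with dose
  dl <- dose_latency_summary(ser)
  expect_true(all(diff(dl$latency_mean) >= -1e-9))
})
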