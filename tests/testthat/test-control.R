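# Closed-loop targeting (strain localization, iterative correction) and
# closed-loop dosing (thermometry estimators, threshold controller).

make_blob <- function(center = c(2, -1, 3), axis45 = FALSE, n = 48, vs = 1) {
  ax <- (seq_len(n) - 0.5) * vs - n * vs / 2
  g <- expand.grid(x = ax, y = ax, z = ax)
  if (axis45) {
    u <- (g$x - center[1] + g$z - center[3]) / sqrt(2)   # along (1,0,1)
    v1 <- (g$x - center[1] - (g$z - center[3])) / sqrt(2)
    dT <- 8 * exp(-(v1^2 + (g$y - center[2])^2) / (2 * 1.5^2) - u^2 / (2 * 6^2))
  } else {
    dT <- 8 * exp(-((g$x - center[1])^2 + (g$y - center[2])^2) / (2 * 1.5^2) -
                    (g$z - center[3])^2 / (2 * 6^2))
  }
  list(dT = array(dT, c(n, n, n)), origin = rep(-n * vs / 2, 3), vs = vs)
}

test_that("strain volumes are noise-only at zero temperature and localize blobs", {
  z <- simulate_strain_volume(array(0, c(10, 10, 10)), noise_sd = 1e-4, seed = 3)
  expect_lt(abs(mean(z)), 1e-4)
  b <- make_blob()
  sv <- simulate_strain_volume(b$dT, noise_sd = 0)
  fx <- localize_focus(sv, 0.0012 * 1, b$vs, b$origin)
  expect_false(is_no_fix(fx))
  expect_lt(dbacsim:::vnorm(fx$focus - c(2, -1, 3)), 1.5)
})

test_that("noise-only strain volumes give a no-fix outcome", {
  sv <- simulate_strain_volume(array(0, c(20, 20, 20)), noise_sd = 1e-4,
                               seed = 5)
  expect_true(is_no_fix(localize_focus(sv, 0.05, 1, c(-10, -10, -10))))
})

test_that("the fitted beam axis is accurate and robust to hot outliers", {
  b <- make_blob(axis45 = TRUE)
  sv <- simulate_strain_volume(b$dT, noise_sd = 0)
  fx <- localize_focus(sv, 0.0012, b$vs, b$origin)
  ang <- acos(abs(sum(fx$axis_dir * c(1, 0, 1) / sqrt(2)))) * 180 / pi
  expect_lt(ang, 1)
  # a single bright off-axis voxel barely moves the weighted fit
  sv2 <- sv
  sv2[5, 40, 5] <- max(sv) * 1.2
  fx2 <- localize_focus(sv2, 0.0012, b$vs, b$origin)
  ang2 <- acos(abs(sum(fx2$axis_dir * c(1, 0, 1) / sqrt(2)))) * 180 / pi
  expect_lt(ang2, 2)
})

test_that("strain-peak localization stays within 1 mm at moderate noise", {
  b <- make_blob()
  errs <- vapply(1:50, function(s) {
    sv <- simulate_strain_volume(b$dT, noise_sd = 0.0012 * 0.8,
                                 noise_corr_vox = 2, seed = s)
    fx <- localize_focus(sv, 0.0012 * 2, b$vs, b$origin)
    if (is_no_fix(fx)) return(NA_real_)
    dbacsim:::vnorm(fx$focus - c(2, -1, 3))
  }, 0)
  expect_lt(mean(errs, na.rm = TRUE), 1)
})

test_that("iterative correction converges injected offsets to the tolerance", {
  plan <- list(tiles = lapply(1:6, function(i) list(id = i)))
  fixes <- correct_targeting(plan, c(0, 0, 0), initial_offsets = 5,
                             max_iter = 5, noise_sd_mm = 0.5, seed = 7)
  for (f in fixes) {
    expect_true(f$converged)
    expect_lt(f$final_offset_mm, 3)
  }
  # zero injected offset converges on the first measurement, uncorrected
  z <- correct_targeting(plan, c(0, 0, 0),
                         initial_offsets = matrix(0, 6, 3),
                         max_iter = 5, noise_sd_mm = 0.1, seed = 8)
  for (f in z) {
    expect_true(f$converged)
    expect_equal(f$final_offset_mm, 0)
    expect_length(f$offsets, 1)
  }
})

test_that("noiseless correction contracts the offset monotonically", {
  plan <- list(tiles = list(list(id = 1)))
  f <- correct_targeting(plan, c(0, 0, 0),
                         initial_offsets = matrix(c(8, 0, 0), 1),
                         max_iter = 5, noise_sd_mm = 0, seed = 1)[[1]]
  expect_true(f$converged)
  expect_true(all(diff(f$offsets) < 0))
  expect_equal(f$final_offset_mm, 0, tolerance = 1e-12)
})

test_that("more correction iterations never reduce the convergence rate", {
  plan <- list(tiles = list(list(id = 1)))
  rate <- function(iters) mean(vapply(1:100, function(s) {
    correct_targeting(plan, c(0, 0, 0), initial_offsets = 3 + (s %% 8),
                      max_iter = iters, noise_sd_mm = 0.5,
                      seed = s)[[1]]$converged
  }, TRUE))
  expect_gte(rate(5), rate(3))
})

test_that("the strain-volume measurement route also converges", {
  plan <- list(tiles = list(list(id = 1)))
  f <- correct_targeting(plan, c(0, 0, 0),
                         initial_offsets = matrix(c(5, 2, 0), 1),
                         max_iter = 5, noise_sd_mm = 0.3, seed = 3,
                         measure = "strain")[[1]]
  expect_true(f$converged)
  expect_lt(f$final_offset_mm, 3)
})

test_that("feature streams are at baseline without heating and reproducible", {
  s0 <- simulate_features(rep(0, 20), 0, seed = 4)
  expect_equal(max(abs(s0$features[, "strain"])), 0, tolerance = 1e-4)
  expect_equal(max(abs(s0$features[, "displacement"])), 0)
  expect_gt(min(s0$features[, "correlation"]), 0.9)
  expect_identical(simulate_features(1:10, 1, seed = 9)$features,
                   simulate_features(1:10, 1, seed = 9)$features)
})

test_that("apparent strain saturates so a linear readout under-reads high dT", {
  ramp <- seq(0, 30, length.out = 61)
  st <- simulate_features(ramp, 1, noise_sd = 0, seed = 1)
  lin <- st$features[, "strain"] / st$lambda_true
  expect_gte(1 - lin[61] / 30, 0.20)
})

test_that("TSI is exact on unsaturated data and divides strain by lambda", {
  cfg <- thermometry_config("TSI")
  st <- simulate_features(seq(0, 8, length.out = 20), 1, noise_sd = 0, seed = 1)
  expect_equal(estimate_temperature(st, cfg), st$dT, tolerance = 1e-9)
  st2 <- st
  st2$features[, "strain"] <- 0.012
  expect_equal(estimate_temperature(st2, cfg), rep(10, 20))
})

test_that("TSI is unbiased below 5 degrees on lightly noisy data", {
  cfg <- thermometry_config("TSI")
  maes <- vapply(1:20, function(s) {
    dT <- seq(0, 5, length.out = 30)
    st <- simulate_features(dT, 0.2, noise_sd = 0.02, seed = 100 + s)
    mean(abs(estimate_temperature(st, cfg) - dT))
  }, 0)
  expect_lt(mean(maes), 0.5)
})

test_that("estimator training is deterministic and accurate on easy data", {
  e1 <- train_estimator(n_streams = 60, seed = 5, noise_sd = 0,
                        lambda_jitter = 0)
  e2 <- train_estimator(n_streams = 60, seed = 5, noise_sd = 0,
                        lambda_jitter = 0)
  expect_identical(e1$beta, e2$beta)
  expect_lt(e1$report$heldout_mae[["overall"]], 0.5)
  expect_true(all(c("band_0_10", "band_11_30") %in%
                    names(e1$report$heldout_mae)))
  expect_error(thermometry_config("RNN"), "trained")
})

test_that("the recurrent estimator beats TSI on held-out hot streams", {
  est <- train_estimator(n_streams = 200, seed = 2)
  cfg_r <- thermometry_config("RNN", estimator = est)
  cfg_t <- thermometry_config("TSI")
  rng <- dbacsim:::local_rng(77)
  dr <- dt_ <- numeric(0)
  for (i in 1:25) {
    A <- rng$runif(1, 12, 32); tau <- rng$runif(1, 8, 25)
    dT <- A * (1 - exp(-(0:59) * 0.5 / tau))
    st <- simulate_features(dT, A / 30, seed = 500 + i)
    hi <- dT > 10
    dr <- c(dr, abs(estimate_temperature(st, cfg_r)[hi] - dT[hi]))
    dt_ <- c(dt_, abs(estimate_temperature(st, cfg_t)[hi] - dT[hi]))
  }
  expect_lt(mean(dr), mean(dt_))
})

test_that("the dose controller shuts off at threshold and respects the time limit", {
  ph <- make_limb_phantom(15, 0, 0, seed = 1, n_bones = 0)
  cf <- fx_cuff15()
  target <- c(0, 0, 0)
  cands <- available_tiles(cf, ph, target)
  plan <- select_tile_group(cands, target, minTx = 3, maxTx = 3,
                            Q_0_w = 30, tissue = ph$tissue, depth_cm = 7.5)
  g <- grid_around(target, 10, 1)
  dep <- deposition_from_plan(plan, ph, g)
  cfg <- thermometry_config("TSI")
  rec <- dose_controller(plan, ph, dep, cfg, dT_threshold = 5, seed = 3)
  expect_identical(rec$shutoff_cause, "threshold")
  expect_lt(rec$t_dose_s, 30)
  rec_inf <- dose_controller(plan, ph, dep, cfg, dT_threshold = Inf, seed = 3)
  expect_identical(rec_inf$shutoff_cause, "time-limit")
  expect_equal(rec_inf$t_dose_s, 30)
  for (r in list(rec, rec_inf)) expect_lte(r$t_dose_s, 30)
  fixture_env$controller <- list(ph = ph, plan = plan, g = g, cfg = cfg)
})

test_that("a cold vessel lumen inside the MTV biases shut-off late", {
  ph <- make_limb_phantom(15, 2, 1, seed = 4, length_cm = 8, n_bones = 0)
  tc <- ph$vessel_tree$tc_markers[[1]]$point
  cf <- fx_cuff15()
  cands <- available_tiles(cf, ph, tc)
  plan <- select_tile_group(cands, tc, minTx = 3, maxTx = 3, Q_0_w = 30,
                            tissue = ph$tissue,
                            depth_cm = dbacsim:::point_depth_mm(ph, tc) / 10)
  dep <- deposition_from_plan(plan, ph, grid_around(tc, 10, 1))
  cfg <- thermometry_config("TSI")
  warm <- dose_controller(plan, ph, dep, cfg, dT_threshold = 5,
                          lumen_sink = FALSE, seed = 3)
  cold <- dose_controller(plan, ph, dep, cfg, dT_threshold = 5,
                          lumen_sink = TRUE, seed = 3)
  expect_identical(cold$shutoff_cause, "threshold")
  expect_gt(cold$true_peak_mtv_c, cold$threshold_c)     # wall overshoots
  expect_gte(cold$t_dose_s, warm$t_dose_s)              # sink delays trip
  expect_gt(cold$true_peak_mtv_c, warm$true_peak_mtv_c)
})
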