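# Time-of-flight simulation, multilateration pose recovery and
# registration error reporting.

fx_tof <- function() fixture("tof", function() {
  ph <- make_limb_phantom(25, 1, 0, seed = 1, length_cm = 10, n_bones = 0)
  nom <- build_cuff(7, 25)
  truth <- perturb_cuff(nom, 2, 1, seed = 11)
  list(ph = ph, nom = nom, truth = truth)
})

test_that("homogeneous-medium arrival times equal distance over speed", {
  fx <- fx_tof()
  ph <- fx$ph
  ph$tissue$sound_speed <- 1480               # match the water jacket
  tof <- simulate_tof(fx$truth, ph, jitter_sd_s = 0, c_water_m_s = 1480)
  sa <- dbacsim:::cuff_sub_apertures(fx$truth)
  i <- sample(nrow(tof$pairs), 20)
  d <- sqrt(rowSums((sa$pos[tof$pairs$emitter[i], ] -
                       sa$pos[tof$pairs$receiver[i], ])^2))
  expect_equal(tof$pairs$t_s[i], d / (1480 * 1000), tolerance = 1e-12)
})

test_that("bone-occluded sub-aperture pairs are dropped", {
  fx <- fx_tof()
  ph <- fx$ph
  free <- simulate_tof(fx$truth, ph, jitter_sd_s = 0)
  ph$bones <- list(list(center = c(0, 0, 0), axis = c(0, 0, 1),
                        radius_mm = 30))
  blocked <- simulate_tof(fx$truth, ph, jitter_sd_s = 0)
  expect_lt(nrow(blocked$pairs), nrow(free$pairs))
})

test_that("the noiseless solve recovers poses, speeds and the side count", {
  fx <- fx_tof()
  tof0 <- simulate_tof(fx$truth, fx$ph, jitter_sd_s = 0, seed = 5)
  est0 <- solve_poses(tof0, fx$nom)
  err0 <- registration_error(est0, fx$truth)
  expect_lt(err0$max_position_err_mm, 0.5)
  expect_lt(err0$median_ixtx_dist_err_mm, 0.2)
  expect_equal(est0$side_count, 7L)
  expect_lt(abs(est0$c_tissue - fx$ph$tissue$sound_speed), 1)
  expect_lt(abs(est0$c_water - 1480), 1)
})

test_that("at one-period jitter the registration meets its accuracy envelope", {
  fx <- fx_tof()
  tof <- simulate_tof(fx$truth, fx$ph, jitter_sd_s = 0.4e-6, seed = 5)
  est <- solve_poses(tof, fx$nom)
  fixture_env$tof_solved <- list(est = est, truth = fx$truth, tof = tof)
  err <- registration_error(est, fx$truth)
  expect_lte(err$median_ixtx_dist_err_mm, 2)
  expect_lte(err$median_tx_normal_err_deg, 0.5)
  expect_lt(abs(est$c_tissue - fx$ph$tissue$sound_speed), 5)
  # residual statistics reflect the injected jitter
  expect_lt(abs(est$rms_residual_s / 0.4e-6 - 1), 0.25)
})

test_that("registration errors are gauge invariant and zero on self", {
  sol <- fixture_env$tof_solved
  est <- sol$est
  shifted <- est
  shifted$arrays <- lapply(est$arrays, function(a) {
    a$center <- a$center + c(30, -12, 5); a
  })
  e1 <- registration_error(est, sol$truth)
  e2 <- registration_error(shifted, sol$truth)
  expect_equal(e1$max_position_err_mm, e2$max_position_err_mm,
               tolerance = 1e-9)
  expect_equal(e1$median_ixtx_dist_err_mm, e2$median_ixtx_dist_err_mm,
               tolerance = 1e-9)
  # est == truth gives zero errors
  self <- est
  self$arrays <- c(lapply(sol$truth$tiles, function(t)
    list(kind = "tx", id = t$id, center = t$center, normal = t$normal)),
    lapply(sol$truth$probes, function(p)
      list(kind = "ix", id = p$id, center = p$center, normal = p$normal)))
  e0 <- registration_error(self, sol$truth)
  expect_lt(e0$max_position_err_mm, 1e-9)
  expect_lt(e0$max_normal_err_deg, 1e-4)
})

test_that("estimated pairwise distances satisfy the triangle inequality", {
  X <- fixture_env$tof_solved$est$sub_positions
  idx <- matrix(sample(nrow(X), 60, replace = TRUE), ncol = 3)
  for (r in seq_len(nrow(idx))) {
    a <- X[idx[r, 1], ]; b <- X[idx[r, 2], ]; cc <- X[idx[r, 3], ]
    expect_lte(dbacsim:::vnorm(a - b),
               dbacsim:::vnorm(a - cc) + dbacsim:::vnorm(cc - b) + 1e-9)
  }
})

test_that("position error grows with timing jitter", {
  fx <- fx_tof()
  err_at <- function(j) {
    tof <- simulate_tof(fx$truth, fx$ph, jitter_sd_s = j, seed = 9)
    registration_error(solve_poses(tof, fx$nom), fx$truth)$median_position_err_mm
  }
  expect_lt(err_at(0), err_at(1e-6))
})

test_that("a degraded cuff still identifies seven panels within 1 cm", {
  fx <- fx_tof()
  truth_d <- remove_arrays(fx$truth, tile_ids = 21, probe_ids = 6)
  nom_d <- remove_arrays(fx$nom, tile_ids = 21, probe_ids = 6)
  tof_d <- simulate_tof(truth_d, fx$ph, jitter_sd_s = 0.4e-6, seed = 6)
  est_d <- solve_poses(tof_d, nom_d)
  expect_equal(est_d$side_count, 7L)
  err_d <- registration_error(est_d, truth_d)
  expect_lte(err_d$max_position_err_mm, 10)
})

test_that("under-determined geometries are rejected with a diagnostic", {
  fx <- fx_tof()
  tof <- simulate_tof(fx$truth, fx$ph, jitter_sd_s = 0, seed = 2)
  starved <- tof
  keep <- starved$pairs$emitter > 3            # strip point 1-3 measurements
  starved$pairs <- starved$pairs[keep & starved$pairs$receiver > 3, ]
  expect_error(solve_poses(starved, fx$nom), "under-determined")
})

test_that("ToF CSV export uses the emitter,receiver,t_s contract", {
  fx <- fx_tof()
  tof <- simulate_tof(fx$truth, fx$ph, jitter_sd_s = 0, seed = 2)
  p <- withr::local_tempfile(fileext = ".csv")
  write_tof_csv(tof, p)
  d <- utils::read.csv(p)
  expect_identical(names(d), c("emitter", "receiver", "t_s"))
  expect_equal(nrow(d), nrow(tof$pairs))
})
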