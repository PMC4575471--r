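# Phased-array beam fields, side lobes and deposition maps.

test_that("the unsteered rectangular aperture shows the sinc-squared first side lobe", {
  cf <- build_cuff(7, 25)
  tl <- cf$tiles[[2]]
  focus <- tl$center + tl$normal * 100
  xs <- seq(-15, 15, by = 0.05)
  line <- t(vapply(xs, function(x) focus + x * tl$u, numeric(3)))
  v <- beam_field(tl, focus, line)
  expect_equal(max(v), v[which.min(abs(xs))], tolerance = 1e-6)
  pk <- which.max(v)
  dv <- diff(v)
  locmax <- which(diff(sign(dv)) < 0) + 1
  side <- locmax[abs(xs[locmax]) > 1]
  lobe_db <- 10 * log10(max(v[side]))
  expect_lt(abs(lobe_db - (-13.26)), 1)
})

test_that("focal 3-dB widths track f-number times wavelength within 15%", {
  cf <- build_cuff(7, 25)
  tl <- cf$tiles[[2]]
  lambda <- 1.515
  for (rng in c(52, 130)) {          # f# 1 and 2.5
    focus <- tl$center + tl$normal * rng
    xs <- seq(-6, 6, by = 0.02)
    line <- t(vapply(xs, function(x) focus + x * tl$u, numeric(3)))
    v <- beam_field(tl, focus, line)
    w <- diff(range(xs[v >= 0.5]))
    fn <- rng / 52
    expect_lt(abs(w / (fn * lambda) - 1), 0.15)
    expect_gt(w, 1.0); expect_lt(w, 3.9)
  }
})

test_that("steering beyond the tile limits is rejected", {
  cf <- build_cuff(7, 25)
  tl <- cf$tiles[[2]]
  bad <- tl$center + 50 * tl$normal + 150 * tl$u  # ~72 deg azimuth
  expect_error(beam_field(tl, bad, matrix(0, 1, 3)), "steering")
})

test_that("sidelobe_ratio reports the floor for a delta field", {
  g <- grid_around(c(0, 0, 0), 5, 1)
  f <- array(0, g$dims); f[6, 6, 6] <- 1
  expect_equal(sidelobe_ratio(f, g, c(0, 0, 0), 3), -100)
})

test_that("deposition conserves the planned absorbed power in the MTV", {
  ph <- make_limb_phantom(15, 0, 0, seed = 1, n_bones = 0)
  cf <- fx_cuff15()
  target <- c(0, 0, 0)
  cands <- available_tiles(cf, ph, target)
  plan <- select_tile_group(cands, target, minTx = 3, maxTx = 3,
                            tissue = ph$tissue, depth_cm = 7.5)
  g <- grid_around(target, 14, 1)
  dep <- deposition_from_plan(plan, ph, g)
  fixture_env$dep15 <- list(ph = ph, plan = plan, g = g, dep = dep)
  expect_lt(abs(dbacsim:::absorbed_in_sphere(dep, target, 8) /
                  plan$total_absorbed_w - 1), 0.05)
  expect_true(all(dep$q >= 0))
  # energy bookkeeping: domain absorption cannot exceed emission
  tot <- sum(dep$q) * (dep$voxel_size / 10)^3
  expect_lt(tot, sum(plan$powers_w))
})

test_that("a zero-power plan deposits nothing", {
  fx <- fixture_env$dep15
  plan0 <- fx$plan
  plan0$Q_equalized_w <- 0
  dep0 <- deposition_from_plan(plan0, fx$ph, grid_around(c(0, 0, 0), 8, 2))
  expect_equal(max(dep0$q), 0)
})

test_that("a symmetric 4-tile on-axis plan gives a 90-degree symmetric map", {
  ph <- make_limb_phantom(15, 0, 0, seed = 1, n_bones = 0)
  cf <- build_cuff(4, 15)
  target <- c(0, 0, 0)
  cands <- available_tiles(cf, ph, target)
  ctr <- vapply(cands, function(cc) abs(cc$tile$center[3]) < 1e-6, TRUE)
  plan <- select_tile_group(cands[ctr], target, minTx = 4, maxTx = 4,
                            tissue = ph$tissue, depth_cm = 7.5)
  plan$dither$points <- plan$dither$points[1, , drop = FALSE]  # undithered
  g <- grid_around(target, 10, 1)
  dep <- deposition_from_plan(plan, ph, g)
  rot <- aperm(dep$q[dim(dep$q)[1]:1, , , drop = FALSE], c(2, 1, 3))
  expect_lt(max(abs(rot - dep$q)) / max(dep$q), 0.05)
})

test_that("tissue path attenuation is direction-symmetric", {
  p <- c(-85, 0, 0); q <- c(60, 20, 10)
  a <- dbacsim:::tissue_path_mm(p, matrix(q, 1), 75)
  b <- dbacsim:::tissue_path_mm(q, matrix(p, 1), 75)
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("per-tile emission under the cap keeps nominal skin intensity within the limit", {
  cf <- fx_cuff15()
  for (w in c(0.3, 1)) {
    p_tile <- w * cf$tile_power_cap_w
    expect_lte(p_tile / dbacsim:::TILE_APERTURE_CM2,
               dbac_requirements()$skin_intensity_limit_w_cm2 + 1e-9)
  }
})
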