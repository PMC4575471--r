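# Tile availability, transport efficiency, absorbed power, group
# selection with power equalization, and dither patterns.

test_that("an on-axis target in a bone-free 7-panel cuff sees all 21 tiles", {
  ph <- make_limb_phantom(25, 1, 0, seed = 1, length_cm = 10, n_bones = 0)
  cf <- build_cuff(7, 25)
  cands <- available_tiles(cf, ph, c(0, 0, 0))
  expect_length(cands, 21)
  expect_true(all(!vapply(cands, `[[`, TRUE, "obstructed")))
})

test_that("bones and steering limits exclude tiles", {
  ph <- make_limb_phantom(25, 1, 0, seed = 1, length_cm = 10, n_bones = 0)
  cf <- build_cuff(7, 25)
  # bone across panel 1's line of sight to the center
  t1 <- cf$tiles[[2]]
  ph$bones <- list(list(center = t1$center * 0.4, axis = c(0, 0, 1),
                        radius_mm = 10))
  cands <- available_tiles(cf, ph, c(0, 0, 0))
  expect_lt(length(cands), 21)
  expect_false(any(vapply(cands, function(cc) cc$tile$panel, 0) == 1 &
                     abs(vapply(cands, `[[`, 0, "az_deg")) < 5 &
                     abs(vapply(cands, `[[`, 0, "el_deg")) < 5))
  # an extreme off-axis target exceeds elevation steering for distant tiles
  ph2 <- make_limb_phantom(25, 1, 0, seed = 1, length_cm = 30, n_bones = 0)
  cands2 <- available_tiles(cf, ph2, c(0, 0, 130))
  expect_lt(length(cands2), 21)
})

test_that("transport efficiency has the closed attenuation form and monotone steering", {
  cand0 <- list(az_deg = 0, el_deg = 0, tissue_cm = 0)
  expect_equal(transport_efficiency(cand0), 0.5)
  ts <- tissue_properties(attenuation_np_cm = 0.05)
  cand <- list(az_deg = 0, el_deg = 0, tissue_cm = 10)
  expect_equal(transport_efficiency(cand, 1, ts), 0.5 * exp(-1))
  etas <- vapply(c(0, 15, 30, 45, 60), function(a)
    transport_efficiency(list(az_deg = a, el_deg = 0, tissue_cm = 5)), 0)
  expect_true(all(diff(etas) < 0))
})

test_that("absorbed power follows Q0 * eta * (1 - exp(-2 alpha d0))", {
  expect_equal(absorbed_power(100, 0.5, 0.1, 0.8),
               100 * 0.5 * (1 - exp(-0.16)))
  expect_equal(absorbed_power(100, 0.5, 0, 0.8), 0)
  expect_equal(absorbed_power(100, 0, 0.1, 0.8), 0)
})

test_that("group selection equalizes to the weakest member and maximizes total", {
  cands <- lapply(c(10, 9, 5, 2), function(q)
    list(id = q, Q_cap_w = q, distance_cm = 5))
  pl <- select_tile_group(cands, minTx = 1, maxTx = 4)
  expect_length(pl$tiles, 2)
  expect_equal(pl$total_absorbed_w, 18)
  expect_equal(pl$weights, c(0.9, 1.0))
  # identical tiles: recruit the maximum, all weights 1
  same <- lapply(1:6, function(i) list(id = i, Q_cap_w = 7, distance_cm = 5))
  pl2 <- select_tile_group(same, minTx = 2, maxTx = 6)
  expect_length(pl2$tiles, 6)
  expect_true(all(pl2$weights == 1))
  expect_error(select_tile_group(same[1], minTx = 2), "planning failure")
})

test_that("selection matches the brute-force oracle over 200 random draws", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(2:10, 1)
    Q <- round(runif(n, 0.5, 12), 3)
    cands <- lapply(Q, function(q) list(id = q, Q_cap_w = q, distance_cm = 5))
    pl <- select_tile_group(cands, minTx = 1, maxTx = 6)
    or <- oracle_select(Q, 1, 6)
    expect_equal(length(pl$tiles), or$k)
    expect_equal(pl$total_absorbed_w, or$total)
    expect_true(all(pl$weights > 0 & pl$weights <= 1))
  }
})

test_that("adding a strong candidate never decreases the selected total", {
  set.seed(7)
  for (i in 1:50) {
    Q <- runif(sample(3:8, 1), 1, 10)
    cands <- lapply(Q, function(q) list(id = q, Q_cap_w = q, distance_cm = 5))
    base <- select_tile_group(cands, minTx = 2, maxTx = 6)$total_absorbed_w
    k <- length(select_tile_group(cands, minTx = 2, maxTx = 6)$tiles)
    qnew <- sort(Q, decreasing = TRUE)[k] + runif(1, 0.1, 5)
    more <- c(cands, list(list(id = 99, Q_cap_w = qnew, distance_cm = 5)))
    expect_gte(select_tile_group(more, minTx = 2, maxTx = 6)$total_absorbed_w,
               base)
  }
})

test_that("dither patterns follow the depth rule and span the therapeutic volume", {
  expect_equal(nrow(select_dither(5)$points), 12)
  expect_equal(nrow(select_dither(10)$points), 9)
  expect_equal(nrow(select_dither(7)$points), 12)  # boundary inclusive
  expect_error(select_dither(0))
  for (d in c(5, 10)) {
    p <- select_dither(d)
    r <- sqrt(p$points[, 1]^2 + p$points[, 2]^2)
    expect_lte(max(r), 4)      # inside the 8-mm MTV laterally
    expect_gte(max(r), 2.5)    # spans it, not a point cluster
    expect_lte(p$switching_rate_khz, 10)
  }
})

test_that("plan JSON export records tiles, weights and pattern", {
  cands <- lapply(c(8, 6, 4), function(q)
    list(id = as.integer(q), Q_cap_w = q, distance_cm = 5))
  pl <- select_tile_group(cands, target = c(1, 2, 3), minTx = 2, maxTx = 3)
  p <- withr::local_tempfile(fileext = ".json")
  write_plan_json(pl, p)
  x <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(x$target, c(1, 2, 3))
  expect_equal(length(x$weights), length(pl$tiles))
  expect_lte(x$t_dose_s, 30)
})
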