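# Synthetic phantom, vascular tree and flow waveform generators.

test_that("waveform profiles set the resistive index by construction", {
  for (s in 1:20) {
    expect_lte(compute_ri(make_flow_waveform("bleeder", 20, 60, s)), 0.70)
    expect_gte(compute_ri(make_flow_waveform("normal", 20, 60, s)), 0.80)
  }
  w <- make_flow_waveform("irregular-slow", 6, 60, 2)
  expect_lte(w$mean_velocity, 4)
  w3 <- make_flow_waveform("bleeder", 3, 60, 2)
  expect_equal(w3$mean_velocity, 3, tolerance = 1e-9)
  expect_gt(w3$V_diastole, 0)
})

test_that("waveform invariants and error handling hold", {
  w <- make_flow_waveform("normal", 15, 72, 5)
  expect_equal(w$V_systole, max(w$velocity))
  expect_equal(w$V_diastole, min(w$velocity))
  expect_gte(w$V_systole, w$V_diastole)
  expect_error(make_flow_waveform("normal", -1), "positive")
  expect_identical(make_flow_waveform("bleeder", 20, 60, 9),
                   make_flow_waveform("bleeder", 20, 60, 9))
  p <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(w, p)
  w2 <- read_waveform_csv(p)
  expect_equal(w2$velocity, w$velocity, tolerance = 1e-6)
})

test_that("bleeder-profile RI stays classifiable across seeds", {
  for (s in 1:25)
    expect_lt(compute_ri(make_flow_waveform("bleeder", 10, 60, s)), 0.75)
})

test_that("limb phantom enforces the radius-of-curvature envelope", {
  expect_error(make_limb_phantom(5, 1, 0, 0), "MinRC")
  expect_error(make_limb_phantom(30, 1, 0, 0), "MaxRC")
  ph <- make_limb_phantom(25, 4, 1, 7)
  expect_lte(dbacsim:::max_bleeder_depth_mm(ph), 125)
  expect_gt(dbacsim:::max_bleeder_depth_mm(ph), 250 / 4)  # deeper than D/4
  ph2 <- make_limb_phantom(7.5, 2, 1, 7, length_cm = 8)
  expect_lte(dbacsim:::max_bleeder_depth_mm(ph2), 37.5)
})

test_that("phantom generation is deterministic and geometrically sound", {
  ph <- make_limb_phantom(15, 3, 1, seed = 11, length_cm = 8)
  ph2 <- make_limb_phantom(15, 3, 1, seed = 11, length_cm = 8)
  expect_identical(ph$vessel_tree, ph2$vessel_tree)
  R <- 75
  for (b in ph$vessel_tree$branches) {
    expect_true(all(sqrt(b$points[, 1]^2 + b$points[, 2]^2) < R))
    expect_true(all(abs(b$points[, 3]) < 40))
  }
  # bleeder stub: straight leaf, long enough to carry the TC marker
  bid <- dbacsim:::bleeder_branch_ids(ph$vessel_tree)
  expect_length(bid, 1)
  stub <- ph$vessel_tree$branches[[bid]]
  expect_gte(dbacsim:::polyline_length(stub$points), 30)
  kids <- which(vapply(ph$vessel_tree$branches,
                       function(x) identical(x$parent, bid), TRUE))
  expect_length(kids, 0)
  # TC marker 20 mm downstream along the stub
  tc <- ph$vessel_tree$tc_markers[[1]]
  expect_equal(tc$branch, bid)
  expect_equal(as.numeric(tc$point),
               as.numeric(dbacsim:::polyline_point_at(stub$points, 20)),
               tolerance = 1e-9)
})

test_that("child radii follow the Murray-type reduction", {
  tr <- make_limb_phantom(25, 4, 0, seed = 2)$vessel_tree
  for (b in seq_along(tr$branches)) {
    par <- tr$branches[[b]]$parent
    if (!is.na(par))
      expect_lt(tr$branches[[b]]$radius_mm, tr$branches[[par]]$radius_mm)
  }
})

test_that("rasterization conserves tube volume within 10%", {
  tr <- fx_tube_tree()
  ras <- dbacsim:::rasterize_tree(tr, 0.25)
  vol_vox <- sum(ras$lumen) * 0.25^3
  vol_true <- pi * 1.5^2 * 30
  expect_lt(abs(vol_vox / vol_true - 1), 0.10)
})

test_that("a 0.6-mm vessel is represented continuously at 0.25-mm voxels", {
  tr <- fx_tube_tree()
  tr$branches[[1]]$radius_mm <- 0.3
  ras <- dbacsim:::rasterize_tree(tr, 0.25)
  idx <- which(ras$lumen, arr.ind = TRUE)
  xs <- ras$origin[1] + (idx[, 1] - 0.5) * 0.25
  # every 1-mm bin along the tube contains lumen voxels (no gaps)
  bins <- table(cut(xs, breaks = seq(-14.5, 14.5, by = 1)))
  expect_true(all(bins >= 1))
})

test_that("phantom JSON export round-trips the tree topology", {
  ph <- make_limb_phantom(15, 2, 1, seed = 3, length_cm = 6)
  p <- withr::local_tempfile(fileext = ".json")
  write_phantom_json(ph, p)
  x <- jsonlite::read_json(p, simplifyVector = FALSE)
  expect_equal(length(x$branches), length(ph$vessel_tree$branches))
  expect_equal(x$diameter_cm, 15)
  expect_equal(sum(vapply(x$branches, function(b) b$flag == "bleeder", TRUE)), 1)
})
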