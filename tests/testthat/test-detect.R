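# Vessel segmentation, centerlines, bifurcations, gates, RI classification
# and the end-to-end D&L chain.

test_that("segmentation recovers the lumen and rejects empty volumes", {
  tr <- fx_tube_tree()
  ras <- dbacsim:::rasterize_tree(tr, 0.5)
  vol <- doppler_volume(array(100 * ras$lumen, dim(ras$lumen)), 0.5, ras$origin)
  m <- segment_vessels(vol, close_radius_vox = 0)
  expect_identical(array(m, dim(m)), ras$lumen)
  empty <- doppler_volume(array(0, c(10, 10, 10)), 0.5, c(0, 0, 0))
  expect_false(any(segment_vessels(empty)))
})

test_that("segmentation at SNR 5 reaches Dice >= 0.9 against the true lumen", {
  ph <- fx_phantom15()
  cf <- fx_cuff15()
  vol <- render_power_doppler(ph, cf, 0.5, noise_seed = 2, noise_sd = 5)
  m <- segment_vessels(vol)
  lum <- attr(vol, "truth")$lumen
  dice <- 2 * sum(m & lum) / (sum(m) + sum(lum))
  expect_gte(dice, 0.9)
})

test_that("a straight tube yields one edge and no bifurcations", {
  m <- rasterized_mask(fx_tube_tree())
  g <- extract_centerlines(m)
  expect_length(g$edges, 1)
  expect_equal(nrow(detect_bifurcations(g)), 0)
  expect_error(extract_centerlines(array(FALSE, c(5, 5, 5)),
                                   voxel_size_mm = 1, origin_mm = c(0, 0, 0)),
               "empty mask")
})

test_that("a Y-junction yields one bifurcation within 1 mm of the true junction", {
  m <- rasterized_mask(fx_y_tree(), 0.4)
  g <- extract_centerlines(m)
  b <- detect_bifurcations(g)
  expect_equal(nrow(b), 1)
  expect_lt(dbacsim:::vnorm(b[1, ] - c(0, 0, 0)), 1)
})

test_that("a two-junction tree recovers at least four terminal branches", {
  ph <- make_limb_phantom(15, 2, 1, seed = 9, length_cm = 8, n_bones = 0)
  m <- rasterized_mask(ph$vessel_tree, 0.5)
  g <- extract_centerlines(m)
  expect_gte(sum(g$degree == 1), 4)
  expect_gte(nrow(detect_bifurcations(g)), 2)
})

test_that("spectral gates sit at the prescribed arclength with one proximal role", {
  tr <- fx_y_tree()
  m <- rasterized_mask(tr, 0.4)
  g <- extract_centerlines(m)
  b <- detect_bifurcations(g)[1, ]
  gates <- place_sd_gates(b, g, gate_distance_mm = 5, tree = tr)
  expect_length(gates, 3)
  for (gt in gates) {
    expect_false(gt$flagged_short)
    expect_equal(gt$arclength_mm, 5)
    expect_lt(abs(dbacsim:::vnorm(gt$location - b) - 5), 1.2)
  }
  expect_equal(sum(vapply(gates, function(x) x$role == "proximal", TRUE)), 1)
  # round trip: every gate lands on a vessel for spectral sampling
  for (gt in gates)
    expect_false(is_no_signal(sample_spectral_doppler(gt$location, tr)))
})

test_that("gates on branches shorter than the gate distance fall back to midpoints", {
  tr <- fx_y_tree()
  tr$branches[[2]]$points <- cbind(seq(0, 4, by = 1) * sin(pi / 5), 0,
                                   seq(0, 4, by = 1) * cos(pi / 5))
  m <- rasterized_mask(tr, 0.4)
  g <- extract_centerlines(m)
  bifs <- detect_bifurcations(g)
  gates <- place_sd_gates(bifs[1, ], g, gate_distance_mm = 5, tree = tr)
  short <- vapply(gates, `[[`, TRUE, "flagged_short")
  expect_true(any(short))
  sg <- gates[[which(short)[1]]]
  e <- g$edges[[sg$edge]]
  expect_equal(sg$arclength_mm, e$length_mm / 2)
  expect_error(place_sd_gates(c(500, 500, 500) * 0 + c(0, 0, -12), g),
               "degree")
})

test_that("resistive index arithmetic and classification are strict", {
  w <- list(V_systole = 10, V_diastole = 3)
  class(w) <- "flow_waveform"
  expect_equal(compute_ri(w), 0.70)
  w$V_diastole <- 10; expect_equal(compute_ri(w), 0)
  w$V_diastole <- 0; expect_equal(compute_ri(w), 1)
  w$V_systole <- 0; expect_true(is.na(compute_ri(w)))
  expect_identical(classify_branch(0.70), "bleeder")
  expect_identical(classify_branch(0.75), "normal")   # strict <
  expect_identical(classify_branch(0.95), "normal")
  expect_identical(classify_branch(NA_real_), "unclassifiable")
  # pure function: repeated application gives identical results
  expect_identical(classify_branch(0.70), classify_branch(0.70))
})

test_that("generator waveforms keep RI in [0, 1]", {
  for (s in 1:10) {
    for (pr in c("normal", "bleeder", "irregular-slow")) {
      ri <- compute_ri(make_flow_waveform(pr, 10, 60, s))
      expect_gte(ri, 0); expect_lte(ri, 1)
    }
  }
})

test_that("RI classification degrades on irregular-slow flow relative to bleeder flow", {
  acc <- function(profile) mean(vapply(1:40, function(s)
    classify_branch(compute_ri(
      make_flow_waveform(profile, 3, 60, s))) == "bleeder", TRUE))
  expect_lt(acc("irregular-slow"), acc("bleeder"))
})

test_that("the D&L chain finds the bleeder with the correct branch id", {
  ph <- fx_phantom15()
  cf <- fx_cuff15()
  rep <- run_dl(ph, cf, seed = 2, voxel_size_mm = 0.5)
  expect_s3_class(rep, "dl_report")
  expect_gte(rep$n_bifurcations, 1)
  expect_equal(rep$n_bleeders, 1)
  bid <- dbacsim:::bleeder_branch_ids(ph$vessel_tree)
  expect_equal(rep$bleeders[[1]]$branch, bid)
  # localization: target coordinate within 3 mm of the true branch
  nb <- dbacsim:::nearest_tree_branch(ph$vessel_tree,
                                      rep$bleeders[[1]]$target_coordinate)
  expect_equal(nb$branch, bid)
  expect_lt(nb$dist, 3)
  expect_equal(rep$timings$total_s,
               rep$timings$acquisition_s + rep$timings$characterization_s)
})

test_that("a phantom without bleeders reports none", {
  ph <- make_limb_phantom(15, 2, 0, seed = 9, length_cm = 7, n_bones = 0)
  cf <- fx_cuff15()
  rep <- run_dl(ph, cf, seed = 3, voxel_size_mm = 0.5)
  expect_equal(rep$n_bleeders, 0)
})

test_that("a 0.6-mm bleeder is detected at 0.25-mm voxels", {
  ph <- make_limb_phantom(15, 1, 1, seed = 6, length_cm = 5, n_bones = 0,
                          root_radius_mm = 1.5, bleeder_radius_mm = 0.3)
  cf <- fx_cuff15()
  rep <- run_dl(ph, cf, seed = 2, voxel_size_mm = 0.25)
  expect_equal(rep$n_bleeders, 1)
  expect_equal(rep$bleeders[[1]]$branch,
               dbacsim:::bleeder_branch_ids(ph$vessel_tree))
})
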