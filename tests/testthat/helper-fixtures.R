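# Shared fixtures, built in code and cached per test run.

fixture_env <- new.env()

fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

# standard 15-cm phantom with one bleeder plus its 5-panel cuff
fx_phantom15 <- function() fixture("ph15", function()
  make_limb_phantom(15, 3, 1, seed = 4, length_cm = 8, n_bones = 1))
fx_cuff15 <- function() fixture("cf15", function() build_cuff(5, 15))

# a single straight horizontal tube (one branch, no bifurcations)
fx_tube_tree <- function() fixture("tube", function() {
  tr <- make_vessel_tree(15, 8, 0, 0, seed = 1)
  tr$branches[[1]]$points <- cbind(seq(-15, 15, by = 5), 0, 0)
  tr$branches[[1]]$radius_mm <- 1.5
  tr
})

# symmetric Y-junction tree: trunk along +z splitting into two branches
fx_y_tree <- function() fixture("ytree", function() {
  tr <- make_vessel_tree(15, 8, 0, 0, seed = 1)
  trunk <- cbind(0, 0, seq(-12, 0, by = 3))
  b1 <- cbind(seq(0, 8, by = 2) * sin(pi / 5), 0,
              seq(0, 8, by = 2) * cos(pi / 5))
  b2 <- cbind(-seq(0, 8, by = 2) * sin(pi / 5), 0,
              seq(0, 8, by = 2) * cos(pi / 5))
  w <- tr$branches[[1]]$waveform
  tr$branches <- list(
    list(points = trunk, radius_mm = 1.5, flag = "normal",
         parent = NA_integer_, waveform = w),
    list(points = b1, radius_mm = 1.2, flag = "normal", parent = 1L,
         waveform = w),
    list(points = b2, radius_mm = 1.2, flag = "normal", parent = 1L,
         waveform = w))
  tr$bifurcations <- matrix(c(0, 0, 0), 1)
  tr$bif_at_branch <- 1L
  tr
})

# mask + grid attrs for an arbitrary tree rasterized noiselessly
rasterized_mask <- function(tree, voxel = 0.5) {
  ras <- dbacsim:::rasterize_tree(tree, voxel)
  m <- ras$lumen
  attr(m, "voxel_size") <- voxel
  attr(m, "origin") <- ras$origin
  m
}

# independent brute-force oracle for equalized tile-group selection
oracle_select <- function(Q, minTx, maxTx) {
  s <- sort(Q, decreasing = TRUE)
  ks <- minTx:min(maxTx, length(Q))
  totals <- vapply(ks, function(k) k * s[k], 0)
  k <- ks[which.max(totals)]
  list(k = k, total = k * s[k])
}
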