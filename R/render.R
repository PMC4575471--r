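#' Render a compounded 3D power-Doppler volume of a phantom
#'
#' Geometric Doppler rendering: the vessel lumen is rasterized into the
#' voxel grid, each imaging probe contributes intensity scaled by the
#' Doppler angle factor |cos(theta)| between its beam direction and the
#' local flow direction (zero signal at orthogonal insonation -- the
#' Doppler dropout), and the per-probe views are compounded by taking the
#' maximum across probes, which restores dropout wherever at least one
#' probe sees the flow at |cos(theta)| >= 0.3. Voxels whose flow speed is
#' below the minimum detectable velocity return no Doppler signal.
#' Additive Gaussian noise (seeded) is applied last. This is a geometric
#' observation model for exercising detection logic, not an RF simulation.
#'
#' @param phantom a `limb_phantom`.
#' @param cuff a `cuff_geometry` enclosing the phantom.
#' @param voxel_size_mm voxel edge; must be at most half the smallest lumen
#'   diameter in the tree (Nyquist on vessel diameter; 0.3 mm resolves the
#'   0.6-mm minimum-structure vessel).
#' @param noise_seed RNG seed for the additive noise.
#' @param noise_sd additive noise SD in intensity units (signal peak = 100).
#' @param mdv_cm_s minimum detectable velocity (cm/s).
#' @param angle_effects logical; FALSE disables the Doppler-angle model so
#'   the noiseless render equals the rasterized lumen exactly.
#' @param bbox optional list(lo, hi) rendering box (mm); default the vessel
#'   tree bounding box.
#' @return a `doppler_volume` (P-mode) with attribute `truth` holding the
#'   rasterization ground truth.
#' @export
render_power_doppler <- function(phantom, cuff, voxel_size_mm = 0.3,
                                 noise_seed = 1, noise_sd = 5,
                                 mdv_cm_s = dbac_requirements()$mdv_cm_s,
                                 angle_effects = TRUE, bbox = NULL) {
  tree <- phantom$vessel_tree
  min_diam <- 2 * min(vapply(tree$branches, `[[`, 0, "radius_mm"))
  if (voxel_size_mm > min_diam / 2 + 1e-9)
    stop(sprintf("voxel_size %.3g mm too coarse: smallest lumen diameter is %.3g mm (need <= diameter/2)",
                 voxel_size_mm, min_diam))
  if (cuff$apothem_mm < phantom$diameter_cm * 10 / 2)
    stop("cuff does not enclose the phantom")
  ras <- rasterize_tree(tree, voxel_size_mm, bbox)
  S0 <- 100
  signal <- array(0, ras$dims)
  lum_idx <- which(ras$lumen)
  if (length(lum_idx)) {
    detectable <- ras$speed[lum_idx] >= mdv_cm_s
    if (angle_effects) {
      ijk <- arrayInd(lum_idx, ras$dims)
      P <- sweep((ijk - 0.5) * voxel_size_mm, 2, ras$origin, `+`)
      fx <- ras$dir$x[lum_idx]; fy <- ras$dir$y[lum_idx]; fz <- ras$dir$z[lum_idx]
      best <- numeric(length(lum_idx))
      for (pr in cuff$probes) {
        bx <- P[, 1] - pr$center[1]; by <- P[, 2] - pr$center[2]
        bz <- P[, 3] - pr$center[3]
        rng <- sqrt(bx^2 + by^2 + bz^2)
        # in-sector check (vectorized)
        ax_ <- bx * pr$u[1] + by * pr$u[2] + bz * pr$u[3]
        el_ <- bx * pr$v[1] + by * pr$v[2] + bz * pr$v[3]
        nz_ <- bx * pr$normal[1] + by * pr$normal[2] + bz * pr$normal[3]
        insec <- nz_ > 0 &
          abs(atan2(ax_, nz_)) <= deg2rad(pr$sector_az_deg / 2) &
          abs(atan2(el_, nz_)) <= deg2rad(pr$sector_el_deg / 2) &
          rng <= pr$max_depth_mm
        cosang <- abs(bx * fx + by * fy + bz * fz) / pmax(rng, 1e-9)
        cosang[!insec] <- 0
        best <- pmax(best, cosang)
      }
      signal[lum_idx] <- S0 * best * detectable
    } else {
      signal[lum_idx] <- S0 * detectable
    }
  }
  if (noise_sd > 0) {
    rng <- local_rng(noise_seed)
    signal <- signal + array(rng$rnorm(length(signal), 0, noise_sd), ras$dims)
  }
  signal[signal < 0] <- 0
  vol <- doppler_volume(signal, voxel_size_mm, ras$origin, "P-mode")
  attr(vol, "truth") <- ras
  attr(vol, "signal_level") <- S0
  attr(vol, "noise_sd") <- noise_sd
  vol
}

#' Sample a spectral-Doppler waveform at a gate location
#'
#' Returns the flow waveform of the branch whose centerline passes within
#' the gate capture radius of the requested location, with multiplicative
#' speckle-like Gaussian noise applied sample-wise; systolic and diastolic
#' velocities are recomputed from the noisy trace. If no branch centerline
#' is within reach the result is a distinguishable no-signal outcome.
#'
#' @param gate_location 3D point (mm, limb frame).
#' @param tree a `vessel_tree`.
#' @param noise_seed RNG seed.
#' @param noise_sd multiplicative noise SD (fraction; 0.05 = 5% speckle).
#' @param capture_radius_mm gate capture radius (default 2 mm).
#' @return a `flow_waveform` (with `branch` attribute), or an object of
#'   class `sd_no_signal`.
#' @export
sample_spectral_doppler <- function(gate_location, tree, noise_seed = 1,
                                    noise_sd = 0.05, capture_radius_mm = 2) {
  best <- list(dist = Inf, branch = NA_integer_)
  for (b in seq_along(tree$branches)) {
    pts <- tree$branches[[b]]$points
    for (s in seq_len(nrow(pts) - 1)) {
      d <- point_segment_dist(gate_location, pts[s, ], pts[s + 1, ])
      # reach extends through the lumen: centerline distance within
      # capture radius + lumen radius
      if (d$dist < best$dist) best <- list(dist = d$dist, branch = b)
    }
  }
  reach <- capture_radius_mm + tree$branches[[best$branch]]$radius_mm
  if (!is.finite(best$dist) || best$dist > reach)
    return(structure(list(gate = gate_location, reason = "no vessel within capture radius"),
                     class = "sd_no_signal"))
  w <- tree$branches[[best$branch]]$waveform
  v <- w$velocity
  if (noise_sd > 0) {
    rng <- local_rng(noise_seed)
    v <- v * (1 + rng$rnorm(length(v), 0, noise_sd))
  }
  out <- new_flow_waveform(w$time, v, w$profile)
  attr(out, "branch") <- best$branch
  attr(out, "gate_distance_mm") <- best$dist
  out
}

#' @export
print.sd_no_signal <- function(x, ...) {
  cat("<sd_no_signal>", x$reason, "\n")
  invisible(x)
}

#' Test whether a spectral-Doppler sample returned a signal
#' @param x result of [sample_spectral_doppler()].
#' @export
is_no_signal <- function(x) inherits(x, "sd_no_signal")
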