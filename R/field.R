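# Focused-beam intensity fields and dither-averaged power deposition.
#
# Monochromatic linear propagation: each tile is summed as a phased grid of
# baffled point sources with focusing delays (far-field element summation).
# No nonlinear propagation, cavitation or tissue motion is modelled.

#' Regular grid specification for field and thermal computations
#' @param origin_mm low corner (mm, limb frame).
#' @param voxel_size_mm isotropic spacing.
#' @param dims integer vector (nx, ny, nz).
#' @export
grid_spec <- function(origin_mm, voxel_size_mm, dims) {
  list(origin = origin_mm, voxel_size = voxel_size_mm,
       dims = as.integer(dims))
}

#' Centered cubic grid around a point
#' @param center_mm grid center.
#' @param half_mm half-width (mm).
#' @param voxel_size_mm spacing.
#' @export
grid_around <- function(center_mm, half_mm, voxel_size_mm) {
  n <- 2L * as.integer(ceiling(half_mm / voxel_size_mm)) + 1L
  org <- center_mm - (n / 2) * voxel_size_mm
  grid_spec(org, voxel_size_mm, c(n, n, n))
}

grid_points <- function(grid) {
  ax <- lapply(1:3, function(a)
    grid$origin[a] + (seq_len(grid$dims[a]) - 0.5) * grid$voxel_size)
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  as.matrix(g)
}

#' Compute a focused-beam intensity field for one tile
#'
#' Coherent summation of the tile's element grid (optionally grouped by an
#' integer decimation factor for speed) with focusing delays to `focus`,
#' spherical spreading and baffled-cosine element directivity, evaluated at
#' the grid voxel centers. The result is normalized to the focal peak.
#' The focus must lie within the tile's steering limits.
#'
#' @param tile tile entry of a `cuff_geometry`.
#' @param focus 3D focal point (mm, limb frame).
#' @param grid a [grid_spec()] (or matrix of points, n x 3).
#' @param f_c_mhz carrier (MHz).
#' @param sound_speed_m_s propagation speed.
#' @param element_decimation integer factors (az, el) grouping elements
#'   into super-sources; 1 = full 4608-element sum.
#' @return numeric array (grid dims) or vector (points), normalized so the
#'   focal intensity is 1.
#' @export
beam_field <- function(tile, focus, grid, f_c_mhz = TILE_FC_MHZ,
                       sound_speed_m_s = 1515,
                       element_decimation = c(1L, 1L)) {
  f <- target_in_tile_frame(tile, focus)
  if (abs(f$az_deg) > tile$steer_az_deg || abs(f$el_deg) > tile$steer_el_deg)
    stop(sprintf("focus at (az %.1f, el %.1f) deg exceeds steering limits (%g, %g)",
                 f$az_deg, f$el_deg, tile$steer_az_deg, tile$steer_el_deg))
  el <- element_grid_local(as.integer(element_decimation))
  # element positions in the limb frame
  ex <- tile$center[1] + el$x * tile$u[1] + el$y * tile$v[1]
  ey <- tile$center[2] + el$x * tile$u[2] + el$y * tile$v[2]
  ez <- tile$center[3] + el$x * tile$u[3] + el$y * tile$v[3]
  k <- 2 * pi * f_c_mhz * 1e6 / sound_speed_m_s / 1000  # rad/mm
  pts <- if (is.matrix(grid)) grid else grid_points(grid)
  val <- cpp_beamsum(pts[, 1], pts[, 2], pts[, 3], ex, ey, ez,
                     tile$normal[1], tile$normal[2], tile$normal[3],
                     k, focus[1], focus[2], focus[3])
  peak <- cpp_beamsum(focus[1], focus[2], focus[3], ex, ey, ez,
                      tile$normal[1], tile$normal[2], tile$normal[3],
                      k, focus[1], focus[2], focus[3])
  val <- val / peak
  if (is.matrix(grid)) val else array(val, grid$dims)
}

#' Strongest side lobe relative to the focal peak
#'
#' Ratio (dB, negative) of the maximum intensity outside an exclusion
#' sphere around the focus to the focal peak. A field with no energy
#' outside the exclusion radius reports the floor (-100 dB).
#'
#' @param field numeric array from [beam_field()] (or any intensity array).
#' @param grid the [grid_spec()] the field was computed on.
#' @param focus focal point (mm).
#' @param exclusion_radius_mm radius of the main-lobe exclusion sphere.
#' @return side-lobe level in dB (negative).
#' @export
sidelobe_ratio <- function(field, grid, focus, exclusion_radius_mm) {
  pts <- grid_points(grid)
  r2 <- (pts[, 1] - focus[1])^2 + (pts[, 2] - focus[2])^2 +
        (pts[, 3] - focus[3])^2
  peak <- max(field)
  outside <- as.vector(field)[r2 > exclusion_radius_mm^2]
  if (!length(outside) || max(outside) <= 0) return(-100)
  max(-100, 10 * log10(max(outside) / peak))
}

# vectorized chord length of segments p->each row of Q inside the limb
# cylinder (axis z, radius R) -- used for per-voxel tissue path attenuation
tissue_path_mm <- function(p, Q, R) {
  n <- nrow(Q)
  out <- numeric(n)
  dx <- Q[, 1] - p[1]; dy <- Q[, 2] - p[2]; dz <- Q[, 3] - p[3]
  L <- sqrt(dx^2 + dy^2 + dz^2)
  ok <- L > 0
  ux <- dx / L; uy <- dy / L
  a <- ux^2 + uy^2
  b <- 2 * (p[1] * ux + p[2] * uy)
  cc <- p[1]^2 + p[2]^2 - R^2
  disc <- b^2 - 4 * a * cc
  hit <- ok & disc > 0 & a > 1e-12
  t1 <- (-b[hit] - sqrt(disc[hit])) / (2 * a[hit])
  t2 <- (-b[hit] + sqrt(disc[hit])) / (2 * a[hit])
  lo <- pmax(0, pmin(t1, t2)); hi <- pmin(L[hit], pmax(t1, t2))
  out[hit] <- pmax(0, hi - lo)
  out[!ok] <- 0
  # parallel-to-axis segments entirely inside
  par <- ok & a <= 1e-12
  out[par] <- ifelse(cc <= 0, L[par], 0)
  out
}

# integer voxel shift of a 3D array (zero-filled)
shift_array <- function(a, s) {
  d <- dim(a)
  out <- array(0, d)
  src <- dst <- vector("list", 3)
  for (i in 1:3) {
    if (s[i] >= 0) { src[[i]] <- seq_len(d[i] - s[i]); dst[[i]] <- src[[i]] + s[i] }
    else { src[[i]] <- seq(1 - s[i], d[i]); dst[[i]] <- src[[i]] + s[i] }
    if (length(src[[i]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Dither-averaged absorbed-power deposition map for a dose plan
#'
#' For each recruited tile the focused intensity field is computed once at
#' the plan target and the dither pattern is applied as a time-averaged
#' superposition of focus-translated copies (valid for the few-mm dither
#' spans used here). Per-voxel volumetric heating is
#' q = 2 alpha f I(r) exp(-2 alpha f d_tissue(r)), calibrated per tile so
#' that the power absorbed inside the therapeutic sphere equals the plan's
#' equalized per-tile contribution.
#'
#' @param plan a `dose_plan`.
#' @param phantom a `limb_phantom`.
#' @param grid a [grid_spec()] covering at least the therapeutic volume.
#' @param element_decimation element grouping for speed (default 2 in azimuth,
#'  full sampling in elevation so the grouped pitch stays below the
#'  wavelength and no grating lobes appear).
#' @return object of class `deposition_map`: `q` (W/cm^3 array), grid
#'   metadata, per-tile calibration and intensity scale.
#' @export
deposition_from_plan <- function(plan, phantom, grid,
                                 element_decimation = c(2L, 1L)) {
  R <- phantom$diameter_cm * 10 / 2
  tissue <- phantom$tissue
  alpha <- attenuation_at(tissue, TILE_FC_MHZ)     # Np/cm
  pts <- grid_points(grid)
  vox_cm3 <- (grid$voxel_size / 10)^3
  mtv_r <- dbac_requirements()$mtv_diameter_mm / 2
  in_mtv <- (pts[, 1] - plan$target[1])^2 + (pts[, 2] - plan$target[2])^2 +
            (pts[, 3] - plan$target[3])^2 <= mtv_r^2
  q <- array(0, grid$dims)
  intensity_scale <- numeric(length(plan$tiles))
  for (i in seq_along(plan$tiles)) {
    cand <- plan$tiles[[i]]
    tile <- cand$tile
    I <- beam_field(tile, plan$target, grid,
                    sound_speed_m_s = tissue$sound_speed,
                    element_decimation = element_decimation)
    # dither: average of focus-translated copies in the beam-lateral plane
    if (!is.null(plan$dither) && nrow(plan$dither$points) > 1) {
      Fr <- complete_frame(unitv(plan$target - tile$center))
      acc <- array(0, grid$dims)
      for (p in seq_len(nrow(plan$dither$points))) {
        off <- Fr %*% c(plan$dither$points[p, 1:2], 0)
        sv <- as.integer(round(off / grid$voxel_size))
        acc <- acc + shift_array(I, sv)
      }
      I <- acc / nrow(plan$dither$points)
    }
    att <- exp(-2 * alpha * tissue_path_mm(tile$center, pts, R) / 10)
    qi <- as.vector(I) * att                      # relative absorbed density
    mtv_sum <- sum(qi[in_mtv]) * vox_cm3
    scale <- if (mtv_sum > 0) plan$Q_equalized_w / mtv_sum else 0
    q <- q + array(qi * scale, grid$dims)
    intensity_scale[i] <- scale / (2 * alpha)     # W/cm^2 per relative unit
  }
  structure(list(q = q, origin = grid$origin, voxel_size = grid$voxel_size,
                 dims = grid$dims, plan = plan,
                 intensity_scale = intensity_scale,
                 alpha_np_cm = alpha),
            class = "deposition_map")
}

#' @export
print.deposition_map <- function(x, ...) {
  cat(sprintf("<deposition_map> %dx%dx%d @ %.2g mm, total absorbed %.2f W\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size,
              sum(x$q) * (x$voxel_size / 10)^3))
  invisible(x)
}

# power absorbed (W) inside a sphere
absorbed_in_sphere <- function(dep, center, diameter_mm) {
  pts <- grid_points(dep)
  r2 <- (pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2 +
        (pts[, 3] - center[3])^2
  sum(dep$q[r2 <= (diameter_mm / 2)^2]) * (dep$voxel_size / 10)^3
}
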