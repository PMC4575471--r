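#' Build a polygonal multi-panel HIFU cuff around a limb
#'
#' The cuff is a regular polygon of 4--7 rigid panels (square, pentagon,
#' hexagon, heptagon) circumscribing the limb plus a water-jacket standoff.
#' Each panel carries three therapy tiles (Tx; 52 x 52 mm aperture of four
#' 96 x 12-element acoustic modules, 4608 elements, 1 MHz, electronic
#' steering to 60 deg azimuth / 45 deg elevation) laid out axially with a
#' 2-mm gap, and one 3D imaging probe (Ix; 2.5 MHz, pyramidal sector
#' volume). All tile normals point at the limb axis.
#'
#' @param n_panels 4..7.
#' @param limb_diameter_cm limb diameter the cuff is worn on.
#' @param standoff_cm water-jacket thickness between skin and panels.
#' @param tile_gap_mm axial gap between adjacent tiles on a panel.
#' @param tile_power_cap_w per-tile acoustic power cap (W); default derived
#'   from the 6 W/cm^2 skin intensity limit via [tile_power_cap()].
#' @return Object of class `cuff_geometry` with `tiles` and `probes` lists;
#'   each entry holds `center` (mm, limb frame), `normal` (unit, inward),
#'   `u` (in-plane azimuthal axis), `v` (in-plane axial axis).
#' @export
build_cuff <- function(n_panels, limb_diameter_cm, standoff_cm = 1,
                       tile_gap_mm = 2, tile_power_cap_w = NULL) {
  if (!n_panels %in% 4:7)
    stop("n_panels must be one of 4, 5, 6, 7 (square to heptagon)")
  R <- limb_diameter_cm * 10 / 2
  apothem <- R + standoff_cm * 10       # mm, axis -> panel plane
  tile_pitch <- TILE_AM_AZ_MM + tile_gap_mm
  tiles <- list(); probes <- list()
  for (p in seq_len(n_panels)) {
    phi <- 2 * pi * (p - 1) / n_panels
    normal <- -c(cos(phi), sin(phi), 0)          # inward
    u <- c(-sin(phi), cos(phi), 0)               # panel lateral (azimuthal)
    v <- c(0, 0, 1)                              # panel axial
    base <- -normal * apothem                    # panel center
    for (k in -1:1) {
      center <- base + v * (k * tile_pitch)
      tiles[[length(tiles) + 1]] <- list(
        id = length(tiles) + 1L, panel = p, center = center,
        normal = normal, u = u, v = v,
        f_c_mhz = TILE_FC_MHZ,
        steer_az_deg = TILE_STEER_AZ_DEG, steer_el_deg = TILE_STEER_EL_DEG)
    }
    # probes staggered axially panel-to-panel so compounding sees axial
    # flow at usable Doppler angles from somewhere on the cuff
    probes[[length(probes) + 1]] <- list(
      id = length(probes) + 1L, panel = p,
      center = base + u * min(30, max(10, apothem * tan(pi / n_panels) - 15)) +
        v * ((((p - 1L) %% 3L) - 1L) * 40),
      normal = normal, u = u, v = v,
      f_c_mhz = IX_FC_MHZ,
      sector_az_deg = 76, sector_el_deg = 76, max_depth_mm = 160)
  }
  cap <- if (is.null(tile_power_cap_w))
    dbac_requirements()$skin_intensity_limit_w_cm2 * TILE_APERTURE_CM2
  else tile_power_cap_w
  structure(list(n_panels = n_panels, limb_diameter_cm = limb_diameter_cm,
                 standoff_cm = standoff_cm, apothem_mm = apothem,
                 tiles = tiles, probes = probes, tile_power_cap_w = cap),
            class = "cuff_geometry")
}

#' @export
print.cuff_geometry <- function(x, ...) {
  cat(sprintf("<cuff_geometry> %d panels, %d Tx tiles, %d Ix probes, apothem %.1f mm\n",
              x$n_panels, length(x$tiles), length(x$probes), x$apothem_mm))
  invisible(x)
}

#' Total therapy element count of a cuff
#'
#' Each tile carries 4 acoustic modules of 96 x 12 elements (4608 per tile);
#' a fully populated 7-panel cuff (21 tiles) has 96,768 elements.
#' @param cuff a `cuff_geometry`.
#' @return integer element count.
#' @export
total_elements <- function(cuff) {
  length(cuff$tiles) * TILE_N_ELEMENTS
}

#' Per-tile acoustic power cap from the skin intensity limit
#'
#' The maximum acoustic power a single tile may emit is set by the skin
#' burn limit: cap = limit x full tile aperture area (4 x 5.2 x 1.3 cm^2 =
#' 27.04 cm^2). At the program's 6 W/cm^2 limit this gives 162.2 W,
#' reported as 163 W to three significant figures.
#'
#' @param tile a tile entry from a `cuff_geometry` (unused beyond its
#'   standard aperture; present for future per-tile apertures).
#' @param skin_intensity_limit_w_cm2 W/cm^2, > 0.
#' @return acoustic power cap (W), linear in the limit.
#' @export
tile_power_cap <- function(tile = NULL, skin_intensity_limit_w_cm2 = 6) {
  stopifnot(skin_intensity_limit_w_cm2 > 0)
  skin_intensity_limit_w_cm2 * TILE_APERTURE_CM2
}

# target position expressed in a tile/probe local frame: returns range (mm),
# azimuth and elevation steering angles (deg)
target_in_tile_frame <- function(tile, target) {
  d <- target - tile$center
  x <- sum(d * tile$u); y <- sum(d * tile$v); z <- sum(d * tile$normal)
  r <- vnorm(d)
  list(range_mm = r,
       az_deg = rad2deg(atan2(x, z)),
       el_deg = rad2deg(atan2(y, z)),
       axial_mm = z)
}

# is `point` inside the pyramidal image sector of `probe`?
in_probe_sector <- function(probe, point) {
  f <- target_in_tile_frame(probe, point)
  f$axial_mm > 0 &&
    abs(f$az_deg) <= probe$sector_az_deg / 2 &&
    abs(f$el_deg) <= probe$sector_el_deg / 2 &&
    f$range_mm <= probe$max_depth_mm
}

#' Imaging and therapy coverage of a phantom by a cuff
#'
#' Samples the tissue on a regular grid and counts, per sample point, the
#' imaging sectors containing it (bone-occlusion aware) and the therapy
#' tiles holding it within steering and focal range with an unobstructed
#' path. Reports the fraction of tissue at depth >= 5 cm covered by at
#' least one and at least two probes.
#'
#' @param cuff a `cuff_geometry`.
#' @param phantom a `limb_phantom`; the cuff must enclose it.
#' @param grid_mm sample spacing (mm).
#' @return list with per-point counts and summary fractions.
#' @export
coverage <- function(cuff, phantom, grid_mm = 8) {
  R <- phantom$diameter_cm * 10 / 2
  if (cuff$apothem_mm < R) stop("cuff does not enclose the phantom")
  zh <- phantom$length_cm * 10 / 2
  xs <- seq(-R, R, by = grid_mm)
  zs <- seq(-zh * 0.6, zh * 0.6, by = grid_mm)
  pts <- as.matrix(expand.grid(x = xs, y = xs, z = zs))
  inside <- sqrt(pts[, 1]^2 + pts[, 2]^2) <= R - 1
  pts <- pts[inside, , drop = FALSE]
  n_probe <- integer(nrow(pts)); n_tile <- integer(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    np <- 0L
    for (pr in cuff$probes) {
      if (in_probe_sector(pr, p) && !bone_occluded(phantom, pr$center, p))
        np <- np + 1L
    }
    nt <- 0L
    for (tl in cuff$tiles) {
      f <- target_in_tile_frame(tl, p)
      if (abs(f$az_deg) <= tl$steer_az_deg && abs(f$el_deg) <= tl$steer_el_deg &&
          f$range_mm >= 30 && f$range_mm <= 160 &&
          !bone_occluded(phantom, tl$center, p))
        nt <- nt + 1L
    }
    n_probe[i] <- np; n_tile[i] <- nt
  }
  depth <- R - sqrt(pts[, 1]^2 + pts[, 2]^2)
  deep <- depth >= 50
  list(points = pts, n_probes = n_probe, n_tiles = n_tile, depth_mm = depth,
       frac_deep_ge1_probe = if (any(deep)) mean(n_probe[deep] >= 1) else NA_real_,
       frac_deep_ge2_probes = if (any(deep)) mean(n_probe[deep] >= 2) else NA_real_)
}

#' Persist a cuff description as JSON
#' @param cuff a `cuff_geometry`.
#' @param path output path.
#' @export
write_cuff_json <- function(cuff, path) {
  x <- list(n_panels = cuff$n_panels, limb_diameter_cm = cuff$limb_diameter_cm,
            standoff_cm = cuff$standoff_cm, apothem_mm = cuff$apothem_mm,
            tile_power_cap_w = cuff$tile_power_cap_w,
            tiles = cuff$tiles, probes = cuff$probes)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
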