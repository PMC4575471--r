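#' Generate a cylindrical limb phantom with embedded vasculature
#'
#' The phantom is a tissue cylinder (limb axis along +z, origin at the axis
#' midpoint) with soft-tissue acoustic/thermal properties, an embedded
#' vascular tree with optional vented bleeder branches, optional bone
#' surrogate cylinders, and a water coupling jacket between the skin and the
#' cuff panels. Standard limb diameters are 7.5, 15 and 25 cm; any diameter
#' in that range is accepted. The maximum achievable target depth equals the
#' limb radius (e.g. 12.5 cm in the 25-cm phantom).
#'
#' @param diameter_cm limb diameter, in [7.5, 25] cm (the cuff's minimum and
#'   maximum radius-of-curvature bounds MinRC = 3.75 cm, MaxRC = 12.5 cm).
#' @param n_bifurcations vascular junction count.
#' @param n_bleeders vented bleeder branch count (<= n_bifurcations).
#' @param seed RNG seed; identical seeds give identical phantoms.
#' @param length_cm phantom length (default 10 cm; desk-scale section of a
#'   limb rather than a full 60-cm phantom).
#' @param n_bones number of bone surrogate cylinders (parallel to the limb
#'   axis).
#' @param tissue a [tissue_properties()] object.
#' @param water_jacket_cm coupling water jacket thickness between skin and
#'   cuff panels.
#' @param ... passed to [make_vessel_tree()] (e.g. `bleeder_velocity_cm_s`,
#'   `bleeder_profile`, `root_radius_mm`).
#' @return Object of class `limb_phantom`.
#' @export
make_limb_phantom <- function(diameter_cm, n_bifurcations = 3, n_bleeders = 1,
                              seed = 1, length_cm = 10, n_bones = 1,
                              tissue = tissue_properties(),
                              water_jacket_cm = 1, ...) {
  req <- dbac_requirements()
  if (diameter_cm / 2 < req$min_rc || diameter_cm / 2 > req$max_rc)
    stop(sprintf(paste0("limb diameter %.2f cm outside the supported range: ",
                        "radius of curvature must lie in [MinRC = %.2f cm, ",
                        "MaxRC = %.1f cm]"),
                 diameter_cm, req$min_rc, req$max_rc))
  stopifnot(n_bleeders <= n_bifurcations)
  tree <- make_vessel_tree(diameter_cm, length_cm, n_bifurcations,
                           n_bleeders, seed, ...)
  rng <- local_rng(seed + 7)
  R <- diameter_cm * 10 / 2
  bones <- list()
  if (n_bones > 0) {
    for (i in seq_len(n_bones)) {
      # bone offset from the axis, radius scaled to the limb
      ang <- rng$runif(1, 0, 2 * pi)
      off <- rng$runif(1, 0.35, 0.55) * R
      bones[[i]] <- list(center = c(off * cos(ang), off * sin(ang), 0),
                         axis = c(0, 0, 1),
                         radius_mm = max(4, 0.1 * R))
    }
  }
  structure(list(diameter_cm = diameter_cm, length_cm = length_cm,
                 tissue = tissue, vessel_tree = tree, bones = bones,
                 water_jacket_cm = water_jacket_cm, seed = seed),
            class = "limb_phantom")
}

#' @export
print.limb_phantom <- function(x, ...) {
  cat(sprintf("<limb_phantom> D=%.1f cm L=%.1f cm, %d bones, jacket %.1f cm\n",
              x$diameter_cm, x$length_cm, length(x$bones), x$water_jacket_cm))
  print(x$vessel_tree)
  invisible(x)
}

# depth below the skin surface (mm) of a point in the limb frame
point_depth_mm <- function(phantom, p) {
  phantom$diameter_cm * 10 / 2 - sqrt(p[1]^2 + p[2]^2)
}

# deepest bleeder TC-marker depth (mm); NA when no bleeders
max_bleeder_depth_mm <- function(phantom) {
  tc <- phantom$vessel_tree$tc_markers
  if (!length(tc)) return(NA_real_)
  max(vapply(tc, function(m) point_depth_mm(phantom, m$point), 0))
}

# is the straight segment p->q (limb frame, mm) blocked by any bone?
bone_occluded <- function(phantom, p, q) {
  for (b in phantom$bones) {
    if (segment_hits_cylinder(p, q, b$center, b$axis, b$radius_mm)) return(TRUE)
  }
  FALSE
}

#' Persist a phantom description as JSON
#'
#' Writes tree topology (branch polylines, radii, flags, waveform
#' parameters), bones, and material properties. Rendered volumes are saved
#' separately ([write_volume()]).
#' @param phantom a `limb_phantom`.
#' @param path output path (.json).
#' @export
write_phantom_json <- function(phantom, path) {
  x <- list(
    diameter_cm = phantom$diameter_cm, length_cm = phantom$length_cm,
    water_jacket_cm = phantom$water_jacket_cm, seed = phantom$seed,
    tissue = unclass(phantom$tissue),
    bones = phantom$bones,
    branches = lapply(phantom$vessel_tree$branches, function(b) {
      list(points = b$points, radius_mm = b$radius_mm, flag = b$flag,
           parent = b$parent,
           waveform = list(profile = b$waveform$profile,
                           mean_velocity = b$waveform$mean_velocity,
                           V_systole = b$waveform$V_systole,
                           V_diastole = b$waveform$V_diastole))
    }),
    bifurcations = phantom$vessel_tree$bifurcations,
    tc_markers = lapply(phantom$vessel_tree$tc_markers, function(m)
      list(branch = m$branch, point = m$point))
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
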