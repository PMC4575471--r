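#' Program requirement constants
#'
#' Quantitative performance bounds for the cuff system, used for input
#' validation and pass/fail reporting throughout the package:
#' \describe{
#'   \item{min_rc, max_rc}{minimum / maximum limb radius of curvature the
#'     cuff must conform to (cm); limb diameters 7.5--25 cm.}
#'   \item{min_dp, max_dp}{minimum / maximum bleeder depth of penetration (cm).}
#'   \item{min_td_lo, min_td_hi}{end-of-dose temperature rise window at the
#'     target, 33--58 deg C above baseline (phantom-equivalent of a 70--95
#'     deg C tissue window at 37 deg C core).}
#'   \item{mtsd}{maximum thermal skin dose: skin temperature rise <= 20 deg C.}
#'   \item{mttd_radius_cm}{no significant heating outside a 1-cm lateral
#'     radius around the target.}
#'   \item{mtv_diameter_mm}{minimum therapeutic volume: 8-mm sphere.}
#'   \item{msr_mm}{minimum structure resolution: 0.6-mm vessel diameter.}
#'   \item{mdv_cm_s}{minimum detectable mean flow velocity: 3 cm/s.}
#'   \item{t_dose_max_s}{maximum single-dose exposure: 30 s.}
#'   \item{ri_threshold}{resistive index below which a branch is classified
#'     as a bleeder: 0.75 (strict inequality).}
#'   \item{skin_intensity_limit_w_cm2}{skin intensity cap: 6 W/cm^2.}
#'   \item{targeting_tol_mm}{closed-loop targeting convergence tolerance: 3 mm.}
#' }
#'
#' @return A named list of constants.
#' @export
dbac_requirements <- function() {
  list(
    min_rc = 3.75, max_rc = 12.5,          # cm
    min_dp = 3.75, max_dp = 12.5,          # cm
    min_td_lo = 33, min_td_hi = 58,        # deg C (delta T at end of dose)
    mtsd = 20,                             # deg C skin delta T
    mttd_radius_cm = 1,
    mtv_diameter_mm = 8,
    msr_mm = 0.6,
    mdv_cm_s = 3,
    t_dose_max_s = 30,
    ri_threshold = 0.75,
    skin_intensity_limit_w_cm2 = 6,
    targeting_tol_mm = 3
  )
}

# Tile aperture geometry: 4 acoustic modules of 52 x 13 mm (96 x 12 elements)
# stacked in elevation into a 52 x 52 mm, 4608-element square tile.
TILE_AM_AZ_MM <- 52
TILE_AM_EL_MM <- 13
TILE_AM_N_AZ <- 96L
TILE_AM_N_EL <- 12L
TILE_N_AM <- 4L
TILE_N_ELEMENTS <- TILE_N_AM * TILE_AM_N_AZ * TILE_AM_N_EL  # 4608
TILE_APERTURE_CM2 <- TILE_N_AM * (TILE_AM_AZ_MM / 10) * (TILE_AM_EL_MM / 10)
TILE_STEER_AZ_DEG <- 60
TILE_STEER_EL_DEG <- 45
TILE_FC_MHZ <- 1
IX_FC_MHZ <- 2.5
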