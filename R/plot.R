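# Base-graphics views of the main objects.

#' Plot a flow waveform
#' @param x a `flow_waveform`.
#' @param ... passed to `plot`.
#' @export
plot.flow_waveform <- function(x, ...) {
  graphics::plot(x$time, x$velocity, type = "l", xlab = "time (s)",
                 ylab = "velocity (cm/s)",
                 main = sprintf("%s  RI = %.2f", x$profile, compute_ri(x)), ...)
  graphics::abline(h = c(x$V_systole, x$V_diastole), lty = 3, col = "grey40")
  invisible(x)
}

#' Cross-section plot of a cuff on a phantom
#' @param x a `cuff_geometry`.
#' @param phantom optional `limb_phantom` drawn inside.
#' @param ... passed to `plot`.
#' @export
plot.cuff_geometry <- function(x, phantom = NULL, ...) {
  r <- x$apothem_mm / cos(pi / x$n_panels) * 1.1
  graphics::plot(NA, xlim = c(-r, r), ylim = c(-r, r), asp = 1,
                 xlab = "x (mm)", ylab = "y (mm)",
                 main = sprintf("%d-panel cuff", x$n_panels), ...)
  th <- seq(0, 2 * pi, length.out = 181)
  if (!is.null(phantom)) {
    R <- phantom$diameter_cm * 5
    graphics::lines(R * cos(th), R * sin(th), col = "tan3")
    for (b in phantom$bones)
      graphics::lines(b$center[1] + b$radius_mm * cos(th),
                      b$center[2] + b$radius_mm * sin(th), col = "grey50")
  }
  for (tl in x$tiles) {
    e1 <- tl$center + 26 * tl$u; e2 <- tl$center - 26 * tl$u
    graphics::segments(e1[1], e1[2], e2[1], e2[2], lwd = 3, col = "steelblue")
  }
  for (pr in x$probes)
    graphics::points(pr$center[1], pr$center[2], pch = 17, col = "firebrick")
  invisible(x)
}

#' Plot the vessel tree projected on a coordinate plane
#' @param x a `vessel_tree`.
#' @param plane "xy", "xz" or "yz".
#' @param ... passed to `plot`.
#' @export
plot.vessel_tree <- function(x, plane = "xy", ...) {
  ax <- switch(plane, xy = c(1, 2), xz = c(1, 3), yz = c(2, 3))
  pts <- do.call(rbind, lapply(x$branches, `[[`, "points"))
  graphics::plot(NA, xlim = range(pts[, ax[1]]), ylim = range(pts[, ax[2]]),
                 asp = 1, xlab = paste0(substr(plane, 1, 1), " (mm)"),
                 ylab = paste0(substr(plane, 2, 2), " (mm)"), ...)
  for (b in x$branches)
    graphics::lines(b$points[, ax[1]], b$points[, ax[2]],
                    lwd = 1 + b$radius_mm,
                    col = if (b$flag == "bleeder") "firebrick" else "steelblue4")
  if (nrow(x$bifurcations))
    graphics::points(x$bifurcations[, ax[1]], x$bifurcations[, ax[2]],
                     pch = 19, cex = 0.7)
  invisible(x)
}

#' Midplane heat map of a thermal field
#' @param x a `thermal_field`.
#' @param ... passed to `image`.
#' @export
plot.thermal_field <- function(x, ...) {
  k <- ceiling(x$dims[3] / 2)
  ax <- lapply(1:2, function(a)
    x$origin[a] + (seq_len(x$dims[a]) - 0.5) * x$voxel_size)
  graphics::image(ax[[1]], ax[[2]], x$final[, , k],
                  col = grDevices::hcl.colors(64, "Inferno"), asp = 1,
                  xlab = "x (mm)", ylab = "y (mm)",
                  main = sprintf("dT at t = %g s (mid-z)", x$t_dose_s), ...)
  invisible(x)
}
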