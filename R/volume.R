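# Regular scalar volumes in the limb frame.
# Voxels are 0-based with half-open extents: voxel (i,j,k) covers
# origin + [i,i+1) * voxel_size along x, etc.; its centre is at
# origin + (i + 0.5) * voxel_size.

#' Construct a Doppler (or generic scalar) volume
#'
#' @param grid 3D numeric array (x, y, z order).
#' @param voxel_size_mm isotropic voxel edge (mm).
#' @param origin_mm coordinate (mm, limb frame) of the low corner of voxel
#'   (0,0,0).
#' @param modality "P-mode", "B-mode" or "C-mode".
#' @return object of class `doppler_volume`.
#' @export
doppler_volume <- function(grid, voxel_size_mm, origin_mm,
                           modality = "P-mode") {
  stopifnot(length(dim(grid)) == 3, voxel_size_mm > 0,
            length(origin_mm) == 3)
  structure(list(grid = grid, voxel_size = voxel_size_mm,
                 origin = origin_mm, modality = modality),
            class = "doppler_volume")
}

#' @export
print.doppler_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<doppler_volume> %s  %dx%dx%d @ %.3g mm  origin (%.1f, %.1f, %.1f) mm\n",
              x$modality, d[1], d[2], d[3], x$voxel_size,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

# voxel-centre coordinates along each axis
voxel_axes <- function(vol) {
  d <- dim(vol$grid)
  lapply(1:3, function(a) vol$origin[a] + (seq_len(d[a]) - 0.5) * vol$voxel_size)
}

# world (mm) -> 1-based voxel index, clamped
world_to_index <- function(vol, p) {
  d <- dim(vol$grid)
  i <- floor((p - vol$origin) / vol$voxel_size) + 1
  pmin(pmax(i, 1), d)
}

index_to_world <- function(vol, ijk) {
  vol$origin + (ijk - 0.5) * vol$voxel_size
}

#' Save / load a volume (RDS payload)
#'
#' Volumes are numeric 3D payloads; they are persisted as RDS with the
#' voxel size and origin carried inside the object.
#' @param vol a `doppler_volume`.
#' @param path output path (.rds).
#' @export
write_volume <- function(vol, path) { saveRDS(vol, path); invisible(path) }

#' @rdname write_volume
#' @export
read_volume <- function(path) readRDS(path)

# ---------------------------------------------------------------------------
# Rasterize the vessel tree into a voxel grid. Returns lumen mask plus
# per-voxel flow speed (cm/s), unit flow direction, and branch id.
rasterize_tree <- function(tree, voxel_size, bbox = NULL) {
  if (is.null(bbox)) bbox <- tree_bbox(tree)
  origin <- bbox$lo
  dims <- pmax(2L, as.integer(ceiling((bbox$hi - bbox$lo) / voxel_size)))
  lumen <- array(FALSE, dims)
  speed <- array(0, dims)
  dirx <- array(0, dims); diry <- array(0, dims); dirz <- array(0, dims)
  bid <- array(0L, dims)
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 0.5) * voxel_size)
  for (b in seq_along(tree$branches)) {
    br <- tree$branches[[b]]
    r <- br$radius_mm
    v <- br$waveform$mean_velocity
    pts <- br$points
    for (s in seq_len(nrow(pts) - 1)) {
      a <- pts[s, ]; bpt <- pts[s + 1, ]
      tdir <- bpt - a
      L <- sqrt(sum(tdir^2))
      if (L == 0) next
      tdir <- tdir / L
      lo <- pmin(a, bpt) - r - voxel_size
      hi <- pmax(a, bpt) + r + voxel_size
      i0 <- pmax(1L, floor((lo - origin) / voxel_size) + 1L)
      i1 <- pmin(dims, ceiling((hi - origin) / voxel_size))
      if (any(i0 > i1)) next
      xs <- ax[[1]][i0[1]:i1[1]]; ys <- ax[[2]][i0[2]:i1[2]]
      zs <- ax[[3]][i0[3]:i1[3]]
      g <- expand.grid(x = xs, y = ys, z = zs)
      dx <- g$x - a[1]; dy <- g$y - a[2]; dz <- g$z - a[3]
      tpar <- pmin(pmax((dx * tdir[1] + dy * tdir[2] + dz * tdir[3]) / L, 0), 1)
      px <- a[1] + tpar * (bpt[1] - a[1]); py <- a[2] + tpar * (bpt[2] - a[2])
      pz <- a[3] + tpar * (bpt[3] - a[3])
      inside <- (g$x - px)^2 + (g$y - py)^2 + (g$z - pz)^2 <= r^2
      if (!any(inside)) next
      sub <- array(FALSE, i1 - i0 + 1L)
      sub[inside] <- TRUE
      ix <- i0[1]:i1[1]; iy <- i0[2]:i1[2]; iz <- i0[3]:i1[3]
      cur <- lumen[ix, iy, iz, drop = FALSE]
      lumen[ix, iy, iz] <- cur | sub
      spd <- speed[ix, iy, iz, drop = FALSE]; spd[sub] <- v
      speed[ix, iy, iz] <- spd
      w <- bid[ix, iy, iz, drop = FALSE]; w[sub] <- b
      bid[ix, iy, iz] <- w
      d1 <- dirx[ix, iy, iz, drop = FALSE]; d1[sub] <- tdir[1]
      dirx[ix, iy, iz] <- d1
      d2 <- diry[ix, iy, iz, drop = FALSE]; d2[sub] <- tdir[2]
      diry[ix, iy, iz] <- d2
      d3 <- dirz[ix, iy, iz, drop = FALSE]; d3[sub] <- tdir[3]
      dirz[ix, iy, iz] <- d3
    }
  }
  list(lumen = lumen, speed = speed, dir = list(x = dirx, y = diry, z = dirz),
       branch = bid, origin = origin, voxel_size = voxel_size, dims = dims)
}
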