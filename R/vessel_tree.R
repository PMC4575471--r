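# Synthetic vascular tree generator.
#
# Trees are built by recursive binary branching from a root artery, with
# child radii following a Murray-type law r_p^2.5 = r_1^2.5 + r_2^2.5.
# Bleeder branches are straight vented stubs (leaves) of length >= 30 mm so
# that the thermocouple marker 20 mm downstream of the bifurcation lies on
# the branch. Branch polylines wander gently so centerline extraction is
# exercised on curved vessels.

MURRAY_EXP <- 2.5
MIN_VESSEL_DIAMETER_MM <- 0.6
BLEEDER_STUB_MIN_MM <- 30
TC_DOWNSTREAM_MM <- 20

# Grow one polyline branch from `start` along `dir`, total length L (mm),
# in steps of ~5 mm with small direction jitter, steering back inside the
# cylinder (radius limit rmax, |z| limit zmax) when necessary.
grow_polyline <- function(start, dir, L, rng, rmax, zmax, wiggle = 0.12,
                          straight = FALSE) {
  step <- 5
  n_steps <- max(2, ceiling(L / step))
  pts <- matrix(0, n_steps + 1, 3)
  pts[1, ] <- start
  d <- unitv(dir)
  for (i in seq_len(n_steps)) {
    if (!straight) {
      ax <- unitv(rng$rnorm(3))
      d <- as.vector(rot_axis(ax, rng$rnorm(1, 0, wiggle)) %*% d)
    }
    nxt <- pts[i, ] + d * (L / n_steps)
    # steer back toward the axis / interior if leaving the safe region
    rad <- sqrt(sum(nxt[1:2]^2))
    if (rad > rmax) {
      inward <- unitv(c(-nxt[1], -nxt[2], 0))
      d <- unitv(d + 0.8 * inward)
      nxt <- pts[i, ] + d * (L / n_steps)
    }
    if (abs(nxt[3]) > zmax) {
      d <- unitv(d - c(0, 0, 1.5 * sign(nxt[3])))
      nxt <- pts[i, ] + d * (L / n_steps)
    }
    pts[i + 1, ] <- nxt
  }
  pts
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

# Point at arclength s along polyline (clamped to the end).
polyline_point_at <- function(pts, s) {
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  cs <- cumsum(seg)
  if (s <= 0) return(pts[1, ])
  if (s >= cs[length(cs)]) return(pts[nrow(pts), ])
  i <- which(cs >= s)[1]
  s0 <- if (i == 1) 0 else cs[i - 1]
  f <- (s - s0) / seg[i]
  pts[i, ] + f * (pts[i + 1, ] - pts[i, ])
}

# Direction (unit tangent, downstream) at arclength s.
polyline_dir_at <- function(pts, s) {
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  cs <- cumsum(seg)
  i <- if (s >= cs[length(cs)]) length(seg) else which(cs >= max(s, 1e-9))[1]
  unitv(pts[i + 1, ] - pts[i, ])
}

#' Generate a synthetic vascular tree inside a cylindrical limb
#'
#' Builds a binary branching arterial tree with `n_bifurcations` junctions,
#' of which `n_bleeders` carry a vented bleeder stub as one outgoing branch.
#' Branching half-angles scale with limb diameter (narrower trees in small
#' limbs). Every branch carries a pulsatile flow waveform: `normal` profile
#' on intact branches, `bleeder` profile (low resistive index) on vented
#' stubs. Thermocouple markers are placed 20 mm downstream of the
#' bifurcation on each bleeder branch.
#'
#' @param diameter_cm limb diameter (cm); sets the radial extent.
#' @param length_cm limb length (cm).
#' @param n_bifurcations number of junction nodes.
#' @param n_bleeders number of bleeder stubs (<= n_bifurcations).
#' @param seed RNG seed.
#' @param root_radius_mm lumen radius of the root artery (default 2.5 mm,
#'   i.e. a 5-mm femoral-scale vessel).
#' @param mean_velocity_cm_s mean flow velocity in the root (scales down
#'   branch-wise with radius).
#' @param bleeder_velocity_cm_s mean velocity in bleeder stubs (default
#'   equal to the local branch velocity; set 3 for minimum-detectable-
#'   velocity studies).
#' @param bleeder_profile waveform profile used on bleeder stubs
#'   ("bleeder" or "irregular-slow").
#' @param bleeder_radius_mm optional override of the bleeder stub lumen
#'   radius (e.g. 0.3 for a 0.6-mm minimum-structure-resolution bleeder);
#'   default inherits the converted branch's Murray radius.
#' @param heart_rate bpm.
#' @return Object of class `vessel_tree`: list of `branches` (each with
#'   `points` polyline mm, `radius_mm`, `flag`, `parent`, `waveform`),
#'   `bifurcations` (matrix of junction coordinates), `tc_markers`.
#' @export
make_vessel_tree <- function(diameter_cm, length_cm, n_bifurcations,
                             n_bleeders, seed,
                             root_radius_mm = 2.5,
                             mean_velocity_cm_s = 20,
                             bleeder_velocity_cm_s = NULL,
                             bleeder_profile = "bleeder",
                             bleeder_radius_mm = NULL,
                             heart_rate = 60) {
  stopifnot(n_bleeders <= n_bifurcations, n_bifurcations >= 0)
  rng <- local_rng(seed)
  R <- diameter_cm * 10 / 2             # mm
  zmax <- length_cm * 10 / 2 - 3
  rmax <- R - max(3, 0.1 * R)           # keep lumen strictly interior
  half_angle <- deg2rad(28 * diameter_cm / 25 + 8)  # narrower in small limbs

  branches <- list()
  # root enters at the lower end, on-axis (deep), heading +z
  root_pts <- grow_polyline(c(0, 0, -zmax + 1), c(0, 0, 1),
                            L = max(15, zmax * 0.6), rng = rng,
                            rmax = rmax * 0.4, zmax = zmax)
  branches[[1]] <- list(points = root_pts, radius_mm = root_radius_mm,
                        flag = "normal", parent = NA_integer_, depth_gen = 0L)
  open_branches <- 1L                   # branch ids whose tip can bifurcate
  n_bif_made <- 0L
  bif_at_branch <- integer(0)           # branch id whose tip is each junction

  while (n_bif_made < n_bifurcations && length(open_branches) > 0) {
    # bifurcate the open branch with the largest radius (proximal first)
    radii <- vapply(open_branches, function(i) branches[[i]]$radius_mm, 0)
    b <- open_branches[which.max(radii)]
    open_branches <- setdiff(open_branches, b)
    parent <- branches[[b]]
    tip <- parent$points[nrow(parent$points), ]
    tdir <- polyline_dir_at(parent$points, Inf)
    # Murray split with random asymmetry
    f <- rng$runif(1, 0.4, 0.6)
    rp <- parent$radius_mm
    r1 <- max(rp * f^(1 / MURRAY_EXP), MIN_VESSEL_DIAMETER_MM / 2)
    r2 <- max(rp * (1 - f)^(1 / MURRAY_EXP), MIN_VESSEL_DIAMETER_MM / 2)
    # children directions: rotate tangent by +/- half_angle about a random
    # axis perpendicular to the tangent
    perp <- unitv(pracma_cross(tdir, unitv(rng$rnorm(3))))
    a1 <- half_angle * rng$runif(1, 0.7, 1.3)
    a2 <- -half_angle * rng$runif(1, 0.7, 1.3)
    for (k in 1:2) {
      ang <- if (k == 1) a1 else a2
      rad <- if (k == 1) r1 else r2
      d <- as.vector(rot_axis(perp, ang) %*% tdir)
      L <- rng$runif(1, 18, 30)
      pts <- grow_polyline(tip, d, L, rng, rmax, zmax)
      branches[[length(branches) + 1]] <-
        list(points = pts, radius_mm = rad, flag = "normal", parent = b,
             depth_gen = parent$depth_gen + 1L)
      open_branches <- c(open_branches, length(branches))
    }
    n_bif_made <- n_bif_made + 1L
    bif_at_branch <- c(bif_at_branch, b)
  }

  # convert children into bleeder stubs at n_bleeders junctions; pick the
  # deepest junctions (closest to the axis) first so at least one bleeder
  # is deeper than diameter/4
  if (n_bleeders > 0) {
    jc <- t(vapply(bif_at_branch, function(b) {
      p <- branches[[b]]$points; p[nrow(p), ]
    }, numeric(3)))
    ord <- order(sqrt(jc[, 1]^2 + jc[, 2]^2))      # deepest first
    # prefer junctions that still have a leaf child (the stub replaces it
    # directly); junctions whose children both bifurcated further require
    # pruning the chosen child's subtree
    has_leaf <- vapply(bif_at_branch, function(b) {
      kids <- which(vapply(branches, function(x) identical(x$parent, b), TRUE))
      any(vapply(kids, function(k)
        !any(vapply(branches, function(x) identical(x$parent, k), TRUE)), TRUE))
    }, TRUE)
    ranked <- c(bif_at_branch[ord][has_leaf[ord]],
                bif_at_branch[ord][!has_leaf[ord]])
    chosen <- ranked[seq_len(min(n_bleeders, length(ranked)))]
    pruned <- integer(0)
    for (b in chosen) {
      if (b %in% pruned) next           # junction vanished with a subtree
      kids <- which(vapply(branches, function(x) identical(x$parent, b), TRUE))
      kids <- setdiff(kids, pruned)
      # prefer a leaf child (no grandchildren) to keep the tree connected
      is_leaf <- vapply(kids, function(k)
        !any(vapply(branches, function(x) identical(x$parent, k), TRUE)), TRUE)
      k <- if (any(is_leaf)) kids[is_leaf][which.min(
        vapply(kids[is_leaf], function(i) branches[[i]]$radius_mm, 0))] else kids[1]
      if (!is_leaf[match(k, kids)]) {
        # vented stub replaces the whole subtree below this child
        stack <- k
        while (length(stack)) {
          desc <- which(vapply(branches, function(x)
            x$parent %in% stack[1], TRUE))
          pruned <- c(pruned, setdiff(desc, k))
          stack <- c(stack[-1], desc)
        }
      }
      tip <- branches[[b]]$points[nrow(branches[[b]]$points), ]
      d0 <- polyline_dir_at(branches[[k]]$points, 0.1)
      sib <- setdiff(kids, k)
      d_sib <- if (length(sib)) polyline_dir_at(branches[[sib[1]]]$points, 0.1)
               else c(0, 0, 1)
      # straight vented stub, long enough to carry the 20-mm TC marker,
      # steered away from the sibling branch (so the lumens stay resolved)
      # and gently toward the axis so the marker stays deep
      inward <- if (sqrt(sum(tip[1:2]^2)) > 1)
        unitv(c(-tip[1], -tip[2], 0)) else c(0, 0, 0)
      d <- unitv(d0 - 0.45 * d_sib + 0.2 * inward)
      L <- max(BLEEDER_STUB_MIN_MM + 5, 35)
      pts <- grow_polyline(tip, d, L, rng, rmax, zmax, straight = TRUE)
      branches[[k]]$points <- pts
      branches[[k]]$flag <- "bleeder"
      if (!is.null(bleeder_radius_mm))
        branches[[k]]$radius_mm <- max(bleeder_radius_mm,
                                       MIN_VESSEL_DIAMETER_MM / 2)
    }
    if (length(pruned)) {
      # compact the branch list: drop pruned subtrees, remap indices
      keep <- setdiff(seq_along(branches), pruned)
      remap <- match(seq_along(branches), keep)
      branches <- lapply(branches[keep], function(br) {
        if (!is.na(br$parent)) br$parent <- remap[br$parent]
        br
      })
      bif_at_branch <- remap[bif_at_branch]
      bif_at_branch <- bif_at_branch[!is.na(bif_at_branch)]
    }
  }

  # waveforms: velocity scales with sqrt(radius ratio); bleeder stubs use
  # the bleeder profile
  for (i in seq_along(branches)) {
    br <- branches[[i]]
    v <- max(3, mean_velocity_cm_s * sqrt(br$radius_mm / root_radius_mm))
    if (br$flag == "bleeder") {
      vb <- if (is.null(bleeder_velocity_cm_s)) v else bleeder_velocity_cm_s
      branches[[i]]$waveform <- make_flow_waveform(bleeder_profile, vb,
                                                   heart_rate, seed + 1000 + i)
    } else {
      branches[[i]]$waveform <- make_flow_waveform("normal", v, heart_rate,
                                                   seed + 1000 + i)
    }
  }

  bif_pts <- if (length(bif_at_branch))
    t(vapply(bif_at_branch, function(b) {
      p <- branches[[b]]$points; p[nrow(p), ]
    }, numeric(3)))
  else matrix(0, 0, 3)

  tc <- lapply(which(vapply(branches, function(x) x$flag == "bleeder", TRUE)),
               function(i) {
                 list(branch = i,
                      point = polyline_point_at(branches[[i]]$points,
                                                TC_DOWNSTREAM_MM))
               })

  structure(list(branches = branches, bifurcations = bif_pts,
                 bif_at_branch = bif_at_branch, tc_markers = tc,
                 diameter_cm = diameter_cm, length_cm = length_cm),
            class = "vessel_tree")
}

#' @export
print.vessel_tree <- function(x, ...) {
  nb <- sum(vapply(x$branches, function(b) b$flag == "bleeder", TRUE))
  cat(sprintf("<vessel_tree> %d branches, %d bifurcations, %d bleeders\n",
              length(x$branches), nrow(x$bifurcations), nb))
  invisible(x)
}

# Bounding box (mm) of all branch polylines, padded by max radius.
tree_bbox <- function(tree, pad = 2) {
  pts <- do.call(rbind, lapply(tree$branches, `[[`, "points"))
  rmax <- max(vapply(tree$branches, `[[`, 0, "radius_mm"))
  list(lo = apply(pts, 2, min) - rmax - pad,
       hi = apply(pts, 2, max) + rmax + pad)
}

# ground-truth bleeder branch ids
bleeder_branch_ids <- function(tree) {
  which(vapply(tree$branches, function(b) b$flag == "bleeder", TRUE))
}
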