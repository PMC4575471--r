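# Time-of-flight array registration: simulate sub-aperture arrival times
# through the layered water-jacket + tissue medium, then recover all
# sub-aperture positions and the two layer sound speeds by alternating
# multilateration (positions | slownesses), and derive array poses by
# rigid fitting of each array's nominal sub-aperture layout.
#
# Rays are straight two-segment paths split by the (known) limb cylinder;
# at the few-percent speed contrast between degassed water and tissue
# surrogate the Snell bend is a fraction of a degree and is neglected on
# both the forward and inverse sides.

# local sub-aperture layout (mm, in the array's (u, v) plane):
# 4 corners + center; tiles span the 52 x 52 mm face, probes a smaller
# footprint.
sub_aperture_layout <- function(kind = c("tx", "ix")) {
  kind <- match.arg(kind)
  s <- if (kind == "tx") 23 else 9
  rbind(c(-s, -s, 0), c(s, -s, 0), c(s, s, 0), c(-s, s, 0), c(0, 0, 0))
}

# all sub-aperture world positions of a cuff; returns matrix + index table
cuff_sub_apertures <- function(cuff) {
  pos <- NULL
  tab <- NULL
  add <- function(arr, kind, aid) {
    lay <- sub_aperture_layout(kind)
    P <- t(apply(lay, 1, function(o)
      arr$center + o[1] * arr$u + o[2] * arr$v))
    pos <<- rbind(pos, P)
    tab <<- rbind(tab, data.frame(kind = kind, array_id = aid,
                                  sub = seq_len(nrow(P))))
  }
  for (tl in cuff$tiles) add(tl, "tx", tl$id)
  for (pr in cuff$probes) add(pr, "ix", pr$id)
  list(pos = pos, table = tab)
}

#' Randomly perturb the as-worn cuff geometry
#'
#' Applies small independent position and orientation errors to every
#' array, emulating the deviation of a flexible worn cuff from its nominal
#' polygon. The nominal cuff remains the solver's initial estimate.
#'
#' @param cuff a `cuff_geometry`.
#' @param pos_sd_mm per-array position noise SD.
#' @param rot_sd_deg per-array orientation noise SD.
#' @param seed RNG seed.
#' @return a perturbed `cuff_geometry`.
#' @export
perturb_cuff <- function(cuff, pos_sd_mm = 2, rot_sd_deg = 1, seed = 1) {
  rng <- local_rng(seed)
  jig <- function(arr) {
    arr$center <- arr$center + rng$rnorm(3, 0, pos_sd_mm)
    ax <- unitv(rng$rnorm(3))
    Rm <- rot_axis(ax, deg2rad(rng$rnorm(1, 0, rot_sd_deg)))
    arr$normal <- as.vector(Rm %*% arr$normal)
    arr$u <- as.vector(Rm %*% arr$u)
    arr$v <- as.vector(Rm %*% arr$v)
    arr
  }
  cuff$tiles <- lapply(cuff$tiles, jig)
  cuff$probes <- lapply(cuff$probes, jig)
  cuff
}

#' Remove arrays from a cuff (degraded-cuff scenarios)
#' @param cuff a `cuff_geometry`.
#' @param tile_ids,probe_ids ids to drop.
#' @export
remove_arrays <- function(cuff, tile_ids = integer(0), probe_ids = integer(0)) {
  cuff$tiles <- Filter(function(t) !(t$id %in% tile_ids), cuff$tiles)
  cuff$probes <- Filter(function(p) !(p$id %in% probe_ids), cuff$probes)
  cuff
}

# pairwise two-segment path lengths: water and tissue components of the
# straight segments P[i,] -> Q[i,] through the limb cylinder (radius R)
path_split <- function(P, Q, R) {
  dx <- Q[, 1] - P[, 1]; dy <- Q[, 2] - P[, 2]; dz <- Q[, 3] - P[, 3]
  L <- sqrt(dx^2 + dy^2 + dz^2)
  ux <- dx / L; uy <- dy / L
  a <- ux^2 + uy^2
  b <- 2 * (P[, 1] * ux + P[, 2] * uy)
  cc <- P[, 1]^2 + P[, 2]^2 - R^2
  disc <- b^2 - 4 * a * cc
  tis <- numeric(length(L))
  hit <- disc > 0 & a > 1e-12
  if (any(hit)) {
    s <- sqrt(disc[hit])
    t1 <- (-b[hit] - s) / (2 * a[hit]); t2 <- (-b[hit] + s) / (2 * a[hit])
    lo <- pmax(0, pmin(t1, t2)); hi <- pmin(L[hit], pmax(t1, t2))
    tis[hit] <- pmax(0, hi - lo)
  }
  par <- a <= 1e-12
  if (any(par)) tis[par] <- ifelse(cc[par] <= 0, L[par], 0)
  list(water = L - tis, tissue = tis, total = L)
}

#' Simulate sub-aperture time-of-flight measurements
#'
#' Every ordered pair of sub-apertures on distinct arrays whose connecting
#' ray lies within `max_angle_deg` of both face normals (steerability) and
#' is not blocked by a bone contributes one arrival time:
#' t = L_water / c_water + L_tissue / c_tissue + jitter,
#' with the water/tissue split taken along the straight ray through the
#' limb cylinder.
#'
#' @param cuff the as-worn (`perturb_cuff`ed) `cuff_geometry` -- ground
#'   truth for the measurement.
#' @param phantom a `limb_phantom` (limb radius, tissue speed, bones).
#' @param jitter_sd_s arrival-time jitter SD (s); default one carrier
#'   period at 2.5 MHz (0.4 us).
#' @param seed RNG seed.
#' @param c_water_m_s water-jacket sound speed.
#' @param max_angle_deg maximum ray angle off either face normal.
#' @return object of class `tof_set`: `pairs` data.frame
#'   (emitter, receiver, t_s), sub-aperture `table`, media description.
#' @export
simulate_tof <- function(cuff, phantom, jitter_sd_s = 0.4e-6, seed = 1,
                         c_water_m_s = 1480, max_angle_deg = 72) {
  sa <- cuff_sub_apertures(cuff)
  n <- nrow(sa$pos)
  R <- phantom$diameter_cm * 10 / 2
  ct <- phantom$tissue$sound_speed
  # face normals per sub-aperture
  normals <- matrix(0, n, 3)
  arrays <- c(cuff$tiles, cuff$probes)
  ai <- paste(sa$table$kind, sa$table$array_id)
  akey <- c(paste("tx", vapply(cuff$tiles, `[[`, 0L, "id")),
            paste("ix", vapply(cuff$probes, `[[`, 0L, "id")))
  for (i in seq_len(n)) normals[i, ] <- arrays[[match(ai[i], akey)]]$normal
  em <- rep(seq_len(n), each = n)
  rc <- rep(seq_len(n), times = n)
  keep <- ai[em] != ai[rc] & em < rc
  em <- em[keep]; rc <- rc[keep]
  P <- sa$pos[em, , drop = FALSE]; Q <- sa$pos[rc, , drop = FALSE]
  d <- Q - P
  L <- sqrt(rowSums(d^2))
  cos_e <- rowSums(d * normals[em, , drop = FALSE]) / L
  cos_r <- rowSums(-d * normals[rc, , drop = FALSE]) / L
  amin <- cos(deg2rad(max_angle_deg))
  ok <- cos_e >= amin & cos_r >= amin
  em <- em[ok]; rc <- rc[ok]; P <- P[ok, , drop = FALSE]; Q <- Q[ok, , drop = FALSE]
  if (length(phantom$bones)) {
    blocked <- vapply(seq_along(em), function(i)
      bone_occluded(phantom, P[i, ], Q[i, ]), TRUE)
    em <- em[!blocked]; rc <- rc[!blocked]
    P <- P[!blocked, , drop = FALSE]; Q <- Q[!blocked, , drop = FALSE]
  }
  sp <- path_split(P, Q, R)
  t <- sp$water / (c_water_m_s * 1000) + sp$tissue / (ct * 1000)  # mm / (mm/s)
  if (jitter_sd_s > 0) {
    rng <- local_rng(seed)
    t <- t + rng$rnorm(length(t), 0, jitter_sd_s)
  }
  structure(list(pairs = data.frame(emitter = em, receiver = rc, t_s = t),
                 table = sa$table,
                 limb_radius_mm = R,
                 jitter_sd_s = jitter_sd_s,
                 c_water_true = c_water_m_s, c_tissue_true = ct),
            class = "tof_set")
}

#' @export
print.tof_set <- function(x, ...) {
  cat(sprintf("<tof_set> %d measurements over %d sub-apertures (jitter %.2g us)\n",
              nrow(x$pairs), nrow(x$table), x$jitter_sd_s * 1e6))
  invisible(x)
}

#' Write a ToF measurement set as CSV (`emitter,receiver,t_s`)
#' @param tof a `tof_set`.
#' @param path output path.
#' @export
write_tof_csv <- function(tof, path) {
  utils::write.csv(tof$pairs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Recover array poses and layer sound speeds from time-of-flight data
#'
#' Alternating multilateration: given positions, the two layer slownesses
#' follow from linear least squares on t = L_w u_w + L_t u_t; given
#' slownesses, every sub-aperture position is refined by Gauss-Newton on
#' its incident measurements (numeric Jacobian), with a weak prior pull
#' toward the polygon initial estimate to pin the rigid gauge. Array poses
#' come from a rigid (Kabsch) fit of each array's nominal sub-aperture
#' layout to its solved positions; the cuff's polygon side count is
#' identified by clustering the solved tile-normal azimuths.
#'
#' @param tof a `tof_set`.
#' @param polygon_prior the nominal (unperturbed) `cuff_geometry` used as
#'   the initial estimate.
#' @param n_outer alternation rounds.
#' @param prior_sd_mm prior SD (mm) of the gauge regularization.
#' @param c_water0,c_tissue0 initial speed guesses (m/s).
#' @return object of class `pose_estimate`: `arrays` (kind, id, center,
#'   normal), `sub_positions`, `c_water`, `c_tissue`, `rms_residual_s`,
#'   `side_count`.
#' @export
solve_poses <- function(tof, polygon_prior, n_outer = 8, prior_sd_mm = 25,
                        c_water0 = 1500, c_tissue0 = 1500) {
  sa0 <- cuff_sub_apertures(polygon_prior)
  if (nrow(sa0$table) != nrow(tof$table) ||
      any(paste(sa0$table$kind, sa0$table$array_id) !=
          paste(tof$table$kind, tof$table$array_id)))
    stop("polygon prior does not match the measurement sub-aperture table")
  X <- sa0$pos
  n <- nrow(X)
  em <- tof$pairs$emitter; rc <- tof$pairs$receiver; tm <- tof$pairs$t_s
  deg <- tabulate(c(em, rc), nbins = n)
  if (any(deg < 3))
    stop(sprintf("under-determined geometry: %d sub-aperture(s) with < 3 measurements",
                 sum(deg < 3)))
  R <- tof$limb_radius_mm
  uw <- 1 / (c_water0 * 1000); ut <- 1 / (c_tissue0 * 1000)  # s/mm
  pred <- function(X) {
    sp <- path_split(X[em, , drop = FALSE], X[rc, , drop = FALSE], R)
    sp$water * uw + sp$tissue * ut
  }
  # gauge prior scaled to the measurement noise: with exact times the data
  # dominate completely; with jitter the prior only pins the rigid gauge
  sigma_range_mm <- max(tof$jitter_sd_s, 1e-9) * 1.5e6   # ~ c * jitter
  w_prior <- (sigma_range_mm / prior_sd_mm)^2
  for (outer in seq_len(n_outer)) {
    # (a) slownesses by linear LS
    sp <- path_split(X[em, , drop = FALSE], X[rc, , drop = FALSE], R)
    A <- cbind(sp$water, sp$tissue)
    sol <- stats::lm.fit(A, tm)$coefficients
    if (!any(is.na(sol))) { uw <- sol[1]; ut <- sol[2] }
    # (b) per-point Gauss-Newton updates
    tau_scale <- 1 / uw                       # mm per s, to condition J
    for (i in seq_len(n)) {
      rows_e <- which(em == i); rows_r <- which(rc == i)
      oth <- c(rc[rows_e], em[rows_r])
      ti <- c(tm[rows_e], tm[rows_r])
      if (length(oth) < 3) next
      Po <- X[oth, , drop = FALSE]
      f <- function(p) {
        sp <- path_split(matrix(p, length(oth), 3, byrow = TRUE), Po, R)
        sp$water * uw + sp$tissue * ut
      }
      for (gn in 1:2) {
        p0 <- X[i, ]
        r0 <- ti - f(p0)
        J <- matrix(0, length(oth), 3)
        dl <- 0.05
        for (a in 1:3) {
          dp <- p0; dm <- p0
          dp[a] <- dp[a] + dl; dm[a] <- dm[a] - dl
          J[, a] <- (f(dp) - f(dm)) / (2 * dl)
        }
        # scaled normal equations with gauge prior toward the polygon
        Js <- J * tau_scale; rs <- r0 * tau_scale
        H <- crossprod(Js) + w_prior * diag(3)
        g <- crossprod(Js, rs) + w_prior * (sa0$pos[i, ] - p0)
        step <- tryCatch(solve(H, g), error = function(e) rep(0, 3))
        X[i, ] <- p0 + as.vector(step)
      }
    }
  }
  # joint refinement: damped Gauss-Newton over all positions and both
  # slownesses (the alternation above is the initializer; it crawls along
  # sloppy near-gauge modes that the joint step removes)
  rows_of <- lapply(seq_len(n), function(i) which(em == i | rc == i))
  dl <- 0.05
  for (joint in 1:10) {
    sp <- path_split(X[em, , drop = FALSE], X[rc, , drop = FALSE], R)
    r0 <- tm - (sp$water * uw + sp$tissue * ut)
    m <- length(r0)
    J <- matrix(0, m, 3 * n + 2)
    for (i in seq_len(n)) {
      rws <- rows_of[[i]]
      if (!length(rws)) next
      oth <- ifelse(em[rws] == i, rc[rws], em[rws])
      Po <- X[oth, , drop = FALSE]
      for (a in 1:3) {
        pp <- X[i, ]; pm <- X[i, ]
        pp[a] <- pp[a] + dl; pm[a] <- pm[a] - dl
        sp_p <- path_split(matrix(pp, length(rws), 3, byrow = TRUE), Po, R)
        sp_m <- path_split(matrix(pm, length(rws), 3, byrow = TRUE), Po, R)
        J[rws, 3 * (i - 1) + a] <-
          ((sp_p$water - sp_m$water) * uw + (sp_p$tissue - sp_m$tissue) * ut) /
          (2 * dl)
      }
    }
    J[, 3 * n + 1] <- sp$water
    J[, 3 * n + 2] <- sp$tissue
    # column equilibration (positions in mm, slownesses in s/mm differ by
    # ~1e7 in scale); weak gauge prior on the position block
    sc <- 1 / uw                      # time -> mm
    Js <- J * sc; rs <- r0 * sc
    cn <- sqrt(colSums(Js^2)); cn[cn == 0] <- 1
    Jn <- sweep(Js, 2, cn, `/`)
    pos_ix <- seq_len(3 * n)
    H <- crossprod(Jn)
    diag(H)[pos_ix] <- diag(H)[pos_ix] + w_prior / cn[pos_ix]^2
    H <- H + diag(1e-10, nrow(H))
    g <- crossprod(Jn, rs)
    g[pos_ix] <- g[pos_ix] +
      (w_prior / cn[pos_ix]) * as.vector(t(sa0$pos - X))
    stepn <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(stepn)) break
    step <- as.vector(stepn) / cn
    X <- X + matrix(step[pos_ix], n, 3, byrow = TRUE)
    uw <- uw + step[3 * n + 1]
    ut <- ut + step[3 * n + 2]
    if (sqrt(mean(step[pos_ix]^2)) < 1e-7) break
  }
  resid <- tm - pred(X)
  # array poses by rigid fit of the nominal local layout
  keys <- unique(paste(tof$table$kind, tof$table$array_id))
  prior_arrays <- c(polygon_prior$tiles, polygon_prior$probes)
  prior_key <- c(paste("tx", vapply(polygon_prior$tiles, `[[`, 0L, "id")),
                 paste("ix", vapply(polygon_prior$probes, `[[`, 0L, "id")))
  arrays <- lapply(keys, function(k) {
    rows <- which(paste(tof$table$kind, tof$table$array_id) == k)
    kind <- tof$table$kind[rows[1]]
    lay <- sub_aperture_layout(kind)
    tr <- kabsch(lay, X[rows, , drop = FALSE])
    nrm <- as.vector(tr$R %*% c(0, 0, 1))
    uax <- as.vector(tr$R %*% c(1, 0, 0))
    vax <- as.vector(tr$R %*% c(0, 1, 0))
    # the square layout is invariant under a 180-deg in-plane flip, which
    # negates the face normal; pick the branch facing like the prior
    pn <- prior_arrays[[match(k, prior_key)]]$normal
    if (sum(nrm * pn) < 0) { nrm <- -nrm; vax <- -vax }
    list(kind = kind, id = tof$table$array_id[rows[1]],
         center = as.vector(tr$t), normal = nrm, u = uax, v = vax)
  })
  # polygon side count from tile-normal azimuth clustering (10 deg gaps)
  tx_n <- vapply(Filter(function(a) a$kind == "tx", arrays),
                 function(a) atan2(a$normal[2], a$normal[1]), 0)
  side_count <- count_angle_clusters(tx_n, gap = deg2rad(10))
  structure(list(arrays = arrays, sub_positions = X,
                 table = tof$table,
                 c_water = 1 / uw / 1000, c_tissue = 1 / ut / 1000,
                 rms_residual_s = sqrt(mean(resid^2)),
                 side_count = side_count),
            class = "pose_estimate")
}

count_angle_clusters <- function(ang, gap) {
  if (!length(ang)) return(0L)
  a <- sort(ang %% (2 * pi))
  d <- diff(c(a, a[1] + 2 * pi))
  sum(d > gap)
}

#' @export
print.pose_estimate <- function(x, ...) {
  cat(sprintf("<pose_estimate> %d arrays; c_water %.0f, c_tissue %.0f m/s; RMS resid %.3g us; %d sides\n",
              length(x$arrays), x$c_water, x$c_tissue,
              x$rms_residual_s * 1e6, x$side_count))
  invisible(x)
}

#' Registration errors of a pose estimate against the true cuff
#'
#' After best-fit rigid alignment of the estimated array centers to the
#' true (as-worn) geometry: per-array position errors, per-array normal
#' angle errors, and all imaging-to-therapy (Ix-Tx) inter-array distance
#' errors, with medians and maxima. Errors are invariant to any global
#' rigid transform of the estimate.
#'
#' @param est a `pose_estimate`.
#' @param truth the ground-truth `cuff_geometry` (same array ids).
#' @return list of error summaries (mm / degrees).
#' @export
registration_error <- function(est, truth) {
  tr_arr <- c(lapply(truth$tiles, function(t) list(kind = "tx", id = t$id,
                                                   center = t$center,
                                                   normal = t$normal)),
              lapply(truth$probes, function(p) list(kind = "ix", id = p$id,
                                                    center = p$center,
                                                    normal = p$normal)))
  key <- function(a) paste(a$kind, a$id)
  tk <- vapply(tr_arr, key, "")
  ek <- vapply(est$arrays, key, "")
  common <- intersect(ek, tk)
  E <- t(vapply(est$arrays[match(common, ek)], `[[`, numeric(3), "center"))
  Tm <- t(vapply(tr_arr[match(common, tk)], `[[`, numeric(3), "center"))
  En <- t(vapply(est$arrays[match(common, ek)], `[[`, numeric(3), "normal"))
  Tn <- t(vapply(tr_arr[match(common, tk)], `[[`, numeric(3), "normal"))
  tr <- kabsch(E, Tm)
  Ea <- apply_rigid(E, tr)
  Ena <- En %*% t(tr$R)
  pos_err <- sqrt(rowSums((Ea - Tm)^2))
  dotp <- pmin(1, pmax(-1, rowSums(Ena * Tn)))
  ang_err <- rad2deg(acos(dotp))
  kinds <- est$table$kind[match(common, paste(est$table$kind, est$table$array_id))]
  is_tx <- grepl("^tx", common)
  # Ix-Tx pairwise distance errors (rigid-invariant, no alignment needed)
  dist_err <- c()
  ixs <- which(!is_tx); txs <- which(is_tx)
  for (i in ixs) for (j in txs) {
    de <- vnorm(E[i, ] - E[j, ]) - vnorm(Tm[i, ] - Tm[j, ])
    dist_err <- c(dist_err, abs(de))
  }
  list(position_err_mm = pos_err,
       max_position_err_mm = max(pos_err),
       median_position_err_mm = stats::median(pos_err),
       normal_err_deg = ang_err,
       median_normal_err_deg = stats::median(ang_err),
       max_normal_err_deg = max(ang_err),
       tx_normal_err_deg = ang_err[is_tx],
       median_tx_normal_err_deg = stats::median(ang_err[is_tx]),
       ixtx_dist_err_mm = dist_err,
       median_ixtx_dist_err_mm = stats::median(dist_err),
       max_ixtx_dist_err_mm = max(dist_err))
}

#' Persist a pose estimate as JSON
#' @param est a `pose_estimate`.
#' @param path output path.
#' @export
write_pose_json <- function(est, path) {
  x <- list(c_water_m_s = est$c_water, c_tissue_m_s = est$c_tissue,
            rms_residual_s = est$rms_residual_s, side_count = est$side_count,
            arrays = est$arrays)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
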