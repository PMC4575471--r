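# Closed-loop targeting and dosing.
#
# Targeting: a low-power test pulse heats a thin volume along the beam; the
# apparent thermal strain is segmented, a strain-weighted total-least-squares
# line gives the beam axis, and the peak-strain point is the focus. The
# measured focus-target offset is fed back as a steering correction until
# the offset is inside the 3-mm tolerance.
#
# Dosing: echo-derived features (apparent displacement, thermal strain,
# backscatter change, inter-frame correlation) drive either a linear
# thermal-strain (TSI) estimator or a small recurrent (echo-state)
# estimator; the controller powers off when the MTV spatial-average
# estimate reaches the threshold or the 30-s limit.

TSI_LAMBDA <- 0.0012  # strain per deg C

#' Simulate an apparent thermal-strain volume
#'
#' strain = lambda_true x deltaT + spatially correlated Gaussian noise.
#' @param dT 3D temperature-rise array (deg C), e.g. `thermal_field$final`
#'   or a synthetic blob.
#' @param lambda_true strain per deg C (per-phantom values are near
#'   0.0012).
#' @param noise_sd noise SD in strain units.
#' @param noise_corr_vox correlation length of the noise (voxels; noise is
#'   smoothed with a box kernel of this width).
#' @param seed RNG seed.
#' @return 3D strain array (class `strain_volume` attributes preserved).
#' @export
simulate_strain_volume <- function(dT, lambda_true = TSI_LAMBDA,
                                   noise_sd = 0, noise_corr_vox = 2,
                                   seed = 1) {
  s <- lambda_true * dT
  if (noise_sd > 0) {
    rng <- local_rng(seed)
    n <- array(rng$rnorm(length(dT), 0, noise_sd), dim(dT))
    if (noise_corr_vox > 1) {
      k <- as.integer(noise_corr_vox)
      for (ax in 1:3) {
        n <- apply(n, setdiff(1:3, ax), function(v)
          as.numeric(stats::filter(v, rep(1 / k, k), circular = TRUE)))
        n <- aperm(array(n, dim(dT)[c(ax, setdiff(1:3, ax))]),
                   order(c(ax, setdiff(1:3, ax))))
      }
      n <- n * noise_sd / stats::sd(n)
    }
    s <- s + n
  }
  s
}

#' Localize a beam focus from a strain volume
#'
#' Segments super-threshold voxels, fits a strain-weighted total-least-
#' squares straight line (the beam axis) through them, and reports the
#' peak-strain voxel projected onto the axis as the focus. Returns a
#' no-fix outcome when nothing exceeds the threshold.
#'
#' @param sv 3D strain array.
#' @param threshold segmentation threshold (strain units).
#' @param voxel_size_mm grid spacing.
#' @param origin_mm grid origin (low corner, mm).
#' @return object of class `focus_fix`: `axis_point`, `axis_dir`, `focus`
#'   (mm), `n_voxels`; or class `no_fix`.
#' @export
localize_focus <- function(sv, threshold, voxel_size_mm = 1,
                           origin_mm = c(0, 0, 0)) {
  idx <- which(sv > threshold)
  if (!length(idx))
    return(structure(list(reason = "no super-threshold voxels"),
                     class = "no_fix"))
  # keep the largest connected component: the heated volume is contiguous,
  # scattered super-threshold noise voxels are not part of it
  d3 <- dim(sv)
  lab <- cpp_label3d(as.logical(sv > threshold), d3[1], d3[2], d3[3])
  main <- which.max(tabulate(lab))
  idx <- idx[lab[idx] == main]
  ijk <- arrayInd(idx, dim(sv))
  P <- sweep((ijk - 0.5) * voxel_size_mm, 2, origin_mm, `+`)
  s <- as.vector(sv)[idx]
  fit_line <- function(P, w) {
    w <- w / sum(w)
    ctr <- colSums(P * w)
    P0 <- sweep(P, 2, ctr)
    C <- t(P0 * w) %*% P0
    list(ctr = ctr, axis = eigen(C, symmetric = TRUE)$vectors[, 1])
  }
  fit <- fit_line(P, s)
  # trimmed refit: isolated hot noise voxels far off the first-pass axis
  # are discarded and the line refit
  d <- sweep(P, 2, fit$ctr)
  lat2 <- rowSums(d^2) - as.vector(d %*% fit$axis)^2
  rms <- sqrt(stats::weighted.mean(lat2, s))
  keep <- lat2 <= (3 * max(rms, voxel_size_mm))^2
  if (any(keep) && sum(keep) < length(idx))
    fit <- fit_line(P[keep, , drop = FALSE], s[keep])
  # focus: weighted quadratic vertex fit of strain along the axis
  # coordinate (argmax alone wanders along an elongated blob under noise)
  tax <- as.vector(sweep(P, 2, fit$ctr) %*% fit$axis)
  top <- keep & s >= 0.5 * max(s[keep])
  t_est <- if (sum(top) >= 6) {
    co <- stats::coef(stats::lm(s[top] ~ tax[top] + I(tax[top]^2),
                                weights = s[top]))
    if (is.na(co[3]) || co[3] >= 0) tax[which.max(s)]
    else max(min(-co[2] / (2 * co[3]), max(tax[top])), min(tax[top]))
  } else tax[which.max(s)]
  focus <- fit$ctr + t_est * fit$axis
  structure(list(axis_point = fit$ctr, axis_dir = fit$axis, focus = focus,
                 n_voxels = length(idx)),
            class = "focus_fix")
}

#' @export
print.focus_fix <- function(x, ...) {
  cat(sprintf("<focus_fix> focus (%.1f, %.1f, %.1f) mm, axis (%.2f, %.2f, %.2f), %d voxels\n",
              x$focus[1], x$focus[2], x$focus[3],
              x$axis_dir[1], x$axis_dir[2], x$axis_dir[3], x$n_voxels))
  invisible(x)
}

#' Test for a failed focus localization
#' @param x result of [localize_focus()].
#' @export
is_no_fix <- function(x) inherits(x, "no_fix")

#' Iterative closed-loop correction of per-tile beam foci
#'
#' Each recruited tile starts with an injected focus offset (simulating
#' registration and sound-speed errors). Per iteration the focus position
#' is measured (true focus plus Gaussian localization noise, or a full
#' strain-volume localization when `measure = "strain"`), and the full
#' negative measured offset is applied to the steering. A tile is
#' converged when its measured offset magnitude drops below `tol_mm`.
#'
#' @param plan a `dose_plan` (or any list with `tiles`).
#' @param target intended target (mm).
#' @param initial_offsets matrix (n_tiles x 3, mm) of injected focus
#'   errors; or a single magnitude drawn isotropically per tile.
#' @param max_iter iteration cap (default 5).
#' @param tol_mm convergence tolerance (default 3 mm).
#' @param noise_sd_mm localization noise SD per axis (default 0.5 mm).
#' @param seed RNG seed.
#' @param measure "gaussian" (direct noise model) or "strain" (synthesize
#'   a strain blob at the true focus and run [localize_focus()]).
#' @param damping fraction of the measured offset applied (1 = full).
#' @return list of per-tile histories: `converged`, `iterations`,
#'   `final_offset_mm` (true |focus - target| at stop), `offsets` (per
#'   iteration measured magnitudes).
#' @export
correct_targeting <- function(plan, target, initial_offsets, max_iter = 5,
                              tol_mm = dbac_requirements()$targeting_tol_mm,
                              noise_sd_mm = 0.5, seed = 1,
                              measure = c("gaussian", "strain"),
                              damping = 1) {
  measure <- match.arg(measure)
  n <- length(plan$tiles)
  rng <- local_rng(seed)
  if (is.null(dim(initial_offsets))) {
    mags <- rep_len(initial_offsets, n)
    dirs <- matrix(rng$rnorm(3 * n), n, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    initial_offsets <- dirs * mags
  }
  # convergence is declared on the measured offset; a noise margin keeps
  # the declaration honest (a measurement noise-pulled just under the
  # tolerance must not stop the loop while the true offset is outside it)
  declare_mm <- max(tol_mm / 2, tol_mm - 3 * noise_sd_mm)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    true_off <- initial_offsets[i, ]
    hist_mag <- numeric(0)
    converged <- FALSE
    iter_used <- 0L
    for (it in seq_len(max_iter)) {
      meas_off <- measure_focus_offset(true_off, target, noise_sd_mm,
                                       rng, measure)
      if (is.null(meas_off)) { iter_used <- it; break }  # no-fix: drop tile
      hist_mag <- c(hist_mag, vnorm(meas_off))
      iter_used <- it
      if (vnorm(meas_off) < declare_mm) { converged <- TRUE; break }
      true_off <- true_off - damping * meas_off
    }
    out[[i]] <- list(tile = plan$tiles[[i]]$id %||% i,
                     converged = converged, iterations = iter_used,
                     final_offset_mm = vnorm(true_off),
                     offsets = hist_mag)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

measure_focus_offset <- function(true_off, target, noise_sd_mm, rng, measure) {
  if (measure == "gaussian")
    return(true_off + rng$rnorm(3, 0, noise_sd_mm))
  # strain-volume route: ellipsoidal heated blob at the true focus
  vs <- 0.5
  half <- 12
  nv <- as.integer(2 * half / vs)
  ax <- (seq_len(nv) - 0.5) * vs - half
  g <- expand.grid(x = ax, y = ax, z = ax)
  fo <- true_off
  dT <- 5 * exp(-(((g$x - fo[1])^2 + (g$y - fo[2])^2) / (2 * 1.5^2) +
                    (g$z - fo[3])^2 / (2 * 5^2)))
  sv <- simulate_strain_volume(array(dT, c(nv, nv, nv)),
                               noise_sd = noise_sd_mm * TSI_LAMBDA * 2,
                               seed = floor(rng$runif(1, 1, 1e8)))
  fx <- localize_focus(sv, threshold = TSI_LAMBDA * 1.0, voxel_size_mm = vs,
                       origin_mm = c(-half, -half, -half))
  if (is_no_fix(fx)) return(NULL)
  fx$focus
}

# ---------------------------------------------------------------------------
# Acoustic thermometry

#' Thermometry configuration
#' @param method "TSI" or "RNN".
#' @param lambda strain per deg C used by the TSI estimator.
#' @param tsi_poly cubic calibration coefficients (intercept, linear,
#'   quadratic, cubic) applied to strain/lambda; default identity.
#' @param estimator trained recurrent estimator (for method "RNN"), from
#'   [train_estimator()].
#' @export
thermometry_config <- function(method = c("TSI", "RNN"),
                               lambda = TSI_LAMBDA,
                               tsi_poly = c(0, 1, 0, 0),
                               estimator = NULL) {
  method <- match.arg(method)
  stopifnot(lambda > 0)
  if (method == "RNN" && is.null(estimator))
    stop("RNN thermometry requires a trained estimator (train_estimator)")
  structure(list(method = method, lambda = lambda, tsi_poly = tsi_poly,
                 estimator = estimator),
            class = "thermometry_config")
}

# saturating apparent-strain response: linear at low delta T, slope halves
# above the 10 C knee, so a linear strain readout underestimates high
# temperatures by ~1/3 at 30 C
strain_response <- function(dT, lambda) {
  knee <- 10
  eff <- ifelse(dT <= knee, dT, knee + 0.5 * (dT - knee))
  lambda * eff
}

#' Simulate the echo-feature stream for a heating history
#'
#' Produces per-frame features at the target: apparent thermal strain
#' (saturating in delta T), radiation-force displacement (proportional to
#' applied power), backscatter intensity change (monotone in delta T) and
#' inter-frame correlation (decreasing with heating rate), all with
#' seeded Gaussian noise.
#'
#' @param dT_history temperature-rise trace (deg C) at the frame rate.
#' @param power_history applied acoustic power per frame (W); recycled.
#' @param frame_s frame period (s).
#' @param lambda_true true strain coefficient for this phantom.
#' @param noise_sd fractional feature noise.
#' @param seed RNG seed.
#' @return object of class `feature_stream`: matrix `features` with
#'   columns (strain, displacement, backscatter, correlation) and the
#'   ground-truth `dT`.
#' @export
simulate_features <- function(dT_history, power_history = 1, frame_s = 0.5,
                              lambda_true = TSI_LAMBDA, noise_sd = 0.02,
                              seed = 1) {
  n <- length(dT_history)
  pw <- rep_len(power_history, n)
  rng <- local_rng(seed)
  nz <- function(sd) if (sd > 0) rng$rnorm(n, 0, sd) else numeric(n)
  strain <- strain_response(dT_history, lambda_true) *
    (1 + nz(noise_sd)) + nz(noise_sd * lambda_true)
  disp <- 0.02 * pw * (1 + nz(noise_sd))
  backsc <- 0.01 * dT_history * (1 + nz(noise_sd)) + nz(noise_sd * 0.05)
  rate <- c(0, diff(dT_history)) / frame_s
  corr <- pmin(1, pmax(-1, 1 - 0.01 * abs(rate) + nz(noise_sd * 0.2)))
  structure(list(features = cbind(strain = strain, displacement = disp,
                                  backscatter = backsc, correlation = corr),
                 dT = dT_history, frame_s = frame_s,
                 lambda_true = lambda_true),
            class = "feature_stream")
}

# echo-state reservoir forward pass: features (n x 4) -> states (n x units)
esn_states <- function(est, X) {
  n <- nrow(X)
  H <- matrix(0, n, est$units)
  h <- numeric(est$units)
  Xs <- sweep(sweep(X, 2, est$in_center), 2, est$in_scale, `/`)
  for (t in seq_len(n)) {
    u <- tanh(est$Win %*% Xs[t, ] + est$W %*% h + est$bias)
    h <- (1 - est$leak) * h + est$leak * as.vector(u)
    H[t, ] <- h
  }
  H
}

#' Train the recurrent temperature estimator
#'
#' Builds a synthetic training corpus of heating runs at randomized power
#' levels (first-order thermal ramps, temperature rises up to ~35 deg C),
#' simulates their echo-feature streams, and fits a small echo-state
#' recurrent network (single reservoir, <= 32 units, fixed seeded weights)
#' with a ridge-regression readout from reservoir state + instantaneous
#' features to delta T. Deterministic for a fixed seed. Mean absolute
#' error is reported on a held-out fifth of the corpus, overall and in the
#' 0--10 and 11--30 deg C bands.
#'
#' @param n_streams corpus size (default 250).
#' @param seed RNG seed.
#' @param units reservoir size (<= 32).
#' @param frames frames per stream.
#' @param frame_s frame period (s).
#' @param noise_sd feature noise level.
#' @param lambda_jitter SD of per-stream true strain-coefficient variation
#'   around 0.0012 (fraction).
#' @param ridge readout regularization.
#' @return object of class `temp_estimator` with training report
#'   `$report`.
#' @export
train_estimator <- function(n_streams = 250, seed = 1, units = 32,
                            frames = 60, frame_s = 0.5, noise_sd = 0.02,
                            lambda_jitter = 0.05, ridge = 1e-3) {
  stopifnot(units <= 32, n_streams >= 10)
  rng <- local_rng(seed)
  est <- list(units = units, leak = 0.5)
  est$Win <- matrix(rng$rnorm(units * 4, 0, 0.5), units, 4)
  W <- matrix(rng$rnorm(units * units, 0, 1), units, units)
  W[matrix(rng$runif(units * units) > 0.2, units, units)] <- 0
  sr <- max(abs(eigen(W, only.values = TRUE)$values))
  est$W <- W * (0.9 / max(sr, 1e-9))
  est$bias <- rng$rnorm(units, 0, 0.1)
  # synthetic corpus: first-order ramps dT(t) = A (1 - exp(-t/tau))
  t <- (seq_len(frames) - 1) * frame_s
  streams <- lapply(seq_len(n_streams), function(i) {
    A <- rng$runif(1, 1, 35)
    tau <- rng$runif(1, 8, 25)
    pw <- A / 30
    dT <- A * (1 - exp(-t / tau))
    lam <- TSI_LAMBDA * (1 + rng$rnorm(1, 0, lambda_jitter))
    simulate_features(dT, pw, frame_s, lam, noise_sd, seed = seed + 13 * i)
  })
  X <- do.call(rbind, lapply(streams, `[[`, "features"))
  est$in_center <- colMeans(X)
  est$in_scale <- pmax(apply(X, 2, stats::sd), 1e-9)
  ho <- seq_len(n_streams) %% 5 == 0    # held-out fifth
  feat_of <- function(ss) {
    H <- do.call(rbind, lapply(ss, function(s) esn_states(est, s$features)))
    Xr <- do.call(rbind, lapply(ss, `[[`, "features"))
    cbind(1, H, sweep(sweep(Xr, 2, est$in_center), 2, est$in_scale, `/`))
  }
  Ztr <- feat_of(streams[!ho]); ytr <- unlist(lapply(streams[!ho], `[[`, "dT"))
  Zho <- feat_of(streams[ho]); yho <- unlist(lapply(streams[ho], `[[`, "dT"))
  A <- crossprod(Ztr) + ridge * diag(ncol(Ztr))
  est$beta <- solve(A, crossprod(Ztr, ytr))
  mae <- function(Z, y) {
    p <- as.vector(Z %*% est$beta)
    lo <- y <= 10; hi <- y > 10 & y <= 30
    c(overall = mean(abs(p - y)),
      band_0_10 = if (any(lo)) mean(abs(p - y)[lo]) else NA_real_,
      band_11_30 = if (any(hi)) mean(abs(p - y)[hi]) else NA_real_)
  }
  est$report <- list(train_mae = mae(Ztr, ytr), heldout_mae = mae(Zho, yho),
                     n_streams = n_streams, seed = seed)
  class(est) <- "temp_estimator"
  est
}

#' @export
print.temp_estimator <- function(x, ...) {
  cat(sprintf("<temp_estimator> %d units; held-out MAE %.2f C (0-10: %.2f, 11-30: %.2f)\n",
              x$units, x$report$heldout_mae[["overall"]],
              x$report$heldout_mae[["band_0_10"]],
              x$report$heldout_mae[["band_11_30"]]))
  invisible(x)
}

#' Estimate the temperature-rise history from a feature stream
#'
#' TSI mode: delta T = cubic calibration of strain / lambda (default
#' identity, i.e. the linear strain-temperature model -- which saturates
#' and under-reads above ~10 deg C). RNN mode: readout of the trained
#' recurrent estimator over all four features.
#'
#' @param stream a `feature_stream`.
#' @param cfg a [thermometry_config()].
#' @return numeric vector of estimated delta T per frame.
#' @export
estimate_temperature <- function(stream, cfg) {
  if (cfg$method == "TSI") {
    x <- stream$features[, "strain"] / cfg$lambda
    p <- cfg$tsi_poly
    return(p[1] + p[2] * x + p[3] * x^2 + p[4] * x^3)
  }
  est <- cfg$estimator
  if (is.null(est)) stop("RNN thermometry requires a trained estimator")
  H <- esn_states(est, stream$features)
  Xs <- sweep(sweep(stream$features, 2, est$in_center), 2, est$in_scale, `/`)
  as.vector(cbind(1, H, Xs) %*% est$beta)
}

# ---------------------------------------------------------------------------
# Closed-loop dosing controller

#' Run a thermometry-feedback dose with threshold shut-off
#'
#' Steps the bioheat solver frame by frame with the plan's deposition map;
#' each frame, the spatial-average temperature over the MTV sphere (voxel
#' mean, including any cold vessel lumen) drives the feature simulator and
#' the configured estimator; power is shut off when the estimate reaches
#' `dT_threshold` or at the 30-s limit. The record reports the shut-off
#' cause, the estimator trace, and the true solver temperatures (MTV
#' stats and the hottest vessel-wall-adjacent voxel).
#'
#' @param plan a `dose_plan`.
#' @param phantom a `limb_phantom`.
#' @param deposition a `deposition_map` for the plan.
#' @param cfg a [thermometry_config()].
#' @param dT_threshold shut-off threshold (deg C); `Inf` runs to the limit.
#' @param t_limit_s exposure limit (default 30 s).
#' @param frame_s control frame period (s).
#' @param lumen_sink forward to [solve_bioheat()] (cold-lumen scenario).
#' @param noise_sd feature noise.
#' @param seed RNG seed.
#' @return object of class `dose_record`.
#' @export
dose_controller <- function(plan, phantom, deposition, cfg,
                            dT_threshold = 5,
                            t_limit_s = dbac_requirements()$t_dose_max_s,
                            frame_s = 0.5, lumen_sink = FALSE,
                            noise_sd = 0.02, seed = 1) {
  grid <- grid_spec(deposition$origin, deposition$voxel_size, deposition$dims)
  target <- plan$target
  mtv_d <- dbac_requirements()$mtv_diameter_mm
  pts <- grid_points(grid)
  r2 <- (pts[, 1] - target[1])^2 + (pts[, 2] - target[2])^2 +
        (pts[, 3] - target[3])^2
  in_mtv <- which(r2 <= (mtv_d / 2)^2)
  n_frames <- as.integer(ceiling(t_limit_s / frame_s))
  dT <- array(0, grid$dims)
  mtv_mean <- numeric(0); est_trace <- numeric(0)
  shutoff <- "time-limit"; t_off <- t_limit_s
  power_on <- TRUE
  rng <- local_rng(seed)
  lam <- TSI_LAMBDA * (1 + rng$rnorm(1, 0, 0.05))
  for (fr in seq_len(n_frames)) {
    dT <- step_state(phantom, deposition, dT, frame_s, power_on, lumen_sink)
    mtv_mean <- c(mtv_mean, mean(as.vector(dT)[in_mtv]))
    stream <- simulate_features(mtv_mean,
                                power_history = sum(plan$powers_w) * power_on,
                                frame_s = frame_s, lambda_true = lam,
                                noise_sd = noise_sd, seed = seed + 101)
    est <- estimate_temperature(stream, cfg)
    est_trace <- est
    if (power_on && est[length(est)] >= dT_threshold) {
      shutoff <- "threshold"; t_off <- fr * frame_s
      power_on <- FALSE
      break
    }
  }
  eod <- mtv_stats_from_array(dT, grid, target, mtv_d)
  true_peak <- max(as.vector(dT)[in_mtv])
  req <- dbac_requirements()
  structure(list(plan = plan, t_dose_s = t_off, shutoff_cause = shutoff,
                 dT_eod = eod, true_peak_mtv_c = true_peak,
                 estimated_trace = est_trace, mtv_mean_trace = mtv_mean,
                 threshold_c = dT_threshold,
                 cem43_min = cem43(mtv_mean, frame_s,
                                   phantom$tissue$baseline_temperature),
                 pass_min_td = eod[["min"]] >= req$min_td_lo &&
                               eod[["max"]] <= req$min_td_hi),
            class = "dose_record")
}

# one explicit-control-frame update reusing the solver on the current state
step_state <- function(phantom, deposition, dT0, frame_s, power_on,
                       lumen_sink) {
  ts <- phantom$tissue
  grid <- grid_spec(deposition$origin, deposition$voxel_size, deposition$dims)
  h <- grid$voxel_size / 1000
  rc <- ts$density * ts$specific_heat
  dt_bound <- 0.9 * h^2 * rc / (6 * ts$conductivity)
  nsteps <- max(1L, as.integer(ceiling(frame_s / dt_bound)))
  dt_s <- frame_s / nsteps
  cdiff <- ts$conductivity * dt_s / (rc * h^2)
  src <- as.vector(deposition$q) * 1e6 * dt_s / rc * as.numeric(power_on)
  sink <- rep(RHOB_CB * ts$perfusion * dt_s / rc, length(src))
  if (lumen_sink) {
    ras <- rasterize_tree(phantom$vessel_tree, grid$voxel_size,
                          bbox = list(lo = grid$origin,
                                      hi = grid$origin + grid$dims * grid$voxel_size))
    dd <- pmin(dim(ras$lumen), grid$dims)
    lum <- array(FALSE, grid$dims)
    lum[seq_len(dd[1]), seq_len(dd[2]), seq_len(dd[3])] <-
      ras$lumen[seq_len(dd[1]), seq_len(dd[2]), seq_len(dd[3])]
    sink[as.vector(lum)] <- sink[as.vector(lum)] + RHOB_CB * 2 * dt_s / rc
  }
  res <- cpp_bioheat(as.vector(dT0), src, sink, grid$dims[1], grid$dims[2],
                     grid$dims[3], cdiff, nsteps, 0L, integer(0))
  array(res$final, grid$dims)
}

mtv_stats_from_array <- function(dT, grid, center, diameter_mm) {
  pts <- grid_points(grid)
  r <- diameter_mm / 2
  inside <- (pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2 +
            (pts[, 3] - center[3])^2 <= r^2
  v <- as.vector(dT)[inside]
  c(min = min(v), mean = mean(v), max = max(v))
}

#' @export
print.dose_record <- function(x, ...) {
  cat(sprintf("<dose_record> t=%g s (%s), dT_eod MTV min/mean/max = %.1f/%.1f/%.1f C, CEM43 %.2g min\n",
              x$t_dose_s, x$shutoff_cause, x$dT_eod[["min"]],
              x$dT_eod[["mean"]], x$dT_eod[["max"]], x$cem43_min))
  invisible(x)
}
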