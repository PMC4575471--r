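#' Tissue acoustic and thermal properties
#'
#' Container for the material constants used by the acoustic and bioheat
#' solvers. Defaults describe a soft-tissue-mimicking gel phantom: sound
#' speed 1515 m/s, attenuation 0.05 Np/cm at 1 MHz with linear frequency
#' scaling, density 1050 kg/m^3, specific heat 3600 J/(kg K), conductivity
#' 0.55 W/(m K), zero perfusion (phantom mode).
#'
#' @param sound_speed m/s, must lie in [1400, 1650].
#' @param attenuation_np_cm Np/cm at `attenuation_ref_mhz`.
#' @param attenuation_ref_mhz reference frequency for `attenuation_np_cm`.
#' @param attenuation_exponent frequency-scaling exponent (1 = linear).
#' @param density kg/m^3.
#' @param specific_heat J/(kg K).
#' @param conductivity W/(m K).
#' @param perfusion 1/s; 0 for phantoms.
#' @param baseline_temperature deg C.
#' @return An object of class `tissue_properties`.
#' @export
tissue_properties <- function(sound_speed = 1515,
                              attenuation_np_cm = 0.05,
                              attenuation_ref_mhz = 1,
                              attenuation_exponent = 1,
                              density = 1050,
                              specific_heat = 3600,
                              conductivity = 0.55,
                              perfusion = 0,
                              baseline_temperature = 20) {
  stopifnot(sound_speed >= 1400, sound_speed <= 1650,
            attenuation_np_cm > 0, density > 0, specific_heat > 0,
            conductivity > 0, perfusion >= 0)
  structure(list(sound_speed = sound_speed,
                 attenuation_np_cm = attenuation_np_cm,
                 attenuation_ref_mhz = attenuation_ref_mhz,
                 attenuation_exponent = attenuation_exponent,
                 density = density,
                 specific_heat = specific_heat,
                 conductivity = conductivity,
                 perfusion = perfusion,
                 baseline_temperature = baseline_temperature),
            class = "tissue_properties")
}

# attenuation in Np/cm at frequency f (MHz)
attenuation_at <- function(tissue, f_mhz) {
  tissue$attenuation_np_cm *
    (f_mhz / tissue$attenuation_ref_mhz)^tissue$attenuation_exponent
}

# Canonical single-cycle arterial pulse shape on t in [0,1): narrow systolic
# peak plus diastolic decay; returns values in [0, 1] with min 0 and max 1.
pulse_shape <- function(t) {
  s <- exp(-((t - 0.15) / 0.08)^2) + 0.35 * exp(-((t - 0.38) / 0.12)^2)
  s <- s - min(s)
  s / max(s)
}

#' Generate a single-cycle pulsatile flow waveform
#'
#' Constructs one cardiac cycle of centerline flow velocity for a vessel
#' branch. The shape is a stereotyped arterial pulse; the resistive index
#' RI = (V_systole - V_diastole) / V_systole is set by construction:
#' `normal` branches draw RI uniformly in [0.82, 0.95] (high peripheral
#' resistance), `bleeder` branches in [0.55, 0.70] (vented, low-resistance
#' outflow), and `irregular-slow` produces a slow (mean <= 4 cm/s)
#' non-periodic trace whose cycle-to-cycle RI is unreliable -- the regime in
#' which RI-based classification degrades.
#'
#' @param profile one of "normal", "bleeder", "irregular-slow".
#' @param mean_velocity cm/s, > 0. For "irregular-slow" it is capped at 4.
#' @param heart_rate beats per minute.
#' @param seed integer RNG seed (reproducible waveforms).
#' @param n_samples samples per cycle.
#' @return Object of class `flow_waveform` with fields `time` (s),
#'   `velocity` (cm/s), `V_systole`, `V_diastole`, `mean_velocity`,
#'   `profile`.
#' @export
make_flow_waveform <- function(profile = c("normal", "bleeder", "irregular-slow"),
                               mean_velocity, heart_rate = 60, seed = 1,
                               n_samples = 128) {
  profile <- match.arg(profile)
  if (!is.numeric(mean_velocity) || mean_velocity <= 0)
    stop("mean_velocity must be positive (cm/s)")
  rng <- local_rng(seed)
  period <- 60 / heart_rate
  t <- seq(0, period, length.out = n_samples + 1)[1:n_samples]
  tn <- t / period
  if (profile == "irregular-slow") {
    mean_velocity <- min(mean_velocity, 4)
    # non-periodic modulation: incommensurate sinusoids + smoothed noise
    base <- pulse_shape(tn)
    mod <- 0.6 * sin(2 * pi * tn * exp(1)) + 0.4 * sin(2 * pi * tn * pi * 1.3)
    rough <- stats::filter(rng$rnorm(n_samples), rep(1 / 8, 8), circular = TRUE)
    v <- base + 0.5 * (mod - min(mod)) + 0.6 * as.numeric(rough)
    v <- v - min(v) + 0.05
    v <- v * mean_velocity / mean(v)
  } else {
    ri <- if (profile == "normal") rng$runif(1, 0.82, 0.95) else rng$runif(1, 0.55, 0.70)
    shape <- pulse_shape(tn)            # in [0,1]
    # v = Vd + (Vs - Vd) * shape, Vd = (1 - ri) * Vs
    # mean(v) = Vs * ((1-ri) + ri * mean(shape))  =>  solve for Vs
    vs <- mean_velocity / ((1 - ri) + ri * mean(shape))
    v <- (1 - ri) * vs + ri * vs * shape
  }
  new_flow_waveform(t, v, profile)
}

new_flow_waveform <- function(time, velocity, profile) {
  structure(list(time = time,
                 velocity = velocity,
                 V_systole = max(velocity),
                 V_diastole = min(velocity),
                 mean_velocity = mean(velocity),
                 profile = profile),
            class = "flow_waveform")
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf("<flow_waveform> profile=%s  mean=%.2f cm/s  Vs=%.2f  Vd=%.2f  RI=%.3f\n",
              x$profile, x$mean_velocity, x$V_systole, x$V_diastole, compute_ri(x)))
  invisible(x)
}

#' Write / read a waveform as CSV (`time_s,velocity_cm_s`)
#' @param w a `flow_waveform`.
#' @param path file path.
#' @export
write_waveform_csv <- function(w, path) {
  utils::write.csv(data.frame(time_s = w$time, velocity_cm_s = w$velocity),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  d <- utils::read.csv(path)
  new_flow_waveform(d$time_s, d$velocity_cm_s, "normal")
}

# Scoped RNG: draws from a private stream without touching the global
# .Random.seed, so seeded generators are reproducible and composable.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  draw <- function(fn) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    out
  }
  list(rnorm = draw(stats::rnorm), runif = draw(stats::runif),
       sample = draw(base::sample), rpois = draw(stats::rpois))
}
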