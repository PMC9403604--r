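#' Parametric nystagmus waveform specification
#'
#' Describes one eye-movement waveform. Jerk nystagmus alternates a slow
#' drift phase with a fast (saccadic) corrective phase of equal amplitude in
#' the opposite direction; the slow-phase velocity profile may be constant
#' (`jerk_linear`), exponentially decaying (`jerk_velocity_decreasing`,
#' gaze-evoked pattern) or growing (`jerk_velocity_increasing`). Pendular
#' nystagmus is a sinusoid with no fast phase. Positions are expressed in
#' degrees of gaze angle; rendering converts them to pixels via a gain.
#'
#' A clip counts as nystagmus when it contains at least two consecutive
#' beats (slow/fast alternations).
#'
#' @param kind one of `"none"`, `"jerk_linear"`, `"jerk_velocity_decreasing"`,
#'   `"jerk_velocity_increasing"`, `"pendular"`.
#' @param slow_phase_duration slow-phase duration in ms (physiological range
#'   roughly 150-350 ms).
#' @param amplitude beat amplitude in degrees.
#' @param direction unit 2-D vector (x, y) of the slow-phase drift.
#' @param n_beats number of beats (>= 2 for a nystagmus label).
#' @param onset waveform onset in seconds.
#' @param pendular_frequency oscillation frequency in Hz (pendular only).
#' @param decay_constant per-second exponential rate of the slow-phase
#'   velocity (velocity-decreasing/increasing kinds).
#' @return an object of class `waveform_spec`.
#' @export
waveform_spec <- function(kind = c("none", "jerk_linear",
                                   "jerk_velocity_decreasing",
                                   "jerk_velocity_increasing", "pendular"),
                          slow_phase_duration = 250, amplitude = 2,
                          direction = c(1, 0), n_beats = 0, onset = 0,
                          pendular_frequency = 3, decay_constant = 8) {
  kind <- match.arg(kind)
  if (slow_phase_duration <= 0) stop("'slow_phase_duration' must be > 0")
  if (n_beats < 0) stop("'n_beats' must be >= 0")
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("'direction' must be a nonzero vector")
  structure(list(kind = kind, slow_phase_duration = slow_phase_duration,
                 amplitude = amplitude, direction = direction / nrm,
                 n_beats = n_beats, onset = onset,
                 pendular_frequency = pendular_frequency,
                 decay_constant = decay_constant),
            class = "waveform_spec")
}

#' Non-nystagmus distractor specification
#'
#' Blinks, sustained lid closure, square-wave jerks (a saccade away from
#' fixation and back after a latency), slow drift and tremor-like position
#' noise. Distractors alone never satisfy the two-beat nystagmus rule.
#'
#' @param blink_times blink onsets in seconds.
#' @param blink_duration blink duration in ms.
#' @param lid_closure_intervals list of `c(start, end)` in seconds.
#' @param square_wave_jerks data.frame with columns `time` (s),
#'   `amplitude` (deg), `return_latency` (s); may be `NULL`.
#' @param drift_velocity slow drift in deg/s along the x axis.
#' @param tremor_noise_sd Gaussian position noise SD in degrees.
#' @return an object of class `distractor_spec`.
#' @export
distractor_spec <- function(blink_times = numeric(0), blink_duration = 150,
                            lid_closure_intervals = list(),
                            square_wave_jerks = NULL,
                            drift_velocity = 0, tremor_noise_sd = 0) {
  structure(list(blink_times = blink_times, blink_duration = blink_duration,
                 lid_closure_intervals = lid_closure_intervals,
                 square_wave_jerks = square_wave_jerks,
                 drift_velocity = drift_velocity,
                 tremor_noise_sd = tremor_noise_sd),
            class = "distractor_spec")
}

#' Synthetic eye appearance parameters
#'
#' Geometry and intensities of the rendered eye at the reference resolution
#' 240 x 320; radii and offsets are rescaled proportionally when rendering
#' at other resolutions. The pupil must be the darkest structure, as in
#' infrared recordings.
#'
#' @param pupil_radius,iris_radius radii in px at 240 x 320.
#' @param sclera_intensity,iris_intensity,pupil_intensity mean gray levels
#'   in `[0, 255]`.
#' @param illumination_gradient peak-to-peak relative strength of a linear
#'   multiplicative shading field (0 = flat lighting).
#' @param sensor_noise_sd per-pixel Gaussian noise SD in intensity units.
#' @param gaze_offset `c(x, y)` eccentric fixation offset in px at 240x320.
#' @param gain_px_per_deg pixels per degree of gaze angle at 240 x 320.
#' @return an object of class `eye_appearance`.
#' @export
eye_appearance <- function(pupil_radius = 20, iris_radius = 55,
                           sclera_intensity = 170, iris_intensity = 95,
                           pupil_intensity = 15,
                           illumination_gradient = 0.15,
                           sensor_noise_sd = 2,
                           gaze_offset = c(0, 0),
                           gain_px_per_deg = 4) {
  if (pupil_radius >= iris_radius)
    stop("'pupil_radius' must be smaller than 'iris_radius'")
  if (!(pupil_intensity < iris_intensity && pupil_intensity < sclera_intensity))
    stop("pupil must be the darkest structure")
  structure(list(pupil_radius = pupil_radius, iris_radius = iris_radius,
                 sclera_intensity = sclera_intensity,
                 iris_intensity = iris_intensity,
                 pupil_intensity = pupil_intensity,
                 illumination_gradient = illumination_gradient,
                 sensor_noise_sd = sensor_noise_sd,
                 gaze_offset = gaze_offset,
                 gain_px_per_deg = gain_px_per_deg),
            class = "eye_appearance")
}

# run expr with a private RNG stream; global .Random.seed is untouched
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a ground-truth gaze trace
#'
#' Realizes a [waveform_spec] plus [distractor_spec] into a `T x 2` gaze
#' position time series (degrees, relative to fixation) with exact beat
#' annotations. Fast phases are rendered as near-instant transitions (one
#' sample at 60 Hz): saccadic velocities far exceed the sampling rate, so a
#' sampled jerk waveform is a sawtooth.
#'
#' @param spec a [waveform_spec].
#' @param distractors a [distractor_spec].
#' @param rate sampling rate in Hz.
#' @param duration clip duration in seconds.
#' @param seed integer seed for tremor noise.
#' @return an object of class `gaze_trace`: list with `positions` (`T x 2`,
#'   degrees), `rate`, `beats` (data.frame `slow_start`, `slow_end`,
#'   `fast_start`, `fast_end`, sample indices), `occlusion` (data.frame
#'   `start`, `end` in seconds) and the input specs.
#' @export
gen_trace <- function(spec, distractors = distractor_spec(), rate, duration,
                      seed = 1) {
  T <- floor(duration * rate)
  if (T < 2L) stop("duration x rate must be >= 2 samples")
  tt <- (seq_len(T) - 1) / rate
  w <- numeric(T)          # waveform displacement along spec$direction (deg)
  beats <- data.frame(slow_start = integer(0), slow_end = integer(0),
                      fast_start = integer(0), fast_end = integer(0))
  d_s <- spec$slow_phase_duration / 1000
  n_slow <- max(1L, round(d_s * rate))
  n_fast <- max(1L, round(rate / 60))     # ~1 sample at 60 Hz
  A <- spec$amplitude
  if (spec$kind %in% c("jerk_linear", "jerk_velocity_decreasing",
                       "jerk_velocity_increasing") && spec$n_beats > 0) {
    i0 <- floor(spec$onset * rate) + 1L
    lam <- spec$decay_constant
    u <- (seq_len(n_slow)) / (n_slow)     # normalized slow-phase time (0,1]
    prof <- switch(spec$kind,
      jerk_linear = u,
      # velocity decays: position saturates; velocity grows: position curves up
      jerk_velocity_decreasing = (1 - exp(-lam * d_s * u)) / (1 - exp(-lam * d_s)),
      jerk_velocity_increasing = (exp(lam * d_s * u) - 1) / (exp(lam * d_s) - 1))
    for (b in seq_len(spec$n_beats)) {
      s0 <- i0 + (b - 1L) * (n_slow + n_fast)
      s1 <- s0 + n_slow - 1L
      f0 <- s1 + 1L
      f1 <- f0 + n_fast - 1L
      if (f1 > T) break
      w[s0:s1] <- A * prof
      # fast phase: linear return to baseline over n_fast samples
      w[f0:f1] <- A * (1 - seq_len(n_fast) / n_fast)
      beats <- rbind(beats, data.frame(slow_start = s0, slow_end = s1,
                                       fast_start = f0, fast_end = f1))
    }
  } else if (spec$kind == "pendular") {
    on <- tt >= spec$onset
    w[on] <- A * sin(2 * pi * spec$pendular_frequency * (tt[on] - spec$onset))
    # no fast phase; annotate each full cycle as one beat (first half-cycle
    # as the "slow" interval, second as the corrective interval)
    cyc <- 1 / spec$pendular_frequency
    n_cyc <- floor((duration - spec$onset) / cyc)
    half <- round(cyc / 2 * rate)
    if (n_cyc >= 1 && half >= 1) {
      starts <- floor(spec$onset * rate) + 1L + (seq_len(n_cyc) - 1L) * 2L * half
      beats <- data.frame(slow_start = starts, slow_end = starts + half - 1L,
                          fast_start = starts + half,
                          fast_end = pmin(starts + 2L * half - 1L, T))
    }
  }
  pos <- outer(w, spec$direction)
  # distractors
  pos[, 1] <- pos[, 1] + distractors$drift_velocity * tt
  swj <- distractors$square_wave_jerks
  if (!is.null(swj) && nrow(swj) > 0) {
    for (r in seq_len(nrow(swj))) {
      on <- tt >= swj$time[r] & tt < swj$time[r] + swj$return_latency[r]
      pos[on, 1] <- pos[on, 1] + swj$amplitude[r]
    }
  }
  if (distractors$tremor_noise_sd > 0) {
    pos <- pos + with_seed(seed,
      matrix(stats::rnorm(2 * T, 0, distractors$tremor_noise_sd), T, 2))
  }
  occl <- data.frame(start = numeric(0), end = numeric(0))
  if (length(distractors$blink_times) > 0) {
    occl <- rbind(occl, data.frame(
      start = distractors$blink_times,
      end = distractors$blink_times + distractors$blink_duration / 1000))
  }
  for (iv in distractors$lid_closure_intervals) {
    occl <- rbind(occl, data.frame(start = iv[1], end = iv[2]))
  }
  structure(list(positions = pos, rate = rate, duration = duration,
                 beats = beats, occlusion = occl,
                 spec = spec, distractors = distractors),
            class = "gaze_trace")
}

#' Render a gaze trace into a synthetic video clip
#'
#' Draws a monocular infrared-style eye (bright sclera, darker iris disk,
#' dark pupil disk) centered at the trace position plus any eccentric gaze
#' offset, with antialiased disk edges so sub-pixel motion survives spatial
#' downscaling. Blinks and lid closure are drawn as an occluding lid band;
#' a fixed multiplicative illumination gradient and per-frame Gaussian
#' sensor noise are applied. The clip label follows the two-beat rule from
#' the trace annotations. Rendering is deterministic given
#' `(trace, appearance, seed)`.
#'
#' @param trace a [gaze_trace].
#' @param appearance an [eye_appearance].
#' @param resolution integer `c(H, W)`.
#' @param seed integer seed for sensor noise and gradient orientation.
#' @param patient_id,condition,id metadata forwarded to the clip.
#' @return a labeled [vog_clip].
#' @export
render_clip <- function(trace, appearance = eye_appearance(),
                        resolution = c(240, 320), seed = 1,
                        patient_id = NA_character_,
                        condition = NA_character_, id = NULL) {
  H <- resolution[1]; W <- resolution[2]
  s <- H / 240                                   # geometry scale
  gain <- appearance$gain_px_per_deg * s
  cx <- (W + 1) / 2 + appearance$gaze_offset[1] * s
  cy <- (H + 1) / 2 + appearance$gaze_offset[2] * s
  r_iris <- appearance$iris_radius * s
  r_pupil <- appearance$pupil_radius * s
  T <- nrow(trace$positions)
  px <- cx + trace$positions[, 1] * gain
  py <- cy + trace$positions[, 2] * gain
  if (any(px - r_iris < 0 | px + r_iris > W + 1 |
          py - r_iris < 0 | py + r_iris > H + 1))
    stop("eye excursion leaves the frame; reduce amplitude or offset")
  occ_frames <- rep(FALSE, T)
  if (nrow(trace$occlusion) > 0) {
    tt <- (seq_len(T) - 1) / trace$rate
    for (r in seq_len(nrow(trace$occlusion))) {
      occ_frames <- occ_frames |
        (tt >= trace$occlusion$start[r] & tt < trace$occlusion$end[r])
    }
  }
  xg <- matrix(seq_len(W), H, W, byrow = TRUE)
  yg <- matrix(seq_len(H), H, W)
  frames <- array(0, dim = c(H, W, T))
  with_seed(seed, {
    theta <- stats::runif(1, 0, 2 * pi)
    grad <- 1 + appearance$illumination_gradient *
      ((cos(theta) * (xg - W / 2) / W + sin(theta) * (yg - H / 2) / H))
    lid_edge <- cy + 0.4 * r_iris                # lid band lower boundary
    sig <- appearance$sensor_noise_sd
    for (t in seq_len(T)) {
      d <- sqrt((xg - px[t])^2 + (yg - py[t])^2)
      a_iris <- pmin(pmax(r_iris + 0.5 - d, 0), 1)
      a_pupil <- pmin(pmax(r_pupil + 0.5 - d, 0), 1)
      img <- appearance$sclera_intensity * (1 - a_iris) +
        appearance$iris_intensity * (a_iris - a_pupil) +
        appearance$pupil_intensity * a_pupil
      if (occ_frames[t]) {
        lid <- pmin(pmax(lid_edge - yg, 0), 1)
        img <- img * (1 - lid) + 0.85 * appearance$sclera_intensity * lid
      }
      img <- img * grad
      if (sig > 0) img <- img + stats::rnorm(H * W, 0, sig)
      frames[, , t] <- img
    }
  })
  frames <- pmin(pmax(frames, 0), 255)
  label <- if (nrow(trace$beats) >= 2) "nystagmus" else "no_nystagmus"
  vog_clip(frames, rate = trace$rate, label = label,
           patient_id = patient_id, condition = condition, id = id,
           source = "simulated")
}

#' Generate a labeled synthetic video-oculography dataset
#'
#' Emulates the composition of a clinical VOG study: roughly balanced
#' nystagmus / no-nystagmus classes, 95% linear-jerk / 5%
#' velocity-decreasing waveforms among positives, slow-phase durations drawn
#' uniformly from 150-350 ms, a configurable fraction of eccentric-gaze
#' clips, and per-patient appearance variation with every simulated patient
#' contributing both classes. Negative clips carry realistic distractors
#' (blinks, square-wave jerks, drift, tremor) and at most one isolated beat,
#' so they never satisfy the two-beat rule.
#'
#' @param n_videos number of clips.
#' @param class_ratio fraction of nystagmus clips, in (0, 1).
#' @param rate sampling rate in Hz.
#' @param resolution integer `c(H, W)`.
#' @param duration clip duration in seconds.
#' @param eccentric_fraction fraction of clips rendered with eccentric gaze.
#' @param patients number of simulated patients.
#' @param amplitude_range range (degrees) the per-clip beat amplitude is
#'   drawn from. The default spans roughly 2.5-9 px of motion at 240 x 320;
#'   note the lower end falls below one pixel once clips are rendered at or
#'   degraded to small resolutions.
#' @param seed master seed; the whole dataset is a deterministic function
#'   of it.
#'
#' @details Defaults mirror a full clinical-scale study (435 ten-second
#'   60 Hz clips at 240 x 320 from 30 patients, 44.3% eccentric). Clips are
#'   held in memory as double arrays (~368 MB per full-resolution clip), so
#'   for training experiments on modest hardware generate at a reduced
#'   resolution (e.g. `resolution = c(60, 80)`, ~23 MB per clip) and/or a
#'   smaller `n_videos`.
#' @return list of labeled [vog_clip]s with a `manifest` attribute
#'   (data.frame: id, label, patient_id, condition, kind, n_beats,
#'   slow_phase_ms, amplitude_deg, seed).
#' @export
make_dataset <- function(n_videos = 435, class_ratio = 0.5, rate = 60,
                         resolution = c(240, 320), duration = 10,
                         eccentric_fraction = 0.443, patients = 30,
                         amplitude_range = c(0.6, 2.2), seed = 1) {
  if (class_ratio <= 0 || class_ratio >= 1)
    stop("'class_ratio' must be in (0, 1)")
  if (patients < 1) stop("'patients' must be >= 1")
  n_pos <- round(n_videos * class_ratio)
  n_neg <- n_videos - n_pos
  if (n_pos == 0 || n_neg == 0) stop("class ratio leaves one class empty")
  labels <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
  params <- with_seed(seed, {
    # patients cycle within each class so everyone contributes both classes
    pat <- c(sample(rep_len(seq_len(patients), n_pos)),
             sample(rep_len(seq_len(patients), n_neg)))
    n_ecc <- round(eccentric_fraction * n_videos)
    ecc <- sample(n_videos) <= n_ecc
    list(pat = pat, ecc = ecc,
         pat_app = lapply(seq_len(patients), function(p) list(
           pupil = stats::runif(1, 14, 26), iris = stats::runif(1, 45, 65),
           sclera = stats::runif(1, 150, 200), irisv = stats::runif(1, 70, 115),
           noise = stats::runif(1, 1, 4), illum = stats::runif(1, 0.05, 0.3))),
         sub = sample.int(2^31 - 1, n_videos))
  })
  clips <- vector("list", n_videos)
  for (i in seq_len(n_videos)) {
    clips[[i]] <- with_seed(params$sub[i], {
      pos <- labels[i]
      if (pos) {
        kind <- if (stats::runif(1) < 0.95) "jerk_linear"
                else "jerk_velocity_decreasing"
        spd <- stats::runif(1, 150, 350)
        amp <- stats::runif(1, amplitude_range[1], amplitude_range[2])
        onset <- stats::runif(1, 0, 1.5)
        beat_len <- spd / 1000 + 1 / 60
        n_beats <- floor((duration - onset - 0.5) / beat_len)
        n_beats <- max(2L, min(n_beats, floor(stats::runif(1, 6, 40))))
      } else {
        kind <- if (stats::runif(1) < 0.3) "jerk_linear" else "none"
        spd <- stats::runif(1, 150, 350)
        amp <- stats::runif(1, amplitude_range[1], amplitude_range[2])
        onset <- stats::runif(1, 0, 4)
        n_beats <- if (kind == "none") 0L else 1L   # a single isolated beat
      }
      n_blinks <- stats::rpois(1, 2)
      blink_times <- sort(stats::runif(n_blinks, 0.2, duration - 0.6))
      n_swj <- stats::rpois(1, if (pos) 0.5 else 1.5)
      swj <- if (n_swj > 0) data.frame(
        time = sort(stats::runif(n_swj, 0.2, duration - 1)),
        amplitude = stats::runif(n_swj, 0.3, 1.2) *
          sample(c(-1, 1), n_swj, replace = TRUE),
        return_latency = stats::runif(n_swj, 0.15, 0.35)) else NULL
      ddir <- c(cos(stats::rnorm(1, 0, 0.3)), sin(stats::rnorm(1, 0, 0.3)))
      if (stats::runif(1) < 0.5) ddir <- -ddir
      spec <- waveform_spec(kind = kind, slow_phase_duration = spd,
                            amplitude = amp, direction = ddir,
                            n_beats = n_beats, onset = onset)
      dist <- distractor_spec(blink_times = blink_times,
                              blink_duration = stats::runif(1, 120, 250),
                              square_wave_jerks = swj,
                              drift_velocity = stats::runif(1, -0.2, 0.2),
                              tremor_noise_sd = stats::runif(1, 0.01, 0.04))
      app_p <- params$pat_app[[params$pat[i]]]
      offs <- if (params$ecc[i])
        stats::runif(2, 15, 45) * sample(c(-1, 1), 2, replace = TRUE) *
          c(1, 0.5) else c(0, 0)
      app <- eye_appearance(pupil_radius = app_p$pupil,
                            iris_radius = app_p$iris,
                            sclera_intensity = app_p$sclera,
                            iris_intensity = app_p$irisv,
                            sensor_noise_sd = app_p$noise,
                            illumination_gradient = app_p$illum,
                            gaze_offset = offs)
      trace <- gen_trace(spec, dist, rate = rate, duration = duration,
                         seed = params$sub[i] %% 2^20 + 1L)
      clip <- render_clip(trace, app, resolution = resolution,
                          seed = params$sub[i] %% 2^20 + 2L,
                          patient_id = sprintf("P%02d", params$pat[i]),
                          condition = if (params$ecc[i]) "eccentric"
                                      else "primary",
                          id = sprintf("vid%04d", i))
      attr(clip, "trace") <- trace
      clip
    })
  }
  man <- do.call(rbind, lapply(seq_len(n_videos), function(i) {
    tr <- attr(clips[[i]], "trace")
    data.frame(id = clips[[i]]$id, label = clips[[i]]$label,
               patient_id = clips[[i]]$patient_id,
               condition = clips[[i]]$condition,
               kind = tr$spec$kind, n_beats = nrow(tr$beats),
               slow_phase_ms = tr$spec$slow_phase_duration,
               amplitude_deg = tr$spec$amplitude,
               seed = params$sub[i], stringsAsFactors = FALSE)
  }))
  attr(clips, "manifest") <- man
  clips
}
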