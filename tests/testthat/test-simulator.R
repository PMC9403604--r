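test_that("a null waveform with no distractors gives a constant trace", {
  tr <- gen_trace(waveform_spec("none"), distractor_spec(), rate = 60,
                  duration = 2, seed = 1)
  expect_equal(nrow(tr$positions), 120)
  expect_equal(max(abs(tr$positions)), 0)
  expect_equal(nrow(tr$beats), 0)
})

test_that("jerk beats have the requested slow-phase sample span", {
  tr <- gen_trace(waveform_spec("jerk_linear", slow_phase_duration = 250,
                                amplitude = 2, n_beats = 4),
                  rate = 60, duration = 3, seed = 1)
  expect_equal(nrow(tr$beats), 4)
  spans <- tr$beats$slow_end - tr$beats$slow_start + 1L
  expect_equal(spans, rep(15L, 4))  # 0.250 s x 60 Hz
  # beats ordered and non-overlapping
  expect_true(all(diff(tr$beats$slow_start) > 0))
  expect_true(all(tr$beats$fast_end[-4] < tr$beats$slow_start[-1]))
})

test_that("linear slow-phase velocity is recovered by regression", {
  A <- 3; spd <- 300
  tr <- gen_trace(waveform_spec("jerk_linear", slow_phase_duration = spd,
                                amplitude = A, n_beats = 5,
                                direction = c(1, 0)),
                  rate = 60, duration = 4, seed = 1)
  b <- tr$beats[2, ]
  idx <- b$slow_start:b$slow_end
  t_s <- (idx - 1) / 60
  v <- unname(coef(lm(tr$positions[idx, 1] ~ t_s))[2])
  expect_equal(v, A / (spd / 1000), tolerance = 0.01)
})

test_that("velocity-decreasing slow phases decelerate, increasing accelerate", {
  for (kind in c("jerk_velocity_decreasing", "jerk_velocity_increasing")) {
    tr <- gen_trace(waveform_spec(kind, slow_phase_duration = 330,
                                  amplitude = 2, n_beats = 3,
                                  decay_constant = 10),
                    rate = 60, duration = 3, seed = 1)
    b <- tr$beats[1, ]
    x <- tr$positions[b$slow_start:b$slow_end, 1]
    v <- diff(x)
    if (kind == "jerk_velocity_decreasing") {
      expect_lt(v[length(v)], v[1])
    } else {
      expect_gt(v[length(v)], v[1])
    }
    # both reach the full amplitude at the slow-phase end
    expect_equal(x[length(x)], 2, tolerance = 1e-9)
  }
})

test_that("pendular traces oscillate at the requested frequency", {
  f0 <- 3
  tr <- gen_trace(waveform_spec("pendular", amplitude = 2,
                                pendular_frequency = f0),
                  rate = 60, duration = 10, seed = 1)
  x <- tr$positions[, 1]
  sp <- Mod(fft(x - mean(x)))[2:300]
  freqs <- (seq_along(sp)) / 10          # bin k -> k/duration Hz
  expect_equal(freqs[which.max(sp)], f0, tolerance = 1e-9)
  expect_gt(nrow(tr$beats), 2)
})

test_that("square-wave jerks and drift displace the trace as specified", {
  swj <- data.frame(time = 1, amplitude = 1.5, return_latency = 0.25)
  tr <- gen_trace(waveform_spec("none"),
                  distractor_spec(square_wave_jerks = swj,
                                  drift_velocity = 0.5),
                  rate = 60, duration = 3, seed = 1)
  tt <- (seq_len(180) - 1) / 60
  drift <- 0.5 * tt
  on <- tt >= 1 & tt < 1.25
  expect_equal(tr$positions[on, 1], drift[on] + 1.5)
  expect_equal(tr$positions[!on, 1], drift[!on])
  expect_equal(nrow(tr$beats), 0)
})

test_that("rendered frames put the darkest pixel at the pupil", {
  tr <- gen_trace(waveform_spec("jerk_linear", amplitude = 2, n_beats = 3),
                  rate = 60, duration = 2, seed = 5)
  app <- eye_appearance(sensor_noise_sd = 0, illumination_gradient = 0)
  cl <- render_clip(tr, app, resolution = c(120, 160), seed = 5)
  s <- 120 / 240
  for (t in c(1, 40, 90)) {
    k <- which.min(cl$frames[, , t])
    row <- (k - 1) %% 120 + 1; col <- (k - 1) %/% 120 + 1
    ex_col <- (160 + 1) / 2 + tr$positions[t, 1] * app$gain_px_per_deg * s
    ex_row <- (120 + 1) / 2 + tr$positions[t, 2] * app$gain_px_per_deg * s
    d <- sqrt((row - ex_row)^2 + (col - ex_col)^2)
    expect_lt(d, app$pupil_radius * s + 1)
  }
})

test_that("a static noiseless trace renders identical frames (zero motion)", {
  tr <- gen_trace(waveform_spec("none"), rate = 60, duration = 1, seed = 2)
  cl <- render_clip(tr, eye_appearance(sensor_noise_sd = 0),
                    resolution = c(60, 80), seed = 2)
  expect_equal(max(filtered_stack(cl, filter_params(0.25))$images), 0)
})

test_that("rendering is bitwise deterministic given the seed", {
  tr <- gen_trace(waveform_spec("jerk_linear", amplitude = 1.5, n_beats = 4),
                  distractor_spec(blink_times = 0.5, tremor_noise_sd = 0.02),
                  rate = 60, duration = 2, seed = 9)
  a <- render_clip(tr, resolution = c(60, 80), seed = 9)
  b <- render_clip(tr, resolution = c(60, 80), seed = 9)
  expect_identical(a$frames, b$frames)
  c2 <- render_clip(tr, resolution = c(60, 80), seed = 10)
  expect_false(identical(a$frames, c2$frames))
})

test_that("blink occlusion changes frames only inside the blink interval", {
  spec <- waveform_spec("none")
  tr0 <- gen_trace(spec, distractor_spec(), rate = 60, duration = 2, seed = 3)
  tr1 <- gen_trace(spec, distractor_spec(blink_times = 1,
                                         blink_duration = 200),
                   rate = 60, duration = 2, seed = 3)
  app <- eye_appearance(sensor_noise_sd = 0)
  a <- render_clip(tr0, app, resolution = c(60, 80), seed = 3)
  b <- render_clip(tr1, app, resolution = c(60, 80), seed = 3)
  tt <- (seq_len(120) - 1) / 60
  blink <- tt >= 1 & tt < 1.2
  expect_identical(b$frames[, , !blink], a$frames[, , !blink])
  expect_false(identical(b$frames[, , blink], a$frames[, , blink]))
})

test_that("labels follow the two-beat rule over randomized specs", {
  for (seed in 1:8) {
    set.seed(seed + 100)
    nb <- sample(0:5, 1)
    kind <- if (nb > 0) "jerk_linear" else "none"
    tr <- gen_trace(waveform_spec(kind, n_beats = nb, amplitude = 1.5),
                    distractor_spec(blink_times = runif(2, 0.2, 3),
                                    tremor_noise_sd = 0.02),
                    rate = 60, duration = 5, seed = seed)
    cl <- render_clip(tr, resolution = c(30, 40), seed = seed)
    expect_equal(cl$label,
                 if (nrow(tr$beats) >= 2) "nystagmus" else "no_nystagmus")
    if (nb <= 1) expect_equal(cl$label, "no_nystagmus")
  }
})

test_that("dataset generation honors class ratio, patients, eccentricity", {
  clips <- make_dataset(n_videos = 40, class_ratio = 0.5, rate = 60,
                        resolution = c(30, 40), duration = 3,
                        eccentric_fraction = 0.25, patients = 10, seed = 42)
  man <- attr(clips, "manifest")
  expect_equal(sum(man$label == "nystagmus"), 20)
  expect_equal(sum(man$label == "no_nystagmus"), 20)
  expect_equal(sum(man$condition == "eccentric"), 10)
  # every patient contributes both classes
  tab <- table(man$patient_id, man$label)
  expect_true(all(tab > 0))
  # eccentric fraction rounding matches the study-scale bookkeeping
  expect_equal(round(0.443 * 435), 193)
  # distractor-only negatives never reach two beats
  expect_true(all(man$n_beats[man$label == "no_nystagmus"] <= 1))
  expect_true(all(man$n_beats[man$label == "nystagmus"] >= 2))
  # slow phases within the physiological range
  expect_true(all(man$slow_phase_ms >= 150 & man$slow_phase_ms <= 350))
})

test_that("dataset generation is deterministic in the master seed", {
  a <- make_dataset(n_videos = 4, resolution = c(20, 26), duration = 2,
                    patients = 2, seed = 7)
  b <- make_dataset(n_videos = 4, resolution = c(20, 26), duration = 2,
                    patients = 2, seed = 7)
  for (i in 1:4) expect_identical(a[[i]]$frames, b[[i]]$frames)
  d <- make_dataset(n_videos = 4, resolution = c(20, 26), duration = 2,
                    patients = 2, seed = 8)
  expect_false(identical(a[[1]]$frames, d[[1]]$frames))
})

test_that("nystagmus clips carry more frame-to-frame motion than fixation", {
  frame_energy <- function(cl) {
    T <- n_frames(cl)
    mean(abs(cl$frames[, , 2:T] - cl$frames[, , 1:(T - 1)]))
  }
  app <- eye_appearance(sensor_noise_sd = 2)
  e_nys <- e_fix <- numeric(5)
  for (s in 1:5) {
    tr_n <- gen_trace(waveform_spec("jerk_linear", amplitude = 1.5,
                                    n_beats = 8),
                      rate = 60, duration = 3, seed = s)
    tr_f <- gen_trace(waveform_spec("none"), rate = 60, duration = 3,
                      seed = s)
    e_nys[s] <- frame_energy(render_clip(tr_n, app, c(30, 40), seed = s))
    e_fix[s] <- frame_energy(render_clip(tr_f, app, c(30, 40), seed = s))
  }
  expect_true(all(e_nys > e_fix))
})
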