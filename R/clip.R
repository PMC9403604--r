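#' Construct a video-oculography clip
#'
#' A `vog_clip` is the unit of classification: an ordered stack of grayscale
#' frames with a sampling rate and optional label/provenance metadata.
#' Frames are stored as a numeric array `H x W x T` with intensities in
#' `[0, 255]`. Time is indexed `1..T`.
#'
#' @param frames numeric array `H x W x T`, or a list of `H x W` matrices,
#'   intensities in `[0, 255]`.
#' @param rate sampling rate in Hz (> 0).
#' @param label optional class label, one of `"nystagmus"`, `"no_nystagmus"`,
#'   or `NA` (unlabeled).
#' @param patient_id optional opaque patient identifier.
#' @param condition optional gaze/positional tag (e.g. `"primary"`,
#'   `"eccentric"`).
#' @param id optional opaque video identifier used to key per-video scores.
#' @param source provenance string.
#' @return an object of class `vog_clip`.
#' @export
vog_clip <- function(frames, rate, label = NA_character_,
                     patient_id = NA_character_, condition = NA_character_,
                     id = NULL, source = "memory") {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L)
      stop("all frames must share identical dimensions")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("'frames' must be an H x W x T array or list of matrices")
  if (dim(frames)[3] < 1L) stop("clip has zero frames")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("'rate' must be a single positive number")
  rng <- range(frames)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop("frame intensities must be finite and within [0, 255]")
  if (!is.na(label) && !label %in% c("nystagmus", "no_nystagmus"))
    stop("'label' must be 'nystagmus', 'no_nystagmus' or NA")
  structure(list(frames = frames, rate = rate, label = label,
                 patient_id = patient_id, condition = condition,
                 id = id, source = source),
            class = "vog_clip")
}

#' Number of frames in a clip
#' @param clip a [vog_clip].
#' @return integer frame count `T`.
#' @export
n_frames <- function(clip) dim(clip$frames)[3]

#' Frame dimensions of a clip
#' @param clip a [vog_clip].
#' @return integer vector `c(H, W)`.
#' @export
clip_resolution <- function(clip) dim(clip$frames)[1:2]

#' @export
print.vog_clip <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<vog_clip> %d frames, %dx%d px, %g Hz (%.2f s)\n",
              d[3], d[1], d[2], x$rate, d[3] / x$rate))
  cat(sprintf("  label: %s  patient: %s  condition: %s  source: %s\n",
              x$label, x$patient_id, x$condition, x$source))
  invisible(x)
}

# replace metadata-preserving frame stack
clip_with_frames <- function(clip, frames, rate = clip$rate) {
  out <- clip
  out$frames <- frames
  out$rate <- rate
  out
}

#' Trim a clip to its leading seconds
#'
#' Keeps the first `floor(seconds * rate)` frames; all metadata is preserved.
#' A 10-s trim of a 60 Hz recording keeps 600 frames.
#'
#' @param clip a [vog_clip].
#' @param seconds duration to keep, in seconds.
#' @return a trimmed [vog_clip].
#' @export
trim_clip <- function(clip, seconds) {
  keep <- floor(seconds * clip$rate)
  if (keep < 1L) stop("'seconds' too short for this sampling rate")
  if (keep > n_frames(clip))
    stop(sprintf("clip has only %.3f s, cannot trim to %g s",
                 n_frames(clip) / clip$rate, seconds))
  clip_with_frames(clip, clip$frames[, , seq_len(keep), drop = FALSE])
}

#' Reduce the sampling rate by frame decimation
#'
#' Keeps every `rate / target_rate`-th frame starting from the first frame;
#' no temporal interpolation is performed, matching how lower-rate variants
#' are simulated from a 60 Hz master recording.
#'
#' @param clip a [vog_clip].
#' @param target_rate new rate in Hz; must divide the source rate evenly.
#' @return a decimated [vog_clip] with updated `rate`.
#' @export
resample_rate <- function(clip, target_rate) {
  step <- clip$rate / target_rate
  if (abs(step - round(step)) > 1e-9)
    stop(sprintf("source rate %g Hz is not an integer multiple of %g Hz",
                 clip$rate, target_rate))
  step <- as.integer(round(step))
  if (step == 1L) return(clip)
  idx <- seq.int(1L, n_frames(clip), by = step)
  clip_with_frames(clip, clip$frames[, , idx, drop = FALSE],
                   rate = target_rate)
}

# area-average resize weight matrix: rows = output pixels, cols = input pixels;
# entry = overlap length of output/input pixel intervals, rows sum to 1
area_weights <- function(n_in, n_out) {
  if (n_out > n_in) stop("upscaling is not supported")
  scale <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    j0 <- floor(lo) + 1L
    j1 <- ceiling(hi)
    for (j in j0:min(j1, n_in)) {
      W[i, j] <- max(0, min(hi, j) - max(lo, j - 1))
    }
  }
  W / scale
}

#' Downscale every frame by area averaging
#'
#' Each output pixel is the average of the source pixels it covers (exact
#' block mean when dimensions divide evenly, overlap-weighted otherwise),
#' which keeps intensities in `[0, 255]` and maps a constant frame to the
#' same constant at any size.
#'
#' @param clip a [vog_clip].
#' @param target_resolution integer `c(H, W)`, each `<=` the source dims.
#' @return a downscaled [vog_clip].
#' @export
downscale <- function(clip, target_resolution) {
  src <- clip_resolution(clip)
  tr <- as.integer(target_resolution)
  if (any(tr > src)) stop("target resolution exceeds source resolution")
  if (all(tr == src)) return(clip)
  Wy <- area_weights(src[1], tr[1])
  Wx <- area_weights(src[2], tr[2])
  T <- n_frames(clip)
  # Wy %*% frame %*% t(Wx), batched over frames via one reshape per side
  a <- Wy %*% matrix(clip$frames, src[1], src[2] * T)    # h x (W*T)
  a <- array(a, dim = c(tr[1], src[2], T))
  a <- aperm(a, c(2, 1, 3))                              # W x h x T
  b <- Wx %*% matrix(a, src[2], tr[1] * T)               # w x (h*T)
  b <- aperm(array(b, dim = c(tr[2], tr[1], T)), c(2, 1, 3))
  clip_with_frames(clip, b)
}

#' Generate all rate-by-resolution degraded variants of a clip
#'
#' One clip per (rate, resolution) pair; the pair matching the source spec is
#' returned unmodified, so the canonical 3 rates x 3 resolutions grid yields
#' the original plus 8 degraded variants.
#'
#' @param clip a [vog_clip].
#' @param rates numeric vector of target rates (Hz).
#' @param resolutions list of `c(H, W)` targets.
#' @return named list of [vog_clip]s, names `"<rate>Hz_<H>x<W>"`.
#' @export
degrade_grid <- function(clip, rates, resolutions) {
  out <- list()
  for (r in rates) {
    clip_r <- resample_rate(clip, r)
    for (res in resolutions) {
      key <- sprintf("%gHz_%dx%d", r, res[1], res[2])
      out[[key]] <- downscale(clip_r, res)
    }
  }
  out
}

#' Reverse the frame order of a clip
#'
#' Used to probe temporal asymmetry of a trained detector (a detector run on
#' time-reversed input should lose its skill if it exploits the slow/fast
#' phase asymmetry of jerk nystagmus).
#'
#' @param clip a [vog_clip].
#' @return the clip with frames in reverse order; all metadata preserved.
#' @export
reverse_clip <- function(clip) {
  T <- n_frames(clip)
  clip_with_frames(clip, clip$frames[, , rev(seq_len(T)), drop = FALSE])
}
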