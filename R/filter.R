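#' Recursive filter parameters
#'
#' The motion representation is governed by a single weight `beta` in
#' `(0, 1]`: the intermediate (background) image forgets past frames at rate
#' `beta` per step. `beta = 1` collapses the recursion to plain
#' frame-to-frame differencing; small `beta` approaches comparison against
#' the first frame. `beta = 0` is disallowed (it degenerates to a constant
#' first-frame comparison and is no longer a recursive filter). An optional
#' `window` length restarts the recursion so that each output image only
#' sees the last `window` frames, bounding the temporal context to roughly
#' one nystagmus beat.
#'
#' @param beta recursion weight in `(0, 1]`.
#' @param window optional window length in frames (`>= 2`); `NULL` for the
#'   non-sliding (full-history) variant.
#' @return an object of class `filter_params`.
#' @export
filter_params <- function(beta, window = NULL) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta > 1)
    stop("'beta' must be a single value in (0, 1]")
  if (!is.null(window)) {
    window <- as.integer(window)
    if (window < 2L) stop("'window' must be >= 2 frames")
  }
  structure(list(beta = beta, window = window), class = "filter_params")
}

#' Convert a clip into a stack of recursive-filtered motion images
#'
#' Each filtered image is the absolute difference between the current frame
#' and an exponentially weighted running image of the past:
#' \deqn{M_1 = I_1,\quad M_t = (1-\beta) M_{t-1} + \beta I_{t-1},\quad
#'       F_t = |I_t - M_t|,\quad t = 2,\dots,T,}
#' yielding `T - 1` images (599 for a 600-frame clip). With a sliding
#' `window` of length `w`, the recursion is restarted on frames
#' `t-w+1 .. t` for each end position `t = w..T`, and only the final `F` of
#' each restarted run is emitted, yielding `T - w + 1` images whose content
#' depends on nothing outside the window.
#'
#' Arithmetic is carried in double precision; values lie in `[0, 255]` by
#' construction. Use [quantize_stack()] to round to 8-bit before image
#' export.
#'
#' @param clip a [vog_clip] with at least 2 frames (or `window` frames).
#' @param params a [filter_params].
#' @return an object of class `filtered_stack`: list with `images`
#'   (`H x W x N` array), `t_index` (source-frame time of each image),
#'   `params`, and `meta` (rate/label/patient/condition/id from the clip).
#' @export
filtered_stack <- function(clip, params) {
  stopifnot(inherits(clip, "vog_clip"), inherits(params, "filter_params"))
  T <- n_frames(clip)
  beta <- params$beta
  w <- params$window
  frames <- clip$frames
  d <- dim(frames)[1:2]
  if (is.null(w)) {
    if (T < 2L) stop("need at least 2 frames for filtering")
    out <- array(0, dim = c(d, T - 1L))
    M <- frames[, , 1]
    for (t in 2:T) {
      # M already equals M_t when entering iteration t (M_2 = I_1)
      out[, , t - 1L] <- abs(frames[, , t] - M)
      M <- (1 - beta) * M + beta * frames[, , t]
    }
    t_index <- 2:T
  } else {
    if (T < w) stop(sprintf("need at least window = %d frames", w))
    n_out <- T - w + 1L
    ends <- w:T
    # restarted recursion in closed form: the running image at a window end
    # is a fixed geometric-weight combination of the first w-1 window frames
    wts <- window_weights(beta, w)
    M <- array(0, dim = c(d, n_out))
    for (j in seq_len(w - 1L)) {
      M <- M + wts[j] * frames[, , ends - w + j, drop = FALSE]
    }
    out <- abs(frames[, , ends, drop = FALSE] - M)
    t_index <- ends
  }
  structure(list(images = out, t_index = t_index, params = params,
                 meta = list(rate = clip$rate, label = clip$label,
                             patient_id = clip$patient_id,
                             condition = clip$condition, id = clip$id)),
            class = "filtered_stack")
}

# weights of frames J_1..J_{w-1} in the restarted running image after w-1
# updates: M_w = (1-b)^(w-2) J_1 + sum_{j=2}^{w-1} b (1-b)^(w-1-j) J_j
window_weights <- function(beta, w) {
  j <- seq_len(w - 1L)
  wts <- beta * (1 - beta)^(w - 1L - j)
  wts[1] <- (1 - beta)^(w - 2L)
  wts
}

#' @export
print.filtered_stack <- function(x, ...) {
  d <- dim(x$images)
  w <- x$params$window
  cat(sprintf("<filtered_stack> %d images, %dx%d px, beta = %g, %s\n",
              d[3], d[1], d[2], x$params$beta,
              if (is.null(w)) "non-sliding" else sprintf("window = %d", w)))
  invisible(x)
}

#' Number of images in a filtered stack
#' @param stack a [filtered_stack].
#' @return integer image count.
#' @export
n_images <- function(stack) dim(stack$images)[3]

#' Quantize a filtered stack to 8-bit intensities
#'
#' @param stack a [filtered_stack].
#' @return the stack with images rounded to integers in `[0, 255]`.
#' @export
quantize_stack <- function(stack) {
  stack$images <- pmin(pmax(round(stack$images), 0), 255)
  stack
}

#' Filter one clip at several beta values
#'
#' The diagnostic sweep used to pick the recursion weight: the canonical
#' grid is `c(0.001, 0.005, 0.01, 0.05, 0.1, 0.25, 0.5)`.
#'
#' @param clip a [vog_clip].
#' @param betas numeric vector of weights in `(0, 1]`.
#' @param window optional shared window length.
#' @return named list of [filtered_stack]s, one per beta.
#' @export
beta_sweep <- function(clip, betas, window = NULL) {
  out <- lapply(betas, function(b) filtered_stack(clip, filter_params(b, window)))
  names(out) <- as.character(betas)
  out
}

#' Export a filtered stack as a PNG image sequence
#'
#' Images are quantized to 8-bit on write.
#'
#' @param stack a [filtered_stack].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
export_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  q <- quantize_stack(stack)
  for (i in seq_len(n_images(q))) {
    png::writePNG(q$images[, , i] / 255,
                  file.path(dir, sprintf("filtered_%05d.png", i)))
  }
  invisible(dir)
}
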