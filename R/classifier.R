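#' Classifier backbone specification
#'
#' The per-image classifier maps one filtered image to a nystagmus
#' probability. Images are first area-averaged down to `input_size` and
#' flattened to a feature vector, so any backbone sees a fixed-length
#' input regardless of the video resolution.
#'
#' Two backbones are registered:
#' \describe{
#'   \item{`tiny_mlp` (default)}{a single-hidden-layer neural network
#'     (tanh hidden units, logistic output) trained by seeded mini-batch
#'     gradient descent with momentum. Small enough to train on one CPU in
#'     seconds-to-minutes, fully deterministic given its seed, and
#'     serializable as plain JSON.}
#'   \item{`logistic`}{penalty-free logistic regression via
#'     [stats::glm.fit]; a convex, training-free-of-tuning reference.}
#' }
#'
#' @param name `"tiny_mlp"` or `"logistic"`.
#' @param input_size integer `c(h, w)` the image is resized to before
#'   flattening.
#' @param hidden hidden-layer width (`tiny_mlp`).
#' @param epochs training epochs (`tiny_mlp`).
#' @param batch_size mini-batch size (`tiny_mlp`).
#' @param learning_rate gradient-descent step size (`tiny_mlp`).
#' @param momentum heavy-ball momentum coefficient (`tiny_mlp`).
#' @param transform input scaling: `"linear"` (default; `[0, 1]` scaling,
#'   keeps motion amplitude, which is informative) or `"sqrt"`
#'   (range-compressing alternative).
#' @param seed seed for weight initialization and batch shuffling.
#' @return an object of class `backbone_spec`.
#' @export
backbone_spec <- function(name = c("tiny_mlp", "logistic"),
                          input_size = c(15, 20), hidden = 32,
                          epochs = 40, batch_size = 256,
                          learning_rate = 0.05, momentum = 0.9,
                          transform = c("linear", "sqrt"), seed = 1) {
  name <- match.arg(name)
  transform <- match.arg(transform)
  structure(list(name = name, input_size = as.integer(input_size),
                 hidden = as.integer(hidden), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 transform = transform, seed = as.integer(seed)),
            class = "backbone_spec")
}

# stack -> n_images x (h*w + 9) feature matrix: area-resized pixels plus
# translation-invariant intensity-band summaries of the full-resolution
# motion image (band fractions separate faint oscillatory motion, strong
# edge motion and blink-scale occlusions wherever the eye sits in frame)
stack_features <- function(stack, input_size, transform = "linear") {
  d <- dim(stack$images)
  h <- input_size[1]; w <- input_size[2]
  flat <- matrix(stack$images, d[1] * d[2], d[3])
  if (d[1] == h && d[2] == w) {
    X <- t(flat)
  } else {
    if (h > d[1] || w > d[2])
      stop("backbone input_size exceeds the image resolution")
    Wk <- kronecker(area_weights(d[2], w), area_weights(d[1], h))
    X <- t(Wk %*% flat)
  }
  edges <- c(2, 5, 10, 20, 40, 80, 160, Inf)
  bands <- vapply(seq_len(length(edges) - 1L), function(i)
    colMeans(flat >= edges[i] & flat < edges[i + 1L]), numeric(d[3]))
  bands <- matrix(bands, nrow = d[3])   # keep shape for single-image stacks
  extra <- cbind(bands, colMeans(flat) / 255,
                 apply(flat, 2, max) / 255)
  # sqrt compresses the dynamic range so faint oscillatory motion is not
  # dwarfed by blinks/lid closures; linear is plain [0,1] scaling
  px <- switch(transform,
               sqrt = sqrt(X / 255),
               linear = X / 255,
               stop("unknown input transform: ", transform))
  cbind(px, extra)
}

#' Train a per-filtered-image classifier
#'
#' Every filtered image inherits the label of the video it came from, so a
#' training split of `V` videos of `T` frames contributes `V * (T - 1)`
#' training images under non-sliding filtering.
#'
#' @param stacks list of labeled [filtered_stack]s (both classes present).
#' @param backbone a [backbone_spec].
#' @return an object of class `vog_classifier`: the fitted weights, the
#'   backbone spec, and (for `tiny_mlp`) a per-epoch training log
#'   (data.frame: epoch, train_loss, train_acc).
#' @export
train_classifier <- function(stacks, backbone = backbone_spec()) {
  labs <- vapply(stacks, function(s) s$meta$label, character(1))
  if (anyNA(labs)) stop("all training stacks must be labeled")
  if (length(unique(labs)) < 2L)
    stop("training set must contain both classes")
  X <- do.call(rbind, lapply(stacks, stack_features,
                             input_size = backbone$input_size,
                             transform = backbone$transform))
  y <- rep(as.numeric(labs == "nystagmus"),
           vapply(stacks, n_images, integer(1)))
  fit <- switch(backbone$name,
    tiny_mlp = mlp_train(X, y, backbone),
    logistic = {
      # perfect separation is routine on motion-energy features; the
      # resulting saturated probabilities are acceptable for voting
      co <- suppressWarnings(
        stats::glm.fit(cbind(1, X), y,
                       family = stats::binomial())$coefficients)
      co[is.na(co)] <- 0
      list(coef = co, log = NULL)
    })
  structure(list(backbone = backbone, fit = fit[names(fit) != "log"],
                 training_log = fit$log, n_train = length(y)),
            class = "vog_classifier")
}

# single-hidden-layer network, tanh/logistic, cross-entropy loss,
# mini-batch gradient descent with momentum; deterministic given the seed
mlp_train <- function(X, y, bb) {
  n <- nrow(X); p <- ncol(X); h <- bb$hidden
  with_seed(bb$seed, {
    W1 <- matrix(stats::rnorm(p * h, 0, sqrt(1 / p)), p, h)
    b1 <- numeric(h)
    W2 <- matrix(stats::rnorm(h, 0, sqrt(1 / h)), h, 1)
    b2 <- 0
    vW1 <- W1 * 0; vb1 <- b1; vW2 <- W2 * 0; vb2 <- 0
    log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      train_acc = numeric(0))
    for (ep in seq_len(bb$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = bb$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + bb$batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
        Hq <- tanh(sweep(Xb %*% W1, 2, b1, "+"))
        pb <- stats::plogis(drop(Hq %*% W2) + b2)
        m <- length(idx)
        dz2 <- (pb - yb) / m
        gW2 <- crossprod(Hq, dz2); gb2 <- sum(dz2)
        dH <- tcrossprod(dz2, W2) * (1 - Hq^2)
        gW1 <- crossprod(Xb, dH); gb1 <- colSums(dH)
        vW1 <- bb$momentum * vW1 - bb$learning_rate * gW1
        vb1 <- bb$momentum * vb1 - bb$learning_rate * gb1
        vW2 <- bb$momentum * vW2 - bb$learning_rate * gW2
        vb2 <- bb$momentum * vb2 - bb$learning_rate * gb2
        W1 <- W1 + vW1; b1 <- b1 + vb1; W2 <- W2 + vW2; b2 <- b2 + vb2
      }
      pr <- mlp_forward(X, W1, b1, W2, b2)
      eps <- 1e-12
      loss <- -mean(y * log(pr + eps) + (1 - y) * log(1 - pr + eps))
      log <- rbind(log, data.frame(epoch = ep, train_loss = loss,
                                   train_acc = mean((pr >= 0.5) == y)))
    }
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, log = log)
  })
}

mlp_forward <- function(X, W1, b1, W2, b2) {
  stats::plogis(drop(tanh(sweep(X %*% W1, 2, b1, "+")) %*% W2) + b2)
}

#' Score every image in a filtered stack
#'
#' Prediction is a pure function of (model, image): duplicated images get
#' identical probabilities and reordering the stack reorders the scores.
#'
#' @param model a trained [vog_classifier].
#' @param stack a [filtered_stack].
#' @return an object of class `per_image_scores`: list with `probs`
#'   (numeric vector in `[0, 1]`, one per image), `t_index`, and `video_id`.
#' @export
predict_stack <- function(model, stack) {
  if (n_images(stack) == 0L) stop("empty filtered stack")
  X <- stack_features(stack, model$backbone$input_size,
                      model$backbone$transform %||% "linear")
  probs <- switch(model$backbone$name,
    tiny_mlp = mlp_forward(X, model$fit$W1, model$fit$b1,
                           model$fit$W2, model$fit$b2),
    logistic = stats::plogis(drop(cbind(1, X) %*% model$fit$coef)))
  structure(list(probs = as.numeric(probs), t_index = stack$t_index,
                 video_id = stack$meta$id %||% NA_character_),
            class = "per_image_scores")
}

#' Save / load a trained classifier as JSON
#'
#' The checkpoint is plain text (weights at full double precision plus the
#' backbone config), so a reloaded model reproduces the original
#' probabilities.
#'
#' @param model a [vog_classifier].
#' @param path output `.json` path.
#' @return `save_classifier`: `path` invisibly; `load_classifier`: the model.
#' @export
save_classifier <- function(model, path) {
  # flatten matrices to (dim, column-major data) pairs so the checkpoint is
  # unambiguous plain JSON
  pack <- function(x) if (is.matrix(x))
    list(dim = dim(x), data = as.numeric(x)) else as.numeric(x)
  obj <- list(backbone = unclass(model$backbone),
              fit = lapply(model$fit, pack), n_train = model$n_train)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bb <- do.call(backbone_spec, as.list(obj$backbone))
  unpack <- function(x) {
    if (is.list(x) && !is.null(x$dim)) {
      matrix(as.numeric(x$data), x$dim[1], x$dim[2])
    } else {
      as.numeric(x)
    }
  }
  fit <- lapply(obj$fit, unpack)
  structure(list(backbone = bb, fit = fit, training_log = NULL,
                 n_train = obj$n_train),
            class = "vog_classifier")
}

#' @export
print.vog_classifier <- function(x, ...) {
  cat(sprintf("<vog_classifier> backbone = %s, input %dx%d, trained on %d images\n",
              x$backbone$name, x$backbone$input_size[1],
              x$backbone$input_size[2], x$n_train))
  invisible(x)
}
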