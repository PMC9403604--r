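#' Fit a video-level nystagmus detector
#'
#' The main fitting function: converts labeled training clips into
#' recursive-filtered image stacks, trains a per-image classifier (each
#' filtered image inheriting its video's label), and packages the result
#' with a voting rule into a video-level detector. Predictions on new clips
#' run the same filter, score every image, and aggregate by the stored
#' voting rule.
#'
#' @param clips list of labeled [vog_clip]s (both classes present).
#' @param beta recursion weight of the filtered-image transform, in (0, 1].
#' @param window optional sliding-window length in frames.
#' @param backbone a [backbone_spec].
#' @param voting a [voting_spec] used at prediction time.
#' @return an object of class `nystagmus_detector` with [predict],
#'   [print], [summary] and [plot] methods.
#' @seealso [filtered_stack()], [train_classifier()], [soft_vote()]
#' @examples
#' \donttest{
#' clips <- make_dataset(n_videos = 12, resolution = c(30, 40),
#'                       duration = 3, patients = 3, seed = 7)
#' fit <- nystagmus_detector(clips[1:8], beta = 0.25,
#'                           backbone = backbone_spec(epochs = 5))
#' predict(fit, clips[9:12])
#' }
#' @export
nystagmus_detector <- function(clips, beta = 0.25, window = NULL,
                               backbone = backbone_spec(),
                               voting = voting_spec("soft")) {
  params <- filter_params(beta, window)
  stacks <- lapply(clips, filtered_stack, params = params)
  clf <- train_classifier(stacks, backbone)
  structure(list(classifier = clf, filter = params, voting = voting,
                 n_videos = length(clips),
                 n_images = sum(vapply(stacks, n_images, integer(1)))),
            class = "nystagmus_detector")
}

#' Predict video-level nystagmus decisions
#'
#' @param object a fitted [nystagmus_detector].
#' @param newdata list of [vog_clip]s (or a single clip).
#' @param type `"decision"` for one row per video (id, score, label),
#'   `"scores"` for the raw per-image probability vectors.
#' @param ... unused.
#' @return a data.frame of decisions, or a list of `per_image_scores`.
#' @export
predict.nystagmus_detector <- function(object, newdata,
                                       type = c("decision", "scores"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "vog_clip")) newdata <- list(newdata)
  scores <- lapply(newdata, function(cl)
    predict_stack(object$classifier, filtered_stack(cl, object$filter)))
  if (type == "scores") return(scores)
  vote_videos(scores, object$voting)
}

#' @export
print.nystagmus_detector <- function(x, ...) {
  w <- x$filter$window
  cat("<nystagmus_detector>\n")
  cat(sprintf("  filter: beta = %g, %s\n", x$filter$beta,
              if (is.null(w)) "non-sliding" else sprintf("window = %d", w)))
  cat(sprintf("  backbone: %s; voting: %s\n",
              x$classifier$backbone$name, x$voting$method))
  cat(sprintf("  trained on %d videos (%d filtered images)\n",
              x$n_videos, x$n_images))
  invisible(x)
}

#' @export
summary.nystagmus_detector <- function(object, ...) {
  print(object)
  log <- object$classifier$training_log
  if (!is.null(log)) {
    lc <- learning_curves(log)
    cat(sprintf("  final train loss %.4f, train acc %.3f (converged: %s)\n",
                utils::tail(log$train_loss, 1),
                utils::tail(log$train_acc, 1), lc$converged))
  }
  invisible(object)
}

#' Plot learning curves of a fitted detector
#'
#' @param x a fitted [nystagmus_detector] (tiny_mlp backbone).
#' @param ... passed to [graphics::plot].
#' @export
plot.nystagmus_detector <- function(x, ...) {
  log <- x$classifier$training_log
  if (is.null(log)) stop("no training log available for this backbone")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(log$epoch, log$train_loss, type = "l", xlab = "epoch",
                 ylab = "training loss", ...)
  graphics::plot(log$epoch, log$train_acc, type = "l", xlab = "epoch",
                 ylab = "training accuracy", ylim = c(0, 1), ...)
  invisible(x)
}
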