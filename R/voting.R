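#' Voting rule specification
#'
#' Converts a vector of per-filtered-image probabilities into one
#' video-level decision. `soft` averages the probabilities; `hard`
#' binarizes each image at `prob_threshold` and takes the positive
#' fraction (a majority vote at the defaults); `temporal` requires a
#' sufficiently long run of consecutive positive images, mirroring the
#' clinical definition of nystagmus as sustained consecutive beats.
#' Ties binarize as positive (`>=`), and video labels use
#' `score >= video_threshold`.
#'
#' @param method `"soft"`, `"hard"` or `"temporal"`.
#' @param prob_threshold per-image binarization threshold in (0, 1).
#' @param video_threshold video-level threshold on the aggregate score.
#' @param run_length required consecutive positives (temporal only);
#'   typical values 50, 100, 150, 350 frames.
#' @return an object of class `voting_spec`.
#' @export
voting_spec <- function(method = c("soft", "hard", "temporal"),
                        prob_threshold = 0.5, video_threshold = 0.5,
                        run_length = 50L) {
  method <- match.arg(method)
  if (prob_threshold <= 0 || prob_threshold >= 1 ||
      video_threshold <= 0 || video_threshold >= 1)
    stop("thresholds must lie in (0, 1)")
  run_length <- as.integer(run_length)
  if (run_length < 1L) stop("'run_length' must be >= 1")
  structure(list(method = method, prob_threshold = prob_threshold,
                 video_threshold = video_threshold,
                 run_length = run_length),
            class = "voting_spec")
}

video_decision <- function(video_id, score, label, method) {
  structure(list(video_id = video_id, score = score,
                 label = if (label) "nystagmus" else "no_nystagmus",
                 method = method),
            class = "video_decision")
}

#' @export
print.video_decision <- function(x, ...) {
  cat(sprintf("<video_decision> %s: %s (score %.4f, %s)\n",
              x$video_id, x$label, x$score, x$method))
  invisible(x)
}

check_scores <- function(scores) {
  if (!inherits(scores, "per_image_scores") || length(scores$probs) == 0L)
    stop("nonempty per_image_scores required")
}

#' Soft (mean-probability) vote
#'
#' @param scores a `per_image_scores` object.
#' @param spec a [voting_spec].
#' @return a `video_decision`: `score` = mean per-image probability,
#'   positive when `score >= video_threshold`.
#' @export
soft_vote <- function(scores, spec = voting_spec("soft")) {
  check_scores(scores)
  sc <- mean(scores$probs)
  video_decision(scores$video_id, sc, sc >= spec$video_threshold, "soft")
}

#' Hard (majority) vote
#'
#' @inheritParams soft_vote
#' @return a `video_decision`: `score` = fraction of images whose
#'   probability is `>= prob_threshold`; positive when that fraction is
#'   `>= video_threshold` (strict majority at the defaults).
#' @export
hard_vote <- function(scores, spec = voting_spec("hard")) {
  check_scores(scores)
  sc <- mean(scores$probs >= spec$prob_threshold)
  video_decision(scores$video_id, sc, sc >= spec$video_threshold, "hard")
}

# length of the longest TRUE run
longest_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Temporal (consecutive-run) vote
#'
#' Positive when the longest run of consecutive positive images reaches
#' `run_length`; with a 60 Hz source, 50 consecutive filtered images span
#' about 750 ms, i.e. at least two short beats.
#'
#' @inheritParams soft_vote
#' @return a `video_decision`: `score` = longest positive run divided by
#'   the stack length; positive when the longest run is `>= run_length`.
#' @export
temporal_vote <- function(scores, spec = voting_spec("temporal")) {
  check_scores(scores)
  run <- longest_run(scores$probs >= spec$prob_threshold)
  video_decision(scores$video_id, run / length(scores$probs),
                 run >= spec$run_length,
                 sprintf("temporal(run>=%d)", spec$run_length))
}

#' Ensemble of two video-level decisions
#'
#' Averages the aggregate scores of two constituent decisions (canonically a
#' soft vote from one model and a hard vote from another) and thresholds the
#' mean at 0.5. Symmetric in its arguments.
#'
#' @param decision_a,decision_b `video_decision`s for the same video.
#' @return a `video_decision` with the averaged score.
#' @export
ensemble_vote <- function(decision_a, decision_b) {
  if (!identical(decision_a$video_id, decision_b$video_id))
    stop("ensemble requires decisions for the same video")
  sc <- (decision_a$score + decision_b$score) / 2
  video_decision(decision_a$video_id, sc, sc >= 0.5,
                 sprintf("ensemble(%s+%s)", decision_a$method,
                         decision_b$method))
}

#' Apply a voting rule to many score vectors
#'
#' @param scores_list list of `per_image_scores`.
#' @param spec a [voting_spec].
#' @return data.frame with columns `video_id`, `score`, `label`, `method`.
#' @export
vote_videos <- function(scores_list, spec = voting_spec("soft")) {
  fun <- switch(spec$method, soft = soft_vote, hard = hard_vote,
                temporal = temporal_vote)
  do.call(rbind, lapply(scores_list, function(s) {
    d <- fun(s, spec)
    data.frame(video_id = d$video_id, score = d$score, label = d$label,
               method = d$method, stringsAsFactors = FALSE)
  }))
}
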