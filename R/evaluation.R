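#' ROC curve and AUROC
#'
#' Sweeps every distinct score as a threshold (predict positive when
#' `score >= threshold`) and integrates the ROC curve by the trapezoid
#' rule. The result equals the pairwise-concordance probability: the
#' chance a random positive outscores a random negative, ties counting
#' one half.
#'
#' @param scores numeric per-video scores (higher = more nystagmus-like).
#' @param labels binary truth: logical, 0/1, or the package's label strings.
#' @return list with `auc` and `curve` (data.frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L)
    stop("both classes must be present to compute a ROC curve")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  P <- sum(y == 1); N <- sum(y == 0)
  tpr <- vapply(thr, function(th) sum(scores >= th & y == 1) / P, numeric(1))
  fpr <- vapply(thr, function(th) sum(scores >= th & y == 0) / N, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc, curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr))
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    as.numeric(as.character(labels) == "nystagmus")
  } else {
    as.numeric(as.logical(labels))
  }
}

#' Confusion-matrix metrics at a score threshold
#'
#' @param scores numeric per-video scores.
#' @param labels binary truth (see [roc_auc]).
#' @param threshold operating threshold; predict positive when
#'   `score >= threshold`.
#' @return an object of class `metrics_report`: TP/FP/TN/FN counts,
#'   `sensitivity`, `specificity`, `accuracy` (percentages),
#'   `operating_threshold` and `n_videos`.
#' @export
metrics_at_threshold <- function(scores, labels, threshold = 0.5) {
  y <- as_binary_labels(labels)
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 sensitivity = 100 * tp / (tp + fn),
                 specificity = 100 * tn / (tn + fp),
                 accuracy = 100 * (tp + tn) / length(y),
                 operating_threshold = threshold,
                 n_videos = length(y)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d @ threshold %.3f\n", x$n_videos,
              x$operating_threshold))
  cat(sprintf("  sens %.1f%%  spec %.1f%%  acc %.1f%%  (TP %d FP %d TN %d FN %d)\n",
              x$sensitivity, x$specificity, x$accuracy,
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Youden-J optimal operating threshold
#'
#' @param scores,labels as in [roc_auc].
#' @return the threshold maximizing sensitivity + specificity - 1.
#' @export
youden_threshold <- function(scores, labels) {
  r <- roc_auc(scores, labels)
  j <- r$curve$tpr - r$curve$fpr
  best <- which.max(j)
  r$curve$threshold[best]
}

#' Stratified group k-fold assignment
#'
#' Partitions videos into `k` folds so that (a) fold sizes are near-equal,
#' (b) each fold's class proportions stay within one video of the global
#' proportions, and (c) each patient's videos of each class are spread
#' across folds, so both classes from a patient appear in every training
#' portion whenever the patient has enough videos. Class balance is the
#' hard constraint; patient balance is best-effort (relaxed second), as
#' full balancing of heterogeneous per-patient video counts is generally
#' infeasible.
#'
#' @param labels per-video binary truth (see [roc_auc]).
#' @param patient_ids per-video patient identifiers.
#' @param k number of folds (>= 2).
#' @param seed shuffle seed.
#' @return an object of class `fold_split`: list with `k`, `assignments`
#'   (integer fold per video) and `constraints_log` (per-fold class counts
#'   and patient coverage).
#' @export
stratified_group_kfold <- function(labels, patient_ids, k = 3, seed = 1) {
  y <- as_binary_labels(labels)
  n <- length(y)
  if (k < 2L) stop("k must be >= 2 (k = 1 leaves no held-out data)")
  if (n < k) stop("fewer videos than folds")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  assign <- integer(n)
  with_seed(seed, {
    for (cls in c(1, 0)) {
      # group this class's videos by patient, visit groups in shuffled
      # order, and drop each video on the currently lightest fold for the
      # class (ties broken at random) -> class balance first, patients spread
      idx_c <- which(y == cls)
      groups <- split(idx_c, patient_ids[idx_c])
      groups <- groups[sample.int(length(groups))]
      counts <- integer(k)
      for (g in groups) {
        g <- g[sample.int(length(g))]
        for (v in g) {
          f <- which(counts == min(counts))
          if (length(f) > 1L) f <- sample(f, 1L)
          assign[v] <- f
          counts[f] <- counts[f] + 1L
        }
      }
    }
  })
  log <- do.call(rbind, lapply(seq_len(k), function(f) {
    data.frame(fold = f, n = sum(assign == f),
               n_pos = sum(assign == f & y == 1),
               n_neg = sum(assign == f & y == 0),
               n_patients = length(unique(patient_ids[assign == f])))
  }))
  structure(list(k = k, assignments = assign, constraints_log = log),
            class = "fold_split")
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf("<fold_split> k = %d\n", x$k))
  print(x$constraints_log, row.names = FALSE)
  invisible(x)
}

#' Unpaired two-sample t-test between model prediction probabilities
#'
#' Classical pooled-variance two-sample t-test (two-sided). When both
#' samples are degenerate (zero variance) the comparison short-circuits to
#' an exact equality test: p = 1 if the means agree, p = 0 otherwise.
#'
#' @param probs_a,probs_b numeric vectors of per-video prediction
#'   probabilities (each of length >= 2).
#' @return an object of class `comparison_result`: `mean_a`, `sd_a`,
#'   `mean_b`, `sd_b`, `t_statistic`, `df`, `p_value`, `alpha = 0.05`.
#' @export
compare_models_ttest <- function(probs_a, probs_b) {
  if (length(probs_a) < 2L || length(probs_b) < 2L)
    stop("each sample must have at least 2 values")
  if (anyNA(probs_a) || anyNA(probs_b) ||
      any(!is.finite(c(probs_a, probs_b))))
    stop("samples must be finite")
  ma <- mean(probs_a); mb <- mean(probs_b)
  sa <- stats::sd(probs_a); sb <- stats::sd(probs_b)
  if (sa == 0 && sb == 0) {
    t_stat <- if (ma == mb) 0 else Inf * sign(ma - mb)
    p <- as.numeric(ma == mb)
    df <- length(probs_a) + length(probs_b) - 2
  } else {
    ht <- stats::t.test(probs_a, probs_b, var.equal = TRUE)
    t_stat <- unname(ht$statistic)
    p <- ht$p.value
    df <- unname(ht$parameter)
  }
  structure(list(mean_a = ma, sd_a = sa, mean_b = mb, sd_b = sb,
                 t_statistic = t_stat, df = df, p_value = p, alpha = 0.05),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> t = %.4f (df %.1f), p = %.4g\n",
              x$t_statistic, x$df, x$p_value))
  cat(sprintf("  A: mean %.3f sd %.3f | B: mean %.3f sd %.3f\n",
              x$mean_a, x$sd_a, x$mean_b, x$sd_b))
  invisible(x)
}

#' Summarize a training log into learning curves
#'
#' @param training_log data.frame with `epoch` and loss/accuracy columns
#'   (as produced by [train_classifier] with the `tiny_mlp` backbone).
#' @param eps slope tolerance: the run is flagged converged when the mean
#'   per-epoch change of the loss over the final window is `>= -eps`.
#' @param window number of final epochs used for the slope.
#' @return list with `curves` (the log, pass-through) and `converged`.
#' @export
learning_curves <- function(training_log, eps = 1e-3, window = 5L) {
  if (is.null(training_log) || nrow(training_log) == 0L)
    stop("empty training log")
  loss <- training_log$train_loss
  w <- min(window, length(loss))
  slope <- if (w < 2L) 0 else mean(diff(utils::tail(loss, w)))
  list(curves = training_log, converged = slope >= -eps, final_slope = slope)
}
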