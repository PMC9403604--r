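# Independent brute-force oracles. These deliberately use plain scalar
# loops / first-principles formulas so they share no code path with the
# package implementations they check.

# random small clip, integer intensities
random_clip <- function(T, H = 4, W = 4, rate = 60, seed = 1,
                        label = NA_character_) {
  set.seed(seed)
  vog_clip(array(as.double(sample(0:255, H * W * T, replace = TRUE)),
                 c(H, W, T)),
           rate = rate, label = label, id = sprintf("rc%d", seed))
}

# unrolled recursion, one pixel at a time:
# M_1 = I_1; M_t = (1-b) M_{t-1} + b I_{t-1}; F_t = |I_t - M_t|, t = 2..T
oracle_filtered_nonsliding <- function(frames, beta) {
  H <- dim(frames)[1]; W <- dim(frames)[2]; T <- dim(frames)[3]
  out <- array(NA_real_, c(H, W, T - 1))
  for (i in seq_len(H)) for (j in seq_len(W)) {
    M <- frames[i, j, 1]
    for (t in 2:T) {
      out[i, j, t - 1] <- abs(frames[i, j, t] - M)
      M <- (1 - beta) * M + beta * frames[i, j, t]
    }
  }
  out
}

# restarted recursion per window end-position
oracle_filtered_sliding <- function(frames, beta, w) {
  H <- dim(frames)[1]; W <- dim(frames)[2]; T <- dim(frames)[3]
  out <- array(NA_real_, c(H, W, T - w + 1))
  for (e in w:T) {
    sub <- frames[, , (e - w + 1):e, drop = FALSE]
    out[, , e - w + 1] <- oracle_filtered_nonsliding(sub, beta)[, , w - 1]
  }
  out
}

# longest run of TRUE by explicit scan
oracle_longest_run <- function(x) {
  best <- 0L; cur <- 0L
  for (v in x) {
    cur <- if (v) cur + 1L else 0L
    best <- max(best, cur)
  }
  best
}

# AUROC as mean pairwise concordance over positive x negative pairs
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# textbook pooled-variance two-sample t-test
oracle_ttest <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, p = 2 * pt(-abs(t), df))
}

scores_obj <- function(probs, id = "v1") {
  structure(list(probs = probs, t_index = seq_along(probs) + 1L,
                 video_id = id),
            class = "per_image_scores")
}
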