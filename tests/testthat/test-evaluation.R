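test_that("AUROC matches the pairwise-concordance oracle and pROC", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  for (seed in 1:5) {
    set.seed(seed)
    y <- rbinom(20, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(runif(20), 2)           # rounding forces ties
    auc <- roc_auc(s, y)$auc
    expect_equal(auc, oracle_auc(s, y), tolerance = 1e-12)
    expect_equal(auc,
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(6)
  y <- rep(c(0, 1), each = 10)
  s <- runif(20)
  base <- roc_auc(s, y)$auc
  expect_equal(roc_auc(2 * s + 3, y)$auc, base)
  expect_equal(roc_auc(exp(s), y)$auc, base)
  expect_equal(roc_auc(qlogis(pmin(pmax(s, 1e-6), 1 - 1e-6)), y)$auc, base)
})

test_that("threshold metrics recompute exactly from confusion counts", {
  m <- metrics_at_threshold(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(m$accuracy, 100)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 100)
  m2 <- metrics_at_threshold(rep(0.9, 6), c(1, 1, 1, 0, 0, 0), 0.5)
  expect_equal(m2$sensitivity, 100)
  expect_equal(m2$specificity, 0)
  # a confusion table with TP=61 FN=8 TN=46 FP=16 gives the clinical-style
  # rate pair 88.4% / 74.2%
  scores <- c(rep(0.9, 61), rep(0.1, 8), rep(0.1, 46), rep(0.9, 16))
  truth <- c(rep(1, 69), rep(0, 62))
  m3 <- metrics_at_threshold(scores, truth, 0.5)
  expect_equal(m3$TP, 61); expect_equal(m3$FN, 8)
  expect_equal(m3$TN, 46); expect_equal(m3$FP, 16)
  expect_equal(m3$sensitivity, 100 * 61 / 69, tolerance = 1e-12)
  expect_equal(m3$specificity, 100 * 46 / 62, tolerance = 1e-12)
  expect_equal(round(m3$sensitivity, 1), 88.4)
  expect_equal(round(m3$specificity, 1), 74.2)
  expect_equal(m3$TP + m3$FP + m3$TN + m3$FN, m3$n_videos)
})

test_that("stratified group k-fold partitions with class balance", {
  # exactly divisible case: 30 videos, 15/15, k = 3 -> folds of 10 with 5/5
  labs <- rep(c(1, 0), each = 15)
  pats <- rep(sprintf("P%d", 1:5), 6)
  fs <- stratified_group_kfold(labs, pats, k = 3, seed = 1)
  expect_equal(sort(unique(fs$assignments)), 1:3)
  expect_equal(unname(table(fs$assignments)), rep(10L, 3), ignore_attr = TRUE)
  expect_equal(fs$constraints_log$n_pos, rep(5L, 3))
  expect_equal(fs$constraints_log$n_neg, rep(5L, 3))
  expect_error(stratified_group_kfold(labs, pats, k = 1), "k = 1|>= 2")
})

test_that("fold class shares stay within one video of global on odd sizes", {
  set.seed(7)
  n <- 435
  labs <- c(rep(1, 218), rep(0, 217))
  pats <- sample(sprintf("P%02d", 1:30), n, replace = TRUE)
  fs <- stratified_group_kfold(labs, pats, k = 3, seed = 2)
  # partition: every video in exactly one fold
  expect_equal(length(fs$assignments), n)
  expect_true(all(fs$assignments %in% 1:3))
  for (f in 1:3) {
    npos <- sum(fs$assignments == f & labs == 1)
    nneg <- sum(fs$assignments == f & labs == 0)
    expect_lte(abs(npos - 218 / 3), 1)
    expect_lte(abs(nneg - 217 / 3), 1)
    expect_gt(npos, 0); expect_gt(nneg, 0)
  }
  # patients with >= k videos of a class appear in more than one fold
  big <- names(which(table(pats[labs == 1]) >= 3))
  for (p in big[1:3]) {
    expect_gt(length(unique(fs$assignments[pats == p & labs == 1])), 1)
  }
})

test_that("two-sample t-test matches the closed-form oracle", {
  ident <- rep(c(0.2, 0.4, 0.6), 3)
  expect_equal(compare_models_ttest(ident, ident)$p_value, 1)
  set.seed(8)
  a <- rnorm(131, 0.25, 0.16)
  b <- rnorm(131, 0.52, 0.34)
  res <- compare_models_ttest(a, b)
  ora <- oracle_ttest(a, b)
  expect_equal(res$t_statistic, ora$t, tolerance = 1e-10)
  expect_equal(res$p_value, ora$p, tolerance = 1e-10)
  expect_equal(res$mean_a, mean(a))
  expect_equal(res$sd_b, sd(b))
  # symmetry: swapping samples negates t, preserves p
  swp <- compare_models_ttest(b, a)
  expect_equal(swp$t_statistic, -res$t_statistic, tolerance = 1e-12)
  expect_equal(swp$p_value, res$p_value, tolerance = 1e-12)
  # degenerate all-zero sample vs. a spread sample: decisive rejection
  dz <- compare_models_ttest(rep(0, 60), rnorm(60, 0.25, 0.15))
  expect_lt(dz$p_value, 0.001)
  # both degenerate with equal means -> exact equality, p = 1
  expect_equal(compare_models_ttest(rep(0.3, 5), rep(0.3, 7))$p_value, 1)
  expect_equal(compare_models_ttest(rep(0.3, 5), rep(0.4, 7))$p_value, 0)
  expect_error(compare_models_ttest(1, c(1, 2)), "at least 2")
  expect_error(compare_models_ttest(c(1, NA), c(1, 2)), "finite")
})

test_that("learning-curve summaries pass data through and flag convergence", {
  log <- data.frame(epoch = 1:10, train_loss = exp(-(1:10)),
                    train_acc = seq(0.5, 0.95, length.out = 10))
  lc <- learning_curves(log)
  expect_true(lc$converged)
  expect_equal(lc$curves, log)
  flat <- data.frame(epoch = 1:5, train_loss = rep(0.7, 5),
                     train_acc = rep(0.5, 5))
  lcf <- learning_curves(flat)
  expect_true(lcf$converged)
  expect_equal(lcf$final_slope, 0)
  # the flag reports "loss is no longer decreasing", so a rising loss is
  # also flagged (slope >= -eps); a steadily falling loss is not
  diverge <- data.frame(epoch = 1:6, train_loss = seq(0.5, 2, length.out = 6),
                        train_acc = rep(0.5, 6))
  expect_true(learning_curves(diverge)$converged)
  falling <- data.frame(epoch = 1:6, train_loss = seq(2, 0.5, length.out = 6),
                        train_acc = rep(0.5, 6))
  expect_false(learning_curves(falling)$converged)
  expect_error(learning_curves(NULL), "empty")
})

test_that("youden threshold maximizes sensitivity + specificity", {
  scores <- c(0.1, 0.2, 0.35, 0.6, 0.7, 0.9)
  truth <- c(0, 0, 0, 1, 1, 1)
  th <- youden_threshold(scores, truth)
  m <- metrics_at_threshold(scores, truth, th)
  expect_equal(m$sensitivity + m$specificity, 200)
})
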