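test_that("elastic net recovers a planted informative feature", {
  set.seed(1)
  X <- matrix(rnorm(60 * 21), 60, 21,
              dimnames = list(NULL, paste0("f", 1:21)))
  X <- scale(X)
  y <- 2 * X[, 3]
  sel <- select_features(X, y, seed = 1)
  expect_true("f3" %in% sel)
  # constant response -> empty selection, with a warning
  expect_warning(sel0 <- select_features(X, rep(7, 60), seed = 1),
                 "constant|no features")
  expect_length(sel0, 0)
})

test_that("duplicated informative features are tolerated by the elastic net", {
  set.seed(2)
  X <- matrix(rnorm(60 * 20), 60, 20,
              dimnames = list(NULL, paste0("f", 1:20)))
  X[, 4] <- X[, 3]
  X <- scale(X)
  X[, 4] <- X[, 3]
  y <- 2 * X[, 3] + rnorm(60, 0, 0.01)
  sel <- select_features(X, y, seed = 2)
  expect_gt(length(sel), 0)
  expect_true(any(c("f3", "f4") %in% sel))
})

test_that("skill model learns separable synthetic data on the training set", {
  set.seed(7)
  n <- 60
  x <- random_feature_table(n, seed = 7)
  s <- runif(n, 1, 4.5)
  # plant a strong skill signal in a few motion features
  x$trial_time <- 400 * exp(-0.4 * (s - 1)) + rnorm(n, 0, 5)
  x$path_total_sum <- 2000 - 350 * s + rnorm(n, 0, 20)
  x$ivel_lin_mag_std_needle <- 30 - 5 * s + rnorm(n, 0, 0.5)
  dom <- domains_from_skill(s)
  fit <- skill_model(x, dom, subset = "TMVG", seed = 7)
  pred <- predict(fit, x)
  truth <- rowSums(dom)
  expect_gte(mean(abs(pred$summed - truth) <= 2), 0.9)
})

test_that("degenerate labels and empty selections fall back as contracted", {
  x <- random_feature_table(20, seed = 3)
  dom_const <- domains_from_skill(rep(3, 20))
  expect_error(skill_model(x, dom_const, "TMVG"), "degenerate labels")
  # labels vary but carry no signal -> median fallback possible; force it by
  # constructing a model whose selection is empty
  dom <- domains_from_skill(c(rep(2, 10), rep(4, 10)))
  fit <- suppressWarnings(skill_model(x, dom, "TMVG", seed = 3))
  if (length(fit$selected) == 0) {
    p <- predict(fit, x)
    expect_true(all(p$summed == round(fit$train_median)))
  }
  # hand-built empty model always predicts the training median
  fit$selected <- character()
  fit$trees <- NULL
  fit$train_median <- 14
  p <- predict(fit, x[1:5, ])
  expect_identical(p$summed, rep(14L, 5))
  expect_identical(p$rounded_avg, rep(3L, 5))
})

test_that("predictions are integer, clipped to [5, 25], and deterministic", {
  fit <- structure(list(selected = character(), trees = NULL,
                        train_median = 3.7,
                        config = skill_config()),
                   class = "skill_model")
  p <- predict(fit, data.frame(a = 1:3))
  expect_identical(p$summed, rep(5L, 3))        # clip floor
  expect_identical(p$rounded_avg, rep(1L, 3))
  x <- random_feature_table(30, seed = 11)
  dom <- domains_from_skill(runif(30, 1, 4.5))
  m <- skill_model(x, dom, "TMVG", seed = 11)
  expect_identical(predict(m, x), predict(m, x))
})

test_that("a TG model never references a tip-motion or visibility feature", {
  set.seed(5)
  n <- 40
  x <- random_feature_table(n, seed = 5)
  s <- runif(n, 1, 4.5)
  x$trial_time <- 400 * exp(-0.4 * (s - 1)) + rnorm(n, 0, 5)
  x$grip_vel_peakrate_10_needle <- 2 + 0.5 * (5 - s) + rnorm(n, 0, 0.05)
  fit <- skill_model(x, domains_from_skill(s), subset = "TG", seed = 5)
  man <- maf_manifest()
  allowed <- man$name[man$category %in% c("time", "grip")]
  expect_true(all(fit$selected %in% allowed))
})

test_that("missing feature columns are reported by name at predict time", {
  x <- random_feature_table(30, seed = 13)
  s <- runif(30, 1, 4.5)
  x$trial_time <- 400 * exp(-0.4 * (s - 1))
  fit <- skill_model(x, domains_from_skill(s), "T", seed = 13)
  expect_gt(length(fit$selected), 0)
  bad <- x[, setdiff(names(x), fit$selected[1])]
  expect_error(predict(fit, bad), fit$selected[1], fixed = TRUE)
})

test_that("metrics match hand computations and flag constant series as NaN", {
  pred <- data.frame(summed = c(10L, 15L, 20L, 5L),
                     rounded_avg = c(2L, 3L, 4L, 1L))
  m <- skill_metrics(pred, c(10L, 15L, 20L, 5L))
  expect_true(all(m$metrics[c("acc_within2_summed", "acc_within4_summed",
                              "acc_exact_avg", "acc_within1_avg")] == 1))
  expect_equal(unname(m$metrics["r_summed"]), 1)
  anti <- data.frame(summed = c(6L, 7L, 8L, 9L), rounded_avg = c(1L, 1L, 2L, 2L))
  m2 <- skill_metrics(anti, c(9L, 8L, 7L, 6L))
  expect_equal(unname(m2$metrics["r_summed"]), -1)
  const <- data.frame(summed = rep(14L, 4), rounded_avg = rep(3L, 4))
  m3 <- skill_metrics(const, c(9L, 14L, 15L, 20L))
  expect_true(is.nan(m3$metrics["r_summed"]))
  expect_error(skill_metrics(pred, 1:3), "length|nrow")
  # confusion matrix row sums equal label counts
  expect_identical(unname(rowSums(m$confusion)), c(1, 1, 1, 1, 0))
})

test_that("accuracy metrics are monotone in their tolerance bands", {
  set.seed(23)
  for (i in 1:20) {
    truth <- sample(5:25, 15, replace = TRUE)
    pred <- data.frame(summed = pmin(pmax(truth + sample(-6:6, 15, TRUE), 5L), 25L))
    pred$rounded_avg <- rounded_average(pred$summed)
    m <- skill_metrics(pred, truth)$metrics
    expect_gte(m["acc_within4_summed"], m["acc_within2_summed"])
    expect_gte(m["acc_within1_avg"], m["acc_exact_avg"])
  }
})

test_that("the random baseline is uniform on 5..20 and the median baseline is constant", {
  p <- baseline_predict("random", n_trials = 1e5, seed = 3)
  freq <- table(factor(p$summed, levels = 5:20)) / 1e5
  expect_true(all(abs(freq - 1 / 16) < 0.005))
  med <- baseline_predict("median", train_summed = c(10, 14, 14, 15, 18),
                          n_trials = 4)
  expect_identical(med$summed, rep(14L, 4))
  expect_identical(med$rounded_avg, rep(3L, 4))
  m <- skill_metrics(med, c(10L, 14L, 15L, 18L))
  expect_true(is.nan(m$metrics["r_summed"]))
})

test_that("the random baseline's exact accuracy matches the analytic value", {
  # uniform summed on 5..20 -> rounded avg P(1)=3/16 P(2)=5/16 P(3)=5/16 P(4)=3/16
  truth <- reference_rating_labels()$rounded_avg
  p_pred <- c(3, 5, 5, 3) / 16
  p_truth <- as.vector(table(factor(truth, levels = 1:4))) / length(truth)
  expected <- sum(p_pred * p_truth)
  n <- 63 * 40
  pred <- baseline_predict("random", n_trials = n, seed = 5)
  emp <- mean(pred$rounded_avg == rep_len(truth, n))
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(emp - expected), 3 * se)
})

test_that("LOSO folds never leak the held-out subject", {
  dat <- small_cohort_features()
  feats <- dat$features; ratings <- dat$cohort$ratings
  ev <- loso_evaluate(feats, ratings[, osats_domain_names()],
                      ratings$subject_id, subset = "T", seed = 1)
  expect_identical(ev$n_folds, length(unique(ratings$subject_id)))
  # perturb one held-out subject's labels: its fold's model cannot change,
  # so its predictions cannot change
  hold <- ratings$subject_id == "S01"
  r2 <- ratings
  r2[hold, osats_domain_names()] <- 5L
  ev2 <- loso_evaluate(feats, r2[, osats_domain_names()],
                       r2$subject_id, subset = "T", seed = 1)
  expect_identical(ev$predictions$summed[hold], ev2$predictions$summed[hold])
})

test_that("LOSO recovers skill on a small synthetic cohort", {
  dat <- small_cohort_features()
  feats <- dat$features; ratings <- dat$cohort$ratings
  ev <- loso_evaluate(feats, ratings[, osats_domain_names()],
                      ratings$subject_id, subset = "TMVG", seed = 1)
  expect_gt(unname(ev$metrics["r_summed"]), 0.5)
  expect_true(all(ev$metrics[c("acc_within2_summed", "acc_within4_summed",
                               "acc_exact_avg", "acc_within1_avg")] >= 0))
  expect_identical(sum(ev$confusion), as.integer(nrow(feats)))
})
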