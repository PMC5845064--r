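# Skill modelling: standardization, elastic-net feature selection,
# per-domain regression trees, LOSO evaluation, baselines and metrics.

#' Default modelling hyperparameters
#'
#' @param alpha_grid elastic-net mixing grid searched jointly with the
#'   penalty strength by inner 5-fold CV (lasso-like values that still
#'   tolerate correlated features).
#' @param nfolds inner CV folds for the penalty search.
#' @param minbucket minimum leaf size for the regression trees.
#' @param mode "per_domain" (five trees, one per OSATS domain, predictions
#'   summed) or "summed" (a single tree on the summed score).
#' @return list of hyperparameters.
#' @export
skill_config <- function(alpha_grid = c(0.5, 0.7, 0.9, 0.95, 1.0),
                         nfolds = 5, minbucket = 3,
                         mode = c("per_domain", "summed")) {
  list(alpha_grid = alpha_grid, nfolds = nfolds, minbucket = minbucket,
       mode = match.arg(mode))
}

# ---- standardization ----

fit_standardizer <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  keep <- sd > 0
  list(mean = mu[keep], sd = sd[keep], keep = names(mu)[keep],
       dropped = names(mu)[!keep])
}

apply_standardizer <- function(std, X) {
  X <- as.matrix(X[, std$keep, drop = FALSE])
  sweep(sweep(X, 2, std$mean), 2, std$sd, "/")
}

# ---- elastic-net feature selection ----

#' Select predictive features by elastic net
#'
#' Fits elastic-net paths over a small mixing grid, picks the
#' (alpha, lambda) pair minimizing inner-CV mean squared error, and returns
#' the features with nonzero coefficients. An all-zero solution returns an
#' empty set with a warning (callers fall back to a median model).
#'
#' @param X standardized numeric matrix (n trials x p features, named
#'   columns), n >= 10.
#' @param y numeric response (summed OSATS score).
#' @param config [skill_config()].
#' @param seed integer seed controlling the inner CV fold assignment.
#' @return character vector of selected feature names (possibly empty).
#' @export
select_features <- function(X, y, config = skill_config(), seed = 1L) {
  stopifnot(nrow(X) >= 10, nrow(X) == length(y))
  if (stats::sd(y) == 0) {
    warning("constant response: no features selected")
    return(character())
  }
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(config$nfolds), nrow(X)))
  best <- NULL
  for (alpha in config$alpha_grid) {
    # small cohorts trip cv.glmnet's per-fold grouping heuristic; harmless
    cv <- withCallingHandlers(
      glmnet::cv.glmnet(X, y, alpha = alpha, foldid = foldid,
                        standardize = FALSE),
      warning = function(w) {
        if (grepl("grouped=FALSE", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    i <- which.min(cv$cvm)
    if (is.null(best) || cv$cvm[i] < best$cvm) {
      best <- list(cvm = cv$cvm[i], fit = cv, lambda = cv$lambda[i],
                   alpha = alpha)
    }
  }
  beta <- as.matrix(stats::coef(best$fit, s = best$lambda))[-1, 1]
  sel <- names(beta)[beta != 0]
  if (length(sel) == 0)
    warning("elastic net selected no features; fall back to median model")
  sel
}

# ---- model fit ----

#' Fit a surgical skill model
#'
#' The classic pipeline: standardize the training features, select
#' predictors with the elastic net against the summed OSATS score, then grow
#' one cost-complexity-pruned regression tree per OSATS domain on the
#' selected features (default), or a single tree on the summed score. The
#' summed prediction is the sum of the per-domain tree outputs, rounded and
#' clipped to [5, 25]. If the elastic net selects nothing, the model
#' predicts the training median everywhere.
#'
#' @param x data.frame or matrix of MAF values (columns named as in
#'   [maf_manifest()]); a `trial_id` column is ignored.
#' @param ratings list of [osats_rating()] (or a data.frame with the five
#'   domain columns of [osats_domain_names()]), one per row of `x`.
#' @param subset sensor subset code ("T", "TG", "TM", "TMV", "TMG", "TMVG");
#'   only features of the corresponding categories are used.
#' @param config [skill_config()].
#' @param seed integer seed for the inner CV.
#' @return object of class `skill_model`.
#' @export
skill_model <- function(x, ratings, subset = "TMVG",
                        config = skill_config(), seed = 1L) {
  dom <- ratings_to_domains(ratings)
  summed <- rowSums(dom)
  if (length(unique(summed)) < 2)
    stop("degenerate labels: need at least 2 distinct summed scores")
  man <- maf_manifest()
  avail <- man$name[man$category %in% subset_categories(subset)]
  x <- as.data.frame(x)
  missing_feats <- setdiff(avail, names(x))
  if (length(missing_feats) > 0)
    stop("feature matrix lacks column(s): ",
         paste(utils::head(missing_feats, 3), collapse = ", "))
  X <- as.matrix(x[, avail, drop = FALSE])
  stopifnot(nrow(X) == nrow(dom))
  std <- fit_standardizer(X)
  Xs <- apply_standardizer(std, X)
  selected <- select_features(Xs, summed, config, seed)
  trees <- NULL
  if (length(selected) > 0) {
    df <- as.data.frame(Xs[, selected, drop = FALSE])
    names(df) <- selected
    ctrl <- rpart::rpart.control(minbucket = config$minbucket,
                                 minsplit = 2 * config$minbucket,
                                 cp = 0, xval = 10)
    grow <- function(yy) {
      d <- df; d$.y <- yy
      set.seed(seed)
      fit <- rpart::rpart(.y ~ ., data = d, method = "anova", control = ctrl)
      cp <- fit$cptable
      best <- cp[which.min(cp[, "xerror"]), "CP"]
      rpart::prune(fit, cp = best)
    }
    trees <- if (config$mode == "per_domain") {
      lapply(as.data.frame(dom), grow)
    } else {
      list(summed = grow(summed))
    }
  }
  structure(list(subset = subset, standardizer = std, selected = selected,
                 trees = trees, config = config, seed = seed,
                 train_median = stats::median(summed),
                 n_train = nrow(X)),
            class = "skill_model")
}

ratings_to_domains <- function(ratings) {
  if (is.data.frame(ratings)) {
    stopifnot(all(osats_domain_names() %in% names(ratings)))
    return(as.matrix(ratings[, osats_domain_names()]))
  }
  do.call(rbind, lapply(ratings, function(r) r$domains))
}

#' @export
print.skill_model <- function(x, ...) {
  cat(sprintf("<skill_model> subset %s, %d trials, %d features selected (%s mode)\n",
              x$subset, x$n_train, length(x$selected), x$config$mode))
  invisible(x)
}

#' @export
summary.skill_model <- function(object, ...) {
  man <- maf_manifest()
  cat_counts <- table(factor(
    man$category[match(object$selected, man$name)],
    levels = c("time", "tip_motion", "visibility", "grip")))
  out <- list(subset = object$subset, n_selected = length(object$selected),
              selected_by_category = cat_counts,
              dropped_zero_variance = object$standardizer$dropped)
  class(out) <- "summary.skill_model"
  out
}

#' @export
print.summary.skill_model <- function(x, ...) {
  cat(sprintf("Skill model, subset %s: %d features selected\n",
              x$subset, x$n_selected))
  print(x$selected_by_category)
  invisible(x)
}

#' Selected-feature coefficients of the elastic-net stage are not retained;
#' coef() reports the features each pruned tree actually splits on.
#' @param object a `skill_model`.
#' @param ... unused.
#' @return named list: selected features and, per tree, the split variables.
#' @export
coef.skill_model <- function(object, ...) {
  splits <- lapply(object$trees, function(tr)
    unique(as.character(tr$frame$var[tr$frame$var != "<leaf>"])))
  list(selected = object$selected, tree_splits = splits)
}

#' Predict OSATS scores for new trials
#'
#' @param object a `skill_model`.
#' @param newdata data.frame/matrix with at least the model's selected
#'   feature columns.
#' @param ... unused.
#' @return data.frame with `summed` (integer, clipped to [5, 25]) and
#'   `rounded_avg` (integer 1-5).
#' @export
predict.skill_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  if (is.null(object$trees)) {
    raw <- rep(object$train_median, nrow(newdata))
  } else {
    missing_feats <- setdiff(object$selected, names(newdata))
    if (length(missing_feats) > 0)
      stop("newdata lacks feature column(s): ",
           paste(missing_feats, collapse = ", "))
    std <- object$standardizer
    idx <- match(object$selected, std$keep)
    std <- list(mean = std$mean[idx], sd = std$sd[idx],
                keep = std$keep[idx])
    Xs <- apply_standardizer(std, newdata[, object$selected, drop = FALSE])
    df <- as.data.frame(Xs)
    names(df) <- object$selected
    preds <- vapply(object$trees, function(tr)
      unname(stats::predict(tr, df)), numeric(nrow(df)))
    if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
    raw <- rowSums(preds)
    if (object$config$mode == "summed") raw <- preds[, 1]
  }
  summed <- pmin(pmax(round(raw), 5L), 25L)
  data.frame(summed = as.integer(summed),
             rounded_avg = rounded_average(as.integer(summed)))
}

# ---- baselines ----

#' Baseline score predictors
#'
#' `random` guesses a summed score uniformly on 5..20 (the observed range of
#' summed scores); `median` always predicts the training-set median summed
#' score and median rounded average.
#'
#' @param kind "random" or "median".
#' @param train_summed training summed scores (required for `median`).
#' @param n_trials number of predictions.
#' @param seed integer seed (random baseline).
#' @return data.frame with `summed` and `rounded_avg`.
#' @export
baseline_predict <- function(kind = c("random", "median"),
                             train_summed = NULL, n_trials, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "random") {
    set.seed(seed)
    summed <- sample(5:20, n_trials, replace = TRUE)
    data.frame(summed = summed, rounded_avg = rounded_average(summed))
  } else {
    stopifnot(length(train_summed) > 0)
    med_sum <- as.integer(round(stats::median(train_summed)))
    med_avg <- as.integer(round(stats::median(rounded_average(train_summed))))
    data.frame(summed = rep(med_sum, n_trials),
               rounded_avg = rep(med_avg, n_trials))
  }
}

# ---- metrics ----

pearson_or_nan <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NaN)
  stats::cor(a, b)
}

#' Scoring metrics against ground-truth ratings
#'
#' Six metrics: on the summed scale, the proportion of trials predicted
#' within 2 and within 4 points plus the Pearson correlation; on the
#' rounded-average scale, exact and within-1 accuracy plus the Pearson
#' correlation. Correlation with a constant series is reported as NaN. Also
#' returns the 5 x 5 confusion matrix of rounded averages (rows = truth)
#' with its row-normalized form.
#'
#' @param pred data.frame with `summed`, `rounded_avg` (as from
#'   [predict.skill_model()]).
#' @param truth_summed integer vector of true summed scores.
#' @return list: `metrics` (named numeric), `confusion`,
#'   `confusion_rownorm`.
#' @export
skill_metrics <- function(pred, truth_summed) {
  stopifnot(nrow(pred) == length(truth_summed), length(truth_summed) >= 1)
  truth_avg <- rounded_average(truth_summed)
  ds <- abs(pred$summed - truth_summed)
  da <- abs(pred$rounded_avg - truth_avg)
  m <- c(acc_within2_summed = mean(ds <= 2),
         acc_within4_summed = mean(ds <= 4),
         r_summed = pearson_or_nan(pred$summed, truth_summed),
         acc_exact_avg = mean(da == 0),
         acc_within1_avg = mean(da <= 1),
         r_avg = pearson_or_nan(pred$rounded_avg, truth_avg))
  conf <- table(factor(truth_avg, levels = 1:5),
                factor(pred$rounded_avg, levels = 1:5))
  rn <- prop.table(conf, 1)
  rn[is.nan(rn)] <- 0
  list(metrics = m, confusion = unclass(conf), confusion_rownorm = unclass(rn))
}

# ---- LOSO evaluation ----

#' Leave-one-subject-out evaluation of a sensor subset
#'
#' One cross-validation fold per subject (folds ordered by sorted subject
#' id): the standardizer, elastic-net selection and trees are fit on the
#' remaining subjects only, then the held-out subject's trials are scored.
#' Pooled predictions are compared with the ratings via [skill_metrics()].
#'
#' @param x feature data.frame (one row per trial).
#' @param ratings list of [osats_rating()] or domain-score data.frame.
#' @param subject_id character/factor vector, one entry per trial.
#' @param subset sensor subset code.
#' @param config [skill_config()].
#' @param seed integer seed (inner CV fold shuffling; offset per fold).
#' @return object of class `skill_eval`: `predictions` (per trial),
#'   `metrics`, `confusion`, `selected_counts` (per-category mean number of
#'   selected features across folds), `n_folds`.
#' @export
loso_evaluate <- function(x, ratings, subject_id, subset = "TMVG",
                          config = skill_config(), seed = 1L) {
  x <- as.data.frame(x)
  dom <- ratings_to_domains(ratings)
  summed <- rowSums(dom)
  subject_id <- as.character(subject_id)
  stopifnot(nrow(x) == length(subject_id), nrow(dom) == nrow(x))
  subjects <- sort(unique(subject_id))
  if (length(subjects) < 2) stop("need at least 2 subjects for LOSO")
  pred <- data.frame(summed = rep(NA_integer_, nrow(x)),
                     rounded_avg = rep(NA_integer_, nrow(x)))
  man <- maf_manifest()
  sel_counts <- matrix(0, length(subjects), 4,
                       dimnames = list(subjects, c("time", "tip_motion",
                                                   "visibility", "grip")))
  for (i in seq_along(subjects)) {
    hold <- subject_id == subjects[i]
    fit <- skill_model(x[!hold, , drop = FALSE],
                       as.data.frame(dom[!hold, , drop = FALSE]),
                       subset = subset, config = config,
                       seed = seed + i)
    p <- predict(fit, x[hold, , drop = FALSE])
    pred[hold, ] <- p
    cats <- man$category[match(fit$selected, man$name)]
    sel_counts[i, ] <- table(factor(cats, levels = colnames(sel_counts)))
  }
  sm <- skill_metrics(pred, summed)
  structure(list(predictions = cbind(data.frame(subject_id = subject_id,
                                                truth_summed = summed), pred),
                 metrics = sm$metrics, confusion = sm$confusion,
                 confusion_rownorm = sm$confusion_rownorm,
                 selected_counts = colMeans(sel_counts),
                 n_folds = length(subjects), subset = subset),
            class = "skill_eval")
}

#' @export
print.skill_eval <- function(x, ...) {
  cat(sprintf("<skill_eval> subset %s, %d LOSO folds\n", x$subset, x$n_folds))
  print(round(x$metrics, 3))
  invisible(x)
}

#' @export
summary.skill_eval <- function(object, ...) {
  cat(sprintf("LOSO evaluation, subset %s (%d folds)\n\nMetrics:\n",
              object$subset, object$n_folds))
  print(round(object$metrics, 3))
  cat("\nMean selected features per fold, by category:\n")
  print(round(object$selected_counts, 1))
  cat("\nConfusion matrix (rows = rated, cols = predicted rounded average):\n")
  print(object$confusion)
  invisible(object)
}

#' Plot a LOSO evaluation: predicted vs rated summed scores
#'
#' @param x a `skill_eval`.
#' @param ... passed to [plot()].
#' @export
plot.skill_eval <- function(x, ...) {
  p <- x$predictions
  graphics::plot(jitter(p$truth_summed, 0.5), jitter(p$summed, 0.5),
                 xlab = "rated summed OSATS", ylab = "predicted summed OSATS",
                 xlim = c(5, 25), ylim = c(5, 25), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
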