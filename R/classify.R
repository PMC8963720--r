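# Linear-SVM group prediction with repeated random-subsample cross-validation,
# shuffled-label baselines, and cross-population prediction.

CCC_FEATURES <- c("alerting_rt", "orienting_rt", "conflict_rt", "overall_rt", "ccc_bps")

#' Assemble and standardize the classification feature matrix
#'
#' Joins the per-subject attention effects and capacity estimates for the
#' selected subjects, keeps the five features (alerting, orienting and
#' conflict RT effects, overall ANT-I RT, and CCC), drops subjects missing
#' either task (logged in the `"dropped"` attribute), and z-scores each
#' feature across the standardization population — by default the whole
#' classified sample, replicating the original analysis (fold-wise scaling is
#' available in [repeated_cv()] via `scale_in_folds`).
#'
#' @param effects Attention-effects table from [score_ant_cohort()].
#' @param capacity Capacity table from [estimate_ccc_cohort()].
#' @param subjects Subject table with `subject_id` and `group`; its rows
#'   define the classification population.
#' @param features Feature column names to keep.
#' @param standardize Z-score the columns (default `TRUE`).
#' @return Data.frame with `subject_id`, `group`, and one column per feature;
#'   attributes `"center"`, `"scale"` (standardization metadata) and
#'   `"dropped"` (subject ids excluded).
#' @export
build_features <- function(effects, capacity, subjects,
                           features = CCC_FEATURES, standardize = TRUE) {
  m <- merge(
    subjects[, c("subject_id", "group")],
    merge(effects, capacity, by = "subject_id", all = FALSE),
    by = "subject_id", all.x = TRUE
  )
  have <- setdiff(features, names(m))
  if (length(have) > 0) {
    stop("missing feature columns: ", paste(have, collapse = ", "), call. = FALSE)
  }
  complete <- stats::complete.cases(m[, features, drop = FALSE])
  dropped <- m$subject_id[!complete]
  m <- m[complete, c("subject_id", "group", features), drop = FALSE]
  ctr <- scl <- stats::setNames(numeric(length(features)), features)
  if (standardize) {
    for (f in features) {
      ctr[f] <- mean(m[[f]])
      scl[f] <- stats::sd(m[[f]])
      if (scl[f] == 0) {
        stop("zero-variance feature cannot be standardized: ", f, call. = FALSE)
      }
      m[[f]] <- (m[[f]] - ctr[f]) / scl[f]
    }
  }
  rownames(m) <- NULL
  attr(m, "center") <- ctr
  attr(m, "scale") <- scl
  attr(m, "dropped") <- dropped
  m
}

#' Chance-level classification accuracy
#'
#' Prevalence of the positive (first-named, more-affected) class:
#' `n_pos / (n_pos + n_neg)`.
#'
#' @param n_pos,n_neg Class sizes.
#' @return Proportion in (0, 1).
#' @export
chance_level <- function(n_pos, n_neg) {
  if (n_pos <= 0 || n_neg <= 0) stop("class sizes must be positive", call. = FALSE)
  n_pos / (n_pos + n_neg)
}

fit_linear_svm <- function(x, y) {
  e1071::svm(x, y, kernel = "linear", cost = 1, scale = FALSE, type = "C-classification")
}

new_classification_result <- function(accuracy, baseline, chance, config) {
  mu <- mean(baseline)
  if (stats::sd(accuracy) == 0) {
    # a degenerate (constant) accuracy distribution: the one-sample t test
    # is improper; report the limiting p value instead
    tval <- if (mean(accuracy) == mu) 0 else sign(mean(accuracy) - mu) * Inf
    df <- length(accuracy) - 1L
    pval <- if (mean(accuracy) > mu) 0 else 1
  } else {
    tt <- stats::t.test(accuracy, mu = mu, alternative = "greater")
    tval <- unname(tt$statistic)
    df <- unname(tt$parameter)
    pval <- unname(tt$p.value)
  }
  structure(list(
    accuracy = accuracy,
    baseline = baseline,
    mean_accuracy = mean(accuracy),
    sd_accuracy = stats::sd(accuracy),
    mean_baseline = mu,
    chance_level = chance,
    t = tval,
    df = df,
    p = pval,
    config = config
  ), class = "ccc_classification")
}

#' Print a classification result
#'
#' @param x A `ccc_classification` object.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
print.ccc_classification <- function(x, ...) {
  cat(sprintf(
    "Linear SVM classification (%d repeats, %s)\n  accuracy %.1f%% +- %.1f%%; shuffled-label baseline %.1f%%; chance %.1f%%\n  one-sided t(%d) = %.2f vs baseline, p = %.3g\n",
    length(x$accuracy), x$config$mode, 100 * x$mean_accuracy,
    100 * x$sd_accuracy, 100 * x$mean_baseline, 100 * x$chance_level,
    x$df, x$t, x$p
  ))
  invisible(x)
}

#' Repeated cross-validated SVM classification
#'
#' Default mode follows the original procedure literally: in each of
#' `n_repeats` repeats a random 1/10 of the sample (`ceiling(N *
#' test_fraction)` subjects) is held out, a linear soft-margin SVM (unit box
#' constraint) is trained on the remainder, and test accuracy is recorded;
#' the per-repeat baseline is the accuracy obtained after randomly shuffling
#' the held-out labels. `mode = "kfold"` instead runs a classical 10-fold
#' partition per repeat and records the mean fold accuracy. A repeat whose
#' test set (or training set) is single-class is resampled (counted in
#' `config$n_resampled`). Significance is a one-sided one-sample t test of
#' the accuracy distribution against the mean baseline accuracy.
#'
#' @param features Feature data.frame from [build_features()] (or any
#'   data.frame with `group` plus numeric feature columns).
#' @param labels Optional label vector overriding `features$group`; the first
#'   factor level is the positive (more-affected) class.
#' @param n_repeats Number of repeats (study default 1000).
#' @param test_fraction Held-out fraction per repeat (default 1/10).
#' @param seed Integer seed; fixed seeds give identical accuracy vectors.
#' @param mode `"subsample"` (default) or `"kfold"`.
#' @param scale_in_folds Re-standardize features inside each training set and
#'   apply to the test set (avoids the whole-sample scaling leakage; default
#'   `FALSE` to replicate the original analysis).
#' @return A `ccc_classification` object: per-repeat `accuracy` and
#'   `baseline` vectors, `mean_accuracy`, `sd_accuracy`, `mean_baseline`,
#'   `chance_level`, the t test (`t`, `df`, `p`) and the `config` used.
#' @export
repeated_cv <- function(features, labels = NULL, n_repeats = 1000,
                        test_fraction = 0.1, seed = 1L,
                        mode = c("subsample", "kfold"),
                        scale_in_folds = FALSE) {
  mode <- match.arg(mode)
  x <- as.matrix(features[, setdiff(names(features), c("subject_id", "group")), drop = FALSE])
  y <- factor(if (is.null(labels)) features$group else labels)
  if (nlevels(y) != 2) stop("binary classification requires 2 classes", call. = FALSE)
  if (min(table(y)) < 2) stop("need at least 2 subjects per class", call. = FALSE)
  n <- nrow(x)
  n_test <- max(1L, ceiling(n * test_fraction))
  chance <- mean(y == levels(y)[1])

  eval_split <- function(train_idx, test_idx) {
    xtr <- x[train_idx, , drop = FALSE]
    xte <- x[test_idx, , drop = FALSE]
    if (scale_in_folds) {
      mu <- colMeans(xtr)
      sg <- apply(xtr, 2, stats::sd)
      sg[sg == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sg, "/")
      xte <- sweep(sweep(xte, 2, mu), 2, sg, "/")
    }
    fit <- fit_linear_svm(xtr, y[train_idx])
    pred <- stats::predict(fit, xte)
    yte <- y[test_idx]
    c(
      acc = mean(pred == yte),
      base = mean(pred == sample(yte))
    )
  }

  n_resampled <- 0L
  res <- with_seed(seed, {
    vapply(seq_len(n_repeats), function(i) {
      if (mode == "subsample") {
        repeat {
          test_idx <- sample.int(n, n_test)
          train_idx <- setdiff(seq_len(n), test_idx)
          if (nlevels(droplevels(y[test_idx])) == 2 &&
            nlevels(droplevels(y[train_idx])) == 2) {
            break
          }
          n_resampled <<- n_resampled + 1L
        }
        eval_split(train_idx, test_idx)
      } else {
        folds <- sample(rep(seq_len(10), length.out = n))
        ok <- vapply(seq_len(10), function(f) {
          nlevels(droplevels(y[folds != f])) == 2
        }, logical(1))
        fold_res <- vapply(which(ok), function(f) {
          eval_split(which(folds != f), which(folds == f))
        }, numeric(2))
        rowMeans(fold_res)
      }
    }, numeric(2))
  })

  new_classification_result(
    accuracy = unname(res["acc", ]),
    baseline = unname(res["base", ]),
    chance = chance,
    config = list(
      kernel = "linear", cost = 1, mode = mode, n_repeats = n_repeats,
      test_fraction = test_fraction, seed = seed,
      scale_in_folds = scale_in_folds, n_resampled = n_resampled,
      positive_class = levels(y)[1]
    )
  )
}

#' Cross-population SVM prediction
#'
#' Trains the linear SVM on the full training population (e.g. ADHD + TD) and
#' evaluates it, per repeat, on a fresh random 1/10 draw from the other
#' population (e.g. subthreshold ADHD + TD). The two populations are expected
#' to be standardized separately (as [build_features()] does when called per
#' population). Shared class labels are required (both populations are
#' relabelled clinical/TD internally via `positive_levels`).
#'
#' @param features_train,features_test Feature data.frames from
#'   [build_features()] for the training and testing populations.
#' @param positive_levels Group labels counted as the positive (clinical)
#'   class in each population, in order (train, test).
#' @param n_repeats,test_fraction,seed As in [repeated_cv()].
#' @return A `ccc_classification` object; `chance_level` refers to the
#'   testing population.
#' @export
cross_classify <- function(features_train, features_test,
                           positive_levels = c("ADHD", "subthreshold"),
                           n_repeats = 1000, test_fraction = 0.1, seed = 1L) {
  feats <- setdiff(names(features_train), c("subject_id", "group"))
  if (!identical(feats, setdiff(names(features_test), c("subject_id", "group")))) {
    stop("training and testing populations must share feature columns", call. = FALSE)
  }
  xtr <- as.matrix(features_train[, feats, drop = FALSE])
  xte <- as.matrix(features_test[, feats, drop = FALSE])
  ytr <- factor(ifelse(features_train$group == positive_levels[1], "clinical", "TD"),
    levels = c("clinical", "TD")
  )
  yte <- factor(ifelse(features_test$group == positive_levels[2], "clinical", "TD"),
    levels = c("clinical", "TD")
  )
  if (nlevels(droplevels(ytr)) != 2) stop("training population must contain both classes", call. = FALSE)
  n <- nrow(xte)
  n_test <- max(1L, ceiling(n * test_fraction))
  fit <- fit_linear_svm(xtr, ytr)
  n_resampled <- 0L
  res <- with_seed(seed, {
    vapply(seq_len(n_repeats), function(i) {
      repeat {
        idx <- sample.int(n, n_test)
        if (nlevels(droplevels(yte[idx])) == 2) break
        n_resampled <<- n_resampled + 1L
      }
      pred <- stats::predict(fit, xte[idx, , drop = FALSE])
      c(acc = mean(pred == yte[idx]), base = mean(pred == sample(yte[idx])))
    }, numeric(2))
  })
  new_classification_result(
    accuracy = unname(res["acc", ]),
    baseline = unname(res["base", ]),
    chance = mean(yte == "clinical"),
    config = list(
      kernel = "linear", cost = 1, mode = "cross", n_repeats = n_repeats,
      test_fraction = test_fraction, seed = seed, n_resampled = n_resampled,
      positive_class = positive_levels[2]
    )
  )
}

#' Compare the accuracy of two feature sets
#'
#' Two-sample t test on the per-repeat accuracy vectors of two
#' classifications of the same target.
#'
#' @param result_a,result_b `ccc_classification` objects with equal-length
#'   accuracy vectors.
#' @return List: `t`, `df`, `p`, `mean_diff` (a minus b).
#' @export
compare_feature_sets <- function(result_a, result_b) {
  a <- result_a$accuracy
  b <- result_b$accuracy
  if (length(a) != length(b)) {
    stop("accuracy vectors must have equal length", call. = FALSE)
  }
  tt <- stats::t.test(a, b)
  list(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = unname(tt$p.value), mean_diff = mean(a) - mean(b)
  )
}
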