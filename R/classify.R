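# Task and condition classification on tangent-space features.
#
# Tasks: one tangent model + one multinomial logistic model over all trials,
# regardless of condition.  Conditions: the same pipeline fitted per task,
# ensembled by summing the six members' probability vectors over a session
# (one subject x one condition); the predicted condition is the argmax of
# the sum, ties broken toward the lowest condition index.

# Ridge-penalised multinomial logistic fit.  `regularization` follows the
# inverse-strength convention (larger = weaker penalty); the glmnet lambda
# is 1 / (n * regularization).
fit_multinomial <- function(x, y, regularization = 1) {
  if (regularization <= 0) {
    abort("regularization must be positive", class = "riemsway_input_error")
  }
  y <- factor(y)
  if (nlevels(y) < 2) {
    abort("Need at least two distinct class labels to train",
          class = "riemsway_training_error")
  }
  lam <- 1 / (nrow(x) * regularization)
  # glmnet warns whenever a class has < 8 observations; per-task members
  # legitimately run at that size, so muffle that advisory alone
  fit <- withCallingHandlers(
    glmnet::glmnet(x, y, family = "multinomial", alpha = 0,
                   lambda = lam, standardize = FALSE),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  list(fit = fit, classes = levels(y), lambda = lam)
}

predict_multinomial <- function(model, x) {
  p <- predict(model$fit, x, type = "response")[, , 1, drop = FALSE]
  p <- matrix(p, nrow = nrow(x), dimnames = list(NULL, model$classes))
  p / rowSums(p)
}

#' Fit the task classifier
#'
#' Single pipeline over all trials regardless of condition: tangent-space
#' features (see [fit_tangent_model()]) followed by a ridge-penalised
#' multinomial logistic model over the task labels.
#'
#' @param trials A trial table with at least two distinct task labels.
#' @param subset,shrinkage Passed to [fit_tangent_model()].
#' @param regularization Inverse penalty strength of the logistic model
#'   (default 1).
#' @return An object of class `sway_task_clf`.
#' @export
fit_task_classifier <- function(trials, subset = NULL, shrinkage = 1e-6,
                                regularization = 1) {
  tm <- fit_tangent_model(trials, subset = subset, shrinkage = shrinkage)
  lr <- fit_multinomial(tm$features, trials$task, regularization)
  structure(list(tangent = tm, logistic = lr, target = "task",
                 regularization = regularization),
            class = "sway_task_clf")
}

#' Predict task labels or probabilities
#'
#' @param object A `sway_task_clf`.
#' @param trials A trial table.
#' @param type `"class"` for labels, `"prob"` for the probability matrix.
#' @param ... Unused.
#' @export
predict.sway_task_clf <- function(object, trials, type = c("class", "prob"),
                                  ...) {
  type <- match.arg(type)
  p <- predict_multinomial(object$logistic, predict(object$tangent, trials))
  if (type == "prob") return(p)
  as.integer(object$logistic$classes[max.col(p, ties.method = "first")])
}

#' @export
print.sway_task_clf <- function(x, ...) {
  cat(sprintf("Task classifier over classes {%s}; %d training trials\n",
              paste(x$logistic$classes, collapse = ","),
              nrow(x$tangent$features)))
  invisible(x)
}

#' Glance at a task classifier
#' @param x A `sway_task_clf`.
#' @param ... Unused.
#' @return One-row tibble of model dimensions and settings.
#' @export
glance.sway_task_clf <- function(x, ...) {
  tibble::tibble(n_trials = nrow(x$tangent$features),
                 n_features = ncol(x$tangent$features),
                 n_classes = length(x$logistic$classes),
                 shrinkage = x$tangent$shrinkage,
                 regularization = x$regularization)
}

#' Fit the per-task condition ensemble
#'
#' Conditions are nested within task clusters, so no single model separates
#' them well.  One feature-plus-logistic pipeline is fitted per task, on
#' that task's trials only; predictions for a session are combined by
#' probability summation (see [predict_condition()]).
#'
#' @inheritParams fit_task_classifier
#' @param expected_tasks Tasks expected in the protocol (default 1:6); a
#'   missing task yields a warning and a smaller ensemble.
#' @return An object of class `sway_condition_ensemble` whose `members`
#'   element maps task id to a fitted pipeline.
#' @export
fit_condition_ensemble <- function(trials, subset = NULL, shrinkage = 1e-6,
                                   regularization = 1,
                                   expected_tasks = 1:6) {
  present <- sort(unique(trials$task))
  absent <- setdiff(expected_tasks, present)
  if (length(absent) > 0) {
    warn(paste0("No trials for task(s) ", paste(absent, collapse = ","),
                "; ensemble will have ", length(present), " members"))
  }
  members <- purrr::map(present, function(k) {
    tk <- trials[trials$task == k, ]
    if (length(unique(tk$condition)) < 2) {
      abort(sprintf("task %d has a single condition label; cannot train", k),
            class = "riemsway_training_error")
    }
    tm <- fit_tangent_model(tk, subset = subset, shrinkage = shrinkage)
    lr <- fit_multinomial(tm$features, tk$condition, regularization)
    list(tangent = tm, logistic = lr, n_train = nrow(tk))
  })
  names(members) <- as.character(present)
  structure(list(members = members, subset = subset, shrinkage = shrinkage,
                 regularization = regularization),
            class = "sway_condition_ensemble")
}

#' @export
print.sway_condition_ensemble <- function(x, ...) {
  cat(sprintf("Condition ensemble with %d per-task members (tasks %s)\n",
              length(x$members), paste(names(x$members), collapse = ",")))
  invisible(x)
}

#' Predict the postural condition of sessions
#'
#' A session is the set of task trials one subject performed under one
#' condition.  Each trial is routed to its own task's member, the members'
#' condition-probability vectors are summed across the session, and the
#' condition with the highest sum wins; ties go to the lowest condition
#' index and are flagged.  With `per_trial = TRUE` every trial is instead
#' predicted alone by its member (no summation), for comparison.
#'
#' @param ensemble A `sway_condition_ensemble`.
#' @param trials A trial table; rows are grouped into sessions by
#'   `(subject, condition)`.  The condition column is used only as the
#'   grouping key and ground truth, never as a predictor.
#' @param per_trial If `TRUE`, predict each trial separately.
#' @return A tibble with one row per session (or trial): identifiers,
#'   `truth`, `predicted`, `tie` flag, and the (summed) probability for
#'   each condition in columns `p1`, `p2`, ...
#' @export
predict_condition <- function(ensemble, trials, per_trial = FALSE) {
  unknown <- setdiff(unique(trials$task), as.integer(names(ensemble$members)))
  if (length(unknown) > 0) {
    abort(paste0("No trained member for task(s) ",
                 paste(unknown, collapse = ",")),
          class = "riemsway_prediction_error")
  }
  classes <- ensemble$members[[1]]$logistic$classes
  probs <- matrix(NA_real_, nrow(trials), length(classes),
                  dimnames = list(NULL, classes))
  for (k in names(ensemble$members)) {
    idx <- which(trials$task == as.integer(k))
    if (length(idx) == 0) next
    m <- ensemble$members[[k]]
    probs[idx, m$logistic$classes] <-
      predict_multinomial(m$logistic, predict(m$tangent, trials[idx, ]))
  }
  df <- dplyr::bind_cols(
    trials[, c("subject", "task", "condition")],
    tibble::as_tibble(probs, .name_repair = ~ paste0("p", classes)))
  if (!per_trial) {
    df <- df |>
      dplyr::group_by(.data$subject, .data$condition) |>
      dplyr::summarise(dplyr::across(dplyr::starts_with("p"), sum),
                       n_trials = dplyr::n(), .groups = "drop")
  }
  pm <- as.matrix(df[, paste0("p", classes)])
  best <- apply(pm, 1, function(v) which(v >= max(v) - 1e-12))
  tie <- purrr::map_lgl(best, ~ length(.x) > 1)
  pred <- as.integer(classes[purrr::map_int(best, min)])
  if (any(tie)) {
    warn(sprintf("%d tie(s) broken toward the lowest condition index",
                 sum(tie)))
  }
  df |>
    dplyr::rename(truth = "condition") |>
    dplyr::mutate(predicted = pred, tie = tie, .after = "truth")
}

# ---- leave-one-subject-out evaluation ----

confusion_percent <- function(truth, predicted, classes) {
  tab <- table(factor(truth, classes), factor(predicted, classes))
  pct <- 100 * prop.table(tab, 1)
  pct[is.nan(pct)] <- 0
  m <- as.matrix(unclass(pct))
  dimnames(m) <- list(truth = classes, predicted = classes)
  m
}

#' Leave-one-subject-out evaluation
#'
#' Each subject is held out in turn; all models — including the tangent
#' reference points — are refitted on the remaining subjects only, and the
#' held-out subject's trials (task target) or sessions (condition target)
#' are predicted.  Trial covariances are computed once up front (they
#' depend only on the trial itself), but nothing fitted ever sees held-out
#' labels.
#'
#' @param trials A trial table with at least two subjects.
#' @param target `"task"` or `"condition"`.
#' @param subset,shrinkage,regularization Passed to the underlying fits.
#' @param per_trial For the condition target, predict per trial instead of
#'   per session.
#' @return An object of class `sway_cv`: per-fold predictions, row-percent
#'   confusion matrix, and overall accuracy in percent.
#' @export
loso_evaluate <- function(trials, target = c("task", "condition"),
                          subset = NULL, shrinkage = 1e-6,
                          regularization = 1, per_trial = FALSE) {
  target <- match.arg(target)
  subjects <- sort(unique(trials$subject))
  if (length(subjects) < 2) {
    abort("LOSO needs at least two subjects", class = "riemsway_input_error")
  }
  if (!is.null(subset)) {
    trials <- select_channels(trials, subset)
    subset <- NULL
  }
  preds <- purrr::map(subjects, function(s) {
    train <- trials[trials$subject != s, ]
    test <- trials[trials$subject == s, ]
    if (target == "task") {
      clf <- fit_task_classifier(train, shrinkage = shrinkage,
                                 regularization = regularization)
      p <- predict(clf, test, type = "prob")
      out <- dplyr::bind_cols(
        test[, c("subject", "task", "condition")],
        tibble::as_tibble(p, .name_repair = ~ paste0("p", colnames(p))))
      out |>
        dplyr::rename(truth = "task") |>
        dplyr::mutate(predicted = as.integer(
          colnames(p)[max.col(p, ties.method = "first")]), .after = "truth")
    } else {
      ens <- fit_condition_ensemble(
        train, shrinkage = shrinkage, regularization = regularization,
        expected_tasks = sort(unique(trials$task)))
      predict_condition(ens, test, per_trial = per_trial)
    }
  })
  preds <- dplyr::bind_rows(preds)
  classes <- sort(unique(c(preds$truth, preds$predicted)))
  cm <- confusion_percent(preds$truth, preds$predicted, classes)
  structure(
    list(target = target, predictions = preds,
         confusion = cm,
         accuracy = 100 * mean(preds$truth == preds$predicted),
         n_folds = length(subjects)),
    class = "sway_cv")
}

#' @export
print.sway_cv <- function(x, ...) {
  cat(sprintf("Leave-one-subject-out %s classification: %.1f%% accuracy over %d folds\n",
              x$target, x$accuracy, x$n_folds))
  cat("Confusion (row %):\n")
  print(round(x$confusion, 1))
  invisible(x)
}

#' Tidy per-fold predictions
#' @param x A `sway_cv` report.
#' @param ... Unused.
#' @return Tibble of per-unit predictions with probability columns.
#' @export
tidy.sway_cv <- function(x, ...) x$predictions

#' One-row summary of a cross-validation report
#' @param x A `sway_cv` report.
#' @param ... Unused.
#' @export
glance.sway_cv <- function(x, ...) {
  tibble::tibble(target = x$target, accuracy = x$accuracy,
                 n_folds = x$n_folds, n_units = nrow(x$predictions))
}

#' Write a cross-validation report to disk
#'
#' Emits `<stem>.json` (accuracy, per-unit predictions) and `<stem>_confusion.csv`
#' (row-percent confusion matrix).
#'
#' @param x A `sway_cv` report.
#' @param stem Output path stem.
#' @return `stem`, invisibly.
#' @export
write_cv_report <- function(x, stem) {
  jsonlite::write_json(
    list(target = x$target, accuracy = x$accuracy, n_folds = x$n_folds,
         predictions = x$predictions),
    paste0(stem, ".json"), digits = NA, auto_unbox = TRUE)
  cm <- tibble::as_tibble(x$confusion, rownames = "truth")
  readr::write_csv(cm, paste0(stem, "_confusion.csv"), progress = FALSE)
  invisible(stem)
}

#' Learning curve for condition classification
#'
#' For each training-set size, draws `repeats` random subject subsets,
#' trains the condition ensemble on them, and evaluates session-level
#' accuracy on all remaining subjects.
#'
#' @param trials A trial table.
#' @param train_sizes Integer vector of subject counts, each between 1 and
#'   `n_subjects - 1`.
#' @param repeats Random draws per size (default 10).
#' @param seed RNG seed for the subject draws.
#' @param subset,shrinkage,regularization Passed to the fits.
#' @return A tibble of class `sway_learning_curve` with columns
#'   `train_size`, `mean_accuracy`, `sd_accuracy`, `repeats`.
#' @export
learning_curve <- function(trials, train_sizes, repeats = 10, seed = 1,
                           subset = NULL, shrinkage = 1e-6,
                           regularization = 1) {
  subjects <- sort(unique(trials$subject))
  if (any(train_sizes < 1 | train_sizes > length(subjects) - 1)) {
    abort(sprintf("train_sizes must lie in [1, %d]", length(subjects) - 1),
          class = "riemsway_input_error")
  }
  if (!is.null(subset)) {
    trials <- select_channels(trials, subset)
    subset <- NULL
  }
  set.seed(seed)
  rows <- purrr::map(sort(train_sizes), function(m) {
    acc <- purrr::map_dbl(seq_len(repeats), function(r) {
      tr_sub <- sample(subjects, m)
      train <- trials[trials$subject %in% tr_sub, ]
      test <- trials[!trials$subject %in% tr_sub, ]
      ens <- fit_condition_ensemble(
        train, shrinkage = shrinkage, regularization = regularization,
        expected_tasks = sort(unique(trials$task)))
      pr <- predict_condition(ens, test)
      100 * mean(pr$truth == pr$predicted)
    })
    tibble::tibble(train_size = m, mean_accuracy = mean(acc),
                   sd_accuracy = if (repeats > 1) sd(acc) else 0,
                   repeats = repeats)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sway_learning_curve", class(out))
  out
}
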