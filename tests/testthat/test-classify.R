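test_that("the task classifier separates well-separated templates", {
  d <- small_mk2()
  clf <- fit_task_classifier(d)
  expect_equal(predict(clf, d), d$task)      # training-set accuracy 100%
  p <- predict(clf, d, type = "prob")
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, nrow(d)), tolerance = 1e-9)
  # single-class input cannot be trained
  expect_error(fit_task_classifier(d[d$task == 1, ]),
               class = "riemsway_training_error")
  # refit on identical data gives identical weights
  clf2 <- fit_task_classifier(d)
  w1 <- purrr::map(coef(clf$logistic$fit), as.matrix)
  w2 <- purrr::map(coef(clf2$logistic$fit), as.matrix)
  expect_equal(w1, w2, tolerance = 1e-10)
})

test_that("the condition ensemble has one member per task, trained disjointly", {
  d <- small_mk2()
  ens <- fit_condition_ensemble(d, expected_tasks = 1:3)
  expect_length(ens$members, 3)
  for (k in 1:3) {
    expect_equal(ens$members[[as.character(k)]]$n_train, sum(d$task == k))
    expect_setequal(ens$members[[as.character(k)]]$tangent$meta$task, k)
  }
  expect_warning(ens2 <- fit_condition_ensemble(d[d$task != 3, ],
                                                expected_tasks = 1:3),
                 "task")
  expect_length(ens2$members, 2)
  # a present task with one condition label is a training error naming it
  d1 <- d[d$task != 1 | d$condition == 2, ]
  expect_error(fit_condition_ensemble(d1, expected_tasks = 1:3), "task 1",
               class = "riemsway_training_error")
})

test_that("condition prediction sums member probabilities over a session", {
  d <- small_mk2()
  ens <- fit_condition_ensemble(d, expected_tasks = 1:3)
  per_trial <- predict_condition(ens, d, per_trial = TRUE)
  sessions <- predict_condition(ens, d)
  pcols <- c("p1", "p2", "p3")
  # per-trial rows are probability vectors; session rows are their sums
  expect_equal(rowSums(as.matrix(per_trial[, pcols])),
               rep(1, nrow(per_trial)), tolerance = 1e-9)
  manual <- per_trial |>
    dplyr::group_by(subject, truth) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(pcols), sum),
                     .groups = "drop")
  joined <- dplyr::inner_join(sessions, manual, by = c("subject", "truth"),
                              suffix = c("", ".man"))
  expect_equal(nrow(joined), nrow(sessions))
  for (p in pcols) expect_equal(joined[[p]], joined[[paste0(p, ".man")]])
  # the label is the argmax of the sum, ties toward the lowest condition
  pm <- as.matrix(sessions[, pcols])
  expect_equal(sessions$predicted,
               apply(pm, 1, function(v) which(v >= max(v) - 1e-12)[1]))
  # a single-trial session reduces to that member's argmax
  one <- predict_condition(ens, d[1, ])
  expect_equal(one$predicted,
               as.integer(which.max(as.matrix(per_trial[1, pcols]))))
  # unknown task is a prediction error
  d_bad <- d[1, ]; d_bad$task <- 9L
  expect_error(predict_condition(ens, d_bad),
               class = "riemsway_prediction_error")
})

test_that("LOSO holds every subject out once and normalizes its confusion", {
  d <- small_mk2()
  cv <- loso_evaluate(d, "condition")
  expect_equal(cv$n_folds, 4)
  expect_setequal(unique(cv$predictions$subject), unique(d$subject))
  expect_equal(unname(rowSums(cv$confusion)), rep(100, 3), tolerance = 0.1)
  g <- glance(cv)
  expect_equal(g$n_units, 4 * 3)            # sessions: subjects x conditions
  cvt <- loso_evaluate(d, "task")
  expect_equal(nrow(tidy(cvt)), nrow(d))    # task target predicts per trial
  expect_equal(unname(rowSums(cvt$confusion)), rep(100, 3), tolerance = 0.1)
  expect_error(loso_evaluate(d[d$subject == "S01", ], "task"),
               class = "riemsway_input_error")
})

test_that("held-out labels never influence the fitted fold models", {
  d <- small_mk2()
  # permute one subject's condition labels; all fold fits must be unchanged,
  # so the held-out probability vectors are identical and only truth moves
  d2 <- d
  idx <- which(d2$subject == "S01")
  perm <- c(2L, 3L, 1L)
  d2$condition[idx] <- perm[d2$condition[idx]]
  # avoid key collisions during validation by construction: permutation is
  # a bijection, keys stay unique
  cv1 <- loso_evaluate(d, "condition", per_trial = TRUE)
  cv2 <- loso_evaluate(d2, "condition", per_trial = TRUE)
  # trial order is preserved fold by fold, so rows align positionally
  p1 <- tidy(cv1) |> dplyr::filter(subject == "S01")
  p2 <- tidy(cv2) |> dplyr::filter(subject == "S01")
  expect_equal(p1[, c("p1", "p2", "p3")], p2[, c("p1", "p2", "p3")],
               tolerance = 1e-12)
})

test_that("a common rotation-plus-scale channel transform leaves LOSO intact", {
  # the affine-invariance rationale: one invertible map applied to every
  # trial must not change accuracy (orthogonal x scale keeps the tangent
  # feature geometry exactly)
  d <- small_mk2() |> select_channels("spine4")
  set.seed(31)
  v <- 1.7 * rand_orth(12)
  d2 <- d
  d2$samples <- purrr::map(d$samples, function(x) {
    y <- v %*% x; rownames(y) <- rownames(x); y
  })
  cv1 <- loso_evaluate(d, "condition")
  cv2 <- loso_evaluate(d2, "condition")
  expect_equal(cv1$accuracy, cv2$accuracy)
  expect_equal(cv1$predictions$predicted, cv2$predictions$predicted)
})

test_that("the learning curve has the requested shape and is reproducible", {
  d <- small_mk2()
  lc <- learning_curve(d, train_sizes = c(2, 3), repeats = 2, seed = 5)
  expect_equal(lc$train_size, c(2, 3))
  expect_true(all(lc$sd_accuracy >= 0))
  lc2 <- learning_curve(d, train_sizes = c(2, 3), repeats = 2, seed = 5)
  expect_identical(lc, lc2)
  expect_error(learning_curve(d, train_sizes = c(0, 2)),
               class = "riemsway_input_error")
  expect_error(learning_curve(d, train_sizes = 4),
               class = "riemsway_input_error")
})
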