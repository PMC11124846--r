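# Label grouping, stratified splitting, classification, and metrics.

test_that("grouping schemes map the ethogram as documented", {
  ep <- tibble::tibble(animal_id = "a", epoch_utc = 1:5,
                       behavior = behavior_levels(), source = "in_pasture")
  act <- group_labels(ep, "activity")
  expect_equal(act$behavior, c("active", "active", "inactive", "inactive", "inactive"))
  gb <- group_labels(ep, "grazing_binary")
  expect_equal(gb$behavior[gb$epoch_utc == 5], "non_grazing")  # grooming
  expect_equal(sum(gb$behavior == "grazing"), 1L)
  expect_identical(group_labels(ep, "full")$behavior, ep$behavior)
  expect_equal(nrow(group_labels(ep, "full4")), 4L)  # grooming dropped
  expect_error(group_labels(ep, c(grazing = "g")), "missing from the grouping")
})

test_that("stratified splits honor the 70/30 ratio per stratum", {
  tab <- tibble::tibble(animal_id = "a", epoch_utc = 1:100,
                        behavior = "grazing", source = "in_pasture", f = 1)
  sp <- split_train_test(tab, seed = 1)
  expect_equal(nrow(sp$train), 70L)
  expect_equal(nrow(sp$test), 30L)

  two <- tibble::tibble(animal_id = rep(c("a", "b"), each = 50),
                        epoch_utc = 1:100, behavior = "grazing",
                        source = "in_pasture", f = 1)
  sp2 <- split_train_test(two, seed = 3)
  per <- table(sp2$train$animal_id)
  expect_true(all(abs(per - 35) <= 1))
})

test_that("splits are deterministic, disjoint, and exhaustive for any seed", {
  tab <- small_feature_table()
  for (s in c(1, 17, 2024)) {
    a <- split_train_test(tab, seed = s)
    b <- split_train_test(tab, seed = s)
    expect_identical(a, b)
    key_a <- paste(a$train$animal_id, a$train$epoch_utc)
    key_b <- paste(a$test$animal_id, a$test$epoch_utc)
    expect_length(intersect(key_a, key_b), 0L)
    expect_equal(nrow(a$train) + nrow(a$test), nrow(tab))
  }
  expect_error(split_train_test(tab[0, ]), "empty")
})

test_that("tiny strata fall back to a pooled split with a warning", {
  tab <- tibble::tibble(animal_id = c(rep("a", 40), "b"), epoch_utc = 1:41,
                        behavior = "grazing", source = "in_pasture", f = 1)
  expect_warning(sp <- split_train_test(tab, seed = 1), "pooled")
  expect_equal(nrow(sp$train) + nrow(sp$test), 41L)
})

test_that("the classifier separates separable classes and is deterministic", {
  tab <- tibble::tibble(animal_id = "a", epoch_utc = 1:40,
                        behavior = rep(c("grazing", "resting"), each = 20),
                        source = "in_pasture",
                        f1 = rep(c(0, 1), each = 20), f2 = rep(c(1, 0), each = 20))
  m <- train_classifier(tab, num_trees = 50, seed = 1)
  rep_ <- evaluate_classifier(m, tab)
  expect_equal(rep_$accuracy, 1.0)

  probe <- small_feature_table()
  sp <- split_train_test(probe, seed = 5)
  m1 <- train_classifier(sp$train, num_trees = 100, seed = 11)
  m2 <- train_classifier(sp$train, num_trees = 100, seed = 11)
  expect_identical(predict(m1, sp$test), predict(m2, sp$test))
})

test_that("degenerate training inputs raise informative errors", {
  one_class <- tibble::tibble(animal_id = "a", epoch_utc = 1:10,
                              behavior = "grazing", source = "in_pasture", f1 = 1:10)
  expect_error(train_classifier(one_class), "single class")
  bad <- tibble::tibble(animal_id = "a", epoch_utc = 1:10,
                        behavior = rep(c("grazing", "resting"), 5),
                        source = "in_pasture", f1 = c(NA, 2:10), f2 = 1:10)
  expect_error(train_classifier(bad), "f1")
})

test_that("prediction enforces the ordered feature schema", {
  tab <- small_feature_table()
  sp <- split_train_test(tab, seed = 2)
  m <- train_classifier(sp$train, num_trees = 50, seed = 2)
  expect_length(predict(m, sp$test[0, ]), 0L)
  expect_true(all(as.character(predict(m, sp$test)) %in% m$classes))
  dropped <- sp$test[setdiff(names(sp$test), "mean_ax_g")]
  expect_error(predict(m, dropped), "mean_ax_g")
  permuted <- sp$test[c(1:3, rev(4:ncol(sp$test)))]
  expect_error(predict(m, permuted), "order")
})

test_that("confusion metrics match hand arithmetic and caret", {
  truth <- c(rep("A", 10), rep("B", 10))
  pred <- c(rep("A", 8), rep("B", 2), rep("A", 1), rep("B", 9))
  r <- confusion_and_metrics(truth, pred)
  expect_equal(r$accuracy, 0.85)
  a <- r$per_class[r$per_class$class == "A", ]
  expect_equal(a$sensitivity, 0.8)
  expect_equal(a$precision, 8 / 9)
  expect_equal(a$specificity, 0.9)
  # binary identity: sensitivity of A equals specificity of B
  b <- r$per_class[r$per_class$class == "B", ]
  expect_equal(a$sensitivity, b$specificity)
  expect_equal(b$sensitivity, a$specificity)

  skip_if_not_installed("caret")
  cm <- caret::confusionMatrix(factor(pred), factor(truth), positive = "A")
  expect_equal(r$accuracy, unname(cm$overall["Accuracy"]))
  expect_equal(a$sensitivity, unname(cm$byClass["Sensitivity"]))
  expect_equal(a$specificity, unname(cm$byClass["Specificity"]))
  expect_equal(a$precision, unname(cm$byClass["Precision"]))
})

test_that("perfect predictions give unit metrics for any class count", {
  truth <- rep(behavior_levels(), times = 3)
  r <- confusion_and_metrics(truth, truth)
  expect_equal(r$accuracy, 1.0)
  expect_true(all(r$per_class$sensitivity == 1 & r$per_class$specificity == 1 &
                    r$per_class$precision == 1))
})

test_that("random predictions over balanced classes approach chance accuracy", {
  withr::with_seed(123, {
    truth <- sample(rep(c("x", "y", "z"), each = 1000))
    pred <- sample(truth)
  })
  r <- confusion_and_metrics(truth, pred)
  expect_equal(r$accuracy, 1 / 3, tolerance = 0.09)
  expect_true(abs(r$accuracy - 1 / 3) < 0.03)
})

test_that("undefined per-class metrics are NA, never zero", {
  expect_warning(r <- confusion_and_metrics(c("A", "A", "B"), c("A", "A", "A"),
                                            levels = c("A", "B", "C")),
                 "undefined")
  c_row <- r$per_class[r$per_class$class == "C", ]
  expect_true(is.na(c_row$sensitivity))  # C never observed
  expect_true(is.na(c_row$precision))    # C never predicted
  b_row <- r$per_class[r$per_class$class == "B", ]
  expect_true(is.na(b_row$precision))
  expect_equal(b_row$sensitivity, 0)
  expect_error(confusion_and_metrics(c("A", "B"), "A"), "length")
})

test_that("micro accuracy equals prevalence-weighted mean sensitivity", {
  withr::with_seed(42, {
    for (i in 1:10) {
      k <- sample(2:5, 1)
      lv <- letters[1:k]
      truth <- sample(lv, 500, replace = TRUE, prob = stats::runif(k) + 0.2)
      pred <- ifelse(stats::runif(500) < 0.6, truth, sample(lv, 500, replace = TRUE))
      r <- suppressWarnings(confusion_and_metrics(truth, pred, levels = lv))
      w <- r$per_class$support / r$n
      expect_equal(r$accuracy, sum(w * r$per_class$sensitivity), tolerance = 1e-12)
    }
  })
})

test_that("tidiers expose importance, schema size, and metrics", {
  tab <- small_feature_table()
  sp <- split_train_test(tab, seed = 4)
  m <- train_classifier(sp$train, num_trees = 50, seed = 4)
  td <- tidy(m)
  expect_equal(nrow(td), length(m$schema))
  gl <- glance(m)
  expect_equal(gl$n_classes, length(m$classes))
  r <- evaluate_classifier(m, sp$test)
  expect_equal(nrow(tidy(r)), length(m$classes))
  expect_equal(glance(r)$n, nrow(sp$test))
})

test_that("coarser groupings are no harder than the full ethogram", {
  tab <- small_feature_table()
  accs <- sapply(1:10, function(s) {
    sapply(c("full", "activity"), function(sc) {
      g <- group_labels(tab, sc)
      sp <- split_train_test(g, seed = s)
      m <- train_classifier(sp$train, num_trees = 60, seed = s)
      evaluate_classifier(m, sp$test)$accuracy
    })
  })
  expect_gte(mean(accs["activity", ]), mean(accs["full", ]) - 0.005)
})

test_that("classifier persistence round-trips predictions", {
  tab <- small_feature_table()
  sp <- split_train_test(tab, seed = 8)
  m <- train_classifier(sp$train, num_trees = 50, seed = 8)
  path <- withr::local_tempfile(fileext = ".rds")
  save_classifier(m, path)
  m2 <- load_classifier(path)
  expect_identical(predict(m2, sp$test), predict(m, sp$test))
  expect_identical(m2$schema, m$schema)
})

test_that("held-out accuracy agrees with the reference forest implementation", {
  skip_if_not_installed("randomForest")
  tab <- small_feature_table()
  sp <- split_train_test(tab, seed = 6)
  ours <- evaluate_classifier(train_classifier(sp$train, num_trees = 150, seed = 6),
                              sp$test)$accuracy
  feat <- setdiff(names(sp$train), grazeclass:::feature_key_cols())
  withr::with_seed(6, {
    ref <- randomForest::randomForest(x = as.data.frame(sp$train[feat]),
                                      y = factor(sp$train$behavior), ntree = 150)
  })
  ref_acc <- mean(predict(ref, as.data.frame(sp$test[feat])) == sp$test$behavior)
  expect_equal(ours, ref_acc, tolerance = 0.05)
})
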