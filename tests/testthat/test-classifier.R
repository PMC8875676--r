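# Outlier filtering, splitting, training, cross-validation, metrics, ROC.

test_that("outlier filtering drops exactly the planted extremes", {
  set.seed(1)
  rec <- data.frame(ddg = runif(200, -2, 2), ddsvib = runif(200, -0.5, 0.5))
  planted <- c(10, 50, 99, 140, 188)
  rec$ddg[planted[1:3]] <- c(100, -80, 120)
  rec$ddsvib[planted[4:5]] <- c(40, -35)
  got <- filter_outliers(rec)
  expect_equal(attr(got, "n_dropped"), 5L)
  # verify against a direct MAD computation
  z1 <- abs(rec$ddg - median(rec$ddg)) / mad(rec$ddg)
  z2 <- abs(rec$ddsvib - median(rec$ddsvib)) / mad(rec$ddsvib)
  expect_equal(sort(which(z1 > 3 | z2 > 3)), sort(planted))
  expect_equal(nrow(got), 195)

  # identical values: zero spread, nothing dropped
  same <- data.frame(ddg = rep(1.3, 20), ddsvib = rep(0.2, 20))
  got2 <- filter_outliers(same)
  expect_equal(nrow(got2), 20)
  expect_equal(attr(got2, "n_dropped"), 0L)

  # tiny sets skip filtering with a warning
  expect_warning(filter_outliers(rec[1:5, ]), "skipped")
})

test_that("stratified 75/25 split is exact, seeded, and class-aware", {
  rec <- data.frame(label = rep(c("high_impact", "neutral"), c(60, 40)),
                    x = rnorm(100))
  sp <- split_train_test(rec, seed = 5)
  expect_equal(nrow(sp$train), 75)
  expect_equal(nrow(sp$test), 25)
  expect_equal(sum(sp$train$label == "high_impact"), 45)
  expect_equal(sum(sp$train$label == "neutral"), 30)
  expect_equal(sum(sp$test$label == "high_impact"), 15)
  expect_equal(sum(sp$test$label == "neutral"), 10)
  # disjoint and exhaustive
  expect_equal(sort(c(rownames(sp$train), rownames(sp$test))),
               sort(rownames(rec)))
  # same seed: identical; different seed: different (w.h.p. at n = 100)
  sp2 <- split_train_test(rec, seed = 5)
  expect_identical(sp$train, sp2$train)
  sp3 <- split_train_test(rec, seed = 6)
  expect_false(identical(rownames(sp$train), rownames(sp3$train)))
  expect_error(split_train_test(rec[rec$label == "neutral", ]), "class")
})

test_that("training separates separable data and returns calibrated probabilities", {
  set.seed(2)
  n <- 400
  rec <- simulate_training_set(n, seed = 2, label_noise = 0,
                               feature_noise = 0.01)
  cfg <- rf_config(n_trees = 200, min_samples_leaf = 5, seed = 9)
  model <- vs_train(rec, cfg)
  pred <- predict(model, rec)
  expect_true(mean(pred$class == rec$label) > 0.99)
  expect_true(all(pred$p_high_impact >= 0 & pred$p_high_impact <= 1))
  expect_equal(pred$p_high_impact + pred$p_neutral, rep(1, n))
  # schema mismatch is a hard error
  bad <- rec; names(bad)[names(bad) == "ddg"] <- "not_ddg"
  expect_error(predict(model, bad), "schema")
  # reproducibility: same records, config, seed -> identical predictions
  model2 <- vs_train(rec, cfg)
  expect_equal(predict(model2, rec), pred)
})

test_that("cross-validation is stratified, seeded, and exact on separable data", {
  rec <- simulate_training_set(300, seed = 3, label_noise = 0,
                               feature_noise = 0.01)
  cfg <- rf_config(n_trees = 150, min_samples_leaf = 2, seed = 4)
  cv <- cross_validate(rec, k = 5, config = cfg)
  expect_length(cv$folds, 5)
  expect_gte(cv$aggregate["accuracy"], 0.95)
  # fold assignment reproducible and stratified
  cv2 <- cross_validate(rec, k = 5, config = cfg)
  expect_identical(cv$assignments, cv2$assignments)
  per_fold <- table(cv$assignments, rec$label)
  expect_true(all(abs(per_fold - mean(per_fold)) <= max(per_fold) * 0.2 + 1))
  # class smaller than k errors out with advice
  tiny <- rec[c(which(rec$label == "neutral")[1:3],
                which(rec$label == "high_impact")[1:40]), ]
  expect_error(cross_validate(tiny, k = 10), "smaller k")
})

test_that("leave-one-out boundary case runs and aggregates", {
  rec <- simulate_training_set(60, seed = 8, label_noise = 0,
                               feature_noise = 0.01)[1:30, ]
  # ensure both classes present
  expect_gte(min(table(rec$label)), 2)
  k <- min(table(rec$label))
  cv <- cross_validate(rec, k = k, config = rf_config(n_trees = 60, seed = 2))
  expect_length(cv$folds, k)
  expect_true(is.finite(cv$aggregate["accuracy"]))
})

test_that("confusion metrics satisfy their identities on random count tuples", {
  m <- compute_metrics(8, 3, 7, 2)
  expect_equal(m$accuracy, 0.55)
  expect_equal(m$tpr, 0.8)
  expect_equal(m$tnr, 0.3)
  m2 <- compute_metrics(10, 10, 0, 0)
  expect_equal(c(m2$accuracy, m2$tpr, m2$tnr, m2$precision), rep(1, 4))
  m3 <- suppressWarnings(compute_metrics(0, 10, 0, 10))
  expect_equal(c(m3$accuracy, m3$tpr, m3$tnr), c(0.5, 0, 1))
  w <- capture_warnings(compute_metrics(0, 5, 0, 0))
  expect_true(any(grepl("TPR undefined", w)))

  set.seed(11)
  for (rep in 1:300) {
    ct <- rpois(4, 8)
    if (sum(ct) == 0) next
    mm <- suppressWarnings(compute_metrics(ct[1], ct[2], ct[3], ct[4]))
    expect_equal(mm$accuracy, (ct[1] + ct[2]) / sum(ct))
    if (ct[1] + ct[4] > 0) expect_equal(mm$tpr, ct[1] / (ct[1] + ct[4]))
    if (ct[2] + ct[3] > 0) expect_equal(mm$tnr, ct[2] / (ct[2] + ct[3]))
    expect_equal(mm$sensitivity_high_impact, mm$tpr)
    expect_equal(mm$sensitivity_neutral, mm$tnr)
  }
})

test_that("ROC: separation, rank-statistic identity, tie grouping, monotone invariance", {
  lab <- rep(c("neutral", "high_impact"), each = 10)
  sep <- c(rnorm(10, -3, 0.1), rnorm(10, 3, 0.1))
  expect_equal(roc_curve(sep, lab)$auc, 1)

  set.seed(21)
  for (rep in 1:25) {
    n <- sample(20:80, 1)
    labels <- sample(c("neutral", "high_impact"), n, replace = TRUE,
                     prob = c(0.4, 0.6))
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding makes ties likely
    r <- roc_curve(scores, labels)
    # Mann-Whitney oracle with midrank tie handling
    pos <- labels == "high_impact"
    rk <- rank(scores)
    u <- sum(rk[pos]) - sum(pos) * (sum(pos) + 1) / 2
    expect_equal(r$auc, u / (sum(pos) * sum(!pos)), tolerance = 1e-12)
    # invariant under strictly monotone transforms
    r2 <- roc_curve(5 * scores - 2, labels)
    expect_equal(r2$auc, r$auc)
    r3 <- roc_curve(atan(scores), labels)
    expect_equal(r3$auc, r$auc, tolerance = 1e-12)
  }
  expect_error(roc_curve(1:5, rep("neutral", 5)), "both classes")
})

test_that("ROC agrees with an established independent implementation", {
  set.seed(31)
  labels <- sample(c("neutral", "high_impact"), 200, replace = TRUE)
  scores <- rnorm(200) + (labels == "high_impact") * 0.8
  ours <- roc_curve(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = factor(labels, levels = c("neutral", "high_impact")),
    predictor = scores, quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("near-random scores give AUC near one half", {
  set.seed(41)
  labels <- rep(c("neutral", "high_impact"), each = 5000)
  scores <- rnorm(10000)
  a <- roc_curve(scores, labels)$auc
  expect_gt(a, 0.47)
  expect_lt(a, 0.53)
})
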