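# Training protocol, fold plans, metrics and the CV harness.

make_separable_images <- function(n_per_class, side = 32L) {
  # two visually distinct synthetic patterns plus pixel jitter
  imgs <- list()
  labels <- integer(0)
  for (i in seq_len(n_per_class)) {
    base1 <- outer(seq_len(side), seq_len(side),
                   function(r, c) 120 + 100 * sin(r / 4))
    base2 <- outer(seq_len(side), seq_len(side),
                   function(r, c) 120 + 100 * sin(c / 4))
    j1 <- rand_image(side, seed = i)
    j2 <- rand_image(side, seed = 100 + i)
    imgs[[2 * i - 1]] <- gray_image(pmin(pmax(round(0.8 * base1 +
      0.2 * unclass(j1)), 0), 255), "GASF")
    imgs[[2 * i]] <- gray_image(pmin(pmax(round(0.8 * base2 +
      0.2 * unclass(j2)), 0), 255), "GASF")
    labels <- c(labels, 1L, 2L)
  }
  list(images = imgs, labels = labels)
}

test_that("stratified folds partition subjects with balanced classes", {
  manifest <- data.frame(
    subject_id = rep(sprintf("S%03d", 1:100), each = 3),
    grade = rep(rep(c("normal", "GOLD2"), each = 50), each = 3)
  )
  plan <- stratified_subject_folds(manifest, k = 10, seed = 1)
  expect_length(plan$assignments, 100)
  expect_setequal(names(plan$assignments), sprintf("S%03d", 1:100))
  for (f in 1:10) {
    ids <- names(plan$assignments)[plan$assignments == f]
    cls <- manifest$grade[match(ids, manifest$subject_id)]
    expect_equal(sum(cls == "normal"), 5)
    expect_equal(sum(cls == "GOLD2"), 5)
  }
  expect_identical(stratified_subject_folds(manifest, 10, seed = 1),
                   plan)
  expect_error(stratified_subject_folds(manifest[1:9, ], k = 10), "folds")
})

test_that("training reduces the loss and can overfit a tiny set", {
  sep <- make_separable_images(16, side = 32)
  m <- build_capnonet(capnonet_config(n_classes = 2, in_side = 32), seed = 1)
  m <- train_capnonet(m, sep$images, sep$labels, epochs = 25, batch = 32,
                      seed = 1)
  expect_length(m$history, 25)
  expect_lt(mean(tail(m$history, 5)), mean(head(m$history, 5)))
  pred <- predict(m, sep$images, type = "class")
  expect_equal(mean(pred == sep$labels), 1.0)
})

test_that("training is seed-deterministic and inert at zero learning rate", {
  sep <- make_separable_images(4, side = 32)
  m0 <- build_capnonet(capnonet_config(n_classes = 2, in_side = 32), seed = 2)
  a <- train_capnonet(m0, sep$images, sep$labels, epochs = 2, seed = 5)
  b <- train_capnonet(m0, sep$images, sep$labels, epochs = 2, seed = 5)
  expect_identical(a$params, b$params)
  expect_identical(a$history, b$history)

  z <- train_capnonet(m0, sep$images, sep$labels, epochs = 2, lr = 0, seed = 5)
  expect_identical(z$params, m0$params)

  expect_error(train_capnonet(m0, list(), integer(0)), "empty")
})

test_that("metrics follow the confusion-matrix formulas", {
  perfect <- compute_metrics(matrix(c(50, 0, 0, 50), 2))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)

  # degenerate classifier predicting only the positive class
  degen <- compute_metrics(matrix(c(0, 0, 10, 10), 2))
  expect_equal(degen$accuracy, 0.5)
  expect_equal(degen$precision, 0.5)
  expect_equal(degen$recall, 1.0)
  expect_equal(degen$f1, 2 / 3)

  expect_error(compute_metrics(matrix(0, 2, 2)), "all zero")
  expect_error(compute_metrics(matrix(1, 2, 3)), "square")
})

test_that("F1 is the harmonic mean of precision and recall", {
  expect_equal(f1_score(1, 1), 1)
  expect_equal(f1_score(0, 0), 0)
  expect_equal(f1_score(0.5, 1), 2 / 3)
  expect_equal(round(f1_score(0.9521, 0.9570), 4), 0.9545)
})

test_that("macro averaging lies between the per-class extremes", {
  withr::with_seed(8, {
    for (rep in 1:20) {
      C <- sample(3:5, 1)
      conf <- matrix(stats::rpois(C * C, 3) + diag(C) * 10, C)
      rep_out <- compute_metrics(conf)
      expect_gte(rep_out$f1, min(rep_out$per_class$f1) - 1e-12)
      expect_lte(rep_out$f1, max(rep_out$per_class$f1) + 1e-12)
      # macro F1 averages per-class F1, not F1 of the averages
      expect_equal(rep_out$f1, mean(rep_out$per_class$f1))
    }
  })
  # binary F1 equals the positive-class entry of the per-class table
  conf <- matrix(c(40, 5, 3, 52), 2)
  out <- compute_metrics(conf)
  expect_equal(out$f1, out$per_class$f1[2])
})

test_that("the CV harness splits by subject, pools subjects and avoids leakage", {
  cohort <- simulate_cohort(cohort_config(n_per_class = 6,
                                          class_set = c("normal", "GOLD4"),
                                          breaths_per_subject = 2, seed = 2))
  res <- run_cv(cohort, task = "detect", side = 32, k = 3, epochs = 2,
                batch = 16, augment = TRUE, seed = 4)
  expect_s3_class(res, "cv_result")
  expect_length(res$folds, 3)
  expect_true(all(!vapply(res$folds, is.null, logical(1))))
  # pooled confusion counts every subject exactly once
  expect_equal(sum(res$pooled$confusion), 12)
  # subject-level splitting: no record id in both train and held-out sets
  for (fa in res$fold_audit) {
    expect_length(intersect(fa$train_records, fa$held_out_records), 0)
  }
  # every subject held out exactly once across folds
  held <- unlist(lapply(res$fold_audit, function(f) {
    unique(sub("_b[0-9]+$", "", f$held_out_records))
  }))
  expect_setequal(held, unique(cohort$manifest$subject_id))
  expect_equal(length(held), 12)
})
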