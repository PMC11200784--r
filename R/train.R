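# Training protocol and evaluation: Adam on softmax cross-entropy
# (lr 0.001, batch 32 by default), stratified subject-level 10-fold
# cross-validation, confusion matrices and accuracy/precision/recall/F1.

#' Train a CapnoNet model
#'
#' Mini-batch Adam on softmax cross-entropy with seeded shuffling; batch
#' normalization uses batch statistics and dropout is active during
#' training. The per-epoch mean loss is recorded in the returned model's
#' `history`.
#'
#' @param model An untrained (or previously trained) `capnonet` model.
#' @param images List of [gray_image()]s, all of one side.
#' @param labels Class labels, one per image: a factor, or integer indices
#'   in `1..n_classes`.
#' @param epochs Training epochs; default 30.
#' @param lr Adam learning rate; default 0.001.
#' @param batch Mini-batch size; default 32.
#' @param seed Integer seed; same data + seed give identical final weights.
#' @param verbose Print the per-epoch loss.
#' @return The trained `capnonet` model with `history` (per-epoch loss) and
#'   `class_levels` attached.
#' @export
train_capnonet <- function(model, images, labels, epochs = 30L, lr = 0.001,
                           batch = 32L, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "capnonet"))
  if (!length(images)) stopf("empty training set")
  if (length(labels) != length(images)) {
    stopf("got %d labels for %d images", length(labels), length(images))
  }
  if (is.factor(labels) || is.character(labels)) {
    f <- factor(labels)
    model$class_levels <- levels(f)
    y <- as.integer(f)
  } else {
    y <- as.integer(labels)
  }
  if (max(y) > model$cfg$n_classes) {
    stopf("label index %d exceeds n_classes = %d", max(y), model$cfg$n_classes)
  }
  side <- nrow(images[[1]])
  n <- length(images)
  history <- numeric(epochs)
  with_seed(seed, {
    st <- .adam_init(model$params)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- c()
      i <- 1L
      while (i <= n) {
        j <- min(i + batch - 1L, n)
        idx <- ord[i:j]
        inp <- .images_to_input(images[idx])
        fw <- .capnonet_forward(model, inp$x, side, inp$B,
                                training = TRUE, cache = TRUE)
        model$state <- fw$state
        ce <- .softmax_ce(fw$logits, y[idx])
        grads <- .capnonet_backward(model, ce$dlogits, fw$caches, side,
                                    inp$B)
        upd <- .adam_step(model$params, grads, st, lr)
        model$params <- upd$params
        st <- upd$st
        losses <- c(losses, ce$loss)
        i <- j + 1L
      }
      history[ep] <- mean(losses)
      if (verbose) {
        message(sprintf("epoch %d/%d  loss %.4f", ep, epochs, history[ep]))
      }
    }
  })
  model$history <- history
  model$trained <- TRUE
  model$train_side <- side
  model
}

#' Stratified subject-level fold assignment
#'
#' Subjects (not individual breaths) are partitioned into `k` folds: within
#' each class the subjects are shuffled (seeded) and dealt round-robin, so
#' per-fold class proportions differ from the global ones by at most one
#' subject per class.
#'
#' @param manifest Data frame with one or more rows per subject and columns
#'   `subject_id` plus the stratification column.
#' @param k Number of folds; default 10.
#' @param seed Integer seed.
#' @param strata Name of the class column used for stratification; default
#'   `"grade"`.
#' @return A `fold_plan`: list with `k`, `seed` and `assignments` (named
#'   integer vector, subject id -> fold).
#' @export
stratified_subject_folds <- function(manifest, k = 10L, seed = 1L,
                                     strata = "grade") {
  if (!all(c("subject_id", strata) %in% names(manifest))) {
    stopf("manifest needs columns subject_id and %s", strata)
  }
  subj <- manifest[!duplicated(manifest$subject_id),
                   c("subject_id", strata)]
  if (nrow(subj) < k) {
    stopf("%d subjects cannot fill %d folds", nrow(subj), k)
  }
  assignments <- integer(0)
  with_seed(seed, {
    for (cls in sort(unique(subj[[strata]]))) {
      ids <- subj$subject_id[subj[[strata]] == cls]
      ids <- ids[sample.int(length(ids))]
      folds <- ((seq_along(ids) - 1L) %% k) + 1L
      names(folds) <- ids
      assignments <- c(assignments, folds)
    }
  })
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 assignments = assignments),
            class = "fold_plan")
}

#' Classification metrics from a confusion matrix
#'
#' Rows are truth, columns are prediction. Accuracy is the trace over the
#' total. In the binary case precision, recall and F1 come from the
#' TP/FP/TN/FN of the positive class (`precision = TP/(TP+FP)`,
#' `recall = TP/(TP+FN)`, F1 their harmonic mean). With more than two
#' classes the three are macro-averaged: computed per class one-vs-rest and
#' averaged unweighted, F1 averaged per class (not recomputed from the
#' averaged precision and recall).
#'
#' @param confusion Square non-negative count matrix.
#' @param positive Index of the positive class for the binary case;
#'   default 2.
#' @return A `metrics_report`: list with `confusion`, `accuracy`,
#'   `precision`, `recall`, `f1` and a `per_class` data frame.
#' @export
compute_metrics <- function(confusion, positive = 2L) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stopf("confusion matrix must be square")
  if (any(confusion < 0)) stopf("confusion matrix has negative counts")
  total <- sum(confusion)
  if (total == 0) stopf("confusion matrix is all zero")
  C <- nrow(confusion)
  acc <- sum(diag(confusion)) / total
  prf <- function(i) {
    tp <- confusion[i, i]
    fp <- sum(confusion[-i, i])
    fn <- sum(confusion[i, -i])
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(precision = p, recall = r, f1 = f)
  }
  per <- t(vapply(seq_len(C), prf, numeric(3)))
  per_class <- data.frame(class = rownames(confusion) %||% seq_len(C), per)
  if (C == 2L) {
    pr <- per[positive, ]
  } else {
    pr <- colMeans(per)
  }
  structure(list(confusion = confusion, accuracy = acc,
                 precision = unname(pr["precision"]),
                 recall = unname(pr["recall"]), f1 = unname(pr["f1"]),
                 per_class = per_class),
            class = "metrics_report")
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 P R / (P + R)`.
#'
#' @param precision,recall Values in \[0, 1\].
#' @return The F1 score.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Confusion matrix (rows = truth, columns = prediction):\n")
  print(x$confusion)
  cat(sprintf("accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

# Majority vote over a subject's breath-level predicted classes; ties are
# broken by the summed class probabilities.
.majority_vote <- function(pred_classes, probs) {
  tab <- tabulate(pred_classes, nbins = ncol(probs))
  top <- which(tab == max(tab))
  if (length(top) == 1L) return(top)
  score <- colSums(probs[, top, drop = FALSE])
  top[which.max(score)]
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' For each fold: GAF images of the training subjects' breaths are augmented
#' (3x, when enabled), a fresh CapnoNet is trained, the held-out subjects'
#' breaths are classified, breath predictions are aggregated per subject by
#' majority vote, and the subject-level confusions are pooled across folds.
#' Held-out images are never passed through the augmentation operators.
#'
#' @param cohort A `vcap_cohort` (see [simulate_cohort()] / [read_cohort()]).
#' @param task `"detect"` (normal vs COPD) or `"grade"` (one class per
#'   severity grade in the cohort).
#' @param kind GAF kind, `"GASF"` (default) or `"GADF"`.
#' @param side Encoding side: breaths are PAA-reduced to this length and
#'   encoded as `side x side` images; default 224.
#' @param k Number of folds; default 10.
#' @param epochs,lr,batch Training protocol passed to [train_capnonet()].
#' @param augment Apply the 3x augmentation policy to training folds;
#'   default `TRUE`.
#' @param seed Master seed for fold assignment, initialization, shuffling
#'   and augmentation.
#' @param verbose Print per-fold progress.
#' @return A `cv_result`: list with `pooled` (a [compute_metrics()] report
#'   over all subjects), `folds` (per-fold reports), `plan`, `class_levels`
#'   and a `fold_audit` of train/held-out record ids.
#' @export
run_cv <- function(cohort, task = c("detect", "grade"), kind = c("GASF", "GADF"),
                   side = 224L, k = 10L, epochs = 30L, lr = 0.001,
                   batch = 32L, augment = TRUE, seed = 1L, verbose = FALSE) {
  task <- match.arg(task)
  kind <- match.arg(kind)
  stopifnot(inherits(cohort, "vcap_cohort"))
  manifest <- cohort$manifest
  class_col <- if (task == "detect") "label" else "grade"
  lv <- sort(unique(manifest[[class_col]]))
  if ("normal" %in% lv) lv <- c("normal", setdiff(lv, "normal"))
  # encode every breath once; one image per valid breath of each record
  images <- list()
  img_subject <- character(0)
  img_class <- character(0)
  img_record <- character(0)
  for (i in seq_len(nrow(manifest))) {
    rec_id <- sub("\\.csv$", "", manifest$record_path[i])
    rec <- cohort$records[[rec_id]]
    series <- preprocess_record(rec, m = side)
    for (s in series) {
      images[[length(images) + 1L]] <- encode_image(s, kind)
      img_subject <- c(img_subject, manifest$subject_id[i])
      img_class <- c(img_class, manifest[[class_col]][i])
      img_record <- c(img_record, rec_id)
    }
  }
  if (!length(images)) stopf("no valid breaths found in the cohort")
  plan <- stratified_subject_folds(manifest, k = k, seed = seed,
                                   strata = class_col)
  y_all <- match(img_class, lv)
  subj_class <- manifest[[class_col]][!duplicated(manifest$subject_id)]
  names(subj_class) <- manifest$subject_id[!duplicated(manifest$subject_id)]
  pooled <- matrix(0L, length(lv), length(lv), dimnames = list(lv, lv))
  fold_reports <- vector("list", k)
  fold_audit <- vector("list", k)
  fold_seeds <- with_seed(seed, sample.int(.Machine$integer.max, 3L * k))
  for (fold in seq_len(k)) {
    held <- names(plan$assignments)[plan$assignments == fold]
    tr_idx <- which(!(img_subject %in% held))
    va_idx <- which(img_subject %in% held)
    if (!length(va_idx) || !length(tr_idx)) next
    tr_images <- images[tr_idx]
    tr_y <- y_all[tr_idx]
    if (augment) {
      tr_images <- expand_training_set(tr_images,
                                       seed = fold_seeds[3L * fold - 2L])
      tr_y <- rep(tr_y, 3L)
    }
    model <- build_capnonet(capnonet_config(n_classes = length(lv),
                                            in_side = side),
                            seed = fold_seeds[3L * fold - 1L])
    model$class_levels <- lv
    model <- train_capnonet(model, tr_images, tr_y, epochs = epochs,
                            lr = lr, batch = batch,
                            seed = fold_seeds[3L * fold])
    probs <- predict(model, images[va_idx], type = "prob", batch = batch)
    pred <- max.col(probs, ties.method = "first")
    conf <- matrix(0L, length(lv), length(lv), dimnames = list(lv, lv))
    for (sid in unique(img_subject[va_idx])) {
      rows <- which(img_subject[va_idx] == sid)
      vote <- .majority_vote(pred[rows], probs[rows, , drop = FALSE])
      truth <- match(subj_class[[sid]], lv)
      conf[truth, vote] <- conf[truth, vote] + 1L
    }
    pooled <- pooled + conf
    fold_reports[[fold]] <- compute_metrics(conf)
    fold_audit[[fold]] <- list(train_records = unique(img_record[tr_idx]),
                               held_out_records = unique(img_record[va_idx]))
    if (verbose) {
      message(sprintf("fold %d/%d  subjects %d  accuracy %.3f", fold, k,
                      length(held), fold_reports[[fold]]$accuracy))
    }
  }
  structure(list(pooled = compute_metrics(pooled), folds = fold_reports,
                 plan = plan, class_levels = lv, task = task, kind = kind,
                 fold_audit = fold_audit),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold stratified subject-level cross-validation (%s, %s)\n",
              x$plan$k, x$task, x$kind))
  print(x$pooled)
  invisible(x)
}
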