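# Training loop, learning-rate schedule, evaluation metrics and
# subject-level cross-validation.

#' Training configuration
#'
#' The published schedule is Adam from 0.001 with a x0.1 step: every 50
#' epochs over 150 total for the ECG configuration, every 80 over 160 for the
#' PCG configuration.  The `"desk"` preset keeps the same optimizer and
#' initial rate but runs 20 epochs for CPU-scale experiments.
#'
#' @param preset `"desk"`, `"ecg"` or `"pcg"`.
#' @param lr0 initial learning rate.
#' @param decay_factor multiplicative step, default 0.1.
#' @param decay_every epochs between steps (preset-dependent).
#' @param total_epochs training epochs (preset-dependent).
#' @param batch_size minibatch size, default 32.
#' @param dropout detection-head dropout, default 0.3.
#' @param folds cross-validation folds, default 5.
#' @param repetitions cross-validation repetitions, default 10.
#' @param pretrain_epochs optional reconstruction-only epochs before joint
#'   training.
#' @param seed RNG seed for shuffling, dropout and initialization.
#' @return a `TrainConfig` list.
#' @export
train_config <- function(preset = c("desk", "ecg", "pcg"), lr0 = 0.001,
                         decay_factor = 0.1, decay_every = NULL,
                         total_epochs = NULL, batch_size = 32L,
                         dropout = 0.3, folds = 5L, repetitions = 10L,
                         pretrain_epochs = 0L, seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(decay_every))
    decay_every <- switch(preset, desk = 50L, ecg = 50L, pcg = 80L)
  if (is.null(total_epochs))
    total_epochs <- switch(preset, desk = 20L, ecg = 150L, pcg = 160L)
  if (lr0 <= 0) stop("lr0 must be > 0")
  if (decay_factor <= 0 || decay_factor > 1)
    stop("decay_factor must be in (0, 1]")
  if (folds < 2L) stop("folds must be >= 2")
  structure(list(preset = preset, lr0 = lr0, decay_factor = decay_factor,
                 decay_every = as.integer(decay_every),
                 total_epochs = as.integer(total_epochs),
                 batch_size = as.integer(batch_size), dropout = dropout,
                 folds = as.integer(folds),
                 repetitions = as.integer(repetitions),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Learning rate at a given epoch
#'
#' Piecewise-constant decay: `lr0 * decay_factor ^ floor(epoch /
#' decay_every)` for `0 <= epoch < total_epochs`.
#'
#' @param cfg a [train_config()].
#' @param epoch 0-based epoch index.
#' @return learning rate.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  if (any(epoch < 0) || any(epoch >= cfg$total_epochs))
    stop("epoch out of range [0, ", cfg$total_epochs, ")")
  cfg$lr0 * cfg$decay_factor^(epoch %/% cfg$decay_every)
}

# ---- metrics ---------------------------------------------------------------

#' Confusion counts
#'
#' @param tp,tn,fp,fn non-negative integer tallies.
#' @return a `ConfusionCounts` list.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  structure(as.list(v), class = "ConfusionCounts")
}

#' Tally a binary confusion matrix from labels
#'
#' @param truth,pred character or factor vectors.
#' @param positive label treated as the positive class.
#' @return a [confusion_counts()] object.
#' @export
count_confusion <- function(truth, pred, positive = "positive") {
  t_pos <- truth == positive
  p_pos <- pred == positive
  confusion_counts(sum(t_pos & p_pos), sum(!t_pos & !p_pos),
                   sum(!t_pos & p_pos), sum(t_pos & !p_pos))
}

#' Wilson score interval for a proportion
#'
#' @param x successes.
#' @param n trials.
#' @param conf confidence level, default 0.95.
#' @return length-2 numeric `c(lower, upper)`.
#' @export
wilson_interval <- function(x, n, conf = 0.95) {
  if (n <= 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, center - half), min(1, center + half))
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Evaluate classification metrics from confusion counts
#'
#' Reports both the published formulas and the standard definitions, clearly
#' labeled.  `paper_accuracy` uses the printed numerator `(TP + FP) / n`;
#' `standard_accuracy` is `(TP + TN) / n` and is the headline metric.
#' `paper_specificity = TP / (TP + FP)` is algebraically the precision
#' (positive predictive value); the conventional specificity
#' `TN / (TN + FP)` is reported as `standard_specificity`.  The F1 score is
#' the harmonic mean of `paper_specificity` and `sensitivity` (identical to
#' the standard F1 of precision and recall).  Zero-denominator metrics are
#' reported as `NA` and listed in `undefined`.  Wilson 95% intervals
#' accompany each defined proportion.
#'
#' @param counts a [confusion_counts()] object.
#' @param conf confidence level for the Wilson intervals.
#' @return a `MetricReport` list.
#' @export
evaluate_metrics <- function(counts, conf = 0.95) {
  stopifnot(inherits(counts, "ConfusionCounts"))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  n <- tp + tn + fp + fn
  if (n < 1) stop("at least one evaluated sample required")
  paper_accuracy <- (tp + fp) / n
  standard_accuracy <- (tp + tn) / n
  paper_specificity <- safe_ratio(tp, tp + fp)   # precision / PPV
  sensitivity <- safe_ratio(tp, tp + fn)         # recall
  standard_specificity <- safe_ratio(tn, tn + fp)
  f1 <- if (is.na(paper_specificity) || is.na(sensitivity) ||
            paper_specificity + sensitivity == 0) NA_real_ else
    2 * paper_specificity * sensitivity / (paper_specificity + sensitivity)
  vals <- list(paper_accuracy = paper_accuracy,
               standard_accuracy = standard_accuracy,
               paper_specificity = paper_specificity,
               sensitivity = sensitivity, f1 = f1,
               precision = paper_specificity, recall = sensitivity,
               standard_specificity = standard_specificity)
  undefined <- names(vals)[vapply(vals, is.na, logical(1))]
  ci <- list(standard_accuracy = wilson_interval(tp + tn, n, conf),
             paper_specificity = if (tp + fp > 0)
               wilson_interval(tp, tp + fp, conf) else c(NA_real_, NA_real_),
             sensitivity = if (tp + fn > 0)
               wilson_interval(tp, tp + fn, conf) else c(NA_real_, NA_real_),
             standard_specificity = if (tn + fp > 0)
               wilson_interval(tn, tn + fp, conf) else c(NA_real_, NA_real_))
  structure(c(vals, list(counts = counts, n = n, undefined = undefined,
                         wilson = ci)),
            class = "MetricReport")
}

#' @export
print.MetricReport <- function(x, ...) {
  cat(sprintf("accuracy %.4f (paper-formula %.4f)  precision %.4f  recall %.4f  F1 %.4f\n",
              x$standard_accuracy, x$paper_accuracy,
              x$paper_specificity, x$sensitivity, x$f1))
  if (length(x$undefined))
    cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

# ---- dataset preparation ---------------------------------------------------

#' Build paired feature-volume tensors from a cohort
#'
#' Segments each subject's ECG and PCG with the class-dependent stride
#' (identical windows for the two modalities), min-max normalizes each
#' segment, and stacks the per-segment feature volumes.  Denoising and
#' false-peak elimination can be enabled for corrupted cohorts.
#'
#' @param cohort result of [generate_cohort()] (or a compatible list of
#'   record pairs).
#' @param stft STFT settings (from `model_config()$sstp$stft`).
#' @param seg a [segmentation_config()].
#' @param wiener optional [wiener_config()] applied before segmentation.
#' @param fpe optional [fpe_config()] applied before segmentation.
#' @return list with `x_ecg`, `x_pcg` (\[H, W, B, 1, N\]), integer `labels`,
#'   `classes`, and per-segment `subject` ids.
#' @export
prepare_dataset <- function(cohort, stft = model_config()$sstp$stft,
                            seg = segmentation_config(), wiener = NULL,
                            fpe = NULL) {
  vols_e <- list(); vols_p <- list(); labels <- character(); subject <- character()
  for (pair in cohort$records) {
    ae <- preprocess_record(pair$ecg, wiener = wiener, fpe = fpe, seg = seg)
    ap <- preprocess_record(pair$pcg, wiener = wiener, fpe = fpe, seg = seg)
    k <- min(nrow(ae$segments), nrow(ap$segments))
    if (k == 0L) next
    for (i in seq_len(k)) {
      vols_e[[length(vols_e) + 1L]] <-
        build_volume(ae$segments[i, ], pair$ecg$fs, stft, seg$window_s)$values
      vols_p[[length(vols_p) + 1L]] <-
        build_volume(ap$segments[i, ], pair$pcg$fs, stft, seg$window_s)$values
      labels <- c(labels, ae$labels[i])
      subject <- c(subject, pair$ecg$record_id)
    }
  }
  if (!length(vols_e)) stop("training error: empty dataset")
  d <- dim(vols_e[[1L]])
  n <- length(vols_e)
  xe <- array(unlist(vols_e), c(d, n)); dim(xe) <- c(d, 1L, n)
  xp <- array(unlist(vols_p), c(d, n)); dim(xp) <- c(d, 1L, n)
  xe <- aperm(xe, c(1L, 2L, 3L, 4L, 5L))
  classes <- intersect(c("negative", "positive", "AD", "MVP", "MPC",
                         "unlabeled"), unique(labels))
  list(x_ecg = xe, x_pcg = xp, labels = match(labels, classes),
       classes = classes, subject = subject)
}

#' Subset a prepared dataset by segment index or subject
#'
#' @param data result of [prepare_dataset()].
#' @param idx segment indices, or (when `subjects` given) ignored.
#' @param subjects subject ids to keep.
#' @return a dataset list of the same form.
#' @export
subset_dataset <- function(data, idx = NULL, subjects = NULL) {
  if (!is.null(subjects)) idx <- which(data$subject %in% subjects)
  list(x_ecg = data$x_ecg[, , , , idx, drop = FALSE],
       x_pcg = data$x_pcg[, , , , idx, drop = FALSE],
       labels = data$labels[idx], classes = data$classes,
       subject = data$subject[idx])
}

# ---- training --------------------------------------------------------------

#' Train the full model
#'
#' Adam with the piecewise-constant learning-rate schedule on the joint
#' objective `CE + lambda_rec * reconstruction`.  All randomness (weight
#' initialization, shuffling, dropout) is driven by `train_cfg$seed`.  When
#' validation data is supplied, the parameters achieving the best validation
#' accuracy are kept (in-memory checkpoint).
#'
#' @param data training dataset from [prepare_dataset()].
#' @param model_cfg a [model_config()]; `n_classes` must match the data.
#' @param train_cfg a [train_config()].
#' @param validation optional held-out dataset for per-epoch evaluation.
#' @param verbose print per-epoch progress.
#' @return list with the trained `model` and a `history` data frame
#'   (epoch, lr, loss, ce, rec, accuracy, val_accuracy).
#' @export
train_model <- function(data, model_cfg = model_config(),
                        train_cfg = train_config(), validation = NULL,
                        verbose = FALSE) {
  n <- length(data$labels)
  if (n == 0L) stop("training error: empty dataset")
  if (length(unique(data$labels)) < 2L)
    stop("training error: need at least 2 classes, got ",
         length(unique(data$labels)))
  if (model_cfg$ende$n_classes < length(data$classes))
    stop("config error: model has fewer classes than the data")
  vol_dim <- dim(data$x_ecg)[1:3]
  model <- model_init(vol_dim, model_cfg, seed = train_cfg$seed)
  opt <- adam_init(model_params(model))
  history <- data.frame()
  best_val <- -Inf; best_params <- NULL
  with_seed(train_cfg$seed + 1L, {
    total <- train_cfg$pretrain_epochs + train_cfg$total_epochs
    for (ep in seq_len(total) - 1L) {
      pretrain <- ep < train_cfg$pretrain_epochs
      joint_ep <- if (pretrain) 0L else ep - train_cfg$pretrain_epochs
      lr <- lr_at_epoch(train_cfg, joint_ep)
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))
      ep_loss <- 0; ep_ce <- 0; ep_rec <- 0; correct <- 0
      for (b in batches) {
        fwd <- model_forward(model,
                             data$x_ecg[, , , , b, drop = FALSE],
                             data$x_pcg[, , , , b, drop = FALSE],
                             labels = data$labels[b], training = TRUE)
        if (!is.finite(fwd$loss))
          stop("training error: non-finite loss at epoch ", ep,
               " (lr ", lr, ", batch of ", length(b), ")")
        if (pretrain) fwd$cache$dz <- array(0, dim = dim(fwd$logits))
        grads <- model_backward(model, fwd)
        params <- model_params(model)
        upd <- adam_step(params, grads, opt, lr)
        opt <- upd$state
        model <- model_set_params(model, upd$params)
        model <- model_update_state(model, fwd)
        ep_loss <- ep_loss + fwd$loss * length(b)
        ep_ce <- ep_ce + fwd$ce * length(b)
        ep_rec <- ep_rec + fwd$rec * length(b)
        correct <- correct + sum(apply(fwd$probs, 2L, which.max) ==
                                   data$labels[b])
      }
      val_acc <- NA_real_
      if (!is.null(validation)) {
        pv <- predict_model(model, validation$x_ecg, validation$x_pcg)
        val_acc <- mean(apply(pv, 2L, which.max) == validation$labels)
        if (val_acc > best_val) {
          best_val <- val_acc
          best_params <- model_params(model)
        }
      }
      history <- rbind(history, data.frame(
        epoch = ep, lr = lr, loss = ep_loss / n, ce = ep_ce / n,
        rec = ep_rec / n, accuracy = correct / n, val_accuracy = val_acc))
      if (verbose)
        message(sprintf("epoch %3d  lr %.1e  loss %.4f  acc %.3f  val %.3f",
                        ep, lr, ep_loss / n, correct / n, val_acc))
    }
  })
  if (!is.null(best_params)) model <- model_set_params(model, best_params)
  list(model = model, history = history)
}

#' Predict class probabilities
#'
#' @param model trained `CardioModel`.
#' @param x_ecg,x_pcg volume batches.
#' @return matrix \[n_classes, N\].
#' @export
predict_model <- function(model, x_ecg, x_pcg) {
  model_forward(model, x_ecg, x_pcg, training = FALSE)$probs
}

#' Stratified subject-level fold assignment
#'
#' Every segment of a subject stays in one fold; folds are stratified by
#' class and deterministic given the seed.
#'
#' @param subjects subject id per unit (one entry per subject).
#' @param labels class label per subject.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer fold assignment (1..k) per subject.
#' @export
make_folds <- function(subjects, labels, k, seed = 1L) {
  if (any(table(labels) < k))
    stop("config error: folds exceed the size of the smallest class")
  fold <- integer(length(subjects))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Subject-level cross-validation
#'
#' Stratified k-fold cross-validation at the subject level (no segment of a
#' test subject ever appears in training), repeated `repetitions` times with
#' re-randomized folds.
#'
#' @param data dataset from [prepare_dataset()].
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()]; `folds` and `repetitions` control the
#'   scheme.
#' @param positive label treated as positive for the binary metrics.
#' @param verbose print progress.
#' @return list with `reports` (per fold x repetition), and `aggregate`
#'   (mean and sd of the headline metrics).
#' @export
cross_validate <- function(data, model_cfg = model_config(),
                           train_cfg = train_config(), positive = "positive",
                           verbose = FALSE) {
  subj <- unique(data$subject)
  subj_lab <- data$classes[data$labels[match(subj, data$subject)]]
  reports <- list()
  for (rep_i in seq_len(train_cfg$repetitions)) {
    fold <- make_folds(subj, subj_lab, train_cfg$folds,
                       seed = train_cfg$seed + 97L * rep_i)
    for (f in seq_len(train_cfg$folds)) {
      test_subj <- subj[fold == f]
      tr <- subset_dataset(data, subjects = setdiff(subj, test_subj))
      te <- subset_dataset(data, subjects = test_subj)
      fit <- train_model(tr, model_cfg, train_cfg)
      probs <- predict_model(fit$model, te$x_ecg, te$x_pcg)
      pred <- te$classes[apply(probs, 2L, which.max)]
      truth <- te$classes[te$labels]
      rep_out <- evaluate_metrics(count_confusion(truth, pred, positive))
      reports[[length(reports) + 1L]] <- rep_out
      if (verbose)
        message(sprintf("rep %d fold %d: accuracy %.3f", rep_i, f,
                        rep_out$standard_accuracy))
    }
  }
  keys <- c("standard_accuracy", "paper_specificity", "sensitivity", "f1")
  agg <- vapply(keys, function(k2) {
    v <- vapply(reports, function(r) r[[k2]], numeric(1))
    c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v))
  }, numeric(2))
  list(reports = reports, aggregate = agg)
}
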