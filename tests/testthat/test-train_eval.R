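test_that("learning-rate schedule follows the published step decay", {
  ecg <- train_config("ecg")
  expect_equal(lr_at_epoch(ecg, 0), 0.001)
  expect_equal(lr_at_epoch(ecg, 50), 0.0001)
  expect_equal(lr_at_epoch(ecg, 100), 0.00001)
  pcg <- train_config("pcg")
  expect_equal(lr_at_epoch(pcg, 79), 0.001)
  expect_equal(lr_at_epoch(pcg, 80), 0.0001)
  expect_error(lr_at_epoch(ecg, 150), "out of range")
  expect_error(lr_at_epoch(ecg, -1), "out of range")

  # piecewise-constant, non-increasing, with the expected number of drops
  lrs <- vapply(0:149, function(e) lr_at_epoch(ecg, e), numeric(1))
  expect_true(all(diff(lrs) <= 0))
  expect_equal(sum(diff(lrs) < 0), (150 - 1) %/% 50)
})

test_that("metric report reproduces the worked confusion example", {
  rep <- evaluate_metrics(confusion_counts(90, 85, 10, 15))
  expect_equal(rep$paper_accuracy, 0.50)
  expect_equal(rep$standard_accuracy, 0.875)
  expect_equal(rep$paper_specificity, 0.90)
  expect_equal(rep$sensitivity, 90 / 105)
  expect_equal(rep$f1, 2 * 0.9 * (90 / 105) / (0.9 + 90 / 105),
               tolerance = 1e-6)
  expect_equal(round(rep$f1, 4), 0.8780)
  expect_length(rep$undefined, 0)
})

test_that("the published F1 equals the standard F1 of precision and recall", {
  set.seed(17)
  for (i in 1:1000) {
    cc <- confusion_counts(sample(0:50, 1), sample(0:50, 1),
                           sample(0:50, 1), sample(0:50, 1))
    if (cc$tp + cc$tn + cc$fp + cc$fn == 0) next
    rep <- evaluate_metrics(cc)
    p <- rep$precision; r <- rep$recall
    if (is.na(p) || is.na(r) || p + r == 0) {
      expect_true(is.na(rep$f1))
    } else {
      expect_equal(rep$f1, 2 * p * r / (p + r), tolerance = 1e-12)
    }
  }
})

test_that("zero-denominator metrics are flagged undefined, not zero", {
  rep <- evaluate_metrics(confusion_counts(0, 10, 0, 5))
  expect_true(is.na(rep$paper_specificity))
  expect_true("paper_specificity" %in% rep$undefined)
  expect_true(is.na(rep$f1))
})

test_that("Wilson intervals match the prop.test oracle", {
  for (case in list(c(9, 10), c(50, 200), c(0, 7), c(193, 200))) {
    got <- wilson_interval(case[1], case[2])
    want <- as.numeric(suppressWarnings(
      stats::prop.test(case[1], case[2], correct = FALSE))$conf.int)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("metrics on permuted balanced predictions concentrate near 1/2", {
  set.seed(18)
  truth <- rep(c("positive", "negative"), each = 100)
  accs <- replicate(100, {
    pred <- sample(truth)
    evaluate_metrics(count_confusion(truth, pred))$standard_accuracy
  })
  expect_lt(abs(mean(accs) - 0.5), 0.02)
  expect_lt(max(abs(accs - 0.5)), 0.2)
})

test_that("fold assignment is a stratified subject-level partition", {
  subj <- sprintf("s%02d", 1:10)
  lab <- rep(c("positive", "negative"), each = 5)
  fold <- make_folds(subj, lab, 5, seed = 3)
  expect_equal(sort(unique(fold)), 1:5)
  expect_true(all(table(fold) == 2))
  expect_true(all(table(fold, lab) == 1))        # stratified: 1 per class
  expect_identical(make_folds(subj, lab, 5, seed = 3), fold)
  expect_false(identical(make_folds(subj, lab, 5, seed = 4), fold))
  expect_error(make_folds(subj, lab, 6, seed = 1), "smallest class")
})

test_that("training reduces the loss and reacts to the reconstruction weight", {
  cfg <- quick_synth_config(n_pos = 4, n_neg = 4, seed = 23)
  coh <- generate_cohort(cfg)
  mcfg <- model_config(desk = TRUE)
  data <- prepare_dataset(coh, stft = mcfg$sstp$stft)
  tcfg <- train_config("desk", total_epochs = 4, seed = 7, batch_size = 32)

  fit <- train_model(data, mcfg, tcfg)
  h <- fit$history
  expect_equal(nrow(h), 4)
  expect_lt(h$loss[4], h$loss[1])
  expect_true(all(is.finite(h$loss)))

  # lambda = 0 reduces the objective to pure cross-entropy
  mcfg0 <- model_config(desk = TRUE, lambda_rec = 0)
  fit0 <- train_model(data, mcfg0, tcfg)
  expect_equal(fit0$history$loss, fit0$history$ce, tolerance = 1e-12)
  # identical seeds, different histories once the reconstruction term acts
  expect_false(isTRUE(all.equal(fit0$history$loss, fit$history$loss)))

  # degenerate datasets fail loudly
  expect_error(train_model(subset_dataset(data, idx = integer())),
               "training error")
  one_class <- subset_dataset(data, idx = which(data$labels == 1))
  expect_error(train_model(one_class, mcfg, tcfg), "training error")
})

test_that("cross-validation evaluates disjoint held-out subjects", {
  cfg <- quick_synth_config(n_pos = 4, n_neg = 4, seed = 29)
  coh <- generate_cohort(cfg)
  mcfg <- model_config(desk = TRUE)
  data <- prepare_dataset(coh, stft = mcfg$sstp$stft)
  tcfg <- train_config("desk", total_epochs = 3, seed = 9, folds = 2,
                       repetitions = 1)
  cv <- cross_validate(data, mcfg, tcfg)
  expect_length(cv$reports, 2)
  ns <- vapply(cv$reports, function(r) r$n, numeric(1))
  expect_equal(sum(ns), length(data$labels))     # test sets exhaust the data
  expect_true(all(is.finite(cv$aggregate["mean", ])))
})
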