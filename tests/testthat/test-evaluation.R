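test_that("confusion matrices conserve counts and diagonalize on perfect input", {
  labs <- ionm_label_vocabulary()$standard
  set.seed(5)
  ref <- sample(labs, 400, replace = TRUE)
  cm <- confusion_matrix(ref, ref)
  m <- attr(cm, "matrix")
  expect_equal(sum(m), 400)
  expect_equal(sum(diag(m)), 400)
  expect_equal(confusion_accuracy(cm), 1)

  pred <- sample(labs, 400, replace = TRUE)
  cm2 <- confusion_matrix(pred, ref)
  m2 <- attr(cm2, "matrix")
  expect_equal(sum(m2), 400)
  # row sums equal reference-class counts
  expect_equal(rowSums(m2), table(factor(ref, labs)) + 0, ignore_attr = TRUE)
  expect_equal(confusion_accuracy(cm2), mean(pred == ref))

  per <- confusion_matrix(pred, ref, "per_head")
  expect_equal(dim(attr(per$nerve, "matrix")), c(3, 3))
  expect_equal(dim(attr(per$side, "matrix")), c(2, 2))
  expect_equal(sum(attr(per$position, "matrix")), 400)
  expect_error(confusion_matrix(c("V1l", "bad"), c("V1l", "V1l")),
               "vocabulary")
})

test_that("binary AUC matches perfect separation, randomness and antisymmetry", {
  # perfectly separated toy scores
  scores <- c(0.9, 0.8, 0.85, 0.2, 0.1, 0.3)
  pos <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(ionmqc:::binary_auc(scores, pos), 1.0)
  # random scores on balanced labels are near 0.5
  set.seed(9)
  s <- runif(10000)
  y <- rep(c(TRUE, FALSE), 5000)
  expect_lt(abs(ionmqc:::binary_auc(s, y) - 0.5), 0.02)
  # complement rule: AUC(s, y) + AUC(s, !y) = 1
  expect_equal(ionmqc:::binary_auc(s, y) + ionmqc:::binary_auc(s, !y), 1)
  # invariance under strictly monotone transforms
  expect_equal(ionmqc:::binary_auc(qlogis(s), y), ionmqc:::binary_auc(s, y))
})

test_that("Hand-Till multiclass AUC agrees with pROC on a toy problem", {
  set.seed(13)
  n <- 300
  ref <- sample(c("a", "b", "c"), n, replace = TRUE)
  scores <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  scores[cbind(seq_len(n), match(ref, c("a", "b", "c")))] <-
    scores[cbind(seq_len(n), match(ref, c("a", "b", "c")))] + 0.8
  scores <- scores / rowSums(scores)
  ours <- auc_hand_till(scores, ref)
  theirs <- as.numeric(pROC::multiclass.roc(ref, scores)$auc)
  expect_equal(ours, theirs, tolerance = 1e-9)
  # degenerate single-class reference: NA sentinel
  expect_true(is.na(auc_hand_till(scores[ref == "a", ], ref[ref == "a"])))
})

test_that("per-head and concatenated AUCs behave at the extremes", {
  labs <- ionm_label_vocabulary()$standard
  set.seed(21)
  ref <- sample(labs, 200, replace = TRUE)
  parts <- split_label(ref)
  perfect <- list(
    nerve = onehot_m(parts$nerve, c("V", "R", "S")),
    side = onehot_m(parts$side, c("l", "r")),
    position = onehot_m(parts$position, c("1", "2"))
  )
  out <- roc_auc(perfect, ref)
  expect_equal(out$auc, rep(1, 4))
  joint <- concatenated_probs(perfect)
  expect_equal(rowSums(joint), rep(1, 200))
  expect_identical(colnames(joint), labs)
  # blending towards uniform keeps rows normalized and lowers AUC
  soft <- lapply(perfect, function(m) 0.6 * m + 0.4 / ncol(m))
  out2 <- roc_auc(soft, ref)
  expect_equal(out2$auc[out2$output == "concatenated"], 1)  # order preserved
  noise <- lapply(perfect, function(m) {
    r <- matrix(runif(length(m)), nrow(m)); r / rowSums(r)
  })
  out3 <- roc_auc(noise, ref)
  expect_true(all(abs(out3$auc - 0.5) < 0.12))
})

test_that("outcome categories partition records and conserve counts", {
  labs <- ionm_label_vocabulary()$standard
  set.seed(3)
  ref <- sample(labs, 150, replace = TRUE)
  cal <- tibble::tibble(row = rep(1:150, 3),
                        head = rep(c("nerve", "side", "position"), each = 150),
                        calibrated = runif(450))
  oc <- outcome_categories(ref, ref, cal)
  expect_setequal(unique(oc$records$category), c("TP", "TN"))
  expect_equal(nrow(oc$records), 150 * 3)  # one-vs-rest over 3 nerve classes
  pred <- sample(labs, 150, replace = TRUE)
  oc2 <- outcome_categories(pred, ref, cal)
  expect_equal(nrow(oc2$records), 450)
  expect_equal(sum(oc2$summary$n), 450)
})

test_that("reports render deterministically with Table-1 shape", {
  labs <- ionm_label_vocabulary()$standard
  set.seed(8)
  ref <- sample(labs, 120, replace = TRUE)
  parts <- split_label(ref)
  probs <- list(
    nerve = onehot_m(parts$nerve, c("V", "R", "S")),
    side = onehot_m(parts$side, c("l", "r")),
    position = onehot_m(parts$position, c("1", "2"))
  )
  f <- small_features()
  runs <- repeated_runs(f, k = 2L, base_seed = 11,
                        config = tiny_config(epochs = 2L))
  rep1 <- evaluation_report(runs, ref, ref, probs)
  expect_equal(nrow(rep1$accuracy), 6)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_report(rep1, d1)
  write_report(rep1, d2)
  for (fn in list.files(d1)) {
    if (dir.exists(file.path(d1, fn))) next
    expect_identical(readLines(file.path(d1, fn)),
                     readLines(file.path(d2, fn)))
  }
  expect_true(file.exists(file.path(d1, "accuracy.csv")))
  expect_true(file.exists(file.path(d1, "confusion_combined.csv")))
})

test_that("autoplot methods return ggplot objects", {
  labs <- ionm_label_vocabulary()$standard
  set.seed(2)
  ref <- sample(labs, 60, replace = TRUE)
  pred <- sample(labs, 60, replace = TRUE)
  cm <- confusion_matrix(pred, ref)
  expect_s3_class(ggplot2::autoplot(cm), "ggplot")
  cal <- tibble::tibble(row = rep(1:60, 3),
                        head = rep(c("nerve", "side", "position"), each = 60),
                        calibrated = runif(180))
  oc <- outcome_categories(pred, ref, cal)
  expect_s3_class(ggplot2::autoplot(oc), "ggplot")
  expect_s3_class(plot_training_history(tiny_trained_model()), "ggplot")
})
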