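# Confusion matrices ---------------------------------------------------------

#' Confusion matrix of decoded labels
#'
#' `mode = "combined"` crosses predictions and reference over the 12 joint
#' standard labels; `mode = "per_head"` splits both sides and returns three
#' matrices (nerve 3x3, side 2x2, position 2x2).
#'
#' @param pred,ref Character vectors of standard labels, equal length.
#' @param mode `"combined"` or `"per_head"`.
#' @return An `ionm_confusion` object (long count tibble with the count
#'   matrix in `attr(, "matrix")`), or a named list of them for
#'   `"per_head"`.
#' @export
confusion_matrix <- function(pred, ref, mode = c("combined", "per_head")) {
  mode <- match.arg(mode)
  if (length(pred) != length(ref)) abort("pred and ref lengths differ")
  if (!all(is_standard_label(c(pred, ref)))) {
    abort("labels outside the 12-label vocabulary")
  }
  if (mode == "combined") {
    return(confusion_build(pred, ref, ionm_label_vocabulary()$standard))
  }
  ps <- split_label(pred)
  rs <- split_label(ref)
  list(
    nerve = confusion_build(ps$nerve, rs$nerve, c("V", "R", "S")),
    side = confusion_build(ps$side, rs$side, c("l", "r")),
    position = confusion_build(ps$position, rs$position, c("1", "2"))
  )
}

confusion_build <- function(pred, ref, levels) {
  m <- table(
    reference = factor(ref, levels = levels),
    predicted = factor(pred, levels = levels)
  )
  long <- tibble::as_tibble(m, n = "n")
  structure(long, matrix = unclass(m),
            class = c("ionm_confusion", class(long)))
}

#' @export
print.ionm_confusion <- function(x, ...) {
  m <- attr(x, "matrix")
  cat(sprintf("<ionm_confusion> %d records, accuracy %.4f\n",
              sum(m), confusion_accuracy(x)))
  print(m)
  invisible(x)
}

#' Accuracy recomputed from a confusion matrix diagonal
#'
#' @param cm An `ionm_confusion`.
#' @return Fraction of records on the diagonal.
#' @export
confusion_accuracy <- function(cm) {
  m <- attr(cm, "matrix")
  sum(diag(m)) / sum(m)
}

# ROC / AUC -------------------------------------------------------------------

binary_auc <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Multiclass AUC (Hand-Till mean of pairwise class AUCs)
#'
#' For every unordered pair of observed classes (i, j) the separability
#' A(i|j) is the probability that a class-i row receives a higher class-i
#' score than a class-j row (Mann-Whitney with midranks); the pairwise AUC
#' is the average of A(i|j) and A(j|i), and the multiclass AUC the mean over
#' pairs. Pairs involving an unobserved class are skipped; with fewer than
#' two observed classes the result is the `NA` sentinel.
#'
#' @param scores Numeric matrix of class probabilities, columns named by
#'   class.
#' @param ref Character vector of reference classes.
#' @return A single AUC value.
#' @export
auc_hand_till <- function(scores, ref) {
  present <- intersect(colnames(scores), unique(ref))
  if (length(present) < 2) return(NA_real_)
  pairs <- utils::combn(present, 2, simplify = FALSE)
  aucs <- vapply(pairs, function(pr) {
    rows <- ref %in% pr
    a_ij <- binary_auc(scores[rows, pr[1]], ref[rows] == pr[1])
    a_ji <- binary_auc(scores[rows, pr[2]], ref[rows] == pr[2])
    (a_ij + a_ji) / 2
  }, numeric(1))
  mean(aucs)
}

#' ROC/AUC analysis per head and for the concatenated prediction
#'
#' Per head, the multiclass (Hand-Till) AUC of that head's probabilities.
#' The concatenated mode joins the three heads into a single 12-class
#' distribution (product of head probabilities, renormalized per row) and
#' computes its multiclass AUC against the joint reference labels.
#'
#' @param probs List of per-head probability matrices (as in an
#'   `ionm_posterior$mean` or built from a [predict.ionm_model()] tibble via
#'   [prediction_probs()]).
#' @param ref Character vector of reference standard labels.
#' @param mode `"per_head"`, `"concatenated"` or `"both"`.
#' @return A tibble with columns `output` and `auc`.
#' @export
roc_auc <- function(probs, ref, mode = c("both", "per_head", "concatenated")) {
  mode <- match.arg(mode)
  rs <- split_label(ref)
  out <- list()
  if (mode %in% c("both", "per_head")) {
    refs <- list(nerve = rs$nerve, side = rs$side, position = rs$position)
    cls <- list(nerve = c("V", "R", "S"), side = c("l", "r"),
                position = c("1", "2"))
    for (h in names(refs)) {
      p <- probs[[h]]
      colnames(p) <- sub(paste0("^p_", h, "_"), "",
                         colnames(p) %||% cls[[h]])
      out[[h]] <- tibble::tibble(output = h, auc = auc_hand_till(p, refs[[h]]))
    }
  }
  if (mode %in% c("both", "concatenated")) {
    joint <- concatenated_probs(probs)
    out$concatenated <- tibble::tibble(
      output = "concatenated",
      auc = auc_hand_till(joint, ref)
    )
  }
  dplyr::bind_rows(out)
}

#' Joint 12-class probabilities from the three heads
#'
#' Treats the heads as independent: the probability of label `N p S` is the
#' product of the head probabilities, renormalized across the 12 labels.
#'
#' @param probs List of per-head probability matrices.
#' @return An n x 12 matrix with the standard labels as columns.
#' @export
concatenated_probs <- function(probs) {
  labs <- ionm_label_vocabulary()$standard
  pn <- probs$nerve; ps <- probs$side; pp <- probs$position
  colnames(pn) <- sub("^p_nerve_", "", colnames(pn) %||% c("V", "R", "S"))
  colnames(ps) <- sub("^p_side_", "", colnames(ps) %||% c("l", "r"))
  colnames(pp) <- sub("^p_position_", "", colnames(pp) %||% c("1", "2"))
  joint <- vapply(labs, function(lab) {
    parts <- split_label(lab)
    pn[, parts$nerve] * pp[, parts$position] * ps[, parts$side]
  }, numeric(nrow(pn)))
  joint <- matrix(joint, nrow = nrow(pn),
                  dimnames = list(NULL, labs))
  joint / rowSums(joint)
}

#' Extract the per-head probability matrices from a prediction tibble
#'
#' @param predictions Output of [predict.ionm_model()].
#' @return A list with `nerve`, `side`, `position` matrices.
#' @export
prediction_probs <- function(predictions) {
  list(
    nerve = as.matrix(predictions[paste0("p_nerve_", c("V", "R", "S"))]),
    side = as.matrix(predictions[paste0("p_side_", c("l", "r"))]),
    position = as.matrix(predictions[paste0("p_position_", c("1", "2"))])
  )
}

#' One-vs-rest ROC curve points
#'
#' Per class of a head, TPR/FPR points of the one-vs-rest ROC curve
#' (computed with pROC), exported as a plain tibble for plotting or CSV.
#'
#' @param scores Probability matrix with class columns.
#' @param ref Reference classes.
#' @return A tibble with `class`, `threshold`, `fpr`, `tpr`.
#' @export
roc_curve_points <- function(scores, ref) {
  out <- lapply(colnames(scores), function(cl) {
    resp <- factor(ref == cl, levels = c(FALSE, TRUE))
    if (length(unique(resp)) < 2) return(NULL)
    r <- pROC::roc(response = resp, predictor = scores[, cl],
                   quiet = TRUE, direction = "<")
    tibble::tibble(class = cl, threshold = r$thresholds,
                   fpr = 1 - r$specificities, tpr = r$sensitivities)
  })
  dplyr::bind_rows(out)
}

# Outcome categories -----------------------------------------------------------

#' Stratify records into TP/TN/FP/FN with their uncertainties
#'
#' One-vs-rest categorization per class of one head (default the nerve
#' head): for class c a record is TP when reference and prediction both
#' equal c, TN when neither does, FP when only the prediction does, FN when
#' only the reference does. Calibrated uncertainties are attached so their
#' distribution can be compared across categories.
#'
#' @param pred,ref Character vectors of standard labels.
#' @param calibrated Long tibble (`row`, `head`, `calibrated`), e.g. from
#'   [calibrate_posterior()].
#' @param head Head to stratify on.
#' @return An `ionm_outcomes` object: `records` (row x class x category x
#'   uncertainty) and `summary` (per-category n, median and quartiles).
#' @export
outcome_categories <- function(pred, ref, calibrated, head = "nerve") {
  ps <- split_label(pred)[[head]]
  rs <- split_label(ref)[[head]]
  classes <- switch(head, nerve = c("V", "R", "S"), side = c("l", "r"),
                    position = c("1", "2"))
  unc <- calibrated[calibrated$head == head, c("row", "calibrated")]
  rows <- lapply(classes, function(cl) {
    cat <- dplyr::case_when(
      rs == cl & ps == cl ~ "TP",
      rs != cl & ps != cl ~ "TN",
      rs != cl & ps == cl ~ "FP",
      TRUE ~ "FN"
    )
    tibble::tibble(row = seq_along(cat), class = cl, category = cat)
  })
  records <- dplyr::bind_rows(rows) |>
    dplyr::left_join(unc, by = "row")
  summary <- records |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.data$calibrated, na.rm = TRUE),
      q25 = quantile(.data$calibrated, 0.25, na.rm = TRUE),
      q75 = quantile(.data$calibrated, 0.75, na.rm = TRUE),
      .groups = "drop"
    )
  structure(list(records = records, summary = summary, head = head),
            class = "ionm_outcomes")
}

#' @export
print.ionm_outcomes <- function(x, ...) {
  cat(sprintf("<ionm_outcomes> one-vs-rest on the %s head\n", x$head))
  print(as.data.frame(x$summary))
  invisible(x)
}

# Report -----------------------------------------------------------------------

#' Assemble the evaluation report
#'
#' Bundles the run accuracy table (mean(sd) per output and phase), the
#' combined and per-head confusion matrices of the test predictions, the
#' per-head and concatenated AUCs, and the uncertainty-by-outcome summary.
#'
#' @param runs An `ionm_runs` (or `NULL` for a single run).
#' @param pred,ref Test-set decoded and reference labels.
#' @param probs Per-head probability matrices for the test set.
#' @param outcomes An `ionm_outcomes` or `NULL`.
#' @return An object of class `ionm_report`.
#' @export
evaluation_report <- function(runs = NULL, pred, ref, probs,
                              outcomes = NULL) {
  structure(
    list(
      accuracy = if (!is.null(runs)) runs$table else NULL,
      confusion = confusion_matrix(pred, ref, "combined"),
      confusion_heads = confusion_matrix(pred, ref, "per_head"),
      auc = roc_auc(probs, ref, "both"),
      outcomes = outcomes,
      n = length(ref)
    ),
    class = "ionm_report"
  )
}

#' @export
print.ionm_report <- function(x, ...) {
  cat(sprintf("<ionm_report> %d test records\n", x$n))
  if (!is.null(x$accuracy)) {
    cat("accuracy, % mean(sd):\n")
    print(as.data.frame(x$accuracy[c("output", "phase", "formatted")]))
  }
  cat("AUC:\n")
  print(as.data.frame(x$auc))
  cat(sprintf("combined 12-label accuracy: %.4f\n",
              confusion_accuracy(x$confusion)))
  invisible(x)
}

#' Write an evaluation report to CSV and plain text
#'
#' Deterministic: identical inputs give byte-identical files.
#'
#' @param report An `ionm_report`.
#' @param dir Output directory (created if missing).
#' @return `dir` invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$accuracy)) {
    readr::write_csv(report$accuracy, file.path(dir, "accuracy.csv"),
                     progress = FALSE)
  }
  readr::write_csv(tibble::as_tibble(report$confusion),
                   file.path(dir, "confusion_combined.csv"), progress = FALSE)
  for (h in names(report$confusion_heads)) {
    readr::write_csv(tibble::as_tibble(report$confusion_heads[[h]]),
                     file.path(dir, sprintf("confusion_%s.csv", h)),
                     progress = FALSE)
  }
  readr::write_csv(report$auc, file.path(dir, "auc.csv"), progress = FALSE)
  if (!is.null(report$outcomes)) {
    readr::write_csv(report$outcomes$summary,
                     file.path(dir, "uncertainty_by_outcome.csv"),
                     progress = FALSE)
  }
  txt <- utils::capture.output(print(report))
  readr::write_lines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
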