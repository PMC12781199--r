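#' The standard IONM label vocabulary
#'
#' During thyroid and parathyroid surgery the operating team annotates
#' selected evoked EMG signals with a three-character code: the stimulated
#' nerve (`V` vagal, `R` recurrent laryngeal, `S` external branch of the
#' superior laryngeal), the stimulation time point (`1` before, `2` after
#' resection) and the neck side (`l`/`r`). Everything else stored in the
#' label column ("baseline", "LOS", "artefact", ...) is a free-text
#' annotation, not a classification target.
#'
#' @return A list with two character vectors: `standard` (the 12 standard
#'   labels) and `annotation` (common non-standard annotations; an open set,
#'   listed here only for simulation and examples).
#' @examples
#' ionm_label_vocabulary()$standard
#' @export
ionm_label_vocabulary <- function() {
  list(
    standard = c(
      "V1l", "V2l", "V1r", "V2r",
      "R1l", "R2l", "R1r", "R2r",
      "S1l", "S2l", "S1r", "S2r"
    ),
    annotation = c(
      "baseline", "LOS", "artefact", "change of side",
      "relevant signal reduction", "non-recurrent nerve"
    )
  )
}

#' Test whether labels are standard three-character IONM labels
#'
#' @param label Character vector of stored labels.
#' @return Logical vector.
#' @export
is_standard_label <- function(label) {
  label %in% ionm_label_vocabulary()$standard
}

#' Split a standard label into nerve, side and position
#'
#' The three-character standard label is decomposed so that nerve, side and
#' stimulation time point can be predicted by separate model heads.
#'
#' @param label Character vector of standard labels (e.g. `"V1l"`).
#' @return A tibble with columns `nerve` (`V`/`R`/`S`), `side` (`l`/`r`) and
#'   `position` (`"1"`/`"2"`), one row per input label.
#' @examples
#' split_label(c("V1l", "S2r"))
#' @export
split_label <- function(label) {
  bad <- !is_standard_label(label)
  if (any(bad)) {
    abort(sprintf(
      "non-standard label(s): %s",
      paste(unique(label[bad]), collapse = ", ")
    ))
  }
  tibble::tibble(
    nerve = substr(label, 1L, 1L),
    side = substr(label, 3L, 3L),
    position = substr(label, 2L, 2L)
  )
}

#' Join nerve, side and position back into a standard label
#'
#' Inverse of [split_label()]: `join_label(split_label(x))` reproduces `x`.
#'
#' @param nerve Character vector in `{V, R, S}`, or a data frame with columns
#'   `nerve`, `side`, `position` (as returned by [split_label()]).
#' @param side Character vector in `{l, r}`.
#' @param position Character vector in `{1, 2}`.
#' @return Character vector of standard labels.
#' @export
join_label <- function(nerve, side = NULL, position = NULL) {
  if (is.data.frame(nerve)) {
    side <- nerve$side
    position <- nerve$position
    nerve <- nerve$nerve
  }
  out <- paste0(nerve, position, side)
  bad <- !is_standard_label(out)
  if (any(bad)) {
    abort(sprintf(
      "invalid label component(s) producing: %s",
      paste(unique(out[bad]), collapse = ", ")
    ))
  }
  out
}
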