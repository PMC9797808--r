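#' Standardize a numeric vector (sample z-scores)
#'
#' `(x - mean(x)) / sd(x)` with the n-1 denominator sample SD, using the
#' analysis sample's own mean and SD (no external norms).
#'
#' @param x Numeric vector with at least 2 values and nonzero SD.
#' @param name Column name used in error messages.
#' @return Numeric vector with sample mean 0 and sample SD 1.
#' @export
zscore <- function(x, name = deparse(substitute(x))) {
  if (length(x) < 2 || anyNA(x) || !is.numeric(x)) {
    abort(paste0("`", name, "` must be numeric, complete, length >= 2."),
          class = "sysseg_validation_error")
  }
  s <- sd(x)
  if (s == 0) {
    abort(paste0("Cannot z-score constant column `", name, "`."),
          class = "sysseg_validation_error")
  }
  (x - mean(x)) / s
}

#' Add the repetitive negative thinking (RNT) composite to a cohort table
#'
#' The RNT composite is the sum of the within-sample z-scores of the three
#' RNT questionnaires: perseverative thinking (PTQ), worry (PSWQ) and
#' rumination (RRS). It is invariant to positive affine rescaling of any
#' component questionnaire.
#'
#' @param data Cohort data frame.
#' @param ptq,pswq,rrs Column names of the three questionnaire totals.
#' @param name Name of the new composite column.
#' @return `data` as a tibble with z-score columns (`z_<col>`) and the
#'   composite column appended.
#' @export
rnt_composite <- function(data, ptq = "ptq", pswq = "pswq", rrs = "rrs",
                          name = "rnt") {
  cols <- c(ptq, pswq, rrs)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "sysseg_validation_error")
  }
  out <- tibble::as_tibble(data)
  zs <- purrr::map(cols, function(cl) zscore(out[[cl]], name = cl))
  for (i in seq_along(cols)) out[[paste0("z_", cols[i])]] <- zs[[i]]
  out[[name]] <- zs[[1]] + zs[[2]] + zs[[3]]
  out
}

#' Reverse-score Likert items
#'
#' Maps a response `raw` on a `item_min..item_max` scale to
#' `item_min + item_max - raw`, e.g. for the cognitive-complaints scale
#' whose 5-point items are reversed so that higher scores mean greater
#' complaints.
#'
#' @param raw Integer vector of raw responses.
#' @param item_min,item_max Scale bounds.
#' @return Reversed responses.
#' @export
reverse_score <- function(raw, item_min, item_max) {
  if (any(raw < item_min | raw > item_max, na.rm = TRUE)) {
    abort(paste0("Responses outside [", item_min, ", ", item_max, "]."),
          class = "sysseg_validation_error")
  }
  item_min + item_max - raw
}

#' Cronbach's alpha (internal consistency)
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))` with
#' n-1 sample variances.
#'
#' @param items An n x k numeric matrix or data frame of item responses
#'   (n >= 3 subjects, k >= 2 items).
#' @return The alpha coefficient (scalar).
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  if (nrow(m) < 3 || ncol(m) < 2 || anyNA(m)) {
    abort("Need a complete matrix with >= 3 subjects and >= 2 items.",
          class = "sysseg_validation_error")
  }
  k <- ncol(m)
  vt <- var(rowSums(m))
  if (vt == 0) {
    abort("Total-score variance is zero; alpha undefined.",
          class = "sysseg_undefined_error")
  }
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / vt)
}

#' Describe a questionnaire instrument
#'
#' @param name Instrument name.
#' @param item_count Number of items.
#' @param item_min,item_max Per-item response bounds.
#' @param reverse_scored Should raw items be reversed before summing?
#' @param subscales Named list of item-index vectors (e.g. the brooding
#'   subset of the rumination scale).
#' @return A `questionnaire_spec` list.
#' @export
questionnaire_spec <- function(name, item_count, item_min, item_max,
                               reverse_scored = FALSE, subscales = list()) {
  stopifnot(item_min < item_max, item_count >= 1)
  for (s in subscales) {
    if (!all(s %in% seq_len(item_count))) {
      abort("Subscale indices must lie in 1..item_count.",
            class = "sysseg_validation_error")
    }
  }
  structure(list(name = name, item_count = item_count, item_min = item_min,
                 item_max = item_max, reverse_scored = reverse_scored,
                 subscales = subscales),
            class = "questionnaire_spec")
}

#' Default questionnaire battery
#'
#' The six instruments of the RNT study battery. Items are scored 0-based
#' (consistent with the cohort's printed score ranges) except emotional
#' stability, whose published total range is 10-50 (1..5 items):
#' * `ptq` - perseverative thinking, 15 items, 0..4
#' * `pswq` - worry, 8 items, 0..4
#' * `rrs` - rumination, 22 items, 0..3, with the maladaptive `brooding`
#'   subscale (items 5, 10, 13, 15, 16)
#' * `dass` - depression/anxiety/stress short form, 21 items, 0..3
#' * `promis` - subjective cognitive complaints, 12 items, 0..4,
#'   reverse-scored so higher totals mean more complaints
#' * `ipip_es` - emotional stability, 10 items, 1..5
#' @return Named list of [questionnaire_spec()] objects.
#' @export
default_questionnaires <- function() {
  list(
    ptq = questionnaire_spec("ptq", 15, 0, 4),
    pswq = questionnaire_spec("pswq", 8, 0, 4),
    rrs = questionnaire_spec("rrs", 22, 0, 3,
                             subscales = list(brooding = c(5, 10, 13, 15, 16))),
    dass = questionnaire_spec("dass", 21, 0, 3),
    promis = questionnaire_spec("promis", 12, 0, 4, reverse_scored = TRUE),
    ipip_es = questionnaire_spec("ipip_es", 10, 1, 5)
  )
}

#' Score a questionnaire from item-level data
#'
#' Applies reverse scoring when the instrument requires it, then sums items
#' into a total and any configured subscale totals.
#'
#' @param items n x k data frame/matrix of raw item responses (columns in
#'   item order).
#' @param spec A [questionnaire_spec()].
#' @return A tibble with column `total` and one column per subscale.
#' @export
score_questionnaire <- function(items, spec) {
  stopifnot(inherits(spec, "questionnaire_spec"))
  m <- as.matrix(items)
  if (ncol(m) != spec$item_count) {
    abort(paste0("`", spec$name, "` expects ", spec$item_count,
                 " items, got ", ncol(m), "."),
          class = "sysseg_validation_error")
  }
  if (any(m < spec$item_min | m > spec$item_max, na.rm = TRUE)) {
    abort(paste0("`", spec$name, "` has responses outside [",
                 spec$item_min, ", ", spec$item_max, "]."),
          class = "sysseg_validation_error")
  }
  if (spec$reverse_scored) {
    m <- reverse_score(m, spec$item_min, spec$item_max)
  }
  out <- tibble::tibble(total = rowSums(m))
  for (nm in names(spec$subscales)) {
    out[[nm]] <- rowSums(m[, spec$subscales[[nm]], drop = FALSE])
  }
  out
}
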