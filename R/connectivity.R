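#' ROI-to-ROI functional connectivity (thresholded Fisher-z)
#'
#' Computes the resting-state functional connectivity (rs-FC) matrix from a
#' subject's ROI time series: pairwise Pearson correlations between ROI
#' signals, Fisher-z transformed (`atanh`), with negative values set to zero
#' and the diagonal (autocorrelations) excluded from every later average.
#'
#' @param ts A numeric T x R matrix or data frame of ROI time series; rows
#'   are timepoints, columns are ROIs. Column names become ROI ids.
#' @param subject_id Optional subject identifier stored on the result.
#' @return An R x R symmetric matrix of class `connectivity` with
#'   non-negative Fisher-z values off the diagonal and `NA` on the diagonal
#'   (masked, never averaged).
#' @details Correlations are clipped to +/-(1 - 1e-12) before `atanh` so a
#'   perfectly (anti)correlated pair maps to a large finite value rather
#'   than +/-Inf. Because `atanh` preserves sign, zeroing negatives after
#'   the transform equals zeroing the correlations first. Inputs must have
#'   at least 3 timepoints, no non-finite values and no constant ROI
#'   (Pearson r is undefined there); such inputs raise a
#'   `sysseg_validation_error` naming the offending ROI.
#' @examples
#' set.seed(1)
#' ts <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("r", 1:4)))
#' compute_connectivity(ts)
#' @export
compute_connectivity <- function(ts, subject_id = NULL) {
  m <- as.matrix(ts)
  if (!is.numeric(m)) {
    abort("Time series must be numeric.", class = "sysseg_validation_error")
  }
  if (nrow(m) < 3) {
    abort(paste0("Need at least 3 timepoints; got ", nrow(m), "."),
          class = "sysseg_validation_error")
  }
  if (ncol(m) < 2) {
    abort("Need at least 2 ROIs.", class = "sysseg_validation_error")
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("roi", seq_len(ncol(m)))
  if (!all(is.finite(m))) {
    bad <- colnames(m)[apply(m, 2, function(x) any(!is.finite(x)))]
    abort(paste0("Non-finite values in ROI(s): ", paste(bad, collapse = ", ")),
          class = "sysseg_validation_error")
  }
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(m)[sds == 0]
    abort(paste0("Constant (zero-variance) ROI(s): ",
                 paste(bad, collapse = ", ")),
          class = "sysseg_validation_error")
  }
  r <- cor(m)
  r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  z <- atanh(r)
  z[z < 0] <- 0
  diag(z) <- NA_real_
  structure(z, class = c("connectivity", "matrix", "array"),
            subject_id = subject_id)
}

#' @export
print.connectivity <- function(x, ...) {
  cat("<connectivity> ", ncol(x), " x ", ncol(x),
      " Fisher-z rs-FC matrix (diagonal masked)\n", sep = "")
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))], ...)
  invisible(x)
}

#' Tidy a connectivity matrix into long edge form
#'
#' @param x A `connectivity` matrix.
#' @param ... Unused.
#' @return A tibble with one row per unordered ROI pair: `roi_a`, `roi_b`,
#'   `fc` (thresholded Fisher-z value).
#' @exportS3Method generics::tidy
tidy.connectivity <- function(x, ...) {
  rois <- colnames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(
    roi_a = rois[idx[, 1]],
    roi_b = rois[idx[, 2]],
    fc = unclass(x)[idx]
  )
}

#' Heatmap of a connectivity matrix
#'
#' @param object A `connectivity` matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.connectivity <- function(object, ...) {
  rois <- colnames(object)
  df <- tidyr::expand_grid(roi_a = rois, roi_b = rois)
  df$fc <- unclass(object)[cbind(match(df$roi_a, rois), match(df$roi_b, rois))]
  df$roi_a <- factor(df$roi_a, levels = rois)
  df$roi_b <- factor(df$roi_b, levels = rev(rois))
  ggplot2::ggplot(df, ggplot2::aes(.data$roi_a, .data$roi_b, fill = .data$fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z-FC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Read ROI time series from delimited text
#'
#' Wide format: T rows x R columns with a header row of ROI ids. Long
#' format: columns `roi`, `t`, `value` (plus optionally `subject`); set
#' `long = TRUE`.
#'
#' @param path CSV/TSV file path (delimiter inferred from extension).
#' @param long Is the file in long format?
#' @return A T x R numeric matrix with ROI ids as column names.
#' @export
read_timeseries <- function(path, long = FALSE) {
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  df <- reader(path, show_col_types = FALSE)
  if (long) {
    need <- c("roi", "t", "value")
    if (!all(need %in% names(df))) {
      abort("Long-format time series needs columns roi, t, value.",
            class = "sysseg_validation_error")
    }
    wide <- tidyr::pivot_wider(df[need], names_from = "roi",
                               values_from = "value")
    wide <- wide[order(wide$t), , drop = FALSE]
    m <- as.matrix(wide[setdiff(names(wide), "t")])
  } else {
    m <- as.matrix(df)
  }
  storage.mode(m) <- "double"
  m
}
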