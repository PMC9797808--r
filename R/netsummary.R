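#' System segregation index
#'
#' The relative excess of within-network over between-network connectivity,
#' `(W - B) / W`. It is 1 when a network is fully segregated (B = 0), 0 when
#' within- and between-network connectivity are balanced (W = B), and
#' negative when a network talks more to the rest of the cortex than within
#' itself.
#'
#' @param w Mean within-network connectivity; must be > 0.
#' @param b Mean between-network connectivity; must be >= 0.
#' @return `(w - b) / w`, vectorised over `w` and `b`.
#' @examples
#' system_segregation(0.5, 0.1) # 0.8
#' @export
system_segregation <- function(w, b) {
  if (any(!is.finite(w)) || any(!is.finite(b))) {
    abort("W and B must be finite.", class = "sysseg_validation_error")
  }
  if (any(w <= 0)) {
    abort("System segregation is undefined for W <= 0.",
          class = "sysseg_undefined_error")
  }
  if (any(b < 0)) {
    abort("B must be non-negative.", class = "sysseg_validation_error")
  }
  (w - b) / w
}

#' Per-network connectivity summary: W, B and system segregation
#'
#' For every network in the parcellation, averages the thresholded Fisher-z
#' connectivity over (i) all unordered within-network ROI pairs (`w`) and
#' (ii) all pairs linking a network ROI to every other ROI of the
#' parcellation, regardless of that ROI's network ("rest of the cortex",
#' `b`), and forms the segregation index `sys = (w - b) / w`.
#'
#' @param conn A `connectivity` matrix from [compute_connectivity()] whose
#'   columns match `parc$roi` in order (or by name if named).
#' @param parc A [parcellation()].
#' @return A tibble of class `network_summary` with columns `network`,
#'   `n_roi`, `w`, `b`, `sys` and logical `sys_defined`. When a network's
#'   `w` is 0 its `sys` is `NA` and `sys_defined` is `FALSE` (flagged, the
#'   rest of the summary is still returned).
#' @details Supplying a parcellation restricted to the networks under study
#'   versus the full atlas changes `b` (the "rest of the cortex" is defined
#'   by the parcellation you pass); the full atlas is the conventional
#'   choice.
#' @export
network_summary <- function(conn, parc) {
  stopifnot(inherits(parc, "parcellation"))
  z <- align_conn(conn, parc)
  nets <- network_levels(parc)
  v <- net_summary_values(z, parc)
  out <- tibble::tibble(
    network = factor(nets, levels = nets),
    n_roi = v$sizes, w = unname(v$w), b = unname(v$b), sys = unname(v$sys),
    sys_defined = v$defined
  )
  class(out) <- c("network_summary", class(out))
  out
}

# W, B, SyS and pairwise means as plain named vectors/matrix (hot path)
net_summary_values <- function(z, parc) {
  nets <- network_levels(parc)
  sums <- net_block_sums(z, parc)  # K x K matrix of edge-value sums
  sizes <- tabulate(as.integer(parc$network), nbins = length(nets))
  r_total <- nrow(parc)
  w <- diag(sums) / 2 / choose(sizes, 2)
  b <- (rowSums(sums) - diag(sums)) / (sizes * (r_total - sizes))
  defined <- is.finite(w) & w > 0
  pair <- sums / outer(sizes, sizes)
  dimnames(pair) <- list(nets, nets)
  list(sizes = sizes, w = setNames(w, nets), b = setNames(b, nets),
       sys = setNames(ifelse(defined, (w - b) / w, NA_real_), nets),
       defined = defined, pair = pair)
}

# sum of connectivity values between each pair of networks (and, on the
# diagonal, twice the within-network pair sum); diagonal of z is ignored
net_block_sums <- function(z, parc) {
  idx <- as.integer(parc$network)
  zs <- z
  diag(zs) <- 0
  by_row <- rowsum(zs, idx, reorder = TRUE)
  t(rowsum(t(by_row), idx, reorder = TRUE))
}

#' Mean connectivity between every pair of networks
#'
#' @inheritParams network_summary
#' @return A tibble with one row per ordered network pair (`net_a`,
#'   `net_b`, `fc`); the table is symmetric in its two network columns, so
#'   `fc(A, B) == fc(B, A)`.
#' @export
pairwise_connectivity <- function(conn, parc) {
  stopifnot(inherits(parc, "parcellation"))
  z <- align_conn(conn, parc)
  nets <- network_levels(parc)
  means <- net_summary_values(z, parc)$pair
  off <- which(row(means) != col(means))
  tibble::tibble(net_a = nets[row(means)[off]], net_b = nets[col(means)[off]],
                 fc = means[off])
}

# check dimensions/ordering of a connectivity matrix against a parcellation
align_conn <- function(conn, parc) {
  z <- unclass(conn)
  if (ncol(z) != nrow(parc)) {
    abort(paste0("Connectivity matrix has ", ncol(z),
                 " ROIs but the parcellation has ", nrow(parc), "."),
          class = "sysseg_validation_error")
  }
  cn <- colnames(z)
  if (!is.null(cn) && all(parc$roi %in% cn)) {
    z <- z[parc$roi, parc$roi]
  }
  z
}

#' Bar plot of within/between connectivity and segregation per network
#'
#' @param object A `network_summary` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.network_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("w", "b", "sys"),
                              names_to = "measure", values_to = "value")
  long$measure <- factor(long$measure, levels = c("w", "b", "sys"),
                         labels = c("within (W)", "between (B)",
                                    "segregation (SyS)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$network, .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Per-subject network summaries for a set of subjects
#'
#' Convenience wrapper mapping [compute_connectivity()] +
#' [network_summary()] over a named list of time-series matrices.
#'
#' @param ts_list Named list of T x R matrices (names are subject ids).
#' @param parc A [parcellation()].
#' @return A tidy tibble: `subject`, `network`, `w`, `b`, `sys`.
#' @export
cohort_network_summary <- function(ts_list, parc) {
  purrr::imap(ts_list, function(ts, id) {
    s <- network_summary(compute_connectivity(ts, subject_id = id), parc)
    dplyr::mutate(tibble::as_tibble(s), subject = id, .before = 1)
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("subject", "network", "w", "b", "sys")
}
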