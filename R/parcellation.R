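#' Define a parcellation: ROIs grouped into named networks
#'
#' A parcellation maps each region of interest (ROI) to exactly one named
#' functional network (e.g. LECN, RECN, ASN, dDMN, vDMN plus the remaining
#' cortical networks of a functional atlas). It defines the within-network,
#' between-network and "rest of cortex" edge sets used by
#' [network_summary()].
#'
#' @param df Data frame with columns `roi` (unique ROI identifiers, in the
#'   column order of the time-series matrices) and `network` (network label).
#' @return A tibble of class `parcellation` with columns `roi` and `network`.
#'   Network order follows first appearance and is kept stable downstream.
#' @details Constraints: at least 4 ROIs, at least 2 distinct networks, each
#'   ROI in exactly one network, and every network must contain at least 2
#'   ROIs (a within-network mean needs at least one ROI pair).
#' @examples
#' parcellation(data.frame(
#'   roi = paste0("r", 1:6),
#'   network = rep(c("LECN", "ASN", "dDMN"), each = 2)
#' ))
#' @export
parcellation <- function(df) {
  if (!is.data.frame(df) || !all(c("roi", "network") %in% names(df))) {
    abort("`df` must be a data frame with columns `roi` and `network`.",
          class = "sysseg_validation_error")
  }
  out <- tibble::as_tibble(df[c("roi", "network")])
  out$roi <- as.character(out$roi)
  out$network <- as.character(out$network)
  if (anyNA(out$roi) || anyNA(out$network)) {
    abort("Parcellation contains missing ROI ids or network labels.",
          class = "sysseg_validation_error")
  }
  if (anyDuplicated(out$roi)) {
    dup <- unique(out$roi[duplicated(out$roi)])
    abort(paste0("Duplicated ROI ids: ", paste(dup, collapse = ", ")),
          class = "sysseg_validation_error")
  }
  if (nrow(out) < 4) {
    abort("A parcellation needs at least 4 ROIs.",
          class = "sysseg_validation_error")
  }
  nets <- unique(out$network)
  if (length(nets) < 2) {
    abort("A parcellation needs at least 2 distinct networks.",
          class = "sysseg_validation_error")
  }
  sizes <- table(out$network)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    abort(paste0("Every network needs >= 2 ROIs; too small: ",
                 paste(small, collapse = ", ")),
          class = "sysseg_validation_error")
  }
  out$network <- factor(out$network, levels = nets)
  class(out) <- c("parcellation", class(out))
  out
}

#' Read a parcellation from a two-column CSV
#'
#' @param path CSV file with columns `roi` and `network` (header required).
#' @return A [parcellation()] tibble.
#' @export
read_parcellation <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  parcellation(df)
}

#' @export
print.parcellation <- function(x, ...) {
  cat("<parcellation> ", nrow(x), " ROIs in ", nlevels(x$network),
      " networks\n", sep = "")
  NextMethod()
}

# network labels in stable order
network_levels <- function(parc) levels(parc$network)
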