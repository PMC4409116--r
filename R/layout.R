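#' Electrode layouts and cluster pooling tables
#'
#' A layout assigns each channel a label, a schematic 2-D scalp position
#' (x lateral, right positive; y anterior positive; unit head radius), a
#' hemisphere (L/R/Z) and one of six region clusters: OC (occipital),
#' P (parietal), PT (parieto-temporal), CE (central), FR (frontal) and
#' AT (anterior-temporal). The default table ships as a plain TSV and is
#' meant to be edited for other montages.
#'
#' @name electrode_layout
NULL

#' Read an electrode layout table
#'
#' @param path TSV file with columns `label`, `x`, `y`, `hemisphere`,
#'   `cluster`.
#' @return data.frame of class `electrode_layout`.
#' @export
read_layout <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("label", "x", "y", "hemisphere", "cluster")
  if (!all(required %in% names(df))) {
    stopf("erm_bad_input", "layout must have columns: %s",
          paste(required, collapse = ", "))
  }
  if (anyDuplicated(df$label)) {
    stopf("erm_bad_input", "duplicate channel labels in layout")
  }
  if (any(is.na(df$cluster) | df$cluster == "")) {
    stopf("erm_bad_input", "every channel must be assigned a cluster")
  }
  class(df) <- c("electrode_layout", "data.frame")
  df
}

#' Default 62-channel 10-10 layout
#'
#' Standard 10-10 labels with schematic positions and the six-cluster
#' assignment used for pooling. Editable: copy the shipped TSV, adjust, and
#' load it with [read_layout()].
#'
#' @return data.frame of class `electrode_layout` (62 channels).
#' @export
default_layout <- function() {
  read_layout(system.file("extdata", "layout_1010.tsv", package = "ermtools",
                          mustWork = TRUE))
}

#' Restrict a layout to a channel subset
#'
#' @param layout an `electrode_layout`.
#' @param channels labels to keep (order preserved).
#' @return the restricted layout.
#' @export
subset_layout <- function(layout, channels) {
  idx <- match(channels, layout$label)
  if (anyNA(idx)) {
    stopf("erm_bad_input", "channels not in layout: %s",
          paste(channels[is.na(idx)], collapse = ", "))
  }
  out <- layout[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
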