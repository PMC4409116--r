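#' Channel-wise condition statistics, pooling and topographies
#'
#' Group-level testing of contour vs non-contour amplitude differences: per
#' channel, the difference of absolute windowed amplitudes
#' `d_i = |amp_CT,i| - |amp_NCT,i|` across subjects i is tested against zero
#' with a two-sided paired t-test, and tiered at alpha = 0.05 / 0.01 / 0.001.
#' No multiple-comparison correction is applied; reporting is per channel.
#'
#' @name channel_stats
NULL

sig_tier <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Paired channel-wise amplitude-difference tests
#'
#' @param amp_ct,amp_nct numeric matrices subjects x channels of (signed)
#'   window-mean amplitudes for the two conditions; absolute values are taken
#'   internally. Column names carry the channel labels.
#' @param channels optional channel labels (defaults to column names).
#' @param mode mode index the amplitudes were measured on (metadata).
#' @param window the [window_def()] used (metadata).
#' @return data.frame of class `channel_stats` with columns `channel`,
#'   `mean_diff` (group mean of d, sign convention CT - NCT), `t_value`,
#'   `p_value`, `tier`.
#' @export
condition_difference_stats <- function(amp_ct, amp_nct, channels = NULL,
                                       mode = NA_integer_, window = NULL) {
  amp_ct <- as.matrix(amp_ct)
  amp_nct <- as.matrix(amp_nct)
  if (!all(dim(amp_ct) == dim(amp_nct))) {
    stopf("erm_dim_mismatch", "amplitude matrices must have equal dimensions")
  }
  n_sub <- nrow(amp_ct)
  if (n_sub < 2L) {
    stopf("erm_bad_input", "paired testing needs at least 2 subjects")
  }
  channels <- channels %||% colnames(amp_ct) %||%
    paste0("ch", seq_len(ncol(amp_ct)))
  d <- abs(amp_ct) - abs(amp_nct)
  res <- data.frame(channel = channels, mean_diff = NA_real_,
                    t_value = NA_real_, p_value = NA_real_,
                    tier = NA_character_, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(d))) {
    dj <- d[, j]
    m <- mean(dj)
    s <- stats::sd(dj)
    if (s == 0) {
      # degenerate: all paired differences identical
      tv <- if (m == 0) 0 else sign(m) * Inf
      pv <- if (m == 0) 1 else 0
    } else {
      tv <- m / (s / sqrt(n_sub))
      pv <- 2 * stats::pt(-abs(tv), df = n_sub - 1L)
    }
    res$mean_diff[j] <- m
    res$t_value[j] <- tv
    res$p_value[j] <- pv
  }
  res$tier <- sig_tier(res$p_value)
  attr(res, "mode") <- mode
  attr(res, "window") <- window
  attr(res, "n_subjects") <- n_sub
  class(res) <- c("channel_stats", "data.frame")
  res
}

#' Pool ERMs over an electrode cluster
#'
#' Samplewise mean of one mode (or a partial reconstruction) over the
#' channels of a layout cluster, separately per condition.
#'
#' @param erms an [erm_set()].
#' @param layout an `electrode_layout` covering the ERM channels.
#' @param cluster cluster name (`"OC"`, `"P"`, `"PT"`, `"CE"`, `"FR"`,
#'   `"AT"`).
#' @param mode mode index or indices to sum before pooling (default 5).
#' @param hemisphere optional `"L"` / `"R"` restriction.
#' @return numeric matrix conditions x samples, with an attribute `channels`
#'   listing the pooled labels.
#' @export
pool_electrodes <- function(erms, layout, cluster, mode = 5L,
                            hemisphere = NULL) {
  stopifnot(inherits(erms, "erm_set"))
  members <- layout$label[layout$cluster == cluster]
  if (!is.null(hemisphere)) {
    members <- intersect(members,
                         layout$label[layout$hemisphere == hemisphere])
  }
  members <- intersect(members, erms$channels)
  if (!length(members)) {
    stopf("erm_bad_input", "cluster %s has no channels in this ERM set",
          cluster)
  }
  series <- erm_partial_reconstruction(erms, modes = mode)
  idx <- match(members, erms$channels)
  pooled <- apply(series[idx, , , drop = FALSE], c(2L, 3L), mean)
  rownames(pooled) <- erms$conditions
  attr(pooled, "channels") <- members
  pooled
}

#' Scalp map of group differences with a significance mask
#'
#' Joins channel statistics onto layout positions: the value at each channel
#' is the group mean difference, the mask flags channels whose tier is not
#' `ns`. Channels present in the layout but missing from the statistics are
#' an error, not silently dropped.
#'
#' @param stats a `channel_stats` table.
#' @param layout an `electrode_layout`.
#' @return data.frame with columns `label`, `x`, `y`, `value`,
#'   `significant`, `tier`.
#' @export
topography_values <- function(stats, layout) {
  idx <- match(layout$label, stats$channel)
  if (anyNA(idx)) {
    stopf("erm_missing_channel", "no statistics for channel(s): %s",
          paste(layout$label[is.na(idx)], collapse = ", "))
  }
  data.frame(
    label = layout$label, x = layout$x, y = layout$y,
    value = stats$mean_diff[idx],
    significant = stats$tier[idx] != "ns",
    tier = stats$tier[idx],
    stringsAsFactors = FALSE
  )
}

#' Interpolate a topography onto a regular grid
#'
#' Inverse-distance-squared weighting of the channel values; a grid point
#' coinciding with a channel position reproduces that channel's value
#' exactly.
#'
#' @param topo a [topography_values()] table.
#' @param grid_n grid resolution per axis (default 32).
#' @return list with vectors `x`, `y` and matrix `value` (`grid_n` square).
#' @export
interpolate_topography <- function(topo, grid_n = 32L) {
  gx <- seq(min(topo$x), max(topo$x), length.out = grid_n)
  gy <- seq(min(topo$y), max(topo$y), length.out = grid_n)
  val <- matrix(NA_real_, grid_n, grid_n)
  for (i in seq_len(grid_n)) {
    for (j in seq_len(grid_n)) {
      d2 <- (topo$x - gx[i])^2 + (topo$y - gy[j])^2
      hit <- which(d2 == 0)
      val[j, i] <- if (length(hit)) topo$value[hit[1L]] else
        sum(topo$value / d2) / sum(1 / d2)
    }
  }
  list(x = gx, y = gy, value = val)
}
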