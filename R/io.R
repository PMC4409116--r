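#' Readers, writers and the end-to-end pipeline driver
#'
#' Interchange formats are plain text: trial tensors as delimited matrices
#' (channels x samples per trial, trials concatenated column-wise) with a
#' JSON sidecar carrying labels, sampling metadata, per-trial conditions and
#' any ground truth; mode sets as delimited matrices with a JSON header.
#' Every writer embeds a format version; readers reject versions they do not
#' know.
#'
#' @name cli_io
NULL

FORMAT_VERSION <- 1L

#' Write a trial tensor
#'
#' @param tt a [trial_tensor()].
#' @param path output TSV path for the numeric matrix.
#' @param sidecar_path output JSON path (default: `path` with `.json`
#'   appended).
#' @return invisibly, `path`.
#' @export
write_trials <- function(tt, path, sidecar_path = paste0(path, ".json")) {
  stopifnot(inherits(tt, "trial_tensor"))
  d <- dim(tt$data)
  flat <- matrix(tt$data, nrow = d[1L])  # channels x (samples * trials)
  utils::write.table(flat, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(format_version = FORMAT_VERSION,
         subject_id = tt$subject_id, channels = tt$channels,
         sample_rate = tt$sample_rate, onset_index = tt$onset_index,
         n_samples = d[2L], n_trials = d[3L],
         conditions = tt$conditions,
         ground_truth = tt$ground_truth),
    sidecar_path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Read a trial tensor
#'
#' Validates matrix dimensions against the sidecar, condition labels and
#' finiteness; each failure is reported distinctly.
#'
#' @param path TSV matrix path.
#' @param sidecar_path JSON sidecar path (default: `path` + `.json`).
#' @return a [trial_tensor()].
#' @export
read_trials <- function(path, sidecar_path = paste0(path, ".json")) {
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(meta$format_version) || meta$format_version != FORMAT_VERSION) {
    stopf("erm_format_version", "unknown trial-file format version: %s",
          meta$format_version %||% "missing")
  }
  flat <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  n_ch <- length(meta$channels)
  if (nrow(flat) != n_ch) {
    stopf("erm_dim_mismatch",
          "sidecar declares %d channels but matrix has %d rows",
          n_ch, nrow(flat))
  }
  expected_cols <- meta$n_samples * meta$n_trials
  if (ncol(flat) != expected_cols) {
    stopf("erm_dim_mismatch",
          "sidecar declares %d samples x %d trials but matrix has %d columns",
          meta$n_samples, meta$n_trials, ncol(flat))
  }
  data <- array(flat, dim = c(n_ch, meta$n_samples, meta$n_trials))
  trial_tensor(meta$subject_id, meta$channels, data, meta$conditions,
               meta$sample_rate, meta$onset_index,
               ground_truth = meta$ground_truth)
}

#' Write a mode set as a delimited matrix with a JSON header
#'
#' @param ms a [mode_set()].
#' @param path output TSV path.
#' @param header_path JSON header path (default: `path` + `.json`).
#' @return invisibly, `path`.
#' @export
write_mode_set <- function(ms, path, header_path = paste0(path, ".json")) {
  stopifnot(inherits(ms, "mode_set"))
  utils::write.table(ms$modes, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(format_version = FORMAT_VERSION, sample_rate = ms$sample_rate,
         n_modes = nrow(ms$modes), n_samples = ncol(ms$modes),
         meta = ms$meta),
    header_path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a mode set
#'
#' @param path TSV matrix path.
#' @param header_path JSON header path (default: `path` + `.json`).
#' @return a [mode_set()].
#' @export
read_mode_set <- function(path, header_path = paste0(path, ".json")) {
  meta <- jsonlite::read_json(header_path, simplifyVector = TRUE)
  if (is.null(meta$format_version) || meta$format_version != FORMAT_VERSION) {
    stopf("erm_format_version", "unknown mode-set format version: %s",
          meta$format_version %||% "missing")
  }
  modes <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(modes) <- NULL
  mode_set(modes, as.numeric(meta$sample_rate), as.list(meta$meta))
}

#' Pipeline run configuration
#'
#' Bundles every stage parameter of the end-to-end analysis. Either
#' `sim` (an [eeg_sim_config()]) or `input_paths` (TSV paths readable with
#' [read_trials()]) must be supplied.
#'
#' @param sim an [eeg_sim_config()] to simulate the dataset, or `NULL`.
#' @param input_paths character vector of trial-tensor files, or `NULL`.
#' @param eemd an [eemd_config()].
#' @param approach `"A"` (decompose averages) or `"B"` (average
#'   decompositions).
#' @param windows list of [window_def()]s to analyze.
#' @param stat_modes mode indices summed before windowed statistics
#'   (default 3:7, the denoised partial reconstruction).
#' @param pool_mode mode index pooled per cluster (default 5).
#' @param layout an `electrode_layout`.
#' @param seed master seed; all stage randomness derives from it.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return object of class `run_config`.
#' @export
run_config <- function(sim = NULL, input_paths = NULL,
                       eemd = eemd_config(), approach = c("A", "B"),
                       windows = list(
                         window_def("P100", "early"),
                         window_def("P100", "late"),
                         window_def("N200", "early"),
                         window_def("N200", "late")),
                       stat_modes = 3:7, pool_mode = 5L,
                       layout = default_layout(), seed = 1L,
                       out_dir = NULL) {
  approach <- match.arg(approach)
  if (is.null(sim) && is.null(input_paths)) {
    stopf("erm_bad_input", "either sim or input_paths must be given")
  }
  structure(
    list(sim = sim, input_paths = input_paths, eemd = eemd,
         approach = approach, windows = windows, stat_modes = stat_modes,
         pool_mode = pool_mode, layout = layout, seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

# Serializable echo of the configuration for output headers.
config_echo <- function(config) {
  list(
    approach = config$approach, seed = config$seed,
    eemd = unclass(config$eemd),
    stat_modes = config$stat_modes, pool_mode = config$pool_mode,
    windows = lapply(config$windows, unclass),
    simulated = !is.null(config$sim),
    sim = if (!is.null(config$sim)) {
      s <- unclass(config$sim)
      s[c("n_subjects", "n_trials_per_condition", "sample_rate",
          "pre_samples", "post_samples", "noise_exponent", "noise_sd",
          "seed")]
    }
  )
}

#' Run the end-to-end analysis
#'
#' Simulates (or reads) the multi-subject dataset, extracts event-related
#' modes per subject with the chosen approach, measures windowed amplitudes
#' on the configured mode subset, runs channel-wise paired tests per window,
#' pools the mode of interest per electrode cluster, and assembles
#' topography tables. Deterministic given `config$seed`. With `out_dir`
#' set, results are written as TSV files plus a JSON header echoing the
#' configuration.
#'
#' @param config a [run_config()].
#' @return list with elements `stats` (one `channel_stats` per window),
#'   `topography` (one table per window), `pooled` (cluster x condition
#'   series, grand-averaged over subjects), `erms` (per-subject ERM sets),
#'   `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tensors <- if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- derive_seed(config$seed, 401L)
    synth_eeg_dataset(sim)
  } else {
    lapply(config$input_paths, read_trials)
  }
  n_sub <- length(tensors)
  channels <- tensors[[1L]]$channels
  layout <- subset_layout(config$layout, channels)

  erms <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    cfg <- config$eemd
    cfg$seed <- derive_seed(config$seed, 307L, s)
    erms[[s]] <- if (config$approach == "A") {
      erms_approach_A(tensors[[s]], cfg)
    } else {
      erms_approach_B(tensors[[s]], cfg)
    }
  }

  stats_list <- list()
  topo_list <- list()
  for (w in config$windows) {
    amp_ct <- amp_nct <- matrix(NA_real_, n_sub, length(channels),
                                dimnames = list(NULL, channels))
    for (s in seq_len(n_sub)) {
      amp <- erm_window_amplitude(erms[[s]], w, mode = config$stat_modes)
      amp_ct[s, ] <- amp[, "CT"]
      amp_nct[s, ] <- amp[, "NCT"]
    }
    key <- paste(w$component, w$phase, sep = "_")
    st <- condition_difference_stats(amp_ct, amp_nct, channels,
                                     mode = config$stat_modes, window = w)
    stats_list[[key]] <- st
    topo_list[[key]] <- topography_values(st, layout)
  }

  clusters <- unique(layout$cluster)
  n_samp <- dim(erms[[1L]]$modes)[4L]
  pooled <- list()
  for (cl in clusters) {
    acc <- matrix(0, 2L, n_samp)
    for (s in seq_len(n_sub)) {
      acc <- acc + pool_electrodes(erms[[s]], layout, cl,
                                   mode = config$pool_mode)
    }
    pooled[[cl]] <- acc / n_sub
    rownames(pooled[[cl]]) <- c("CT", "NCT")
  }

  result <- list(stats = stats_list, topography = topo_list,
                 pooled = pooled, erms = erms, config = config)
  if (!is.null(config$out_dir)) write_results(result, config$out_dir)
  result
}

# Write the result bundle: JSON header with config echo, full-precision
# statistics, a rounded report table (p and T to 3 decimals), pooled series
# and topography tables.
write_results <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(format_version = FORMAT_VERSION, config = config_echo(result$config)),
    file.path(out_dir, "header.json"), auto_unbox = TRUE, digits = NA
  )
  all_stats <- do.call(rbind, lapply(names(result$stats), function(key) {
    st <- result$stats[[key]]
    w <- attr(st, "window")
    cbind(component = w$component, phase = w$phase,
          as.data.frame(st, stringsAsFactors = FALSE))
  }))
  utils::write.table(all_stats, file.path(out_dir, "channel_stats.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  report <- all_stats[all_stats$tier != "ns", , drop = FALSE]
  report$p_value <- sprintf("%.3f%s", report$p_value, report$tier)
  report$t_value <- sprintf("%.3f", report$t_value)
  utils::write.table(
    report[, c("component", "phase", "p_value", "t_value", "channel")],
    file.path(out_dir, "report.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE
  )
  pooled_long <- do.call(rbind, lapply(names(result$pooled), function(cl) {
    p <- result$pooled[[cl]]
    erms1 <- result$erms[[1L]]
    t_ms <- (seq_len(ncol(p)) - 1L - erms1$onset_index) * 1000 /
      erms1$sample_rate
    data.frame(cluster = cl, time_ms = rep(t_ms, each = 2L),
               condition = rep(c("CT", "NCT"), times = ncol(p)),
               amplitude = as.vector(p))
  }))
  utils::write.table(pooled_long, file.path(out_dir, "pooled_erm.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (key in names(result$topography)) {
    utils::write.table(result$topography[[key]],
                       file.path(out_dir, sprintf("topography_%s.tsv", key)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(out_dir)
}
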