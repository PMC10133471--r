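#' Build trials from a 4D array
#'
#' Converts an EEG array laid out as
#' `channels x samples x conditions x blocks` — the trial layout used by
#' the public 40-target SSVEP recordings — into a list of trials, one per
#' (condition, block). Condition `k` (1-based axis position) maps to class
#' index `k - 1` and is matched against the stimulus table.
#'
#' @param arr 4D numeric array.
#' @param table A [build_stimulus_table()] with at least as many classes
#'   as conditions.
#' @param sampling_rate Sampling rate in Hz (default 250).
#' @param subject_id,dataset_tag Identifier metadata.
#' @return An `ssvep_dataset` (list of `ssvep_trial`).
#' @export
trials_from_array <- function(arr, table, sampling_rate = 250,
                              subject_id = "S01", dataset_tag = "array") {
  if (length(dim(arr)) != 4L)
    stop("expected a 4D array (channels x samples x conditions x blocks); ",
         "got ", length(dim(arr)), " axes", call. = FALSE)
  d <- dim(arr)
  if (d[3] > nrow(table))
    stop("array has ", d[3], " conditions but the stimulus table only ",
         nrow(table), " classes (condition axis 3)", call. = FALSE)
  trials <- vector("list", d[3] * d[4])
  i <- 0L
  for (blk in seq_len(d[4])) {
    for (cond in seq_len(d[3])) {
      i <- i + 1L
      row <- which(table$class_index == cond - 1L)
      trials[[i]] <- structure(list(
        data = matrix(arr[, , cond, blk], d[1], d[2]),
        clean = NULL, class_index = cond - 1L,
        frequency = table$frequency[row], phase = table$phase[row],
        sampling_rate = sampling_rate, subject_id = subject_id,
        session_id = sprintf("B%02d", blk), dataset_tag = dataset_tag),
        class = "ssvep_trial")
    }
  }
  structure(trials, class = "ssvep_dataset", table = table)
}

#' Read trials from a MAT file
#'
#' Reads the MAT trial layout used by the public benchmark/BETA SSVEP
#' recordings (one array of `channels x samples x conditions x blocks`
#' under a named key). MAT parsing requires the optional R.matlab package;
#' when it is not installed this reader fails with a clear error and the
#' synthetic path is unaffected.
#'
#' @param path MAT file path.
#' @param table Stimulus table mapping conditions to classes.
#' @param key Name of the data array inside the file (default `"data"`).
#' @param axis_order Permutation mapping the stored axes to
#'   `(channels, samples, conditions, blocks)`.
#' @param sampling_rate Sampling rate in Hz.
#' @param ... Passed to [trials_from_array()].
#' @return An `ssvep_dataset`.
#' @export
read_mat_trials <- function(path, table, key = "data",
                            axis_order = 1:4, sampling_rate = 250, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!requireNamespace("R.matlab", quietly = TRUE))
    stop("reading MAT files requires the optional 'R.matlab' package; ",
         "install it or convert the recordings to RDS/CSV. The synthetic ",
         "data path does not need it.", call. = FALSE)
  mat <- R.matlab::readMat(path)
  if (!key %in% names(mat))
    stop("key '", key, "' not found in ", path, "; available: ",
         paste(names(mat), collapse = ", "), call. = FALSE)
  arr <- mat[[key]]
  if (length(dim(arr)) != 4L)
    stop("array under '", key, "' has ", length(dim(arr)),
         " axes; expected 4", call. = FALSE)
  arr <- aperm(arr, axis_order)
  trials_from_array(arr, table, sampling_rate = sampling_rate, ...)
}

#' Save / load a dataset or segment batch
#'
#' Serialisation uses R's native format plus a CSV metadata table
#' alongside (class, frequency, phase per trial), so datasets remain
#' inspectable without loading R objects.
#'
#' @param x An `ssvep_dataset` or `segment_batch`.
#' @param path Output `.rds` path.
#' @return `path` (save) or the restored object (load).
#' @export
save_dataset <- function(x, path) {
  saveRDS(x, path)
  if (inherits(x, "ssvep_dataset")) {
    meta <- data.frame(
      trial = seq_along(x),
      class_index = vapply(x, function(t) t$class_index, integer(1)),
      frequency = vapply(x, function(t) t$frequency, numeric(1)),
      phase = vapply(x, function(t) t$phase, numeric(1)),
      subject_id = vapply(x, function(t) t$subject_id, character(1)),
      session_id = vapply(x, function(t) t$session_id, character(1)))
    utils::write.csv(meta, paste0(tools::file_path_sans_ext(path),
                                  "_meta.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) readRDS(path)

#' Run configuration
#'
#' Bundles all sub-configurations of an experiment (synthetic generation,
#' filtering, architecture, training, montage, window lengths, seeds) into
#' one object that round-trips through YAML, so every artifact on disk is
#' reproducible from its logged configuration.
#'
#' @param synthetic A [synthetic_config()].
#' @param filter A [filter_spec()].
#' @param gdnet A [gdnet_config()].
#' @param train A [train_config()].
#' @param montage_name Montage subset name (see [channel_montage()]).
#' @param ratios Window lengths in seconds (default 0.2, 0.4, 0.6, 0.8, 1).
#' @param n_classes Number of stimulation classes.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       filter = filter_spec(),
                       gdnet = gdnet_config(synthetic$n_channels, n_classes),
                       train = train_config(),
                       montage_name = "all64",
                       ratios = c(0.2, 0.4, 0.6, 0.8, 1.0),
                       n_classes = 40L) {
  structure(list(synthetic = synthetic, filter = filter, gdnet = gdnet,
                 train = train, montage_name = montage_name,
                 ratios = ratios, n_classes = as.integer(n_classes)),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML path.
#' @return `path` (write) or the restored `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  plain <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config(
    synthetic = do.call(synthetic_config, raw$synthetic),
    filter = do.call(filter_spec, raw$filter),
    gdnet = do.call(gdnet_config, raw$gdnet),
    train = do.call(train_config, raw$train),
    montage_name = raw$montage_name,
    ratios = as.numeric(raw$ratios),
    n_classes = raw$n_classes)
  cfg
}

# append a timestamped line to a run log, recording the config hash and
# seeds so artifacts are reproducible from the log alone
.log_run <- function(log_path, command, config_path, seeds) {
  hash <- if (!is.null(config_path) && file.exists(config_path))
    unname(tools::md5sum(config_path)) else NA_character_
  line <- sprintf("%s\t%s\tconfig_md5=%s\tseeds=%s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), command, hash,
                  paste(seeds, collapse = ","))
  cat(line, "\n", file = log_path, append = TRUE)
  invisible(line)
}
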