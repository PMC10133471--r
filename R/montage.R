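# Canonical 64-channel ordering for synthetic data, using international
# 10-10 labels, ordered front-to-back. When real recordings are used the
# ordering should follow the dataset's own channel file; this list is the
# package's documented canonical ordering for generated data.
.canonical_64 <- c(
  "FP1", "FPZ", "FP2",
  "AF7", "AF3", "AF4", "AF8",
  "F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8",
  "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8",
  "T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8",
  "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8",
  "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8",
  "PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8",
  "CB1", "O1", "OZ", "O2", "CB2"
)

# The 32-channel subset covers occipital, parieto-occipital, parietal,
# centro-parietal and central sites. The exact membership is this
# package's documented reading (the regions are standard; no canonical
# 32-list exists): all O/PO/P/CP labels plus six central electrodes.
.subset_32 <- c(
  "O1", "OZ", "O2",
  "PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8",
  "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8",
  "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6",
  "C5", "C3", "C1", "C2", "C4", "C6"
)

#' Electrode montage subsets
#'
#' Named channel subsets used to study how classification degrades with
#' fewer electrodes: `occ3` = O1, Oz, O2 (occipital); `occ6` adds POz,
#' PO3, PO4; `po9` = O1, Oz, O2, Pz, PO3, PO5, PO4, PO6, POz; `cp32` =
#' 32 channels over occipital/parietal/centro-parietal/central regions;
#' `all64` = the full canonical ordering.
#'
#' @param subset_name One of `"occ3"`, `"occ6"`, `"po9"`, `"cp32"`,
#'   `"all64"`.
#' @return A list of class `"channel_montage"` with `labels`,
#'   `subset_name` and `indices` into the 64-channel ordering.
#' @export
channel_montage <- function(subset_name = c("all64", "occ3", "occ6", "po9",
                                            "cp32")) {
  subset_name <- match.arg(subset_name)
  labels <- switch(subset_name,
    occ3 = c("O1", "OZ", "O2"),
    occ6 = c("O1", "OZ", "O2", "POZ", "PO3", "PO4"),
    po9 = c("O1", "OZ", "O2", "PZ", "PO3", "PO5", "PO4", "PO6", "POZ"),
    cp32 = .subset_32,
    all64 = .canonical_64)
  idx <- match(labels, .canonical_64)
  stopifnot(!anyNA(idx))
  structure(list(labels = labels, subset_name = subset_name,
                 indices = idx), class = "channel_montage")
}

#' Montage from explicit labels
#'
#' @param labels Channel labels (must exist in the canonical 64-channel
#'   ordering).
#' @return A `channel_montage`.
#' @export
montage_from_labels <- function(labels) {
  labels <- toupper(labels)
  idx <- match(labels, .canonical_64)
  if (anyNA(idx))
    stop("unknown channel label(s): ",
         paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
  structure(list(labels = labels, subset_name = "custom", indices = idx),
            class = "channel_montage")
}

#' The canonical 64-channel labels
#'
#' @return Character vector of 64 10-10 labels, front-to-back.
#' @export
canonical_channels <- function() .canonical_64

#' Select a channel subset from trials
#'
#' Re-orders/subsets the rows of every trial according to the montage and
#' records the selected labels; downstream configurations should use the
#' reduced channel count.
#'
#' @param trials An `ssvep_dataset`, a list of trials, or one
#'   `ssvep_trial`.
#' @param montage A [channel_montage()] (its indices must fit the trials'
#'   channel count).
#' @return Object of the same shape with channels subset.
#' @export
select_channels <- function(trials, montage) {
  stopifnot(inherits(montage, "channel_montage"))
  pick <- function(trial) {
    if (!is.null(trial$channel_labels)) {
      # already subset once: match labels against the current rows
      idx <- match(montage$labels, trial$channel_labels)
      if (anyNA(idx))
        stop("channel(s) not present in trial: ",
             paste(montage$labels[is.na(idx)], collapse = ", "),
             call. = FALSE)
    } else {
      idx <- montage$indices
      if (max(idx) > nrow(trial$data))
        stop("montage index ", max(idx),
             " exceeds trial channel count ", nrow(trial$data),
             call. = FALSE)
    }
    trial$data <- trial$data[idx, , drop = FALSE]
    if (!is.null(trial$clean))
      trial$clean <- trial$clean[idx, , drop = FALSE]
    trial$channel_labels <- montage$labels
    trial
  }
  if (inherits(trials, "ssvep_trial")) return(pick(trials))
  out <- lapply(trials, pick)
  attributes(out) <- attributes(trials)
  out
}
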