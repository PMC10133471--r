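#' Build a frequency/phase-coded stimulus table
#'
#' Constructs the table of stimulation conditions for a joint
#' frequency/phase-coded SSVEP paradigm: `n_classes` flicker frequencies
#' starting at `base_frequency` with a fixed `stride`, and a fixed phase
#' increment between adjacent conditions. The canonical 40-target speller
#' layout uses frequencies 8--15 Hz in 0.2 Hz strides with a 0.5*pi phase
#' step between adjacent frequencies.
#'
#' @param n_classes Number of stimulation conditions (>= 2).
#' @param base_frequency Frequency of class 0, in Hz.
#' @param stride Frequency increment between adjacent classes, in Hz (> 0).
#' @param phase_step Phase increment between adjacent classes, in radians.
#' @param base_phase Phase of class 0, in radians.
#'
#' @return A data frame of class `"stimulus_table"` with columns
#'   `class_index` (0-based), `frequency` (Hz) and `phase` (radians, reduced
#'   to `[0, 2*pi)`), ordered by class index.
#'
#' @examples
#' tab <- build_stimulus_table()
#' head(tab)
#' @export
build_stimulus_table <- function(n_classes = 40L, base_frequency = 8.0,
                                 stride = 0.2, phase_step = 0.5 * pi,
                                 base_phase = 0.0) {
  if (!is.numeric(n_classes) || length(n_classes) != 1L || n_classes < 2)
    stop("`n_classes` must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(stride) || length(stride) != 1L || stride <= 0)
    stop("`stride` must be a single positive number (Hz)", call. = FALSE)
  n_classes <- as.integer(n_classes)
  k <- seq_len(n_classes) - 1L
  tab <- data.frame(
    class_index = k,
    frequency   = base_frequency + stride * k,
    phase       = (base_phase + phase_step * k) %% (2 * pi)
  )
  class(tab) <- c("stimulus_table", "data.frame")
  tab
}

#' Write a stimulus table to CSV
#'
#' @param table A `stimulus_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stimulus_table <- function(table, path) {
  stopifnot(inherits(table, "stimulus_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a stimulus table from CSV
#'
#' @param path CSV path previously written by [write_stimulus_table()].
#' @return A `stimulus_table`.
#' @export
read_stimulus_table <- function(path) {
  tab <- utils::read.csv(path)
  stopifnot(all(c("class_index", "frequency", "phase") %in% names(tab)))
  class(tab) <- c("stimulus_table", "data.frame")
  tab
}
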