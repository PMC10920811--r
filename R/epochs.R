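#' Construct an epoch set
#'
#' The central data container: a 3-D array of EEG epochs with sampling rate,
#' channel geometry and per-epoch subject / group / task labels. Group labels
#' are the binary classification target ("M" vs "H" in the default cohorts).
#'
#' @param data Numeric array, epochs x channels x samples. All values finite.
#' @param fs Sampling rate in Hz.
#' @param ch_names Character vector of unique channel names (length =
#'   `dim(data)[2]`).
#' @param positions Optional channels x 3 matrix of sensor positions.
#' @param subject,group,task Character vectors of per-epoch labels (length =
#'   `dim(data)[1]`).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, ch_names, positions = NULL,
                      subject = character(0), group = character(0),
                      task = character(0)) {
  if (!is.array(data) || length(dim(data)) != 3)
    stop_invalid("`data` must be a 3-D array (epochs x channels x samples)")
  n_ep <- dim(data)[1]
  if (n_ep > 0 && !all(is.finite(data)))
    stop_invalid("epoch data contains non-finite values")
  if (length(ch_names) != dim(data)[2])
    stop_invalid("length(ch_names) must equal the channel dimension")
  if (anyDuplicated(ch_names)) stop_invalid("channel names must be unique")
  for (lab in list(subject = subject, group = group, task = task)) NULL
  labs <- list(subject = subject, group = group, task = task)
  for (nm in names(labs)) {
    if (length(labs[[nm]]) != n_ep)
      stop_invalid("label `", nm, "` must have one entry per epoch")
  }
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != length(ch_names) || ncol(positions) != 3)
      stop_invalid("`positions` must be a channels x 3 matrix")
    rownames(positions) <- ch_names
  }
  structure(
    list(data = data, fs = fs, ch_names = as.character(ch_names),
         positions = positions,
         subject = as.character(subject), group = as.character(group),
         task = as.character(task)),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  if (d[1] > 0) {
    cat("  subjects:", length(unique(x$subject)),
        " groups:", paste(sort(unique(x$group)), collapse = "/"),
        " tasks:", paste(sort(unique(x$task)), collapse = "/"), "\n")
  }
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param x An `epoch_set`.
#' @return Integer epoch count.
#' @export
n_epochs <- function(x) dim(x$data)[1]

#' Subset an epoch set by index or by task
#'
#' @param x An `epoch_set`.
#' @param idx Logical or integer epoch index.
#' @param task Optional task label; epochs of other tasks are dropped before
#'   `idx` is applied.
#' @return An `epoch_set` with the selected epochs.
#' @export
subset_epochs <- function(x, idx = NULL, task = NULL) {
  keep <- seq_len(n_epochs(x))
  if (!is.null(task)) keep <- keep[x$task[keep] %in% task]
  if (!is.null(idx)) keep <- keep[idx]
  epoch_set(x$data[keep, , , drop = FALSE], x$fs, x$ch_names, x$positions,
            x$subject[keep], x$group[keep], x$task[keep])
}

#' Cut continuous EEG into fixed-length task epochs
#'
#' For each trial onset, epochs of `epoch_len` seconds are taken back-to-back
#' (no overlap) starting `start_offset` seconds after the onset, and continue
#' until the trial ends. The offset skips the initial stimulus-driven period
#' so that epochs reflect sustained task processing. A trial ends at its
#' entry of `trial_ends` (e.g. the response time) or, when that is `NULL`, at
#' the next onset / end of recording.
#'
#' Onsets whose first epoch would run past the recording are skipped with a
#' warning; zero usable trials yield an empty epoch set, not an error.
#'
#' @param continuous Numeric matrix, channels x samples.
#' @param fs Sampling rate (Hz).
#' @param onsets Trial onset times in seconds.
#' @param subject,group,task Per-trial labels (recycled to each trial's
#'   epochs).
#' @param ch_names Channel names; defaults to rownames of `continuous`.
#' @param positions Optional channels x 3 sensor positions.
#' @param start_offset Seconds between onset and the first epoch (default 5).
#' @param epoch_len Epoch length in seconds (default 2).
#' @param trial_ends Optional per-trial end times in seconds.
#' @return An `epoch_set`.
#' @export
extract_epochs <- function(continuous, fs, onsets, subject, group, task,
                           ch_names = NULL, positions = NULL,
                           start_offset = 5.0, epoch_len = 2.0,
                           trial_ends = NULL) {
  continuous <- as.matrix(continuous)
  n_ch <- nrow(continuous)
  n_s <- ncol(continuous)
  ch_names <- ch_names %||% rownames(continuous) %||%
    sprintf("E%03d", seq_len(n_ch))
  n_trial <- length(onsets)
  subject <- rep_len(as.character(subject), n_trial)
  group <- rep_len(as.character(group), n_trial)
  task <- rep_len(as.character(task), n_trial)
  nsamp <- round(epoch_len * fs)
  rec_end <- n_s / fs
  if (is.null(trial_ends)) {
    # each trial ends at the next onset in time order; last at recording end
    o <- order(onsets)
    te <- rep(rec_end, n_trial)
    if (n_trial > 1) te[o[-n_trial]] <- onsets[o[-1]]
    trial_ends <- te
  }

  pieces <- list(); labs <- list()
  for (tr in seq_len(n_trial)) {
    t0 <- onsets[tr] + start_offset
    avail <- min(trial_ends[tr], rec_end) - t0
    k <- if (avail >= epoch_len) floor(avail / epoch_len) else 0
    if (k == 0) {
      if (t0 + epoch_len > rec_end)
        warning("trial ", tr, ": onset out of range, skipped")
      next
    }
    s0 <- round(t0 * fs)
    for (e in seq_len(k)) {
      a <- s0 + (e - 1) * nsamp + 1
      pieces[[length(pieces) + 1]] <- continuous[, a:(a + nsamp - 1), drop = FALSE]
      labs[[length(labs) + 1]] <- c(subject[tr], group[tr], task[tr])
    }
  }
  n_ep <- length(pieces)
  out <- array(0, dim = c(n_ep, n_ch, nsamp))
  for (e in seq_len(n_ep)) out[e, , ] <- pieces[[e]]
  lab <- if (n_ep > 0) do.call(rbind, labs) else matrix(character(0), 0, 3)
  epoch_set(out, fs, ch_names, positions,
            subject = lab[, 1], group = lab[, 2], task = lab[, 3])
}

#' Reject epochs by peak-to-peak amplitude
#'
#' An epoch is kept only if every channel's peak-to-peak amplitude lies in
#' `[ptp_min, ptp_max]`. Flat channels (below `ptp_min`) mark dead sensors;
#' excursions above `ptp_max` mark artifacts. Defaults are in the units of
#' the data (microvolts for the synthetic cohorts).
#'
#' @param epochs An `epoch_set`.
#' @param ptp_min,ptp_max Peak-to-peak bounds, `ptp_min < ptp_max`.
#' @return A list with `epochs` (the retained `epoch_set`) and `kept`
#'   (logical mask over the input epochs).
#' @export
reject_epochs <- function(epochs, ptp_min = 1, ptp_max = 150) {
  if (!(ptp_min < ptp_max)) stop_invalid("ptp_min must be < ptp_max")
  n_ep <- n_epochs(epochs)
  kept <- logical(n_ep)
  for (e in seq_len(n_ep)) {
    x <- epochs$data[e, , , drop = TRUE]
    ptp <- apply(x, 1, function(ch) max(ch) - min(ch))
    kept[e] <- all(ptp >= ptp_min & ptp <= ptp_max)
  }
  if (n_ep > 0 && !any(kept))
    stop("all epochs rejected by peak-to-peak criteria; nothing to analyze",
         call. = FALSE)
  list(epochs = subset_epochs(epochs, which(kept)), kept = kept)
}
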