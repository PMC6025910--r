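# Labelled multichannel EEG epochs: the container every stage of the
# pipeline consumes (trials x channels x samples plus labels and a
# sampling rate).

#' Construct a labelled epoch set
#'
#' Wraps a numeric `trials x channels x samples` array with per-trial
#' integer class labels and a sampling rate. This is the input container of
#' the whole pipeline; anything that can produce it (the synthetic
#' generator, or an adapter for a real recording format) plugs in.
#'
#' @param data Numeric 3-d array, dimensions `trials x channels x samples`.
#' @param labels Integer vector of class labels, one per trial.
#' @param sampling_rate Sampling rate in Hz.
#' @return An object of class `epoch_set` with fields `data`, `labels`,
#'   `sampling_rate`.
#' @export
epoch_set <- function(data, labels, sampling_rate) {
  if (!is.array(data) || length(dim(data)) != 3L || !is.numeric(data)) {
    stop("`data` must be a numeric trials x channels x samples array",
         call. = FALSE)
  }
  labels <- as.integer(labels)
  if (length(labels) != dim(data)[1L]) {
    stop("`labels` must have one entry per trial", call. = FALSE)
  }
  if (anyNA(labels)) stop("`labels` must not contain NA", call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("`sampling_rate` must be a positive scalar (Hz)", call. = FALSE)
  }
  if (dim(data)[3L] <= dim(data)[2L]) {
    warning("fewer samples than channels: per-epoch covariances will be ",
            "rank deficient")
  }
  structure(
    list(data = data, labels = labels, sampling_rate = as.numeric(sampling_rate)),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Epoch set: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sampling_rate))
  tab <- table(x$labels)
  cat("  trials per class:",
      paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Number of trials / subset of an epoch set
#'
#' @param epochs An [epoch_set()].
#' @param trials Integer or logical index over trials.
#' @return `subset_epochs` returns a new `epoch_set` restricted to the
#'   selected trials; `n_trials` the trial count.
#' @export
subset_epochs <- function(epochs, trials) {
  stopifnot(inherits(epochs, "epoch_set"))
  epoch_set(epochs$data[trials, , , drop = FALSE],
            epochs$labels[trials], epochs$sampling_rate)
}

#' @rdname subset_epochs
#' @export
n_trials <- function(epochs) dim(epochs$data)[1L]

#' Read / write an epoch set container
#'
#' On-disk layout is R's native serialization of the `epoch_set` list (one
#' data tensor, one label vector, one sampling-rate scalar); round trips are
#' bit-exact.
#'
#' @param epochs An [epoch_set()].
#' @param path File path.
#' @return `read_epochs` returns the `epoch_set`; `write_epochs` its path,
#'   invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  saveRDS(epochs, path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  out <- readRDS(path)
  if (!inherits(out, "epoch_set")) stop("not an epoch_set container",
                                        call. = FALSE)
  out
}
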