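#' Construct an epoch container
#'
#' Bundles bandpass-filtered (or broadband) EEG epochs with their metadata.
#' Epochs are stored as a numeric array of dimension
#' \code{n_epochs x n_channels x n_samples}; trial identifiers must be
#' strictly increasing so that the container is always in chronological
#' (session) order, which the chronological cross-validation relies on.
#'
#' @param data numeric array \code{[n_epochs, n_channels, n_samples]} of
#'   voltages (microvolt scale assumed but not enforced).
#' @param sampling_rate sampling rate in Hz.
#' @param channel_names character vector of channel labels (10-20 system
#'   labels expected by the frontal-channel rejection rule); defaults to
#'   \code{"ch1"..}.
#' @param window numeric length-2, epoch window \code{c(t0, t0 + dt)} in
#'   seconds relative to the go-cue.
#' @param band numeric length-2 passband in Hz, or the string
#'   \code{"broadband"} for unfiltered epochs.
#' @param trial_ids integer identifiers, strictly increasing; defaults to
#'   \code{1:n_epochs}.
#' @return an object of class \code{epoch_set}.
#' @export
epoch_set <- function(data, sampling_rate, channel_names = NULL,
                      window = c(0, dim(data)[3] / sampling_rate),
                      band = "broadband", trial_ids = NULL) {
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3-d array [epochs x channels x samples]")
  if (anyNA(data)) stop("epoch data contains NA")
  n_e <- dim(data)[1]; n_c <- dim(data)[2]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(n_c))
  if (length(channel_names) != n_c)
    stop("channel_names length does not match channel dimension")
  if (is.null(trial_ids)) trial_ids <- seq_len(n_e)
  if (n_e > 1 && any(diff(trial_ids) <= 0))
    stop("trial_ids must be strictly increasing (chronological order)")
  structure(list(data = data, sampling_rate = sampling_rate,
                 channel_names = channel_names, window = window,
                 band = band, trial_ids = as.integer(trial_ids)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  bnd <- if (is.character(x$band)) x$band else
    sprintf("[%.2f, %.2f] Hz", x$band[1], x$band[2])
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sampling_rate))
  cat(sprintf("  band: %s   window: [%.3f, %.3f] s rel. go-cue\n",
              bnd, x$window[1], x$window[2]))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

## subset epochs, keeping chronological metadata consistent
subset_epochs <- function(epochs, idx) {
  epoch_set(epochs$data[idx, , , drop = FALSE], epochs$sampling_rate,
            epochs$channel_names, epochs$window, epochs$band,
            epochs$trial_ids[idx])
}

#' Per-epoch channel covariance matrices
#'
#' Computes, for every epoch, the sample covariance of the channels over the
#' epoch's samples (per-channel mean removed within the epoch, denominator
#' \code{n_samples - 1}). The stack is returned flattened as an
#' \code{n_epochs x n_channels^2} matrix because every downstream SPoC
#' quantity (mean covariance, target-weighted covariance, projected epoch
#' variance) is linear in these entries, so cross-validation and the
#' label-noise stress test can reuse one stack across many refits.
#'
#' @param epochs an \code{epoch_set}.
#' @return matrix \code{n_epochs x n_channels^2}, with attribute
#'   \code{n_channels}; row \code{e} is \code{vec(C_e)}.
#' @export
epoch_covariances <- function(epochs) {
  d <- dim(epochs$data)
  n_e <- d[1]; n_c <- d[2]; n_t <- d[3]
  if (n_t < 2) stop("need at least 2 samples per epoch for a covariance")
  out <- matrix(0, n_e, n_c * n_c)
  for (e in seq_len(n_e)) {
    x <- matrix(epochs$data[e, , ], n_c, n_t)
    x <- x - rowMeans(x)
    out[e, ] <- as.vector(tcrossprod(x) / (n_t - 1))
  }
  attr(out, "n_channels") <- n_c
  out
}

#' Write / read the canonical epochs container
#'
#' Serializes an \code{epoch_set} (plus optional per-epoch target variable)
#' to a directory of plain-text files: \code{meta.json} holds sampling rate,
#' band, window, channel names and trial ids; \code{epochs.csv} holds the
#' data flattened to \code{(epoch * sample)} rows by channel columns;
#' \code{z.csv} holds the target when given.
#'
#' @param epochs an \code{epoch_set}.
#' @param path directory to create/overwrite.
#' @param z optional per-epoch target variable.
#' @return \code{path}, invisibly.
#' @export
write_epochs <- function(epochs, path, z = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs$data)
  meta <- list(n_epochs = d[1], n_channels = d[2], n_samples = d[3],
               sampling_rate = epochs$sampling_rate,
               channel_names = epochs$channel_names,
               window = epochs$window, band = epochs$band,
               trial_ids = epochs$trial_ids)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  ## rows ordered epoch-major: all samples of epoch 1, then epoch 2, ...
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)), d[1] * d[3], d[2])
  colnames(flat) <- epochs$channel_names
  utils::write.csv(flat, file.path(path, "epochs.csv"), row.names = FALSE)
  if (!is.null(z))
    utils::write.csv(data.frame(trial_id = epochs$trial_ids, z = z),
                     file.path(path, "z.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  flat <- as.matrix(utils::read.csv(file.path(path, "epochs.csv")))
  data <- aperm(array(flat, c(meta$n_samples, meta$n_epochs,
                              meta$n_channels)), c(2, 3, 1))
  es <- epoch_set(data, meta$sampling_rate, meta$channel_names,
                  as.numeric(meta$window), if (is.character(meta$band))
                    meta$band else as.numeric(meta$band), meta$trial_ids)
  zfile <- file.path(path, "z.csv")
  z <- if (file.exists(zfile)) utils::read.csv(zfile)$z else NULL
  list(epochs = es, z = z)
}
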