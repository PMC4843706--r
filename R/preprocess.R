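#' Butterworth bandpass filter
#'
#' Filters a continuous multichannel signal with a 5th-order Butterworth
#' bandpass \code{[f0, f0 + df]}. Zero-phase (forward-backward) filtering is
#' the default for offline analysis — note this doubles the effective
#' filter order; \code{zero_phase = FALSE} gives the causal variant.
#'
#' @param x numeric matrix, samples x channels (a vector is treated as one
#'   channel).
#' @param f0 lower band edge (Hz).
#' @param df bandwidth (Hz); passband is \code{[f0, f0 + df]}.
#' @param sampling_rate Hz.
#' @param order filter order (default 5).
#' @param zero_phase forward-backward filtering (default TRUE).
#' @return filtered matrix of the same shape.
#' @export
bandpass <- function(x, f0, df, sampling_rate, order = 5, zero_phase = TRUE) {
  nyq <- sampling_rate / 2
  if (f0 <= 0 || df <= 0 || f0 + df >= nyq)
    stop("band must satisfy 0 < f0 < f0 + df < Nyquist")
  x <- as.matrix(x)
  bf <- signal::butter(order, c(f0, f0 + df) / nyq, type = "pass")
  apply(x, 2, function(col) {
    if (zero_phase) signal::filtfilt(bf, col)
    else as.numeric(signal::filter(bf, col))
  })
}

## band-filter an already-epoched set, epoch by epoch, with reflection
## padding so that filter edge transients stay outside the epoch
bandpass_epochs <- function(epochs, f0, df, order = 5) {
  nyq <- epochs$sampling_rate / 2
  if (f0 <= 0 || df <= 0 || f0 + df >= nyq)
    stop("band must satisfy 0 < f0 < f0 + df < Nyquist")
  bf <- signal::butter(order, c(f0, f0 + df) / nyq, type = "pass")
  d <- dim(epochs$data)
  n_t <- d[3]
  pad <- min(n_t - 1L, max(32L, ceiling(2 * epochs$sampling_rate / f0)))
  out <- epochs$data
  for (e in seq_len(d[1])) for (ch in seq_len(d[2])) {
    v <- epochs$data[e, ch, ]
    vp <- c(2 * v[1] - rev(v[2:(pad + 1)]), v,
            2 * v[n_t] - rev(v[(n_t - pad):(n_t - 1)]))
    f <- signal::filtfilt(bf, vp)
    out[e, ch, ] <- f[(pad + 1):(pad + n_t)]
  }
  epoch_set(out, epochs$sampling_rate, epochs$channel_names, epochs$window,
            band = c(f0, f0 + df), trial_ids = epochs$trial_ids)
}

#' Extract epochs around events
#'
#' Cuts half-open sample windows \code{[t0, t0 + dt)} relative to each
#' event time (typically the go-cue) out of a continuous recording. Events
#' whose window falls outside the recording are dropped with a warning.
#' Epochs are returned in chronological event order.
#'
#' @param x continuous signal, samples x channels.
#' @param events event times in seconds from the start of \code{x}.
#' @param t0 window start relative to the event (s); negative = pre-event.
#' @param dt window length (s).
#' @param sampling_rate Hz.
#' @param channel_names optional channel labels.
#' @return an \code{\link{epoch_set}} with \code{T = round(dt *
#'   sampling_rate)} samples per epoch.
#' @export
extract_epochs <- function(x, events, t0, dt, sampling_rate,
                           channel_names = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  n_t <- round(dt * sampling_rate)
  starts <- round((events + t0) * sampling_rate) + 1L
  ok <- starts >= 1L & (starts + n_t - 1L) <= n
  if (any(!ok))
    warning(sprintf("%d event(s) with out-of-bounds windows dropped",
                    sum(!ok)))
  if (!any(ok)) stop("no events with in-bounds windows")
  keep <- which(ok)
  data <- array(0, c(length(keep), ncol(x), n_t))
  for (i in seq_along(keep)) {
    s <- starts[keep[i]]
    data[i, , ] <- t(x[s:(s + n_t - 1L), , drop = FALSE])
  }
  epoch_set(data, sampling_rate, channel_names,
            window = c(t0, t0 + dt), band = "broadband",
            trial_ids = keep)
}

rejection_report <- function(all_ids, rejected, reason, thresholds) {
  structure(list(kept_ids = setdiff(all_ids, rejected),
                 rejected_ids = rejected,
                 reason = reason, thresholds = thresholds),
            class = "rejection_report")
}

#' @export
print.rejection_report <- function(x, ...) {
  cat(sprintf("<rejection_report> %s: kept %d, rejected %d\n",
              x$reason, length(x$kept_ids), length(x$rejected_ids)))
  invisible(x)
}

#' Min-max (peak-to-peak) artifact rejection
#'
#' Rejects an epoch when the peak-to-peak amplitude on any of the listed
#' channels strictly exceeds the threshold; targets eye blinks via the
#' frontal channels. The default channel set is every label starting with
#' Fp, AF or F.
#'
#' @param epochs an \code{\link{epoch_set}}.
#' @param channels channel labels to check (default frontal subset).
#' @param threshold_uV peak-to-peak threshold (default 60).
#' @return a \code{rejection_report} over \code{epochs$trial_ids}.
#' @export
reject_minmax <- function(epochs, channels = NULL, threshold_uV = 60) {
  if (is.null(channels)) {
    channels <- grep("^(Fp|AF|F)", epochs$channel_names, value = TRUE)
    if (!length(channels)) channels <- epochs$channel_names
  }
  idx <- match(channels, epochs$channel_names)
  if (anyNA(idx))
    stop("unknown channel(s): ", paste(channels[is.na(idx)], collapse = ", "))
  d <- dim(epochs$data)
  bad <- vapply(seq_len(d[1]), function(e) {
    any(vapply(idx, function(ch) {
      v <- epochs$data[e, ch, ]; max(v) - min(v)
    }, 0) > threshold_uV)
  }, NA)
  rejection_report(epochs$trial_ids, epochs$trial_ids[bad], "minmax",
                   list(threshold_uV = threshold_uV, channels = channels))
}

#' Variance-based artifact rejection
#'
#' Flags high-variance epochs (muscle artifacts): per channel, the 10th and
#' 90th percentiles of the epoch variances are computed and an epoch is
#' rejected if its variance on any channel exceeds
#' \code{P90 + 2 * (P90 - P10)}. The rule is scale-invariant. This reading
#' of the published rule — an outlier fence above the 90th percentile
#' rather than an unconditional rejection of the top decile — is
#' configurable via \code{fence}.
#'
#' @param epochs an \code{\link{epoch_set}} (>= 10 epochs).
#' @param p_low,p_up percentile pair (defaults 10 / 90).
#' @param fence multiplier on the inter-percentile range (default 2).
#' @return a \code{rejection_report}.
#' @export
reject_variance <- function(epochs, p_low = 10, p_up = 90, fence = 2) {
  d <- dim(epochs$data)
  if (d[1] < 10) stop("need >= 10 epochs for percentile-based rejection")
  v <- matrix(0, d[1], d[2])
  for (e in seq_len(d[1]))
    v[e, ] <- apply(matrix(epochs$data[e, , ], d[2], d[3]), 1, stats::var)
  bad <- rep(FALSE, d[1])
  for (ch in seq_len(d[2])) {
    q <- stats::quantile(v[, ch], c(p_low, p_up) / 100, names = FALSE)
    bad <- bad | v[, ch] > q[2] + fence * (q[2] - q[1])
  }
  rejection_report(epochs$trial_ids, epochs$trial_ids[bad], "variance",
                   list(p_low = p_low, p_up = p_up, fence = fence))
}

#' Behavioral outlier rejection
#'
#' Rejects trials whose active performance metric falls outside a min-max
#' interval. Default intervals: RT in \[150, 900\] ms and NJ in \[0, 1300\]
#' on raw values; DUR in \[-1.5, 2\], CPL in \[-0.6, 0.6\] and ISJ in
#' \[-1.5, 1.5\] on per-condition standardized values (their intervals are
#' z-score-like).
#'
#' @param metrics data.frame with \code{trial_id} and metric columns
#'   (standardized where appropriate, see
#'   \code{\link{standardize_and_pool}}).
#' @param metric which metric is active for the analysis.
#' @param thresholds named list of length-2 ranges overriding the defaults.
#' @return a \code{rejection_report}.
#' @export
reject_behavioral <- function(metrics,
                              metric = c("RT", "DUR", "CPL", "ISJ", "NJ"),
                              thresholds = NULL) {
  metric <- match.arg(metric)
  defaults <- list(RT = c(150, 900), ISJ = c(-1.5, 1.5), CPL = c(-0.6, 0.6),
                   DUR = c(-1.5, 2), NJ = c(0, 1300))
  rng <- (thresholds %||% list())[[metric]] %||% defaults[[metric]]
  x <- metrics[[metric]]
  bad <- x < rng[1] | x > rng[2]
  rejection_report(metrics$trial_id, metrics$trial_id[bad], "behavioral",
                   stats::setNames(list(rng), metric))
}

#' Minimum-trial gate
#'
#' The supervised decomposition needs enough trials to converge; datasets
#' with fewer than \code{n_min} surviving trials are excluded.
#'
#' @param n_kept number of trials surviving rejection.
#' @param n_min minimum (default 150).
#' @return logical: TRUE if the dataset passes.
#' @export
enforce_min_trials <- function(n_kept, n_min = 150) n_kept >= n_min

#' Serialize a rejection report
#'
#' @param report a \code{rejection_report}.
#' @param path output path; \code{.json} writes JSON, anything else CSV.
#' @export
write_rejection_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE)
  } else {
    df <- data.frame(
      trial_id = c(report$kept_ids, report$rejected_ids),
      status = rep(c("kept", "rejected"),
                   c(length(report$kept_ids), length(report$rejected_ids))),
      reason = report$reason)
    utils::write.csv(df[order(df$trial_id), ], path, row.names = FALSE)
  }
  invisible(path)
}
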