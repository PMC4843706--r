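#' Specify a planted oscillatory source
#'
#' Describes one narrowband source of the linear forward model
#' \eqn{x(t) = A s(t)}: its sensor projection (one column of the mixing
#' matrix \eqn{A}), its frequency band, its baseline power, and how strongly
#' its per-epoch log-bandpower comodulates with the target variable.
#'
#' @param pattern numeric vector of per-channel mixing weights (a column of
#'   the mixing matrix; arbitrary units). Must have at least one nonzero
#'   entry.
#' @param center_freq center frequency in Hz.
#' @param bandwidth full bandwidth in Hz (> 0); the source is band-filtered
#'   white noise in \code{center_freq +/- bandwidth/2}.
#' @param comodulation_r target Pearson correlation in \[-1, 1\] between the
#'   per-epoch log-bandpower of the source and the target variable.
#'   |r| must be < 1: an exact correlation of 1 is unattainable because the
#'   realized epoch bandpower is itself a noisy estimate.
#' @param baseline_power mean source power (variance units), default 1.
#' @return an object of class \code{source_spec}.
#' @export
source_spec <- function(pattern, center_freq, bandwidth, comodulation_r,
                        baseline_power = 1) {
  pattern <- as.numeric(pattern)
  if (all(pattern == 0)) stop("pattern must have at least one nonzero entry")
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  if (abs(comodulation_r) > 1) stop("|comodulation_r| must be <= 1")
  if (abs(comodulation_r) >= 0.999)
    stop("|comodulation_r| must be < 0.999 (epoch bandpower is a noisy estimate)")
  if (baseline_power <= 0) stop("baseline_power must be > 0")
  structure(list(pattern = pattern, center_freq = center_freq,
                 bandwidth = bandwidth, comodulation_r = comodulation_r,
                 baseline_power = baseline_power), class = "source_spec")
}

#' Specify a synthetic recording scene
#'
#' A scene is the complete parameterization of one synthetic session:
#' channel/epoch geometry, the planted sources, the sensor noise level and
#' the construction of the per-epoch target variable z(e). The target is
#' standard normal by default; \code{trend_weight} > 0 mixes in a linear
#' session trend (fraction of target variance carried by the trend), and
#' \code{comodulation_driver} chooses whether source power follows the full
#' target or only its trend component — the latter builds session-trend
#' fixtures where overall correlation is high but trial-by-trial
#' (fold-wise) correlation is not.
#'
#' @param n_channels,n_epochs,sampling_rate,epoch_length scene geometry;
#'   epoch_length in seconds.
#' @param sources list of \code{\link{source_spec}} objects.
#' @param noise_power variance of the spatially/temporally white sensor
#'   noise added per channel.
#' @param seed integer RNG seed; the only source of randomness.
#' @param trend_weight fraction in \[0, 1) of target variance contributed by
#'   a linear session trend (0 = pure trial-by-trial target).
#' @param comodulation_driver \code{"target"} (source power follows z) or
#'   \code{"trend"} (source power follows only the trend component of z).
#' @param noise_spectrum \code{"white"} (default) or \code{"pink"} for 1/f
#'   temporal noise.
#' @return an object of class \code{synthetic_scene}.
#' @export
synthetic_scene <- function(n_channels, n_epochs, sampling_rate = 200,
                            epoch_length = 0.75, sources = list(),
                            noise_power = 0.1, seed = 1,
                            trend_weight = 0, comodulation_driver = "target",
                            noise_spectrum = c("white", "pink")) {
  stopifnot(n_epochs >= 1, n_channels >= 1, epoch_length > 0)
  if (trend_weight < 0 || trend_weight >= 1)
    stop("trend_weight must be in [0, 1)")
  comodulation_driver <- match.arg(comodulation_driver, c("target", "trend"))
  noise_spectrum <- match.arg(noise_spectrum)
  for (s in sources) {
    if (!inherits(s, "source_spec")) stop("sources must be source_spec objects")
    if (length(s$pattern) != n_channels)
      stop("source pattern length does not match n_channels")
    if (s$center_freq + s$bandwidth / 2 >= sampling_rate / 2)
      stop("source band exceeds the Nyquist frequency")
  }
  structure(list(n_channels = n_channels, n_epochs = n_epochs,
                 sampling_rate = sampling_rate, epoch_length = epoch_length,
                 sources = sources, noise_power = noise_power, seed = seed,
                 trend_weight = trend_weight,
                 comodulation_driver = comodulation_driver,
                 noise_spectrum = noise_spectrum),
            class = "synthetic_scene")
}

## narrowband unit-variance-ish process: band-filtered white noise.
## Returns a matrix n_epochs x n_samples; epochs are generated independently
## with reflection padding so filter transients never enter the epoch.
narrowband_epochs <- function(n_epochs, n_samples, fs, center, bw, order = 4) {
  lo <- max(center - bw / 2, 1e-3)
  hi <- min(center + bw / 2, fs / 2 * 0.99)
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  pad <- max(n_samples, ceiling(2 * fs / lo))
  out <- matrix(0, n_epochs, n_samples)
  for (e in seq_len(n_epochs)) {
    w <- stats::rnorm(n_samples + 2 * pad)
    f <- signal::filtfilt(bf, w)
    out[e, ] <- f[(pad + 1):(pad + n_samples)]
  }
  out
}

## gain g of the amplitude law sd_e = baseline_sd * exp(g * drive_e) such
## that corr(log bandpower, drive) = r. Exact relation: log power =
## 2 g drive + log V_e with V_e the (independent) sample-variance noise of
## the unit narrowband process, so r = 2g / sqrt(4 g^2 + var(log V)).
## Inverted in closed form; var(log V) is estimated from calibration epochs.
comodulation_gain <- function(r, var_log_v) {
  if (r == 0) return(0)
  sign(r) * sqrt(var_log_v) * abs(r) / (2 * sqrt(1 - r^2))
}

#' Generate a synthetic scene
#'
#' Instantiates the forward model \eqn{x(t) = A s(t) + noise}: each source
#' is narrowband-filtered white noise whose per-epoch standard deviation is
#' modulated as \code{baseline_sd * exp(g * drive(e))}, with the gain
#' \code{g} calibrated so that the Pearson correlation between per-epoch
#' log-bandpower and the target variable matches the requested
#' \code{comodulation_r}. The exponential law keeps power positive and the
#' power-target link monotone. Sensor data are the pattern-weighted sum of
#' sources plus white (or optionally 1/f) noise. Fully deterministic given
#' the scene seed.
#'
#' @param scene a \code{\link{synthetic_scene}}.
#' @return list with elements \code{epochs} (an \code{\link{epoch_set}}),
#'   \code{z} (per-epoch target, zero mean / unit variance),
#'   \code{true_patterns} (n_channels x n_sources mixing columns) and
#'   \code{source_power} (n_epochs x n_sources realized bandpower).
#' @export
generate_scene <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  with_seed(scene$seed, {
    n_e <- scene$n_epochs; n_c <- scene$n_channels
    fs <- scene$sampling_rate
    n_t <- round(scene$epoch_length * fs)

    ## target variable: standardized mixture of white part and linear trend
    trend <- if (n_e > 1) standardize0(seq_len(n_e)) else 0
    eps <- stats::rnorm(n_e)
    z_raw <- sqrt(1 - scene$trend_weight) * eps +
      sqrt(scene$trend_weight) * trend
    z <- standardize0(z_raw)
    drive <- if (scene$comodulation_driver == "trend" && scene$trend_weight > 0)
      standardize0(trend) else z

    M <- length(scene$sources)
    data <- array(0, c(n_e, n_c, n_t))
    patterns <- matrix(0, n_c, max(M, 1))
    spower <- matrix(0, n_e, max(M, 1))
    for (m in seq_len(M)) {
      src <- scene$sources[[m]]
      patterns[, m] <- src$pattern
      ## calibration run: distribution of the epoch sample-variance noise
      calib <- narrowband_epochs(200, n_t, fs, src$center_freq, src$bandwidth)
      v <- apply(calib, 1, stats::var)
      mv <- mean(v)
      g <- comodulation_gain(src$comodulation_r, stats::var(log(v)))
      sig <- narrowband_epochs(n_e, n_t, fs, src$center_freq, src$bandwidth)
      sig <- sig / sqrt(mv)  # unit expected epoch power
      sd_e <- sqrt(src$baseline_power) * exp(g * drive) / sqrt(mean(exp(2 * g * drive)))
      sig <- sig * sd_e
      spower[, m] <- apply(sig, 1, stats::var)
      for (ch in which(src$pattern != 0))
        data[, ch, ] <- data[, ch, ] + src$pattern[ch] * sig
    }
    if (scene$noise_power > 0) {
      noise <- array(stats::rnorm(n_e * n_c * n_t), c(n_e, n_c, n_t))
      if (scene$noise_spectrum == "pink") {
        ## 1/f shaping per epoch/channel via FFT amplitude weighting
        freqs <- c(1, seq_len(n_t - 1))
        wgt <- 1 / sqrt(pmin(freqs, n_t - freqs + 1))
        for (e in seq_len(n_e)) for (ch in seq_len(n_c)) {
          sp <- stats::fft(noise[e, ch, ]) * wgt
          x <- Re(stats::fft(sp, inverse = TRUE)) / n_t
          noise[e, ch, ] <- x / stats::sd(x)
        }
      }
      data <- data + sqrt(scene$noise_power) * noise
    }
    list(epochs = epoch_set(data, fs,
                            window = c(0, scene$epoch_length),
                            band = "broadband"),
         z = z, true_patterns = patterns, source_power = spower)
  })
}

#' Generate a parametric synthetic force trial
#'
#' Builds a single force trajectory of the pinch-force task for exercising
#' the performance metrics: the force rests at zero before the go-cue,
#' rises smoothly over \code{ramp_time} to \code{1 + overshoot} (linearly
#' when \code{overshoot = 0}), then settles to the target force 1. The
#' start-field exit is stamped at the end of the ramp and the first target
#' hit at the end of the settle phase. \code{jerk_scale} superimposes
#' smooth band-limited noise to vary trajectory smoothness.
#'
#' @param ramp_time rise time in seconds (> 0).
#' @param overshoot fractional overshoot above the target force (>= 0).
#' @param jerk_scale amplitude of superimposed smooth noise (0 = clean).
#' @param sampling_rate Hz.
#' @param seed RNG seed (only used when \code{jerk_scale > 0}).
#' @param condition condition label (\code{"seq1"} or \code{"seq2"}).
#' @return a \code{\link{force_trial}}.
#' @export
generate_force_trial <- function(ramp_time, overshoot = 0, jerk_scale = 0,
                                 sampling_rate = 200, seed = 1,
                                 condition = "seq1") {
  stopifnot(ramp_time > 0, overshoot >= 0)
  fs <- sampling_rate
  settle_time <- if (overshoot > 0) 0.3 else 0
  pre <- 0.2; post <- 0.2
  t_go <- pre
  t_exit <- t_go + ramp_time
  t_hit <- t_exit + settle_time
  total <- t_hit + post
  tt <- seq(0, total, by = 1 / fs)
  f <- numeric(length(tt))
  ramp <- tt >= t_go & tt < t_exit
  f[ramp] <- (1 + overshoot) * (tt[ramp] - t_go) / ramp_time
  if (settle_time > 0) {
    st <- tt >= t_exit & tt < t_hit
    f[st] <- 1 + overshoot * (1 - (tt[st] - t_exit) / settle_time)
  }
  f[tt >= t_hit] <- 1
  if (jerk_scale > 0) {
    f <- f + with_seed(seed, {
      bf <- signal::butter(2, min(8 / (fs / 2), 0.9), type = "low")
      n <- signal::filtfilt(bf, stats::rnorm(length(tt)))
      jerk_scale * n / stats::sd(n)
    })
  }
  force_trial(force = f, sampling_rate = fs, t_go = t_go,
              t_T0_exit = t_exit, t_hit = t_hit, condition = condition)
}

#' Write force-trial event table
#'
#' Writes a CSV of trial events (trial_id, condition, t_go, t_T0_exit,
#' t_hit) for a list of force trials, the interchange format read back by
#' the metrics stage.
#'
#' @param trials list of \code{\link{force_trial}} objects.
#' @param path output CSV path.
#' @export
write_force_events <- function(trials, path) {
  df <- data.frame(trial_id = seq_along(trials),
                   condition = vapply(trials, function(t) t$condition, ""),
                   t_go = vapply(trials, function(t) t$t_go, 0),
                   t_T0_exit = vapply(trials, function(t) t$t_T0_exit, 0),
                   t_hit = vapply(trials, function(t) t$t_hit, 0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
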