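#' Construct a force trial
#'
#' One trial of the sequential visual isometric pinch task: the sampled
#' force trace plus its event timestamps. Time is in seconds from the start
#' of the trace; events must satisfy t_go < t_T0_exit <= t_hit and the
#' trace must cover \code{[t_go, t_hit]}.
#'
#' @param force numeric force trace (sensor units).
#' @param sampling_rate Hz.
#' @param t_go go-cue time (s).
#' @param t_T0_exit time the cursor leaves the start field (s); may be
#'   \code{NA} for trials where the event was not registered.
#' @param t_hit time of the first target-field hit (s).
#' @param condition condition label, one of \code{"seq1"}, \code{"seq2"}.
#' @return an object of class \code{force_trial}.
#' @export
force_trial <- function(force, sampling_rate, t_go, t_T0_exit, t_hit,
                        condition = c("seq1", "seq2")) {
  condition <- match.arg(condition)
  if (!is.na(t_T0_exit) && (t_go >= t_T0_exit || t_T0_exit > t_hit))
    stop("events must satisfy t_go < t_T0_exit <= t_hit")
  dur <- (length(force) - 1) / sampling_rate
  if (t_go < 0 || t_hit > dur + 1e-9)
    stop("trace does not cover [t_go, t_hit]")
  structure(list(force = as.numeric(force), sampling_rate = sampling_rate,
                 t_go = t_go, t_T0_exit = t_T0_exit, t_hit = t_hit,
                 condition = condition), class = "force_trial")
}

## sample indices of the half-open-ish metric window [t_go, t_hit]
trial_window <- function(trial) {
  i0 <- round(trial$t_go * trial$sampling_rate) + 1L
  i1 <- round(trial$t_hit * trial$sampling_rate) + 1L
  i0:min(i1, length(trial$force))
}

#' Reaction time (RT)
#'
#' Time from the go-cue to the exit of the start field, in milliseconds.
#'
#' @param trial a \code{\link{force_trial}}.
#' @return RT in ms.
#' @export
compute_rt <- function(trial) {
  if (is.na(trial$t_T0_exit))
    stop("RT undefined: missing start-field exit event")
  (trial$t_T0_exit - trial$t_go) * 1000
}

#' Trial duration (DUR)
#'
#' Time from the go-cue to the first target hit, in seconds.
#'
#' @param trial a \code{\link{force_trial}}.
#' @return DUR in s.
#' @export
compute_dur <- function(trial) trial$t_hit - trial$t_go

#' Cursor path length (CPL)
#'
#' Total variation of the force trace between go-cue and first hit,
#' \eqn{\int |dF/dt| dt}, evaluated as the discrete sum of absolute
#' successive differences.
#'
#' @param trial a \code{\link{force_trial}}.
#' @return CPL in force units.
#' @export
compute_cpl <- function(trial) {
  w <- trial_window(trial)
  if (length(w) < 2) stop("CPL undefined: window shorter than 2 samples")
  sum(abs(diff(trial$force[w])))
}

## third derivative by finite differences; interior: central 5-point stencil
## (exact for cubics), ends: one-sided 4-point stencils (also cubic-exact).
third_derivative <- function(f, fs) {
  n <- length(f)
  h <- 1 / fs
  d <- numeric(n)
  if (n >= 5) {
    i <- 3:(n - 2)
    d[i] <- (f[i + 2] - 2 * f[i + 1] + 2 * f[i - 1] - f[i - 2]) / (2 * h^3)
  }
  one_sided <- function(idx, dir) {
    s <- idx + dir * (0:3)
    dir^3 * (-f[s[1]] + 3 * f[s[2]] - 3 * f[s[3]] + f[s[4]]) / h^3
  }
  d[1] <- one_sided(1, 1); d[2] <- one_sided(2, 1)
  d[n - 1] <- one_sided(n - 1, -1); d[n] <- one_sided(n, -1)
  d
}

#' Integrated squared jerk (ISJ)
#'
#' \eqn{\int |d^3F/dt^3|^2 dt} over \code{[t_go, t_hit]}. The third
#' derivative is estimated by central finite differences (one-sided at the
#' window ends, both stencils exact for cubic polynomials — so ISJ is
#' invariant to adding any quadratic to the trace); the integral is
#' evaluated by the trapezoidal rule.
#'
#' @param trial a \code{\link{force_trial}}.
#' @return ISJ in (force/s^3)^2 * s.
#' @export
compute_isj <- function(trial) {
  w <- trial_window(trial)
  if (length(w) < 4) stop("ISJ undefined: need >= 4 samples in window")
  j2 <- third_derivative(trial$force[w], trial$sampling_rate)^2
  h <- 1 / trial$sampling_rate
  h * (sum(j2) - (j2[1] + j2[length(j2)]) / 2)
}

#' Normalized jerk (NJ)
#'
#' \eqn{ISJ \cdot DUR^{5/2} / CPL^2}. The exponent on DUR is configurable
#' (\code{5} makes the quantity dimensionless; the default \code{5/2}
#' follows the published definition of the score).
#'
#' @param isj,dur,cpl the three ingredient metrics (CPL must be > 0).
#' @param exponent exponent on DUR, default \code{5/2}.
#' @return NJ (scalar).
#' @export
compute_nj <- function(isj, dur, cpl, exponent = 5 / 2) {
  if (cpl <= 0) stop("NJ undefined: CPL must be > 0")
  isj * dur^exponent / cpl^2
}

#' All five performance metrics for a set of trials
#'
#' @param trials list of \code{\link{force_trial}} objects.
#' @param nj_exponent exponent on DUR inside NJ.
#' @return data.frame with one row per trial: trial_id, condition, RT (ms),
#'   DUR (s), CPL, ISJ, NJ.
#' @export
force_metrics <- function(trials, nj_exponent = 5 / 2) {
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    isj <- compute_isj(tr); dur <- compute_dur(tr); cpl <- compute_cpl(tr)
    data.frame(trial_id = i, condition = tr$condition,
               RT = compute_rt(tr), DUR = dur, CPL = cpl, ISJ = isj,
               NJ = compute_nj(isj, dur, cpl, nj_exponent))
  })
  do.call(rbind, rows)
}

#' Standardize metrics per condition and pool chronologically
#'
#' The two target-sequence conditions have different difficulty, so every
#' metric except RT is z-scored within its condition (population standard
#' deviation) before the trials of both conditions are pooled; RT is passed
#' through raw. Rows are returned in the original (chronological) order.
#'
#' @param metrics data.frame as returned by \code{\link{force_metrics}}
#'   (columns \code{condition} plus metric columns).
#' @param standardize character vector of metric columns to standardize;
#'   default all metric columns except \code{RT}.
#' @return data.frame of the same shape with standardized columns.
#' @export
standardize_and_pool <- function(metrics,
                                 standardize = setdiff(
                                   intersect(c("RT", "DUR", "CPL", "ISJ", "NJ"),
                                             names(metrics)), "RT")) {
  out <- metrics
  for (cond in unique(metrics$condition)) {
    idx <- metrics$condition == cond
    if (sum(idx) < 2)
      stop("need >= 2 trials per condition to standardize")
    for (m in standardize)
      out[[m]][idx] <- standardize0(metrics[[m]][idx])
  }
  out
}
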