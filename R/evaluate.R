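#' Chronological cross-validation scheme
#'
#' Splits \code{n_epochs} chronologically ordered trials into \code{K}
#' contiguous, disjoint folds whose sizes differ by at most one (the
#' earlier folds take the remainder). Contiguous time-ordered folds
#' respect the nonstationarity of a session: a model is always tested on a
#' time block it never saw.
#'
#' @param n_epochs number of trials.
#' @param K fold count (default 5).
#' @return object of class \code{cv_scheme}: list with \code{K} and
#'   \code{folds} (list of index vectors).
#' @export
cv_scheme <- function(n_epochs, K = 5) {
  if (n_epochs < 2 * K) stop("need at least 2 trials per fold")
  base <- n_epochs %/% K
  sizes <- rep(base, K) + c(rep(1L, n_epochs %% K), rep(0L, K - n_epochs %% K))
  ends <- cumsum(sizes)
  folds <- Map(function(a, b) a:b, ends - sizes + 1L, ends)
  structure(list(K = K, folds = folds), class = "cv_scheme")
}

#' Overall prediction correlation
#'
#' Pearson correlation between the true target and the concatenated
#' cross-validated predictions.
#'
#' @param z_true,z_est equal-length numeric vectors (length >= 3).
#' @return correlation, or \code{NA} with a warning if either input has
#'   zero variance.
#' @export
r_all <- function(z_true, z_est) {
  if (length(z_true) != length(z_est) || length(z_true) < 3)
    stop("need equal-length vectors of length >= 3")
  if (stats::sd(z_true) == 0 || stats::sd(z_est) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(z_true, z_est)
}

#' Mean fold-wise prediction correlation
#'
#' Mean over folds of the Pearson correlation between true and predicted
#' targets within each fold. Unlike the overall correlation this is blind
#' to slow between-fold (session-trend) covariation, so it isolates
#' genuine trial-by-trial predictive power.
#'
#' @param z_true,z_est per-trial vectors.
#' @param scheme a \code{\link{cv_scheme}}.
#' @return list: \code{r_folds} (mean) and \code{r_j} (per-fold vector).
#' @export
r_folds <- function(z_true, z_est, scheme) {
  r_j <- vapply(scheme$folds, function(f) {
    if (stats::sd(z_true[f]) == 0 || stats::sd(z_est[f]) == 0) NA_real_
    else stats::cor(z_true[f], z_est[f])
  }, 0)
  list(r_folds = mean(r_j), r_j = r_j)
}

#' Fold-sign homogeneity
#'
#' Number of folds whose fold-wise correlation shares the sign of the
#' overall correlation, using the unit step with \eqn{\Theta(0) = 1} (a
#' zero fold correlation counts as a match). A fully homogeneous component
#' reaches \code{K}.
#'
#' @param R_all overall correlation.
#' @param r_j per-fold correlations.
#' @return integer in \code{0..K}.
#' @export
h_folds <- function(R_all, r_j) {
  sum(sign(R_all) * sign(r_j) >= 0)
}

#' ROC separability of the prediction (z-AUC)
#'
#' Casts the continuous prediction as a two-class problem: trials are
#' labeled high/low performance by the 50th percentile (median) of the
#' true target, and the area under the ROC curve of the predicted values
#' against those labels is returned (midrank handling of ties, i.e. the
#' Wilcoxon statistic). Chance level is 0.5; it is invariant under any
#' strictly monotone transform of the predictions.
#'
#' @param z_true true per-trial target.
#' @param z_est predicted per-trial values (the scores).
#' @param split_percentile percentile of \code{z_true} defining the class
#'   split (default 50).
#' @return AUC in \[0, 1\].
#' @export
z_auc <- function(z_true, z_est, split_percentile = 50) {
  thr <- stats::quantile(z_true, split_percentile / 100, names = FALSE)
  pos <- z_true > thr
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    warning("degenerate split: one class empty, z-AUC undefined")
    return(NA_real_)
  }
  r <- rank(z_est)                       # midranks handle ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated single-trial prediction of one component
#'
#' Runs K-fold chronological cross-validation of the SPoC pipeline: for
#' each fold, the decomposition is fitted on the remaining folds (target
#' standardized with training-fold statistics only), the filter of the
#' requested eigenvalue rank predicts the held-out fold's per-epoch
#' bandpower, and the fold's test pattern \eqn{a_j = C_{te,j} w_{tr}} is
#' recorded. Predictions are concatenated in chronological order and the
#' full correlation/separability battery is computed.
#'
#' @param x an \code{\link{epoch_set}} (band-filtered) or covariance stack
#'   from \code{\link{epoch_covariances}}.
#' @param z per-trial target variable.
#' @param scheme a \code{\link{cv_scheme}} (default 5 folds).
#' @param rank eigenvalue rank of the component to evaluate.
#' @param z_score optional alternative target used only for SCORING
#'   (z-AUC/correlations); defaults to \code{z}. Used by the label-noise
#'   stress test, which trains on corrupted labels but always scores
#'   against the clean ones.
#' @param shrinkage passed to \code{\link{spoc}}.
#' @return object of class \code{component_eval}: \code{z_true},
#'   \code{z_est}, \code{R_all}, \code{R_folds}, \code{r_j},
#'   \code{H_folds}, \code{z_auc}, \code{fold_patterns} (channels x K),
#'   \code{rank}, \code{n_epochs}, \code{scheme}; \code{aauc_snr} is
#'   \code{NA} until filled by \code{\link{aauc_snr}}.
#' @export
crossval_predict <- function(x, z, scheme = NULL, rank = 1,
                             z_score = NULL, shrinkage = 0) {
  covs <- if (is.matrix(x) && !is.null(attr(x, "n_channels"))) x
          else epoch_covariances(x)
  n_e <- nrow(covs)
  if (length(z) != n_e) stop("length(z) must equal the number of epochs")
  scheme <- scheme %||% cv_scheme(n_e)
  z_score <- z_score %||% z
  n_c <- attr(covs, "n_channels")
  z_est <- numeric(n_e)
  fold_patterns <- matrix(NA_real_, n_c, scheme$K)
  ok <- TRUE
  for (j in seq_len(scheme$K)) {
    te <- scheme$folds[[j]]
    tr <- setdiff(seq_len(n_e), te)
    covs_tr <- covs[tr, , drop = FALSE]
    attr(covs_tr, "n_channels") <- n_c
    fit <- tryCatch(spoc_core(covs_tr, z[tr], shrinkage = shrinkage),
                    error = function(e) NULL)
    if (is.null(fit) || rank > ncol(fit$W)) { ok <- FALSE; break }
    w <- fit$W[, rank]
    wv <- as.vector(tcrossprod(w))
    z_est[te] <- covs[te, , drop = FALSE] %*% wv
    Cte <- matrix(colMeans(covs[te, , drop = FALSE]), n_c, n_c)
    fold_patterns[, j] <- Cte %*% w
  }
  if (!ok)
    return(structure(list(valid = FALSE, rank = rank, n_epochs = n_e),
                     class = "component_eval"))
  R_all <- r_all(z_score, z_est)
  rf <- r_folds(z_score, z_est, scheme)
  structure(list(valid = TRUE, z_true = z_score, z_est = z_est,
                 R_all = R_all, R_folds = rf$r_folds, r_j = rf$r_j,
                 H_folds = h_folds(R_all, rf$r_j),
                 z_auc = z_auc(z_score, z_est),
                 aauc_snr = NA_real_,
                 fold_patterns = fold_patterns, rank = rank,
                 n_epochs = n_e, scheme = scheme),
            class = "component_eval")
}

#' @export
print.component_eval <- function(x, ...) {
  if (!isTRUE(x$valid)) {
    cat("<component_eval> invalid (cross-validated fit failed)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<component_eval> rank %d, %d trials\n  R_all = %.3f  R_folds = %.3f  H_folds = %d/%d  z-AUC = %.3f  AAUC_SNR = %s\n",
    x$rank, x$n_epochs, x$R_all, x$R_folds, x$H_folds, x$scheme$K,
    x$z_auc, ifelse(is.na(x$aauc_snr), "<not computed>",
                    sprintf("%.3f", x$aauc_snr))))
  invisible(x)
}

## excess-area normalization of a z-AUC-vs-SNR curve
aauc_from_curve <- function(aucs) mean(aucs - 0.5)

#' Label-noise stability (AAUC over an SNR grid)
#'
#' Stresses the robustness of a component by training on progressively
#' corrupted labels: at each SNR level, white noise of variance
#' \eqn{10^{-SNR/10}} is added to the standardized target (so
#' \eqn{SNR_{dB} = 10 \log_{10}(Var[\tilde z]/Var[\epsilon])}), the
#' cross-validated pipeline is retrained on the noisy labels, and z-AUC is
#' scored against the ORIGINAL clean target. The score is the mean excess
#' over chance, \eqn{mean(zAUC(SNR) - 0.5)}, across the grid — large for
#' components whose spatial filter survives heavy label corruption.
#'
#' @param x band-filtered \code{\link{epoch_set}} or covariance stack.
#' @param z clean per-trial target.
#' @param scheme a \code{\link{cv_scheme}}.
#' @param rank component rank.
#' @param snr_grid_db SNR levels in dB (default \code{seq(-20, 10, 5)}).
#' @param reps noisy-label draws per SNR level (default 3).
#' @param seed RNG seed; the result is deterministic given it.
#' @param shrinkage passed to the fits.
#' @return list: \code{aauc_snr} (scalar), \code{curve} (data.frame
#'   snr_db / z_auc averaged over reps).
#' @export
aauc_snr <- function(x, z, scheme = NULL, rank = 1,
                     snr_grid_db = seq(-20, 10, by = 5), reps = 3,
                     seed = 1, shrinkage = 0) {
  covs <- if (is.matrix(x) && !is.null(attr(x, "n_channels"))) x
          else epoch_covariances(x)
  scheme <- scheme %||% cv_scheme(nrow(covs))
  zt <- standardize0(z)
  with_seed(seed, {
    curve <- vapply(snr_grid_db, function(snr) {
      sd_eps <- sqrt(10^(-snr / 10))
      mean(vapply(seq_len(reps), function(r) {
        z_noisy <- zt + stats::rnorm(length(zt), sd = sd_eps)
        ev <- crossval_predict(covs, z_noisy, scheme, rank, z_score = z,
                               shrinkage = shrinkage)
        if (isTRUE(ev$valid)) ev$z_auc else NA_real_
      }, 0), na.rm = TRUE)
    }, 0)
    list(aauc_snr = aauc_from_curve(curve),
         curve = data.frame(snr_db = snr_grid_db, z_auc = curve))
  })
}

#' Selection thresholds for robust components
#'
#' Default thresholds correspond to the 85th percentile of each score over
#' a large component population in the motor-performance study this
#' workflow implements: separability z-AUC >= 0.59, label-noise stability
#' AAUC >= 0.18, full fold-sign homogeneity (all K folds), and at least
#' 150 trials for convergence of the decomposition.
#'
#' @param z_auc_min,aauc_min,h_folds_min,n_e_min the four thresholds.
#' @return list of class \code{selection_thresholds}.
#' @export
selection_thresholds <- function(z_auc_min = 0.59, aauc_min = 0.18,
                                 h_folds_min = 5, n_e_min = 150) {
  structure(list(z_auc_min = z_auc_min, aauc_min = aauc_min,
                 h_folds_min = h_folds_min, n_e_min = n_e_min),
            class = "selection_thresholds")
}

#' Apply the multi-criterion component selection
#'
#' Keeps components satisfying, in parallel: z-AUC >= \code{z_auc_min},
#' AAUC_SNR >= \code{aauc_min}, H_folds == \code{h_folds_min} (all folds
#' sign-homogeneous) and n_epochs >= \code{n_e_min}.
#'
#' @param evals list of \code{component_eval} objects (with
#'   \code{aauc_snr} filled).
#' @param thresholds a \code{\link{selection_thresholds}}.
#' @return logical vector of selection flags.
#' @export
select_components <- function(evals, thresholds = selection_thresholds()) {
  vapply(evals, function(ev) {
    isTRUE(ev$valid) &&
      !is.na(ev$z_auc) && ev$z_auc >= thresholds$z_auc_min &&
      !is.na(ev$aauc_snr) && ev$aauc_snr >= thresholds$aauc_min &&
      ev$H_folds == thresholds$h_folds_min &&
      ev$n_epochs >= thresholds$n_e_min
  }, NA)
}

#' Discriminate single-trial from session-trend predictors
#'
#' A component with high overall correlation but low fold-wise correlation
#' tracks a slow session trend (both the target and the component power
#' drift over the session) rather than trial-by-trial variation; if both
#' are high and sign-consistent it is a genuine single-trial predictor.
#'
#' @param evaluation a \code{component_eval}.
#' @param r_all_min minimum |R_all| to call the component predictive at
#'   all (default 0.2).
#' @param folds_ratio_min minimum |R_folds| / |R_all| for the single-trial
#'   label (default 0.5).
#' @return one of \code{"single_trial"}, \code{"session_trend"},
#'   \code{"neither"}.
#' @export
classify_predictor <- function(evaluation, r_all_min = 0.2,
                               folds_ratio_min = 0.5) {
  if (!isTRUE(evaluation$valid) || is.na(evaluation$R_all))
    return("neither")
  Ra <- evaluation$R_all; Rf <- evaluation$R_folds
  if (abs(Ra) < r_all_min) return("neither")
  if (abs(Rf) >= folds_ratio_min * abs(Ra) && sign(Rf) == sign(Ra))
    "single_trial"
  else "session_trend"
}
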