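#' Source Power Comodulation (SPoC) spatial filtering
#'
#' Fits the SPoC-lambda decomposition: spatial filters \code{w} whose
#' projected per-epoch bandpower \eqn{\Phi(e) = Var[w'x(t)](e)} maximally
#' covaries with a continuous per-trial target variable \code{z}, subject
#' to the unit-variance constraint \eqn{Var[w'x] = 1} on the training data.
#' The objective is solved as a generalized eigenvalue problem
#' \deqn{C_z w = \lambda \bar{C} w}
#' with \eqn{\bar{C}} the epoch-mean channel covariance and
#' \eqn{C_z = mean_e[\tilde z(e) C(e)]} the target-weighted covariance
#' (\eqn{\tilde z} standardized on the training set). Each eigenvalue
#' equals the covariance between the corresponding component's epoch
#' bandpower and \eqn{\tilde z}, so filters are returned in descending
#' eigenvalue order. Activation patterns are recovered from the filters as
#' \eqn{A = \bar{C} W}.
#'
#' Numerically, the problem is solved by symmetric whitening:
#' eigendecompose \eqn{\bar{C}}, floor its spectrum at
#' \code{1e-10 * trace} (rank-deficient input triggers a warning), and
#' eigendecompose the whitened \eqn{C_z}. Filters are rescaled to exact
#' unit projected training variance, and the sign of each filter is fixed
#' so the largest-magnitude entry of its pattern is positive.
#'
#' @param x an \code{\link{epoch_set}} (bandpass-filtered to the band of
#'   interest), a 3-d array \code{[epochs, channels, samples]}, or a
#'   precomputed covariance stack from \code{\link{epoch_covariances}}.
#' @param z numeric per-epoch target variable, length \code{n_epochs}.
#' @param shrinkage optional shrinkage in \[0, 1\] of \eqn{\bar{C}} towards
#'   the scaled identity (Ledoit-Wolf-style target), for ill-conditioned
#'   mean covariances; default 0.
#' @return an object of class \code{spoc}: list with \code{W} (filters,
#'   columns eigen-ordered), \code{lambda}, \code{A} (patterns),
#'   \code{Cbar}, \code{z_mean}, \code{z_sd}, \code{n_epochs},
#'   \code{channel_names}, \code{band}, \code{window}.
#' @references Dähne et al. (2014), SPoC: a novel framework for relating
#'   the amplitude of neuronal oscillations to behaviorally relevant
#'   parameters. NeuroImage 86:111-122.
#' @examples
#' scn <- synthetic_scene(n_channels = 6, n_epochs = 120, seed = 3,
#'                        sources = list(source_spec(c(1, 2, 0, 0, 1, 0),
#'                                                   center_freq = 10,
#'                                                   bandwidth = 4,
#'                                                   comodulation_r = 0.8)))
#' sc <- generate_scene(scn)
#' m <- spoc(sc$epochs, sc$z)
#' m
#' cor(predict(m, sc$epochs), sc$z)
#' @export
spoc <- function(x, z, shrinkage = 0) {
  meta <- list(channel_names = NULL, band = NULL, window = NULL)
  if (inherits(x, "epoch_set")) {
    meta <- x[c("channel_names", "band", "window")]
    covs <- epoch_covariances(x)
  } else if (is.array(x) && length(dim(x)) == 3L) {
    covs <- epoch_covariances(epoch_set(x, sampling_rate = 1))
  } else if (is.matrix(x) && !is.null(attr(x, "n_channels"))) {
    covs <- x
  } else stop("'x' must be an epoch_set, a 3-d array, or a covariance stack")
  if (!all(is.finite(covs)) || !all(is.finite(z))) stop("non-finite data")
  if (nrow(covs) != length(z))
    stop("length(z) must equal the number of epochs")
  fit <- spoc_core(covs, z, shrinkage = shrinkage)
  structure(c(fit, meta), class = "spoc")
}

## core solver on a flattened covariance stack (n_epochs x n_c^2)
spoc_core <- function(covs, z, shrinkage = 0) {
  n_c <- attr(covs, "n_channels")
  n_e <- nrow(covs)
  z_mean <- mean(z)
  z_sd <- sqrt(mean((z - z_mean)^2))
  if (z_sd == 0) stop("target variable has zero variance")
  zt <- (z - z_mean) / z_sd

  Cbar <- matrix(colMeans(covs), n_c, n_c)
  Cz <- matrix(crossprod(covs, zt) / n_e, n_c, n_c)
  Cbar <- (Cbar + t(Cbar)) / 2
  Cz <- (Cz + t(Cz)) / 2
  if (shrinkage > 0) {
    mu <- mean(diag(Cbar))
    Cbar <- (1 - shrinkage) * Cbar + shrinkage * mu * diag(n_c)
  }

  eC <- eigen(Cbar, symmetric = TRUE)
  floor_val <- 1e-10 * sum(diag(Cbar))
  if (any(eC$values < floor_val))
    warning("rank-deficient mean covariance; eigenvalue floor applied")
  d <- pmax(eC$values, floor_val)
  Wh <- eC$vectors %*% (t(eC$vectors) / sqrt(d))   # Cbar^{-1/2}
  S <- Wh %*% Cz %*% t(Wh)
  S <- (S + t(S)) / 2
  eS <- eigen(S, symmetric = TRUE)
  W <- Wh %*% eS$vectors     # Wh symmetric, so this is Cbar^{-1/2} U
  ## exact unit projected training variance w' Cbar w = 1
  pv <- colSums(W * (Cbar %*% W))
  W <- sweep(W, 2, sqrt(pv), "/")
  A <- Cbar %*% W
  ## sign convention: largest-|entry| of each pattern positive
  for (k in seq_len(n_c)) {
    j <- which.max(abs(A[, k]))
    if (A[j, k] < 0) { A[, k] <- -A[, k]; W[, k] <- -W[, k] }
  }
  list(W = W, lambda = eS$values, A = A, Cbar = Cbar,
       z_mean = z_mean, z_sd = z_sd, n_epochs = n_e)
}

#' @export
print.spoc <- function(x, ...) {
  n_c <- nrow(x$W)
  cat(sprintf("SPoC decomposition: %d filters from %d epochs\n",
              n_c, x$n_epochs))
  k <- min(5, n_c)
  cat(sprintf("  top eigenvalues (bandpower-target covariance): %s\n",
              paste(sprintf("%.4f", x$lambda[1:k]), collapse = ", ")))
  rs <- rank_select(x$lambda)
  cat(sprintf("  ranks passing the eigenvalue criterion: %s\n",
              if (length(rs$selected_ranks))
                paste(rs$selected_ranks, collapse = ", ") else "none"))
  invisible(x)
}

#' @export
summary.spoc <- function(object, ...) {
  rs <- rank_select(object$lambda)
  out <- list(n_channels = nrow(object$W), n_epochs = object$n_epochs,
              lambda = object$lambda, rank_selection = rs,
              band = object$band, window = object$window)
  class(out) <- "summary.spoc"
  out
}

#' @export
print.summary.spoc <- function(x, ...) {
  cat(sprintf("SPoC decomposition (%d channels, %d epochs)\n",
              x$n_channels, x$n_epochs))
  if (is.numeric(x$band))
    cat(sprintf("  band [%.2f, %.2f] Hz\n", x$band[1], x$band[2]))
  cat("  eigenvalue spectrum:\n")
  print(round(x$lambda, 4))
  cat(sprintf("  selected ranks (detrended spectrum, 1.5-sigma rule): %s\n",
              if (length(x$rank_selection$selected_ranks))
                paste(x$rank_selection$selected_ranks, collapse = ", ")
              else "none"))
  invisible(x)
}

#' @describeIn spoc spatial filters W (columns = components).
#' @param object,... method arguments.
#' @export
coef.spoc <- function(object, ...) object$W

#' Predict the target variable on new epochs
#'
#' Applies a trained SPoC filter to (test) epochs and returns the per-epoch
#' bandpower of the projected signal, \eqn{z_{est}(e) = Var[w'x(t)](e)} —
#' the single-trial prediction of the target variable (on the bandpower
#' scale; it is compared to the true target by correlation/rank statistics,
#' not absolute value).
#'
#' @param object a fitted \code{\link{spoc}} model.
#' @param newdata an \code{\link{epoch_set}}, 3-d array, or covariance
#'   stack with the same channel count/order as the training data.
#' @param rank which component to use (eigenvalue rank, default 1).
#' @param ... unused.
#' @return numeric vector of per-epoch predictions.
#' @export
predict.spoc <- function(object, newdata, rank = 1, ...) {
  covs <- if (is.matrix(newdata) && !is.null(attr(newdata, "n_channels")))
    newdata
  else if (inherits(newdata, "epoch_set")) epoch_covariances(newdata)
  else if (is.array(newdata) && length(dim(newdata)) == 3L)
    epoch_covariances(epoch_set(newdata, sampling_rate = 1))
  else stop("'newdata' must be an epoch_set, 3-d array, or covariance stack")
  n_c <- attr(covs, "n_channels")
  if (n_c != nrow(object$W))
    stop("channel count mismatch between model and new data")
  w <- object$W[, rank]
  as.numeric(covs %*% as.vector(tcrossprod(w)))
}

#' @describeIn spoc training residuals of the standardized target against
#'   the standardized rank-1 bandpower prediction (requires the training
#'   covariance stack or epochs via \code{newdata}).
#' @param newdata training epochs (needed because the model does not store
#'   the raw data).
#' @param rank component rank.
#' @export
residuals.spoc <- function(object, newdata, z, rank = 1, ...) {
  zt <- (z - object$z_mean) / object$z_sd
  p <- predict(object, newdata, rank = rank)
  zt - standardize0(p)
}

#' Plot a SPoC decomposition
#'
#' Left panel: the eigenvalue spectrum with its least-squares trend line
#' and the 1.5-sigma residual band used by the rank-selection rule; spiked
#' eigenvalues above the band are the informative components. Right panel:
#' the activation pattern of the chosen rank as a channel bar chart.
#'
#' @param x a fitted \code{\link{spoc}} model.
#' @param rank pattern to display (default 1).
#' @param ... unused.
#' @export
plot.spoc <- function(x, rank = 1, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  lam <- x$lambda
  idx <- seq_along(lam)
  graphics::plot(idx, lam, pch = 19, xlab = "rank", ylab = expression(lambda),
                 main = "eigenvalue spectrum")
  fit <- stats::lm.fit(cbind(1, idx), lam)
  graphics::abline(fit$coefficients[1], fit$coefficients[2], lty = 2)
  thr <- fit$coefficients[1] + fit$coefficients[2] * idx +
    1.5 * stats::sd(fit$residuals)
  graphics::lines(idx, thr, col = "red", lty = 3)
  a <- x$A[, rank]
  nm <- x$channel_names %||% paste0("ch", seq_along(a))
  graphics::barplot(a, names.arg = nm, las = 2, cex.names = 0.6,
                    main = sprintf("pattern, rank %d", rank),
                    ylab = "activation (a.u.)")
  invisible(x)
}

#' Fold-wise test pattern
#'
#' The activation pattern of a training-fold filter evaluated on test-fold
#' data, \eqn{a_j = C_{te,j} w_{tr}} with \eqn{C_{te,j}} the mean
#' channel covariance of the test epochs. Comparing fold patterns across
#' folds probes the spatial stationarity of a component.
#'
#' @param w_tr spatial filter (length n_channels).
#' @param test_epochs an \code{\link{epoch_set}}, 3-d array, or covariance
#'   stack of the test fold.
#' @return numeric pattern vector.
#' @export
fold_pattern <- function(w_tr, test_epochs) {
  covs <- if (is.matrix(test_epochs) && !is.null(attr(test_epochs, "n_channels")))
    test_epochs
  else if (inherits(test_epochs, "epoch_set")) epoch_covariances(test_epochs)
  else epoch_covariances(epoch_set(test_epochs, sampling_rate = 1))
  n_c <- attr(covs, "n_channels")
  Cte <- matrix(colMeans(covs), n_c, n_c)
  as.numeric(Cte %*% w_tr)
}

#' Eigenvalue-based rank selection
#'
#' Identifies which SPoC components stand out from the bulk of the
#' eigenvalue spectrum: a least-squares line is fitted to the descending
#' spectrum, and ranks whose residual exceeds \code{1.5 * sd(residuals)}
#' are selected, restricted to positive eigenvalues (only the
#' positive-covariance side is ranked).
#'
#' @param lambda eigenvalues sorted descending (length >= 3).
#' @param n_sigma residual threshold multiplier (default 1.5).
#' @return list of class \code{rank_selection}: \code{selected_ranks},
#'   \code{residuals}, \code{sigma_r}.
#' @export
rank_select <- function(lambda, n_sigma = 1.5) {
  n <- length(lambda)
  if (n < 3) stop("need >= 3 eigenvalues for rank selection")
  if (is.unsorted(rev(lambda))) stop("eigenvalues must be sorted descending")
  idx <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, idx), lambda)
  r <- fit$residuals
  sigma_r <- stats::sd(r)
  sel <- if (sigma_r > 0) which(r > n_sigma * sigma_r & lambda > 0)
         else integer(0)
  structure(list(selected_ranks = as.integer(sel), residuals = r,
                 sigma_r = sigma_r), class = "rank_selection")
}

#' Serialize a SPoC model
#'
#' Writes filters, patterns, eigenvalues and metadata as JSON (matrices in
#' column-major lists) plus a per-channel CSV of the patterns for
#' topography tools.
#'
#' @param model a \code{\link{spoc}} model.
#' @param path output directory.
#' @export
write_spoc <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(W = model$W, lambda = model$lambda, A = model$A,
         Cbar = model$Cbar, z_mean = model$z_mean, z_sd = model$z_sd,
         n_epochs = model$n_epochs, channel_names = model$channel_names,
         band = model$band, window = model$window),
    file.path(path, "spoc_model.json"), digits = NA)
  pat <- as.data.frame(model$A)
  names(pat) <- paste0("rank", seq_len(ncol(pat)))
  pat <- cbind(channel = model$channel_names %||%
                 paste0("ch", seq_len(nrow(pat))), pat)
  utils::write.csv(pat, file.path(path, "patterns.csv"), row.names = FALSE)
  invisible(path)
}
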