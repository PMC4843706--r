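#' Default logarithmic frequency-band grid
#'
#' Builds the band grid of the scan: lower edges \code{f0} log-spaced over
#' \code{[f_min, f_max / (1 + rel_bw)]} with bandwidth growing
#' proportionally to \code{f0} (constant relative bandwidth, so neighbors
#' overlap), and every band intersecting the power-line exclusion zone
#' removed. The defaults emit 55 band configurations spanning roughly
#' 1-100 Hz with a gap around the 50 Hz line.
#'
#' @param f_min,f_max frequency range in Hz.
#' @param n number of \code{f0} grid points before exclusion (default 63).
#' @param rel_bw relative bandwidth: \code{df = rel_bw * f0} (default 0.4).
#' @param exclusion length-2 power-line exclusion zone in Hz (default
#'   \code{c(45, 55)}); \code{NULL} or empty disables it.
#' @return data.frame with columns \code{f0}, \code{df}.
#' @export
default_band_grid <- function(f_min = 1, f_max = 100, n = 63, rel_bw = 0.4,
                              exclusion = c(45, 55)) {
  if (f_min <= 0 || f_min >= f_max) stop("need 0 < f_min < f_max")
  f0 <- exp(seq(log(f_min), log(f_max / (1 + rel_bw)), length.out = n))
  df <- rel_bw * f0
  keep <- rep(TRUE, n)
  if (length(exclusion) == 2) {
    keep <- (f0 + df) < exclusion[1] | f0 > exclusion[2]
  }
  out <- data.frame(f0 = f0[keep], df = df[keep])
  if (!nrow(out)) stop("band grid is empty")
  out
}

#' Scan configuration
#'
#' @param bands data.frame with \code{f0}, \code{df} columns (default
#'   \code{\link{default_band_grid}()}).
#' @param metrics character vector of target metric names to scan.
#' @param window epoch window \code{c(t0, dt)} in seconds relative to the
#'   go-cue; default \code{c(-0.8, 0.75)} — a 750 ms pre-movement window
#'   starting 800 ms before the go-cue.
#' @param K cross-validation folds.
#' @param thresholds a \code{\link{selection_thresholds}}.
#' @param seed RNG seed governing the label-noise stress test.
#' @param compute_aauc run the (costly) label-noise stress test per cell;
#'   if FALSE, \code{aauc_snr} stays \code{NA} and cannot gate selection.
#' @param snr_grid_db,reps stress-test parameters, see
#'   \code{\link{aauc_snr}}.
#' @param max_ranks cap on evaluated ranks per cell (default 3).
#' @param shrinkage covariance shrinkage for all fits.
#' @return list of class \code{scan_config}.
#' @export
scan_config <- function(bands = default_band_grid(),
                        metrics = c("RT", "DUR", "CPL", "ISJ", "NJ"),
                        window = c(-0.8, 0.75), K = 5,
                        thresholds = selection_thresholds(), seed = 1,
                        compute_aauc = TRUE,
                        snr_grid_db = seq(-20, 10, by = 5), reps = 3,
                        max_ranks = 3, shrinkage = 0) {
  stopifnot(nrow(bands) >= 1, length(metrics) >= 1)
  structure(list(bands = bands, metrics = metrics, window = window, K = K,
                 thresholds = thresholds, seed = seed,
                 compute_aauc = compute_aauc, snr_grid_db = snr_grid_db,
                 reps = reps, max_ranks = max_ranks, shrinkage = shrinkage),
            class = "scan_config")
}

## band epochs from either broadband epochs or a continuous recording;
## continuous input is filtered first and epoched afterwards
band_epochs <- function(x, band, config) {
  if (inherits(x, "epoch_set")) {
    bandpass_epochs(x, band$f0, band$df)
  } else if (is.list(x) && !is.null(x$data) && !is.null(x$events)) {
    filt <- bandpass(x$data, band$f0, band$df, x$sampling_rate)
    extract_epochs(filt, x$events, config$window[1], config$window[2],
                   x$sampling_rate, x$channel_names)
  } else stop("'x' must be an epoch_set or list(data, events, sampling_rate)")
}

#' Run the full band x metric x rank grid scan
#'
#' The workflow's main orchestration: for every frequency band the input
#' is bandpass-filtered (continuous input is filtered before epoching;
#' broadband epochs are filtered epoch-wise with reflection padding), and
#' for every target metric a full-data SPoC decomposition determines the
#' eigenvalue ranks worth evaluating (\code{\link{rank_select}}; rank 1 is
#' always evaluated). Each (band, metric, rank) cell is then scored by
#' chronological cross-validation, the z-AUC separability, fold
#' homogeneity and — unless disabled — the label-noise stability AAUC,
#' and flagged by the multi-criterion selection. A channel-wise log-
#' bandpower regression baseline is run per (band, metric) cell for
#' comparison. Failures in individual cells are recorded and the scan
#' continues. Deterministic given the config seed.
#'
#' @param x broadband \code{\link{epoch_set}} or
#'   \code{list(data, events, sampling_rate, channel_names)} for a
#'   continuous recording.
#' @param targets named list or data.frame of per-trial target variables
#'   (one per metric in \code{config$metrics}).
#' @param config a \code{\link{scan_config}}.
#' @return object of class \code{spoc_scan}: \code{table} (one row per
#'   cell), \code{evals} (the \code{component_eval} objects),
#'   \code{baseline} (regression rows), \code{config}.
#' @export
run_scan <- function(x, targets, config = scan_config()) {
  targets <- as.data.frame(targets)
  missing_m <- setdiff(config$metrics, names(targets))
  if (length(missing_m))
    stop("targets missing for metric(s): ", paste(missing_m, collapse = ", "))
  rows <- list(); evals <- list(); brows <- list()
  cell <- 0L
  for (b in seq_len(nrow(config$bands))) {
    band <- config$bands[b, ]
    be <- tryCatch(band_epochs(x, band, config), error = function(e) e)
    if (inherits(be, "error")) {
      for (m in config$metrics) {
        cell <- cell + 1L
        rows[[cell]] <- data.frame(f0 = band$f0, df = band$df, metric = m,
                                   rank = NA_integer_, status = "band_failed",
                                   R_all = NA, R_folds = NA, H_folds = NA,
                                   z_auc = NA, aauc_snr = NA, n_e = NA,
                                   lambda = NA, selected = FALSE)
      }
      next
    }
    covs <- epoch_covariances(be)
    n_e <- nrow(covs)
    scheme <- cv_scheme(n_e, config$K)
    for (m in config$metrics) {
      z <- targets[[m]]
      full <- tryCatch(spoc_core(covs, z, shrinkage = config$shrinkage),
                       error = function(e) NULL)
      ranks <- if (is.null(full)) integer(0) else {
        rs <- rank_select(full$lambda)$selected_ranks
        utils::head(sort(unique(c(1L, rs))), config$max_ranks)
      }
      if (!length(ranks)) {
        cell <- cell + 1L
        rows[[cell]] <- data.frame(f0 = band$f0, df = band$df, metric = m,
                                   rank = NA_integer_, status = "fit_failed",
                                   R_all = NA, R_folds = NA, H_folds = NA,
                                   z_auc = NA, aauc_snr = NA, n_e = n_e,
                                   lambda = NA, selected = FALSE)
        next
      }
      for (rk in ranks) {
        cell <- cell + 1L
        ev <- crossval_predict(covs, z, scheme, rank = rk,
                               shrinkage = config$shrinkage)
        if (isTRUE(ev$valid) && config$compute_aauc) {
          cell_seed <- (config$seed + 7919L * cell) %% 2147483647L
          ev$aauc_snr <- aauc_snr(covs, z, scheme, rank = rk,
                                  snr_grid_db = config$snr_grid_db,
                                  reps = config$reps, seed = cell_seed,
                                  shrinkage = config$shrinkage)$aauc_snr
        }
        sel <- if (config$compute_aauc)
          select_components(list(ev), config$thresholds)
        else isTRUE(ev$valid) &&
          !is.na(ev$z_auc) && ev$z_auc >= config$thresholds$z_auc_min &&
          ev$H_folds == config$thresholds$h_folds_min &&
          ev$n_epochs >= config$thresholds$n_e_min
        evals[[cell]] <- ev
        rows[[cell]] <- data.frame(
          f0 = band$f0, df = band$df, metric = m, rank = rk,
          status = if (isTRUE(ev$valid)) "ok" else "cv_failed",
          R_all = ev$R_all %||% NA, R_folds = ev$R_folds %||% NA,
          H_folds = ev$H_folds %||% NA, z_auc = ev$z_auc %||% NA,
          aauc_snr = ev$aauc_snr %||% NA, n_e = n_e,
          lambda = full$lambda[rk], selected = isTRUE(sel))
      }
      bl <- tryCatch(regression_baseline(covs, z, scheme),
                     error = function(e) NULL)
      if (!is.null(bl))
        brows[[length(brows) + 1L]] <- data.frame(
          f0 = band$f0, df = band$df, metric = m,
          R_all = bl$R_all, R_folds = bl$R_folds, H_folds = bl$H_folds,
          z_auc = bl$z_auc)
    }
  }
  structure(list(table = do.call(rbind, rows), evals = evals,
                 baseline = if (length(brows)) do.call(rbind, brows) else NULL,
                 config = config),
            class = "spoc_scan")
}

#' Channel-wise bandpower regression baseline
#'
#' The comparison model that ignores the forward model: per-channel
#' log-bandpower features (log of each channel's epoch variance) fitted by
#' ordinary least squares on the training folds and applied to the test
#' folds, under the same chronological cross-validation and scoring
#' battery. A singular normal-equation system falls back to a small ridge
#' penalty with a warning. Delivers one component per configuration.
#'
#' @param x band-filtered \code{\link{epoch_set}} or covariance stack.
#' @param z per-trial target.
#' @param scheme a \code{\link{cv_scheme}}.
#' @param log_power use log bandpower features (default TRUE; raw variance
#'   if FALSE).
#' @return a \code{component_eval} (with \code{rank = 0} marking the
#'   baseline; no fold patterns).
#' @export
regression_baseline <- function(x, z, scheme = NULL, log_power = TRUE) {
  covs <- if (is.matrix(x) && !is.null(attr(x, "n_channels"))) x
          else epoch_covariances(x)
  n_c <- attr(covs, "n_channels")
  n_e <- nrow(covs)
  scheme <- scheme %||% cv_scheme(n_e)
  diag_idx <- (seq_len(n_c) - 1L) * n_c + seq_len(n_c)
  X <- covs[, diag_idx, drop = FALSE]
  if (log_power) X <- log(pmax(X, .Machine$double.xmin))
  X <- cbind(1, X)
  z_est <- numeric(n_e)
  for (j in seq_len(scheme$K)) {
    te <- scheme$folds[[j]]
    tr <- setdiff(seq_len(n_e), te)
    XtX <- crossprod(X[tr, , drop = FALSE])
    Xty <- crossprod(X[tr, , drop = FALSE], z[tr])
    beta <- tryCatch(solve(XtX, Xty), error = function(e) {
      warning("singular design; ridge fallback applied")
      solve(XtX + 1e-6 * mean(diag(XtX)) * diag(ncol(X)), Xty)
    })
    z_est[te] <- X[te, , drop = FALSE] %*% beta
  }
  R_all <- r_all(z, z_est)
  rf <- r_folds(z, z_est, scheme)
  structure(list(valid = TRUE, z_true = z, z_est = z_est, R_all = R_all,
                 R_folds = rf$r_folds, r_j = rf$r_j,
                 H_folds = h_folds(R_all, rf$r_j), z_auc = z_auc(z, z_est),
                 aauc_snr = NA_real_, fold_patterns = NULL, rank = 0L,
                 n_epochs = n_e, scheme = scheme),
            class = "component_eval")
}

#' @export
print.spoc_scan <- function(x, ...) {
  tab <- x$table
  cat(sprintf("<spoc_scan> %d bands x %d metrics, %d cells (%d ok, %d selected)\n",
              nrow(x$config$bands), length(x$config$metrics), nrow(tab),
              sum(tab$status == "ok"), sum(tab$selected)))
  invisible(x)
}

#' Summarize a grid scan
#'
#' Aggregates the selected components into histograms over frequency band,
#' target metric and eigenvalue rank, and reports the best selected
#' component (highest overall correlation).
#'
#' @param object a \code{spoc_scan}.
#' @param ... unused.
#' @return list of class \code{summary.spoc_scan}: \code{n_selected},
#'   counts \code{by_band}, \code{by_metric}, \code{by_rank}, and
#'   \code{best} (row of the scan table or \code{NULL}).
#' @export
summary.spoc_scan <- function(object, ...) {
  tab <- object$table
  sel <- tab[tab$selected, , drop = FALSE]
  best <- if (nrow(sel)) sel[which.max(abs(sel$R_all)), ] else NULL
  structure(list(
    n_selected = nrow(sel),
    n_cells = nrow(tab),
    by_band = if (nrow(sel)) table(sprintf("%.1f-%.1f", sel$f0,
                                           sel$f0 + sel$df)) else table(character()),
    by_metric = if (nrow(sel)) table(sel$metric) else table(character()),
    by_rank = if (nrow(sel)) table(sel$rank) else table(character()),
    best = best,
    median_R_all = stats::median(tab$R_all, na.rm = TRUE),
    median_z_auc = stats::median(tab$z_auc, na.rm = TRUE)),
    class = "summary.spoc_scan")
}

#' @export
print.summary.spoc_scan <- function(x, ...) {
  cat(sprintf("Grid scan: %d cells, %d selected components\n",
              x$n_cells, x$n_selected))
  cat(sprintf("  median R_all = %.3f, median z-AUC = %.3f (all cells)\n",
              x$median_R_all, x$median_z_auc))
  if (!is.null(x$best)) {
    cat(sprintf("  best: band [%.1f, %.1f] Hz, metric %s, rank %d, R_all = %.3f, z-AUC = %.3f\n",
                x$best$f0, x$best$f0 + x$best$df, x$best$metric,
                x$best$rank, x$best$R_all, x$best$z_auc))
    cat("  selected by metric:\n"); print(x$by_metric)
    cat("  selected by rank:\n"); print(x$by_rank)
  }
  invisible(x)
}

#' Write a scan result
#'
#' Writes the scan table and baseline as CSV plus a JSON provenance record
#' (config parameters, seed, config hash).
#'
#' @param result a \code{spoc_scan}.
#' @param path output directory.
#' @export
write_scan_result <- function(result, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$table, file.path(path, "scan_table.csv"),
                   row.names = FALSE)
  if (!is.null(result$baseline))
    utils::write.csv(result$baseline, file.path(path, "baseline.csv"),
                     row.names = FALSE)
  cfg <- result$config
  cfg_json <- jsonlite::toJSON(unclass(cfg)[c("metrics", "window", "K",
                                              "seed", "snr_grid_db", "reps",
                                              "max_ranks", "shrinkage")],
                               auto_unbox = TRUE, digits = NA)
  prov <- list(config = jsonlite::fromJSON(cfg_json),
               n_bands = nrow(cfg$bands),
               config_hash = sum(utf8ToInt(as.character(cfg_json))))
  jsonlite::write_json(prov, file.path(path, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
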