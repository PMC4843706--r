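test_that("the default band grid has 55 configurations spanning ~1-100 Hz with a line gap", {
  g <- default_band_grid()
  expect_equal(nrow(g), 55)
  expect_gte(min(g$f0), 1)
  expect_lte(max(g$f0 + g$df), 100 + 1e-9)
  hi <- g$f0 + g$df
  expect_false(any(hi >= 45 & g$f0 <= 55))       # exclusion respected
  expect_gt(nrow(default_band_grid(exclusion = NULL)), 55)
  sub <- default_band_grid(f_min = 8, f_max = 13, n = 10)
  expect_true(all(sub$f0 >= 8 - 1e-9 & sub$f0 + sub$df <= 13 + 1e-9))
  expect_error(default_band_grid(f_min = 10, f_max = 5), "f_min")
})

test_that("a small scan localizes a planted alpha source and is deterministic", {
  sc <- strong_scene(3, n_channels = 8, n_epochs = 200)
  bands <- data.frame(f0 = c(2, 8, 20, 35), df = c(4, 4, 8, 10))
  cfg <- scan_config(bands = bands, metrics = "RT", K = 5, seed = 2,
                     thresholds = selection_thresholds(n_e_min = 150),
                     reps = 2)
  res <- run_scan(sc$epochs, list(RT = sc$z), cfg)
  tab <- res$table
  expect_true(all(tab$status %in% c("ok", "fit_failed")))
  sel <- tab[tab$selected & !is.na(tab$rank), ]
  expect_gt(nrow(sel), 0)
  best <- tab[which.max(tab$R_all), ]
  expect_true(best$f0 <= 10 && best$f0 + best$df >= 10)  # contains 10 Hz
  res2 <- run_scan(sc$epochs, list(RT = sc$z), cfg)
  expect_identical(res$table, res2$table)
})

test_that("null scans select few cells", {
  sc <- null_scene(5, n_channels = 6, n_epochs = 200)
  bands <- data.frame(f0 = c(8, 20), df = c(4, 8))
  zs <- with_test_seed(50, replicate(3, rnorm(200), simplify = FALSE))
  names(zs) <- c("RT", "CPL", "NJ")
  cfg <- scan_config(bands = bands, metrics = names(zs), K = 5, seed = 3,
                     reps = 2)
  res <- run_scan(sc$epochs, zs, cfg)
  expect_lte(mean(res$table$selected), 0.15)
})

test_that("regression baseline matches lm on the same folds and nulls score at chance", {
  sc <- strong_scene(7, n_channels = 5, n_epochs = 150)
  covs <- epoch_covariances(sc$epochs)
  sch <- cv_scheme(150, 5)
  bl <- regression_baseline(covs, sc$z, sch)
  # oracle: identical fold predictions from stats::lm
  n_c <- 5
  X <- log(covs[, (seq_len(n_c) - 1) * n_c + seq_len(n_c)])
  z_lm <- numeric(150)
  for (j in 1:5) {
    te <- sch$folds[[j]]; tr <- setdiff(1:150, te)
    d <- data.frame(z = sc$z[tr], X[tr, ])
    fit <- stats::lm(z ~ ., data = d)
    z_lm[te] <- stats::predict(fit, data.frame(X[te, , drop = FALSE]))
  }
  expect_equal(bl$z_est, z_lm, tolerance = 1e-8)
  expect_equal(bl$rank, 0L)
  # shuffled target: chance-level separability
  zs <- with_test_seed(9, sample(sc$z))
  bl0 <- regression_baseline(covs, zs, sch)
  expect_lt(abs(bl0$z_auc - 0.5), 0.12)
})

test_that("SPoC beats the channel-wise regression under spatially mixed interference, matches it without", {
  # target source spatially mixed with strong non-comodulating narrowband
  # distractors (structured, spatially correlated "noise"): channel-wise
  # bandpower loses the source, the spatial filter can null the distractors
  diffs <- vapply(1:10, function(s) {
    srcs <- with_test_seed(s + 500, list(
      source_spec(rnorm(8), 10, 4, comodulation_r = 0.9),
      source_spec(rnorm(8), 10, 4, comodulation_r = 0, baseline_power = 30),
      source_spec(rnorm(8), 10.5, 5, comodulation_r = 0, baseline_power = 30)))
    sc <- generate_scene(synthetic_scene(8, 200, seed = s, sources = srcs,
                                         noise_power = 0.1))
    covs <- epoch_covariances(sc$epochs)
    sch <- cv_scheme(200, 5)
    crossval_predict(covs, sc$z, sch)$R_all -
      regression_baseline(covs, sc$z, sch)$R_all
  }, 0)
  expect_gt(mean(diffs), 0)
  # single-channel source, no mixing: nothing to unmix, comparable accuracy
  diffs0 <- vapply(1:6, function(s) {
    scn <- synthetic_scene(n_channels = 4, n_epochs = 200, seed = s,
                           sources = list(source_spec(c(1, 0, 0, 0), 10, 4,
                                                      comodulation_r = 0.6)),
                           noise_power = 0.1)
    sc <- generate_scene(scn)
    covs <- epoch_covariances(sc$epochs)
    sch <- cv_scheme(200, 5)
    crossval_predict(covs, sc$z, sch)$R_all -
      regression_baseline(covs, sc$z, sch)$R_all
  }, 0)
  expect_lt(abs(mean(diffs0)), 0.1)
})

test_that("scan summaries conserve counts", {
  sc <- strong_scene(8, n_channels = 6, n_epochs = 200)
  bands <- data.frame(f0 = c(8, 30), df = c(4, 10))
  cfg <- scan_config(bands = bands, metrics = c("RT", "CPL"), seed = 4,
                     reps = 2)
  res <- run_scan(sc$epochs, list(RT = sc$z,
                                  CPL = with_test_seed(1, rnorm(200))), cfg)
  s <- summary(res)
  expect_equal(sum(s$by_band), s$n_selected)
  expect_equal(sum(s$by_metric), s$n_selected)
  expect_equal(sum(s$by_rank), s$n_selected)
  if (s$n_selected > 0) expect_true(s$best$selected)
  # empty selection still yields a valid report
  nullres <- res
  nullres$table$selected <- FALSE
  s0 <- summary(nullres)
  expect_equal(s0$n_selected, 0)
  expect_null(s0$best)
})
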