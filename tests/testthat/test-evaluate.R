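test_that("chronological folds are contiguous, balanced, earlier folds take the remainder", {
  sch <- cv_scheme(403, 5)
  sizes <- lengths(sch$folds)
  expect_equal(sizes, c(81, 81, 81, 80, 80))
  expect_identical(unlist(sch$folds), 1:403)   # contiguous, ordered, disjoint
  expect_error(cv_scheme(8, 5), "2 trials per fold")
})

test_that("correlation battery matches its definitions", {
  z <- rnorm(50)
  expect_equal(r_all(z, z), 1)
  expect_equal(r_all(z, -z), -1)
  expect_warning(expect_true(is.na(r_all(z, rep(1, 50)))), "zero variance")
  sch <- cv_scheme(50, 5)
  expect_equal(r_folds(z, z, sch)$r_folds, 1)
  expect_equal(r_folds(z, z, cv_scheme(50, 1))$r_folds, r_all(z, z))
})

test_that("a shared between-fold trend inflates R_all but not R_folds", {
  set.seed(21)
  n <- 200; sch <- cv_scheme(n, 5)
  trend <- 6 * seq_len(n) / n
  noise_a <- rnorm(n); noise_b <- rnorm(n)
  z_true <- trend + noise_a
  z_est <- trend + noise_b     # shares only the trend
  expect_gt(r_all(z_true, z_est), 0.5)
  expect_lt(abs(r_folds(z_true, z_est, sch)$r_folds), 0.25)
})

test_that("fold-sign homogeneity counts sign matches with Theta(0) = 1", {
  expect_equal(h_folds(0.5, c(0.2, 0.1, 0.3, 0.05, 0.15)), 5)
  expect_equal(h_folds(0.5, c(0.2, -0.1, 0.3, 0.05, 0.15)), 4)
  expect_equal(h_folds(0.5, c(0.2, 0, 0.3, 0.05, 0.15)), 5)  # zero counts
  expect_equal(h_folds(-0.5, c(-0.2, 0.1, -0.3, -0.05, -0.15)), 4)
})

test_that("z-AUC is a midrank ROC area on the median split", {
  z <- rnorm(101)
  expect_equal(z_auc(z, z), 1.0)
  expect_equal(z_auc(z, -z), 0.0)
  # invariant under strictly monotone transforms of the score
  expect_equal(z_auc(z, exp(2 * z)), 1.0)
  s <- rnorm(101)
  expect_equal(z_auc(z, s), z_auc(z, tanh(s) + 5))
  expect_warning(z_auc(rep(1, 10), rnorm(10)), "degenerate")
})

test_that("z-AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  for (i in 1:5) {
    z_true <- rnorm(80)
    z_est <- 0.5 * z_true + rnorm(80)
    labels <- z_true > median(z_true)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, z_est, quiet = TRUE,
                                          direction = "<")))
    expect_equal(z_auc(z_true, z_est), ref, tolerance = 1e-10)
  }
})

test_that("cross-validated prediction recovers a planted component and nulls stay at chance", {
  sc <- strong_scene(6, n_channels = 16, n_epochs = 300)
  ev <- crossval_predict(sc$epochs, sc$z)
  expect_gte(ev$R_all, 0.6)
  expect_equal(ev$H_folds, 5)
  expect_length(ev$z_est, 300)
  expect_equal(dim(ev$fold_patterns), c(16, 5))
  # shuffled labels: |R_all| small in most seeds
  covs <- epoch_covariances(sc$epochs)
  nulls <- vapply(1:20, function(s) {
    zs <- with_test_seed(s, sample(sc$z))
    abs(crossval_predict(covs, zs)$R_all)
  }, 0)
  expect_gte(mean(nulls <= 2 / sqrt(300)), 0.8)
})

test_that("label-noise stress test: normalization, determinism, monotone in effect", {
  expect_equal(spocflow:::aauc_from_curve(rep(0.5, 7)), 0)
  expect_equal(spocflow:::aauc_from_curve(rep(1.0, 7)), 0.5)
  sc <- strong_scene(9, n_channels = 8, n_epochs = 200)
  covs <- epoch_covariances(sc$epochs)
  a1 <- aauc_snr(covs, sc$z, seed = 4)
  a2 <- aauc_snr(covs, sc$z, seed = 4)
  expect_identical(a1$aauc_snr, a2$aauc_snr)
  strong <- mean(vapply(1:5, function(s) {
    sc <- strong_scene(s, n_channels = 8, n_epochs = 200,
                       comodulation_r = 0.9)
    aauc_snr(epoch_covariances(sc$epochs), sc$z, seed = s)$aauc_snr
  }, 0))
  weak <- mean(vapply(1:5, function(s) {
    sc <- strong_scene(s, n_channels = 8, n_epochs = 200,
                       comodulation_r = 0.2)
    aauc_snr(epoch_covariances(sc$epochs), sc$z, seed = s)$aauc_snr
  }, 0))
  expect_gt(strong, weak)
})

test_that("multi-criterion selection applies all thresholds in parallel", {
  base <- list(valid = TRUE, z_auc = 0.7, aauc_snr = 0.3, H_folds = 5,
               n_epochs = 300)
  class(base) <- "component_eval"
  modify <- function(...) {
    x <- utils::modifyList(base, list(...)); class(x) <- "component_eval"; x
  }
  evals <- list(base,
                modify(z_auc = 0.58),
                modify(H_folds = 4),
                modify(aauc_snr = 0.17),
                modify(n_epochs = 149))
  expect_equal(select_components(evals), c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("predictor classification separates single-trial, session-trend and null scenes", {
  sc <- strong_scene(11, n_channels = 8, n_epochs = 300)
  expect_equal(classify_predictor(crossval_predict(sc$epochs, sc$z)),
               "single_trial")
  tr <- trend_scene(12)
  ev_tr <- crossval_predict(tr$epochs, tr$z)
  expect_equal(classify_predictor(ev_tr), "session_trend")
  expect_lt(abs(ev_tr$R_folds), 0.5 * abs(ev_tr$R_all))
  nu <- null_scene(13)
  expect_equal(classify_predictor(crossval_predict(nu$epochs, nu$z)),
               "neither")
})
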