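test_that("every fitted filter has unit projected training variance and eigen-consistent objective", {
  sc <- strong_scene(1, n_channels = 8, n_epochs = 200)
  m <- spoc(sc$epochs, sc$z)
  covs <- epoch_covariances(sc$epochs)
  zt <- (sc$z - m$z_mean) / m$z_sd
  for (k in seq_len(ncol(m$W))) {
    w <- m$W[, k]
    phi <- as.numeric(covs %*% as.vector(tcrossprod(w)))
    expect_equal(mean(phi), 1, tolerance = 1e-6)    # Var[w'x] = 1
    # eigenvalue equals the bandpower-target covariance it maximizes
    expect_equal(mean(phi * zt), m$lambda[k], tolerance = 1e-8)
  }
  expect_true(all(diff(m$lambda) <= 1e-12))         # descending
  expect_equal(m$A, m$Cbar %*% m$W, tolerance = 1e-10)
})

test_that("with whitened data SPoC filters are the eigenvectors of C_z", {
  set.seed(5)
  n_e <- 300; n_c <- 4; n_t <- 80
  z <- rnorm(n_e)
  data <- array(rnorm(n_e * n_c * n_t), c(n_e, n_c, n_t))
  m <- spoc(data, z)
  covs <- epoch_covariances(epoch_set(data, 1))
  zt <- (z - mean(z)) / sqrt(mean((z - mean(z))^2))
  Cz <- matrix(crossprod(covs, zt) / n_e, n_c, n_c); Cz <- (Cz + t(Cz)) / 2
  ev <- eigen(Cz, symmetric = TRUE)
  # C_bar ~ I so filters align with C_z eigenvectors (up to sampling error)
  for (k in c(1, n_c))
    expect_gt(cosine_sim(m$W[, k], ev$vectors[, k]), 0.9)
})

test_that("the top component recovers a planted source pattern", {
  cs <- vapply(1:10, function(s) {
    sc <- strong_scene(s, n_channels = 16, n_epochs = 250)
    m <- spoc(sc$epochs, sc$z)
    cosine_sim(m$A[, 1], sc$true_patterns[, 1])
  }, 0)
  expect_gte(mean(cs), 0.95)
})

test_that("an independent target yields small top eigenvalues and no selected rank", {
  hits <- vapply(1:10, function(s) {
    sc <- null_scene(s, n_channels = 8, n_epochs = 200)
    m <- spoc(sc$epochs, sc$z)
    length(rank_select(m$lambda)$selected_ranks) > 0
  }, NA)
  expect_lte(sum(hits), 2)  # no rank passes in >= 8/10 seeds
})

test_that("GEVD solution matches a brute-force grid maximization on 3-channel scenes", {
  angs <- vapply(1:10, function(s) {
    pat <- with_test_seed(s, rnorm(3))
    scn <- synthetic_scene(
      n_channels = 3, n_epochs = 150, seed = s,
      sources = list(source_spec(pat, 10, 4, comodulation_r = 0.7)),
      noise_power = 0.3)
    sc <- generate_scene(scn)
    covs <- epoch_covariances(sc$epochs)
    m <- spoc(covs, sc$z)
    zt <- (sc$z - m$z_mean) / m$z_sd
    Cz <- matrix(crossprod(covs, zt) / nrow(covs), 3, 3)
    Cz <- (Cz + t(Cz)) / 2
    # exhaustive 1-degree grid over filter directions; for direction v the
    # unit-variance-constrained objective is the generalized Rayleigh
    # quotient v'Cz v / v'Cbar v
    th <- seq(0, pi, by = pi / 180)
    ph <- seq(0, 2 * pi - 1e-9, by = pi / 180)
    g <- expand.grid(th = th, ph = ph)
    V <- cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
    obj <- rowSums((V %*% Cz) * V) / rowSums((V %*% m$Cbar) * V)
    v <- V[which.max(obj), ]
    acos(min(1, cosine_sim(v, m$W[, 1]))) * 180 / pi
  }, 0)
  expect_true(all(angs <= 2))
})

test_that("predictions are projected epoch bandpower: homogeneous, zero on zero epochs", {
  sc <- strong_scene(3, n_channels = 6, n_epochs = 150)
  m <- spoc(sc$epochs, sc$z)
  p1 <- predict(m, sc$epochs)
  # scaling the data by c scales the variance prediction by c^2
  scaled <- sc$epochs
  scaled$data <- scaled$data * 3
  expect_equal(predict(m, scaled), 9 * p1, tolerance = 1e-10)
  zero <- sc$epochs
  zero$data[] <- 0
  expect_equal(unique(predict(m, zero)), 0)
  expect_gte(cor(p1, sc$z), 0.6)
  wrong <- array(0, c(4, 3, 50))
  expect_error(predict(m, wrong), "channel count mismatch")
})

test_that("held-out prediction accuracy is monotone in the planted comodulation", {
  mean_r <- vapply(c(0.2, 0.5, 0.9), function(r) {
    mean(vapply(1:10, function(s) {
      sc <- strong_scene(s, n_channels = 8, n_epochs = 200,
                         comodulation_r = r)
      ev <- crossval_predict(sc$epochs, sc$z)
      ev$R_all
    }, 0))
  }, 0)
  expect_true(all(diff(mean_r) > 0))
})

test_that("fold patterns are covariance-propagated filters", {
  w <- c(1, -2, 0.5)
  covs_id <- matrix(rep(as.vector(diag(3)), 5), 5, 9, byrow = TRUE)
  attr(covs_id, "n_channels") <- 3L
  expect_equal(fold_pattern(w, covs_id), w)
  covs_2id <- 2 * covs_id
  attr(covs_2id, "n_channels") <- 3L
  expect_equal(fold_pattern(w, covs_2id), 2 * w)
  # stationary planted scene: fold patterns pairwise aligned
  sc <- strong_scene(4, n_channels = 8, n_epochs = 250)
  ev <- crossval_predict(sc$epochs, sc$z)
  fp <- ev$fold_patterns
  pairs <- utils::combn(ncol(fp), 2)
  cosines <- apply(pairs, 2, function(p) cosine_sim(fp[, p[1]], fp[, p[2]]))
  expect_true(all(cosines >= 0.9))
})

test_that("rank selection flags spiked eigenvalues only", {
  lin <- seq(5, 1, length.out = 10)
  expect_length(rank_select(lin)$selected_ranks, 0)
  spiked <- lin; spiked[1] <- spiked[1] + 10
  expect_identical(rank_select(spiked)$selected_ranks, 1L)
  allneg <- seq(-5, -12, length.out = 8)
  spikedneg <- allneg; spikedneg[1] <- allneg[1] + 3  # spiked but still < 0
  expect_length(rank_select(spikedneg)$selected_ranks, 0)  # positivity
  expect_error(rank_select(c(2, 1)), ">= 3")
  expect_error(rank_select(c(1, 2, 3)), "descending")
})

test_that("fit validates inputs", {
  sc <- strong_scene(2, n_channels = 4, n_epochs = 60)
  expect_error(spoc(sc$epochs, sc$z[-1]), "length")
  bad <- sc$z; bad[3] <- NA
  expect_error(spoc(sc$epochs, bad), "non-finite")
  expect_error(spoc(sc$epochs, rep(1, 60)), "zero variance")
})
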