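test_that("design matrices carry HRF task columns, DCT drifts and a constant", {
  des <- event_design(onset = 10, duration = 2.4, condition = "word",
                      run_length = 720, tr = 2)
  dm <- build_design_matrix(des, n_vols = 360, hpf_cutoff_s = 128)
  ## floor(2 * 360 * 2 / 128) = 11 drift columns
  expect_equal(sum(grepl("^drift", dm$names)), 11)
  expect_equal(dm$names[length(dm$names)], "constant")
  expect_true(all(dm$x[, "constant"] == 1))
  expect_equal(dm$n_task, 1)

  ## drift columns are mutually orthogonal
  D <- dm$x[, grepl("^drift", dm$names)]
  off <- crossprod(D)
  expect_lt(max(abs(off[upper.tri(off)])), 1e-8)

  ## a single event at t = 0 peaks 4-6 s after onset
  des0 <- event_design(onset = 0, duration = 0.5, condition = "x",
                       run_length = 64, tr = 2)
  dm0 <- build_design_matrix(des0, n_vols = 32, hpf_cutoff_s = Inf)
  tpk <- ((which.max(dm0$x[, "x"])) - 0.5) * 2
  expect_gte(tpk, 4)
  expect_lte(tpk, 6)

  ## no events: drifts + constant only
  dme <- build_design_matrix(event_design(numeric(0), numeric(0), character(0),
                                          run_length = 100, tr = 2),
                             n_vols = 50)
  expect_equal(dme$n_task, 0)
  expect_equal(ncol(dme$x), floor(2 * 50 * 2 / 128) + 1)

  ## events outside the acquisition window fail
  expect_error(build_design_matrix(des, n_vols = 4), "outside")
})

test_that("LSS betas equal independent per-trial normal-equations solutions", {
  set.seed(10)
  shape <- c(10, 10, 5)
  mask <- array(TRUE, shape)
  des <- make_event_design(c(stats::setNames(rep(1, 8), sprintf("w%02d", 1:8)),
                             pseudoword = 8),
                           seed = 3)
  n_vols <- as.integer(ceiling(attr(des, "run_length") / 2))
  arr <- array(rnorm(prod(shape) * n_vols), c(shape, n_vols))
  vol <- volume_series(arr, mask = mask, tr = 2)
  tb <- lss_betas(vol, des, ar1 = FALSE, hpf_cutoff_s = 128)
  expect_identical(dim(tb$betas), c(8L, 500L))
  expect_identical(tb$concepts, sort(sprintf("w%02d", 1:8)))

  Y <- t(matrix(arr, prod(shape), n_vols))
  for (w in c("w01", "w05", "w08")) {
    ## independent route: relabel events to the 3-regressor trial model and
    ## solve the normal equations directly
    d2 <- des
    d2$condition[d2$condition == w] <- "this"
    d2$condition[!d2$condition %in% c("this", "pseudoword")] <- "other"
    X <- build_design_matrix(d2, n_vols, tr = 2, hpf_cutoff_s = 128)$x
    expect_true(all(c("this", "other", "pseudoword") %in% colnames(X)))
    beta_oracle <- solve(t(X) %*% X, t(X) %*% Y)[match("this", colnames(X)), ]
    expect_lt(max(abs(tb$betas[match(w, tb$concepts), ] - beta_oracle)), 1e-8)
  }

  ## all-zero data gives all-zero betas
  vol0 <- volume_series(array(0, c(shape, n_vols)), mask = mask, tr = 2)
  tb0 <- lss_betas(vol0, des, ar1 = FALSE)
  expect_true(all(tb0$betas == 0))

  ## fewer volumes than regressors fails
  tiny <- volume_series(array(rnorm(prod(shape) * 4), c(shape, 4)),
                        mask = mask, tr = 2)
  destiny <- event_design(c(1, 4), c(2.4, 2.4), c("a", "pseudoword"),
                          run_length = 8, tr = 2)
  expect_error(lss_betas(tiny, destiny, hpf_cutoff_s = Inf), "fewer volumes")
})

test_that("noise-free LSS recovers planted patterns and the planted RDM", {
  target <- rank2_target(6, seed = 4)
  shape <- c(10, 10, 10)
  mask <- array(TRUE, shape)
  roi <- roi_ball(mask, c(5, 5, 5), 80)
  ps <- embed_geometry(target, roi, seed = 2)  # random basis, full-ROI exact
  des <- make_event_design(stats::setNames(rep(1, 6), ps$concepts),
                           iti_mean_ms = 33600, iti_sd_ms = 0, seed = 1)
  vol <- simulate_bold(des, ps, shape, noise_sd = 0, ar1_phi = 0, mask = mask)
  tb <- lss_betas(vol, des, ar1 = FALSE, hpf_cutoff_s = Inf)
  cm <- slrsa:::mask_column_map(mask)
  recovered <- tb$betas[, cm[roi]]
  planted <- ps$patterns[tb$concepts, ]
  expect_lt(max(abs(recovered - planted)), 1e-8)
  nr <- neural_rdm(tb, cm[roi])
  expect_lt(max(abs(nr$d - target$d[tb$concepts, tb$concepts])), 1e-8)
})

test_that("prewhitening with the true phi removes residual autocorrelation", {
  set.seed(99)
  phi <- 0.5
  n <- 200
  X <- cbind(sin(seq_len(n) / 10), 1)
  acs <- replicate(200, {
    e <- as.numeric(stats::filter(rnorm(n, sd = sqrt(1 - phi^2)), phi,
                                  method = "recursive"))
    y <- X %*% c(2, 1) + e
    yw <- slrsa:::ar1_whiten(matrix(y), phi)
    Xw <- slrsa:::ar1_whiten(X, phi)
    r <- yw - Xw %*% qr.coef(qr(Xw), yw)
    sum(r[-1] * r[-n]) / sum(r^2)
  })
  se <- sd(acs) / sqrt(length(acs))
  expect_lt(abs(mean(acs)), 3 * se + 0.02)
})

test_that("pooled AR(1) estimates recover the generating phi", {
  mask <- array(FALSE, c(3, 3, 3)); mask[2, 2, 2] <- TRUE; mask[1, 1, 1] <- TRUE
  des <- event_design(5, 2.4, "x", run_length = 4000, tr = 2)
  vol <- simulate_bold(des, NULL, c(3, 3, 3), noise_sd = 1, ar1_phi = 0.4,
                       seed = 3, mask = mask)
  Y <- slrsa:::mask_timeseries(vol)
  phi_hat <- slrsa:::pooled_ar1_phi(Y - mean(Y))
  expect_lt(abs(phi_hat - 0.4), 0.05)
})

test_that("block GLM contrasts recover planted block amplitudes exactly", {
  des <- make_block_design("visual")
  shape <- c(6, 6, 6)
  mask <- array(TRUE, shape)
  roi <- roi_ball(mask, c(3, 3, 3), 10)
  amp <- 3.7
  ps <- structure(list(concepts = "visual",
                       patterns = matrix(amp, 1, 10),
                       roi_indices = roi, basis = "manual"),
                  class = "pattern_set")
  vol <- simulate_bold(des, ps, shape, noise_sd = 0, ar1_phi = 0, mask = mask)
  res <- block_glm_contrast(vol, des, contrast = 1, ar1 = FALSE)
  expect_lt(max(abs(res$contrast[roi] - amp)), 1e-8)

  expect_error(block_glm_contrast(vol, des, contrast = c(1, -1)), "length")
  expect_error(block_glm_contrast(vol, des, contrast = 0), "all zeros")
})

test_that("block GLM t values equal the closed-form GLM t at one voxel", {
  set.seed(21)
  mask <- array(FALSE, c(2, 2, 2)); mask[1, 1, 1] <- TRUE
  des <- make_block_design("motor")
  n_vols <- 230
  arr <- array(0, c(2, 2, 2, n_vols))
  X <- build_design_matrix(des, n_vols, tr = 2)$x
  y <- X %*% c(2, rnorm(ncol(X) - 1, sd = 0.3)) + rnorm(n_vols)
  arr[1, 1, 1, ] <- y
  vol <- volume_series(arr, mask = mask, tr = 2)
  res <- block_glm_contrast(vol, des, contrast = 1, ar1 = FALSE)
  ## hand-computed (c' beta) / SE
  cvec <- c(1, rep(0, ncol(X) - 1))
  bh <- solve(t(X) %*% X, t(X) %*% y)
  r <- y - X %*% bh
  s2 <- sum(r^2) / (n_vols - ncol(X))
  t_hand <- (t(cvec) %*% bh) / sqrt(s2 * t(cvec) %*% solve(t(X) %*% X, cvec))
  expect_equal(res$stat$values[1, 1, 1], as.numeric(t_hand), tolerance = 1e-10)
  expect_equal(res$df, n_vols - ncol(X))
})

test_that("Gaussian smoothing matches the analytic separable kernel", {
  ## 6 mm FWHM at 2 mm voxels: sigma = 1.2739 voxels (4 decimals)
  sigma <- 6 / (2 * sqrt(2 * log(2))) / 2
  expect_lt(abs(sigma - 1.2739), 1e-4)

  ## constant image is unchanged (boundary-renormalized kernel)
  cimg <- array(5, c(8, 8, 8))
  expect_lt(max(abs(smooth_volume(cimg, 6) - 5)), 1e-12)

  ## unit impulse reproduces the analytic normalized Gaussian profile
  img <- array(0, c(15, 15, 15))
  img[8, 8, 8] <- 1
  sm <- smooth_volume(img, 6, voxel_size = c(2, 2, 2))
  r <- ceiling(4 * sigma)
  w <- exp(-(-r:r)^2 / (2 * sigma^2))
  w <- w / sum(w)
  for (d in list(c(0, 0, 0), c(1, 0, 0), c(2, 1, 0), c(1, 1, 1), c(3, 2, 1))) {
    expected <- prod(w[r + 1 + d])
    expect_lt(abs(sm[8 + d[1], 8 + d[2], 8 + d[3]] - expected), 1e-6)
  }
})
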