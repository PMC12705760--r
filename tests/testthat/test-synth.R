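test_that("semantic space has the requested geometry and is reproducible", {
  sm <- make_semantic_space(58, 400, n_latent = 4, noise_sd = 0.1, seed = 1)
  expect_identical(dim(sm$vectors), c(58L, 400L))
  expect_length(sm$concepts, 58)

  sm2 <- make_semantic_space(58, 400, n_latent = 4, noise_sd = 0.1, seed = 1)
  expect_identical(sm$vectors, sm2$vectors)
  sm3 <- make_semantic_space(58, 400, n_latent = 4, noise_sd = 0.1, seed = 2)
  expect_false(identical(sm$vectors, sm3$vectors))

  ## one latent factor, no noise: all rows perfectly correlated
  sm1 <- make_semantic_space(10, 50, n_latent = 1, noise_sd = 0, seed = 3)
  r1 <- correlation_distance_rdm(sm1$vectors)
  expect_lt(max(abs(r1$d)), 1e-12)

  expect_error(make_semantic_space(1, 10), "at least 2")
  expect_error(make_semantic_space(5, 10, n_latent = 11), "n_latent")
  expect_error(make_semantic_space(5, 0), "n_dims")
})

test_that("semantic-space RDM matches a brute-force pairwise oracle", {
  sm <- make_semantic_space(6, 40, n_latent = 2, noise_sd = 0.1, seed = 9)
  r <- correlation_distance_rdm(sm$vectors)
  expect_lt(max(abs(r$d - manual_corr_dist(sm$vectors))), 1e-12)
})

test_that("property listings match the instructed production rates", {
  pl <- make_property_listings(51, 58, mean_props = 3.5, missing_rate = 0, seed = 1)
  expect_identical(dim(pl$counts), c(51L, 58L, 11L))
  expect_identical(pl$categories, PROPERTY_CATEGORIES)
  expect_length(PROPERTY_CATEGORIES, 11)
  expect_false(any(pl$missing))

  ## mean total properties per listed cell between three and four
  tots <- apply(pl$counts, c(1, 2), sum)
  expect_gt(length(tots), 1000)
  expect_gte(mean(tots), 3)
  expect_lte(mean(tots), 4)

  ## missingness is binomial at the requested rate (3 SE window)
  pl2 <- make_property_listings(51, 58, missing_rate = 0.05, seed = 4)
  n_cells <- 51 * 58
  se <- sqrt(0.05 * 0.95 / n_cells)
  expect_lt(abs(mean(pl2$missing) - 0.05), 3 * se)

  ## missing cells are flagged, and reproducible
  pl3 <- make_property_listings(51, 58, missing_rate = 0.05, seed = 4)
  expect_identical(pl2$counts, pl3$counts)
  expect_identical(pl2$missing, pl3$missing)
  expect_error(make_property_listings(missing_rate = 1), "missing_rate")
})

test_that("event designs respect trial timing and the run constraint", {
  des <- make_event_design(c(word = 64, pseudoword = 64), seed = 1)
  expect_s3_class(des, "event_design")
  expect_true(all(des$duration == 2.4))
  expect_equal(nrow(des), 128)
  expect_true(all(diff(des$onset) > 0))
  expect_true(sequence_ok(des$condition, 3))
  ## no 4 consecutive equal labels anywhere
  expect_true(all(rle(des$condition)$lengths <= 3))

  ## reproducibility and seed sensitivity
  expect_identical(des, make_event_design(c(word = 64, pseudoword = 64), seed = 1))
  expect_false(identical(des$onset,
                         make_event_design(c(word = 64, pseudoword = 64), seed = 2)$onset))

  ## the constraint holds across many draws (property)
  for (s in 1:10) {
    d <- make_event_design(c(a = 20, b = 20), max_run = 2, seed = s)
    expect_true(sequence_ok(d$condition, 2))
  }

  ## unsatisfiable counts fail explicitly
  expect_error(make_event_design(c(a = 10, b = 1), max_run = 3, seed = 1),
               "max-run")
})

test_that("intertrial intervals reproduce the requested mean", {
  itis <- slrsa:::draw_iti(10000, 3.173, 3.435)
  expect_true(all(itis > 0))
  se <- 3.435 / sqrt(10000)
  expect_lt(abs(mean(itis) - 3.173), 3 * se)
  ## right-skew of the matched-moments distribution
  expect_gt(mean((itis - mean(itis))^3), 0)
})

test_that("localizer block designs carry the protocol timings", {
  v <- make_block_design("visual")
  expect_equal(nrow(v), 6)
  expect_true(all(v$duration == 24))
  expect_equal(diff(v$onset), rep(24 + 27.8, 5))

  m <- make_block_design("motor")
  expect_equal(nrow(m), 8)
  expect_true(all(m$duration == 26))
  expect_equal(unique(diff(m$onset)), 52)

  e <- make_block_design("emotional")
  expect_equal(nrow(e), 12)
  expect_true(all(e$duration == 23.8))
  expect_equal(sum(e$condition == "emotional"), 6)
  expect_equal(sum(e$condition == "neutral"), 6)

  expect_error(make_block_design("auditory"))
})

test_that("embed_geometry realizes arbitrary PSD targets exactly on the ROI", {
  sm <- make_semantic_space(5, 60, n_latent = 3, noise_sd = 0.2, seed = 2)
  target <- correlation_distance_rdm(sm$vectors)
  ps <- embed_geometry(target, roi_indices = 1:60, seed = 3)
  expect_identical(dim(ps$patterns), c(5L, 60L))
  realized <- manual_corr_dist(ps$patterns)
  expect_lt(max(abs(realized - target$d)), 1e-8)

  ## all-zero target: S is all ones, rank 1; realized RDM is all zeros
  z <- rdm(matrix(0, 4, 4), letters[1:4])
  psz <- embed_geometry(z, roi_indices = 1:20, seed = 1)
  expect_lt(max(abs(manual_corr_dist(psz$patterns))), 1e-10)

  ## out-of-range distances are rejected before any factorization
  bad <- matrix(0, 3, 3); bad[1, 2] <- bad[2, 1] <- 2.5
  expect_error(rdm(bad, letters[1:3]), "\\[0, 2\\]")

  ## valid range but not correlation-realizable (S not PSD)
  d <- matrix(c(0, 0, 0, 0, 0, 2, 0, 2, 0), 3, 3)
  expect_error(embed_geometry(rdm(d, letters[1:3]), 1:10),
               "not correlation-realizable")

  ## too few voxels for the rank
  expect_error(embed_geometry(target, roi_indices = 1:3), "voxels")
})

test_that("harmonic planting reproduces the target in every interior sphere", {
  target <- rank2_target(12)
  shape <- c(13L, 13L, 13L)
  mask <- array(TRUE, shape)
  roi <- which(mask)
  ps <- embed_geometry(target, roi, basis = "harmonic", dim = shape, radius_vox = 3)
  off <- slrsa:::sphere_offsets(3)
  for (ctr in list(c(7, 7, 7), c(5, 8, 6))) {
    lin <- slrsa:::ijk_to_lin(sweep(off, 2, ctr, "+"), shape)
    realized <- manual_corr_dist(ps$patterns[, match(lin, roi)])
    expect_lt(max(abs(realized - target$d)), 1e-9)
  }
  ## harmonic mode refuses higher-rank structure
  t3 <- correlation_distance_rdm(
    make_semantic_space(8, 50, n_latent = 5, noise_sd = 0.3, seed = 1)$vectors)
  expect_error(embed_geometry(t3, roi, basis = "harmonic", dim = shape),
               "rank-2")
})

test_that("simulated BOLD is exactly the design response when noise-free", {
  sm <- make_semantic_space(4, 30, n_latent = 2, noise_sd = 0.1, seed = 5)
  target <- correlation_distance_rdm(sm$vectors)
  shape <- c(8, 8, 8)
  mask <- array(TRUE, shape)
  roi <- roi_ball(mask, c(4, 4, 4), 20)
  ps <- embed_geometry(target, roi, seed = 1)
  des <- make_event_design(stats::setNames(rep(1, 4), sm$concepts),
                           iti_mean_ms = 4000, iti_sd_ms = 1000, seed = 2)
  vol <- simulate_bold(des, ps, shape, noise_sd = 0, ar1_phi = 0, mask = mask)
  expect_equal(vol$tr, 2)

  ## exact GLM refit: residuals identically zero
  n_vols <- dim(vol$data)[4]
  dm <- build_design_matrix(des, n_vols, tr = 2, hpf_cutoff_s = Inf)
  roi_ts <- t(matrix(vol$data, prod(shape), n_vols)[roi, ])
  fit <- qr(dm$x)
  resid <- roi_ts - dm$x %*% qr.coef(fit, roi_ts)
  expect_lt(max(abs(resid)), 1e-10)

  ## voxels outside the mask are zero
  expect_true(all(vol$data[rep(!mask, n_vols)] == 0))
})

test_that("AR(1) noise has the requested lag-1 autocorrelation", {
  mask <- array(FALSE, c(3, 3, 3)); mask[2, 2, 2] <- TRUE
  des <- event_design(5, 2.4, "x", run_length = 20000, tr = 2)
  vol <- simulate_bold(des, NULL, c(3, 3, 3), noise_sd = 1, ar1_phi = 0.4,
                       seed = 8, mask = mask)
  ts <- vol$data[2, 2, 2, ]
  n <- length(ts)
  expect_equal(n, 10000)
  ac <- sum((ts[-1] - mean(ts)) * (ts[-n] - mean(ts))) / sum((ts - mean(ts))^2)
  expect_lt(abs(ac - 0.4), 3 / sqrt(n))
  ## marginal SD close to the requested value
  expect_lt(abs(sd(ts) - 1), 0.05)
  ## reproducible
  vol2 <- simulate_bold(des, NULL, c(3, 3, 3), noise_sd = 1, ar1_phi = 0.4,
                        seed = 8, mask = mask)
  expect_identical(vol$data, vol2$data)
})

test_that("pseudowords swap exactly one vowel and one consonant", {
  words <- c("flashback", "melancholie", "gravitation", "frequenz")
  for (w in words) {
    for (s in 1:5) {
      pw <- generate_pseudoword(w, seed = s)
      expect_equal(nchar(pw), nchar(w))
      a <- strsplit(w, "")[[1]]
      b <- strsplit(pw, "")[[1]]
      diffs <- which(a != b)
      expect_length(diffs, 2)
      vowels <- c("a", "e", "i", "o", "u", "ä", "ö", "ü")
      is_v <- a[diffs] %in% vowels
      expect_equal(sum(is_v), 1)  # one vowel position changed...
      expect_true(b[diffs[is_v]] %in% vowels)       # ...to another vowel
      expect_false(b[diffs[!is_v]] %in% vowels)     # consonant to consonant
    }
  }
  expect_error(generate_pseudoword("aaa"), "consonant")
  expect_error(generate_pseudoword("bcd"), "vowel")
})

test_that("sequence_ok detects over-long runs", {
  expect_false(sequence_ok(c("W", "W", "W", "W"), 3))
  expect_true(sequence_ok(c("W", "P", "W", "P"), 3))
  expect_true(sequence_ok(c("W", "W", "W", "P"), 3))
  expect_true(sequence_ok(character(0), 3))
})

test_that("length matching uses the pooled two-sample t", {
  a <- c(3, 4, 5); b <- c(4, 5, 6)
  r <- length_match_test(a, b)
  ## closed-form pooled t
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)

  same <- length_match_test(c(2, 2, 7), c(2, 2, 7))
  expect_equal(same$t, 0)
  ## zero variance, equal means: t = 0 by convention
  expect_equal(length_match_test(c(5, 5, 5), c(5, 5))$t, 0)
  expect_error(length_match_test(1, c(1, 2)), "at least 2")
})
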