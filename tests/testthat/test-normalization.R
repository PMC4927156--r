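test_that("position masking flags records without changing the table shape", {
  scr <- toy_plate(n_rows = 8, n_cols = 8)
  tbl <- scr$colonies

  expect_identical(apply_position_mask(tbl, NULL), tbl)
  expect_identical(apply_position_mask(tbl, data.frame(row = integer(0),
                                                       col = integer(0))),
                   tbl)

  masked <- apply_position_mask(tbl, data.frame(row = 3L, col = 5L))
  expect_equal(nrow(masked), nrow(tbl))
  expect_equal(sum(!colony_reliable(masked)), 1L)
  expect_false(colony_reliable(masked)[masked$row == 3 & masked$col == 5])

  expect_error(apply_position_mask(tbl, data.frame(row = 99L, col = 1L)),
               "outside")
})

test_that("surface fit after masking equals the fit with those records deleted", {
  scr <- toy_plate(n_rows = 16, n_cols = 16, noise_sd = 0.1,
                   surface_amplitude = 0.2, seed = 31)
  tbl <- scr$colonies
  # corrupt a corner, then mask it
  corner <- tbl$row <= 2 & tbl$col <= 2
  tbl$opacity[corner] <- tbl$opacity[corner] * 40

  masked <- apply_position_mask(tbl, expand.grid(row = 1:2, col = 1:2))
  fit_masked <- surface_normalize(masked)$fit

  deleted <- tbl[!corner, , drop = FALSE]
  fit_deleted <- surface_normalize(deleted)$fit
  expect_equal(fit_masked$coefficients, fit_deleted$coefficients,
               tolerance = 1e-10)
})

test_that("a constant plate yields a constant surface and unchanged values", {
  scr <- toy_plate(n_rows = 8, n_cols = 8, baseline = 500)
  out <- surface_normalize(scr$colonies)
  expect_equal(out$tbl$opacity, scr$colonies$opacity, tolerance = 1e-9)
  expect_lt(max(abs(out$fit$fitted)), 1e-9)
})

test_that("planted quartic surfaces are recovered exactly from noiseless plates", {
  # constant baseline: the only spatial signal is the planted surface
  scr <- toy_plate(n_rows = 16, n_cols = 24, noise_sd = 0,
                   surface_amplitude = 0.3, edge_multiplier = 1,
                   baseline = 1000, seed = 17)
  fit <- surface_normalize(scr$colonies)$fit
  planted <- scr$truth$config$surface_coeffs[[1]]
  # baselines differ per gene, so only the surface part is identifiable up
  # to the constant term; compare non-constant coefficients
  expect_lt(max(abs(fit$coefficients[-1] - planted[-1])), 1e-6)
})

test_that("trimming makes the surface fit robust to extreme outliers", {
  scr <- toy_plate(n_rows = 16, n_cols = 16, noise_sd = 0.02,
                   surface_amplitude = 0.25, baseline = 1000, seed = 23)
  clean <- scr$colonies
  dirty <- clean
  set.seed(5)
  hit <- sample(nrow(dirty), 10)
  dirty$opacity[hit] <- dirty$opacity[hit] * 1000

  fit_clean <- surface_normalize(clean)$fit
  fit_robust <- surface_normalize(dirty)$fit
  fit_naive <- surface_normalize(dirty, trim_mad = Inf)$fit

  scale <- max(abs(fit_clean$coefficients[-1]))
  err_robust <- max(abs(fit_robust$coefficients[-1] -
                          fit_clean$coefficients[-1])) / scale
  err_naive <- max(abs(fit_naive$coefficients[-1] -
                         fit_clean$coefficients[-1])) / scale
  expect_lt(err_robust, 0.01)
  expect_gt(err_naive, err_robust)
})

test_that("surface normalization is idempotent to first order", {
  scr <- toy_plate(n_rows = 16, n_cols = 16, noise_sd = 0.1,
                   surface_amplitude = 0.3, seed = 41)
  once <- surface_normalize(scr$colonies)
  twice <- surface_normalize(once$tbl)
  expect_lt(max(abs(twice$fit$coefficients[-1])),
            1e-3 * max(abs(once$fit$coefficients[-1])))
})

test_that("surface fit refuses plates with too few colonies", {
  scr <- toy_plate(n_rows = 8, n_cols = 8)
  expect_error(surface_normalize(scr$colonies[1:20, ]), "too few")
})

test_that("power transform selects sensible exponents and preserves ranks", {
  set.seed(6)
  x_norm <- rnorm(5000, mean = 50, sd = 2)
  pt <- power_transform_fit(x_norm)
  expect_lt(abs(pt$lambda - 1), 0.5)

  # lambda = 1 is the identity up to an affine map
  pt1 <- structure(list(lambda = 1, shift = 0), class = "power_transform")
  expect_equal(power_transform_apply(x_norm, pt1), x_norm - 1)

  x_lnorm <- rlnorm(10000, meanlog = 2, sdlog = 0.8)
  ptl <- power_transform_fit(x_lnorm)
  expect_lt(abs(ptl$lambda), 0.1)

  for (lam in c(-2, -0.5, 0, 0.7, 2)) {
    pt <- structure(list(lambda = lam, shift = 0), class = "power_transform")
    y <- power_transform_apply(x_lnorm, pt)
    expect_identical(order(y), order(x_lnorm))
  }

  expect_error(power_transform_fit(c(-1, 2, 3)), "positive")
  expect_error(power_transform_fit(c(1, 2), shift = -1), ">= 0")
})

test_that("variance normalization equalizes group IQRs", {
  set.seed(7)
  vals <- cbind(rnorm(200, sd = 1), rnorm(200, sd = 2))
  rownames(vals) <- sprintf("g%03d", 1:200)
  m <- screen_matrix(vals, toy_conditions(2), stage = "raw")
  vn <- variance_normalize(m)
  iqrs <- apply(vn$values, 2, IQR)
  expect_equal(iqrs[[1]], iqrs[[2]], tolerance = 1e-9)

  # equal-IQR input: unchanged up to centering
  vals2 <- cbind(a = rnorm(200), b = 0)
  vals2[, 2] <- vals2[, 1] + 5
  rownames(vals2) <- rownames(vals)
  m2 <- screen_matrix(vals2, toy_conditions(2), stage = "raw")
  vn2 <- variance_normalize(m2)
  expect_equal(vn2$values[, 1], vn2$values[, 2], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(vn2$values[, 1]),
               vals2[, 1] - median(vals2[, 1]), tolerance = 1e-12,
               ignore_attr = TRUE)

  # zero-IQR group: warned and left unscaled
  vals3 <- cbind(rnorm(50), rep(3, 50))
  rownames(vals3) <- sprintf("g%03d", 1:50)
  m3 <- screen_matrix(vals3, toy_conditions(2), stage = "raw")
  expect_warning(vn3 <- variance_normalize(m3), "zero IQR")
  expect_equal(unname(vn3$values[, 2]), rep(0, 50))
})

test_that("variance normalization improves between-replicate reproducibility", {
  # two replicate plates measuring the same genes with unequal noise scales
  set.seed(8)
  true <- rnorm(300)
  rep1 <- true + rnorm(300, sd = 0.2)
  rep2 <- (true + rnorm(300, sd = 0.2)) * 3  # same info, inflated scale
  vals <- cbind(rep1, rep2)
  rownames(vals) <- sprintf("g%03d", 1:300)
  m <- screen_matrix(vals, toy_conditions(2), stage = "raw")
  vn <- variance_normalize(m)
  sd_before <- mean(apply(vals, 1, sd))
  sd_after <- mean(apply(vn$values, 1, sd))
  expect_lt(sd_after, sd_before)
})

test_that("reliability filtering reaches the brute-force fixed point", {
  # boundary: exactly 75% reliable is retained, below is dropped
  vals <- matrix(rnorm(40), nrow = 2,
                 dimnames = list(c("keep", "drop"), NULL))
  mask <- matrix(TRUE, 2, 20)
  mask[1, 1:5] <- FALSE   # 75% exactly
  mask[2, 1:6] <- FALSE   # 70%
  m <- screen_matrix(vals, toy_conditions(20), mask = mask, stage = "score")
  f <- filter_low_coverage(m, 0.75)
  expect_equal(rownames(f$values), "keep")
  expect_equal(attr(f, "dropped_genes"), "drop")

  # random 20%-missing matrix vs an independent iterative filter
  set.seed(9)
  vals <- matrix(rnorm(100 * 50), nrow = 100,
                 dimnames = list(sprintf("g%03d", 1:100), NULL))
  mask <- matrix(runif(100 * 50) > 0.2, 100, 50)
  m <- screen_matrix(vals, toy_conditions(50), mask = mask, stage = "score")
  f <- filter_low_coverage(m, 0.75)

  # independent fixed-point filter: batch-drop genes against the current
  # condition set, then batch-drop conditions, until nothing changes
  keep_r <- rep(TRUE, 100); keep_c <- rep(TRUE, 50)
  repeat {
    changed <- FALSE
    bad_r <- keep_r &
      apply(mask[, keep_c, drop = FALSE], 1, mean) < 0.75
    if (any(bad_r)) { keep_r[bad_r] <- FALSE; changed <- TRUE }
    bad_c <- keep_c &
      apply(mask[keep_r, , drop = FALSE], 2, mean) < 0.75
    if (any(bad_c)) { keep_c[bad_c] <- FALSE; changed <- TRUE }
    if (!changed) break
  }
  expect_equal(rownames(f$values), rownames(vals)[keep_r])
  expect_equal(ncol(f$values), sum(keep_c))
})
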