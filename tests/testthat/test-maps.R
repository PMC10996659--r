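test_that("polynomial detrending removes constants, ramps and stays orthogonal", {
  expect_equal(detrend_poly(matrix(7, 3, 20), order = 0), matrix(0, 3, 20))
  ramp <- matrix(seq(2, 40, by = 2), nrow = 1)
  expect_equal(detrend_poly(ramp, order = 1), ramp * 0, tolerance = 1e-12)
  set.seed(20)
  y <- matrix(rnorm(5 * 30), 5, 30)
  res <- detrend_poly(y, order = 2, run_lengths = c(14, 16))
  off <- 0
  for (rl in c(14, 16)) {
    cols <- off + seq_len(rl)
    x <- seq(-1, 1, length.out = rl)
    basis <- cbind(1, x, x^2)
    expect_lt(max(abs(res[, cols] %*% basis)), 1e-8)
    off <- off + rl
  }
  expect_error(detrend_poly(matrix(0, 1, 3), order = 2), "too short")
})

test_that("TSNR follows mean/sd with the zero-variance convention", {
  d <- c(4, 4, 2)
  nt <- 50
  sig <- array(100, dim = c(d, nt))
  noi <- array(rnorm(prod(d) * nt, sd = 0.5), dim = c(d, nt))
  noi[1, 1, 1, ] <- 0     # zero-variance voxel
  mask <- array(TRUE, dim = d)
  ts <- tsnr_map(tiny_vol(sig), tiny_vol(noi), mask)
  expect_equal(ts$data[1, 1, 1], 0)
  expect_equal(ts$n_zero_sd, 1)
  inmask <- ts$data[mask][-1]
  expect_equal(mean(inmask), 100 / 0.5, tolerance = 0.1)
})

test_that("volreg-stage TSNR recovers a phantom's injected mean/sd ratio", {
  set.seed(21)
  d <- c(10, 10, 6)
  nt <- 80
  mask <- ellipsoid_mask(d)
  arr <- array(500 + rnorm(prod(d) * nt, sd = 5), dim = c(d, nt))
  ts <- tsnr_volreg(tiny_vol(arr), mask)
  expect_equal(mean(ts$data[mask]), 500 / 5, tolerance = 0.05 * 100)
  expect_true(all(ts$data[mask] >= 0))
})

test_that("gcor handles the perfectly shared and perfectly cancelling cases", {
  set.seed(22)
  s <- rnorm(40)
  y_same <- matrix(rep(s, 30), nrow = 30, byrow = TRUE) *
    runif(30, 0.5, 2)            # positive rescaling allowed
  expect_equal(gcor(y_same), 1, tolerance = 1e-12)
  y_anti <- rbind(matrix(rep(s, 10), 10, byrow = TRUE),
                  matrix(rep(-s, 10), 10, byrow = TRUE))
  expect_equal(gcor(y_anti), 0, tolerance = 1e-12)
})

test_that("gcor equals the brute-force pairwise correlation mean", {
  set.seed(23)
  y <- matrix(rnorm(50 * 60), 50, 60) + outer(rnorm(50), rnorm(60))
  expect_equal(gcor(y), oracle_gcor(y), tolerance = 1e-10)
  expect_gte(gcor(y), 0)
  expect_lte(gcor(y), 1)
})

test_that("corr_brain matches a per-voxel correlation oracle", {
  set.seed(24)
  d <- c(6, 6, 4)
  nt <- 40
  mask <- ellipsoid_mask(d)
  shared <- rnorm(nt)
  arr <- array(rnorm(prod(d) * nt), dim = c(d, nt))
  for (t in seq_len(nt)) arr[, , , t] <- arr[, , , t] + 0.7 * shared[t] * mask
  vol <- tiny_vol(arr)
  cb <- corr_brain(vol, mask)
  y <- matrix(arr, nrow = prod(d))[which(mask), ]
  gm <- colMeans(y)
  want <- apply(y, 1, stats::cor, y = gm)
  expect_equal(cb$data[mask], want, tolerance = 1e-10)
  expect_equal(cb$display_thr, 0.3)
  expect_equal(cb$display_range, 0.6)
})

test_that("corr_brain hits +-1 in the degenerate shared-signal cases", {
  d <- c(4, 4, 2)
  nt <- 20
  s <- sin(seq_len(nt))
  arr <- array(rep(s, each = prod(d)), dim = c(d, nt))
  mask <- array(TRUE, dim = d)
  cb <- corr_brain(tiny_vol(arr), mask)
  expect_equal(unname(cb$data[mask]), rep(1, prod(d)), tolerance = 1e-12)
  arr[1, 1, 1, ] <- -3 * s + 100
  # one anti-correlated voxel: correlation with the (still s-like) mean is -1
  cb2 <- corr_brain(tiny_vol(arr), mask)
  expect_equal(cb2$data[1, 1, 1], -1, tolerance = 1e-6)
})

test_that("radial correlation equals the dense direct-summation oracle", {
  set.seed(25)
  d <- c(16, 16, 16)
  nt <- 10
  mask <- ellipsoid_mask(d)
  arr <- array(rnorm(prod(d) * nt), dim = c(d, nt))
  patch <- array(FALSE, dim = d); patch[4:8, 4:8, 4:8] <- TRUE
  lat <- rnorm(nt)
  for (t in seq_len(nt)) arr[, , , t] <- arr[, , , t] + 2 * lat[t] * (patch & mask)
  vol <- tiny_vol(arr)
  rc <- radial_correlate(vol, mask, fwhm_mm = 14)
  want <- oracle_radcor(vol, mask, fwhm_mm = 14)
  expect_equal(rc$data, want, tolerance = 1e-6)
  expect_true(all(abs(rc$data[mask]) <= 1 + 1e-12))
})

test_that("radial correlation degenerates sensibly", {
  d <- c(6, 6, 4)
  nt <- 15
  s <- cos(seq_len(nt))
  arr <- array(rep(s, each = prod(d)), dim = c(d, nt))
  mask <- array(TRUE, dim = d)
  rc <- radial_correlate(tiny_vol(arr), mask)
  expect_equal(unname(rc$data[mask]), rep(1, prod(d)), tolerance = 1e-12)
  single <- array(FALSE, dim = d); single[3, 3, 2] <- TRUE
  arr2 <- array(rnorm(prod(d) * nt), dim = c(d, nt))
  rc2 <- radial_correlate(tiny_vol(arr2), single)
  expect_equal(rc2$data[3, 3, 2], 1)
  expect_error(radial_correlate(tiny_vol(arr2), mask, fwhm_mm = 0), "positive")
})

test_that("very large FWHM approaches whole-mask correlation", {
  set.seed(26)
  d <- c(8, 8, 6)
  nt <- 30
  mask <- ellipsoid_mask(d)
  shared <- rnorm(nt)
  arr <- array(rnorm(prod(d) * nt), dim = c(d, nt))
  for (t in seq_len(nt)) arr[, , , t] <- arr[, , , t] + shared[t] * mask
  vol <- tiny_vol(arr)
  extent <- max(d) * 3
  rc <- radial_correlate(vol, mask, fwhm_mm = 10 * extent)
  cb <- corr_brain(vol, mask)
  expect_lt(max(abs(rc$data[mask] - cb$data[mask])), 0.05)
})

test_that("seed correlation recovers planted network structure", {
  set.seed(27)
  d <- c(10, 10, 6)
  nt <- 60
  mask <- ellipsoid_mask(d)
  lat <- rnorm(nt)
  arr <- array(rnorm(prod(d) * nt, sd = 1), dim = c(d, nt))
  net <- array(FALSE, dim = d); net[3:4, 3:4, 3] <- TRUE; net[7:8, 7:8, 4] <- TRUE
  net <- net & mask
  anti <- array(FALSE, dim = d); anti[6:7, 3:4, 3] <- TRUE
  anti <- anti & mask & !net
  for (t in seq_len(nt)) {
    arr[, , , t] <- arr[, , , t] + 3 * lat[t] * net - 3 * lat[t] * anti
  }
  seed <- which(net, arr.ind = TRUE)[1, ]
  sc <- seed_corr(tiny_vol(arr), mask, seed, seed_radius_mm = 0)
  expect_equal(sc$data[seed[1], seed[2], seed[3]], 1, tolerance = 1e-12)
  expect_gt(min(sc$data[net]), 0.7)
  expect_lt(max(sc$data[anti]), -0.7)
  bg <- mask & !net & !anti
  expect_lt(stats::quantile(abs(sc$data[bg]), 0.9), 0.5)
  expect_error(seed_corr(tiny_vol(arr), mask, c(50, 1, 1)), "outside the grid")
})

test_that("grayplot clips at the two-sided normal quantile and orders by PC similarity", {
  expect_equal(stats::qnorm(1 - 0.001 / 2), 3.290527, tolerance = 1e-6)
  set.seed(28)
  s <- rnorm(50)
  signs <- rep(c(1, -1), length.out = 20)
  y <- outer(signs * runif(20, 0.5, 3), s)   # rank-1: rows proportional to s
  gp <- grayplot(y)
  expect_equal(gp$clip, stats::qnorm(1 - 0.001 / 2))
  expect_true(all(abs(gp$values) <= gp$clip + 1e-12))
  # every row correlates +-1 with PC1; sorted rows identical up to sign
  ref <- gp$values[1, ]
  for (r in 2:nrow(gp$values))
    expect_equal(abs(stats::cor(gp$values[r, ], ref)), 1, tolerance = 1e-10)
})

test_that("similarity-sorted grayplot is invariant to input row permutation", {
  set.seed(29)
  y <- matrix(rnorm(30 * 40), 30, 40)
  gp1 <- grayplot(y)
  perm <- sample(30)
  gp2 <- grayplot(y[perm, ])
  expect_equal(gp2$values, gp1$values, tolerance = 1e-10)
})

test_that("zero-variance voxels render as zero rows", {
  y <- rbind(matrix(rnorm(5 * 30), 5, 30), matrix(4, 2, 30))
  gp <- grayplot(y, order_mode = "unsorted")
  expect_equal(gp$values[6:7, ], matrix(0, 2, 30))
})
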