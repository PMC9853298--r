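test_that("low-band averaging uses uniform weights that sum to one", {
  a <- rand_img(12, seed = 1); b <- rand_img(12, seed = 2)
  f <- dct_fuse_low(list(a, b))
  expect_equal(attr(f, "weights"), c(0.5, 0.5))
  expect_equal(f[3, 4], (a[3, 4] + b[3, 4]) / 2, tolerance = 1e-15)
  expect_equal(matrix(dct_fuse_low(list(a, a)), 12, 12), a, tolerance = 1e-15)

  p <- dct_fuse_low(list(a, b, a, b, a))
  expect_equal(sum(attr(p, "weights")), 1, tolerance = 1e-10)

  m1 <- matrix(0.2, 4, 4); m2 <- matrix(0.6, 4, 4)
  expect_equal(dct_fuse_low(list(m1, m2))[1, 1], 0.4)
  expect_error(dct_fuse_low(list(a)))
  expect_error(dct_fuse_low(list(a, rand_img(10, seed = 3))))
})

test_that("regional standard deviation matches hand and loop oracles", {
  expect_true(all(region_std(matrix(0.3, 9, 9), 1) == 0))

  x <- matrix(0, 3, 3); x[2, 2] <- 1
  got <- region_std(x, 1)[2, 2]
  expect_equal(got, sqrt(((1 - 1 / 9)^2 + 8 * (1 / 9)^2) / 8),
               tolerance = 1e-12)
  expect_equal(got, 1 / 3, tolerance = 1e-12)

  y <- rand_img(16, seed = 6)
  for (r in c(1, 2)) {
    expect_equal(region_std(y, r), oracle_region_std(y, r), tolerance = 1e-12)
  }
  expect_error(region_std(matrix(1, 3, 3), 2))
})

test_that("high-band selection follows the maximum regional-deviation weight", {
  a <- rand_img(12, seed = 7); b <- rand_img(12, seed = 8)
  f <- dct_fuse_high(list(a, b), radius = 1)
  W <- attr(f, "weights")
  expect_lt(max(abs(W[[1]] + W[[2]] - 1)), 1e-10)
  expect_true(all(W[[1]] >= 0 & W[[2]] >= 0))
  winner <- attr(f, "winner")
  expect_true(all(f[winner == 1] == a[winner == 1]))
  expect_true(all(f[winner == 2] == b[winner == 2]))

  expect_equal(dct_fuse_high(list(a, a), radius = 1), a,
               ignore_attr = TRUE, tolerance = 1e-15)

  # textured left / flat right against its complement: away from the
  # seam each side comes from the textured source
  n <- 16
  tex <- rand_img(n, seed = 9) - 0.5
  A <- cbind(tex[, 1:8], matrix(0, n, 8))
  B <- cbind(matrix(0, n, 8), tex[, 9:16])
  fz <- dct_fuse_high(list(A, B), radius = 1)
  expect_equal(fz[, 1:6], A[, 1:6], tolerance = 1e-12)
  expect_equal(fz[, 11:16], B[, 11:16], tolerance = 1e-12)

  # uniform weights where every deviation vanishes
  f0 <- dct_fuse_high(list(matrix(0, 6, 6), matrix(0, 6, 6)), radius = 1)
  expect_equal(attr(f0, "weights")[[1]], matrix(0.5, 6, 6))
})

test_that("region energy and activity maps match their loop oracles", {
  expect_true(all(region_energy(matrix(0, 8, 8), 1) == 0))
  x <- matrix(0, 9, 9); x[5, 5] <- 1
  e <- region_energy(x, 1)
  expect_equal(sum(e == 1), 9)
  expect_equal(sum(e), 9)

  y <- rand_img(16, seed = 10)
  expect_equal(region_energy(y, 2), oracle_region_energy(y, 2),
               tolerance = 1e-12)

  maps <- array(0, c(2, 2, 2))
  maps[, , 1] <- matrix(c(1, 0, -2, 3), 2, 2)
  expect_equal(activity_map(maps, radius = 1), matrix(1.5, 2, 2),
               tolerance = 1e-12)
  expect_true(all(activity_map(array(0, c(4, 4, 3)), 1) == 0))

  m2 <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  set.seed(31); m2 <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  expect_equal(activity_map(m2, 2), oracle_activity(m2, 2), tolerance = 1e-12)
})

test_that("sum-modified spatial frequency localizes edges and matches its oracle", {
  expect_true(all(nmsf(matrix(0.4, 10, 10), 1) == 0))

  step <- cbind(matrix(0, 12, 6), matrix(1, 12, 6))
  s <- nmsf(step, 1)
  expect_true(all(s[, 6:8] > 0))
  expect_true(all(s[, c(1:4, 10:12)] == 0))

  y <- rand_img(16, seed = 11)
  expect_equal(nmsf(y, 1), oracle_nmsf(y, 1), tolerance = 1e-10)
  expect_equal(nmsf(y, 3), oracle_nmsf(y, 3), tolerance = 1e-10)
})

test_that("sparse-domain fusion selects whole coefficient vectors by salience", {
  dict <- init_dictionary(2, 4, seed = 12)
  n <- 16
  low_a <- rand_img(n, seed = 13) + 0.5
  low_b <- rand_img(n, seed = 14) * 0.1
  enc <- function(img) suppressWarnings(
    csc_encode(img, dict, lambda = 0.01, lambda1 = 0, max_iters = 60,
               tol = 1e-6))
  ma <- enc(low_a); mb <- enc(low_b)

  # A's salience dominates everywhere: the fusion is exactly A's code
  fz <- fuse_low_csr(ma, mb, low_a, low_b, dict, radius = 1)
  expect_true(all(fz$winner == 1L))
  expect_equal(fz$image, csc_reconstruct(ma, dict), tolerance = 1e-12)

  # identical sources tie everywhere and return the common reconstruction
  ft <- fuse_low_csr(ma, ma, low_a, low_a, dict, radius = 1)
  expect_true(all(ft$winner == 0L))
  expect_equal(ft$image, csc_reconstruct(ma, dict), tolerance = 1e-12)

  # swapping the sources flips labels but not values
  f1 <- fuse_low_csr(ma, mb, low_a, low_b, dict, radius = 1)
  f2 <- fuse_low_csr(mb, ma, low_b, low_a, dict, radius = 1)
  expect_equal(f1$image, f2$image, tolerance = 1e-12)

  expect_error(fuse_low_csr(array(0, c(n, n, 1)), mb, low_a, low_b, dict))

  # high-band variant keys on spatial frequency
  hb_a <- rand_img(n, seed = 15) - 0.5
  hb_b <- matrix(0, n, n)
  ha <- enc(hb_a); hz <- enc(hb_b)
  fh <- fuse_high_csr(ha, hz, hb_a, hb_b, dict, radius = 1)
  expect_true(mean(fh$winner == 1L) > 0.99)
  expect_equal(fh$image, csc_reconstruct(ha, dict), tolerance = 1e-10)
})
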