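test_that("total variation: hand value, homogeneity, constants", {
  expect_equal(tv_value(matrix(0.7, 5, 5)), 0)
  x <- matrix(c(0, 0, 1, 1), 2, 2)  # columns (0,0) and (1,1)
  expect_equal(tv_value(x), 4)
  y <- rand_img(9, seed = 4)
  expect_equal(tv_value(-2.5 * y), 2.5 * tv_value(y), tolerance = 1e-12)
  expect_error(tv_value(matrix(c(1, NA, 1, 1), 2, 2)))
})

test_that("encoding finds a planted filter and reaches small reconstruction error", {
  dict <- init_dictionary(1, 8, seed = 7)
  s <- matrix(0, 32, 32)
  s[10:17, 12:19] <- dict$filters[[1]]
  maps <- suppressWarnings(csc_encode(s, dict, lambda = 0.001, lambda1 = 0,
                                      max_iters = 250, tol = 1e-8))
  peak <- which(abs(maps[, , 1]) == max(abs(maps[, , 1])), arr.ind = TRUE)
  expect_equal(as.integer(peak[1, ]), c(10L, 12L))
  rec <- csc_reconstruct(maps, dict)
  expect_lt(sqrt(sum((rec - s)^2) / sum(s^2)), 0.03)
})

test_that("a large sparsity weight zeroes the code and leaves the trivial objective", {
  dict <- init_dictionary(2, 4, seed = 2)
  s <- rand_img(16, seed = 5)
  maps <- suppressWarnings(csc_encode(s, dict, lambda = 1e3, lambda1 = 0,
                                      max_iters = 50, tol = 0))
  expect_lt(max(abs(maps)), 1e-10)
  tr <- attr(maps, "objective_trace")
  expect_equal(tr[length(tr)], 0.5 * sum(s^2), tolerance = 1e-6)
})

test_that("with no TV term the encoder agrees with the learning-stage solver", {
  img <- rand_img(16, seed = 10)
  dict <- init_dictionary(2, 4, seed = 3)
  lam <- 0.05
  maps <- suppressWarnings(csc_encode(img, dict, lambda = lam, lambda1 = 0,
                                      max_iters = 300, tol = 1e-9))
  obj_enc <- csc_objective_of(maps, img, dict, lam)
  st <- csrfuse:::new_cdl_state(list(img), dict, lambda = lam,
                                rho = 10 * lam + 0.1)
  st <- update_coeffs(st, n_iter = 300)
  obj_upd <- csc_objective_of(st$z[[1]], img, dict, lam)
  expect_lt(abs(obj_enc - obj_upd) / obj_upd, 1e-6)
})

test_that("TV-regularized objective is non-increasing within slack and flags non-convergence", {
  dict <- init_dictionary(2, 8, seed = 7)
  s <- rand_img(32, seed = 13)
  maps <- suppressWarnings(csc_encode(s, dict, lambda = 0.01, lambda1 = 1e-3,
                                      max_iters = 60, tol = 0))
  tr <- attr(maps, "objective_trace")
  expect_true(all(diff(tr) <= 0.01 * tr[-length(tr)]))
  expect_false(attr(maps, "converged"))
  expect_warning(csc_encode(s, dict, lambda = 0.01, lambda1 = 1e-3,
                            max_iters = 5, tol = 0), "not converged")

  expect_error(csc_encode(s, dict, lambda = -1))
  expect_error(csc_encode(matrix(0.5, 4, 4), dict))  # filters larger than image
})

test_that("reconstruction is linear and places filters at delta positions", {
  dict <- init_dictionary(3, 4, seed = 9)
  maps <- array(0, c(12, 12, 3))
  expect_true(all(csc_reconstruct(maps, dict) == 0))

  maps[3, 5, 2] <- 1
  rec <- csc_reconstruct(maps, dict)
  expect_equal(rec[3:6, 5:8], dict$filters[[2]], tolerance = 1e-12)

  # against the nested-loop circular convolution oracle, with wrap-around
  set.seed(21)
  maps2 <- array(rnorm(12 * 12 * 3, sd = 0.3), c(12, 12, 3))
  want <- Reduce(`+`, lapply(1:3, function(k) {
    oracle_cconv(dict$filters[[k]], maps2[, , k])
  }))
  expect_equal(csc_reconstruct(maps2, dict), want, tolerance = 1e-10)

  a <- csc_reconstruct(maps, dict); b <- csc_reconstruct(maps2, dict)
  ab <- csc_reconstruct(2 * maps - 3 * maps2, dict)
  expect_equal(ab, 2 * a - 3 * b, tolerance = 1e-10)
  expect_error(csc_reconstruct(array(0, c(12, 12, 2)), dict))
})

test_that("round trip on dictionary-generated sub-images stays within the coding error budget", {
  truth <- init_dictionary(3, 8, seed = 15)
  img <- planted_images(truth, n = 48, m = 1, density = 0.02, noise = 0,
                        seed = 16)[[1]]
  maps <- suppressWarnings(csc_encode(img, truth, lambda = 0.01,
                                      lambda1 = 1e-3, max_iters = 200,
                                      tol = 1e-6))
  rec <- csc_reconstruct(maps, truth)
  expect_lt(sqrt(sum((rec - img)^2) / sum(img^2)), 0.03)

  # zero input -> zero output through the whole path
  z <- suppressWarnings(csc_encode(matrix(0, 16, 16), truth, lambda = 0.01,
                                   lambda1 = 1e-3, max_iters = 10, tol = 0))
  expect_true(all(csc_reconstruct(z, truth) == 0))
})
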