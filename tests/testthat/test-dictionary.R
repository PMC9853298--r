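test_that("dictionary initialization is seeded, unit-norm and DC-free", {
  d1 <- init_dictionary(6, 8, seed = 42)
  d2 <- init_dictionary(6, 8, seed = 42)
  expect_identical(d1, d2)
  d3 <- init_dictionary(6, 8, seed = 43)
  expect_false(identical(d1$filters, d3$filters))
  for (f in d1$filters) {
    expect_equal(sum(f^2), 1, tolerance = 1e-8)
    expect_lt(abs(mean(f)), 1e-10)
  }
  expect_error(init_dictionary(0, 8))
  expect_error(init_dictionary(2, 1))
})

test_that("sparse-coding objective matches a nested-loop evaluation", {
  dict <- init_dictionary(2, 3, seed = 7)
  img <- rand_img(8, seed = 8)
  coeffs <- list(array(rnorm(8 * 8 * 2), c(8, 8, 2)))
  set.seed(11)
  coeffs <- list(array(rnorm(8 * 8 * 2), c(8, 8, 2)))
  got <- cdl_objective(dict, coeffs, list(img), lambda = 0.05)
  want <- oracle_cdl_objective(dict$filters, coeffs, list(img), 0.05)
  expect_equal(got, want, tolerance = 1e-10)

  # all-zero coefficients: objective is half the image energy
  z <- list(array(0, c(8, 8, 2)))
  expect_equal(cdl_objective(dict, z, list(img), 0.3),
               0.5 * sum(img^2), tolerance = 1e-12)

  # lambda = 0 with a perfect reconstruction: objective 0
  delta <- matrix(0, 3, 3); delta[1, 1] <- 1
  ddict <- make_dict(list(delta), s = 3)
  maps <- array(rand_img(8, seed = 9), c(8, 8, 1))
  rec_img <- csc_reconstruct(maps, ddict)
  expect_equal(cdl_objective(ddict, list(maps), list(rec_img), 0), 0,
               tolerance = 1e-12)
})

test_that("coefficient update solves the lasso: kill, fit, and match ISTA", {
  img <- rand_img(16, seed = 10)
  dict <- init_dictionary(2, 4, seed = 3)

  # lambda far above the maximal correlation drives all maps to zero
  st <- csrfuse:::new_cdl_state(list(img), dict, lambda = 1e3, rho = 10)
  st <- update_coeffs(st, n_iter = 10)
  expect_lt(max(abs(st$z[[1]])), 1e-12)

  # lambda = 0 with a delta filter reproduces the image
  delta <- matrix(0, 4, 4); delta[1, 1] <- 1
  ddict <- make_dict(list(delta), s = 4)
  st <- csrfuse:::new_cdl_state(list(img), ddict, lambda = 0, rho = 0.1)
  st <- update_coeffs(st, n_iter = 100)
  expect_lt(max(abs(st$z[[1]][, , 1] - img)), 1e-6)
  expect_error(update_coeffs(csrfuse:::new_cdl_state(list(img), dict, 0.1, -1)))

  # against an independent proximal-gradient solver on a shared instance
  lam <- 0.05
  st <- csrfuse:::new_cdl_state(list(img), dict, lambda = lam, rho = 10 * lam + 0.1)
  st <- update_coeffs(st, n_iter = 300)
  obj_admm <- csc_objective_of(st$z[[1]], img, dict, lam)
  x_ista <- ista_csc(img, dict, lam, iters = 200)
  obj_ista <- csc_objective_of(x_ista, img, dict, lam)
  expect_lt(abs(obj_admm - obj_ista) / obj_ista, 1e-3)
})

test_that("filter update enforces the unit-norm constraint and idles without data", {
  img <- rand_img(32, seed = 12)
  dict <- init_dictionary(4, 8, seed = 5)
  st <- csrfuse:::new_cdl_state(list(img), dict, lambda = 0.05, rho = 0.6)
  st <- update_coeffs(st)
  for (i in 1:3) {
    st <- update_filters(st)
    for (f in st$dict$filters) expect_equal(sum(f^2), 1, tolerance = 1e-8)
  }

  # zero coefficient maps carry no signal: filters unchanged by projection
  st0 <- csrfuse:::new_cdl_state(list(matrix(0, 32, 32)), dict,
                                 lambda = 0.05, rho = 0.6)
  st0 <- update_filters(st0)
  for (k in seq_len(dict$K)) {
    expect_equal(st0$dict$filters[[k]], dict$filters[[k]], tolerance = 1e-10)
  }
})

test_that("dictionary learning descends, stops on tolerance, and is reproducible", {
  imgs <- lapply(1:4, function(i) rand_img(64, seed = 20 + i))
  d1 <- learn_dictionary(imgs, K = 16, s = 8, lambda = 0.01,
                         max_iters = 20, tol = 0, seed = 3)
  d2 <- learn_dictionary(imgs, K = 16, s = 8, lambda = 0.01,
                         max_iters = 20, tol = 0, seed = 3)
  expect_identical(d1$filters, d2$filters)
  expect_identical(attr(d1, "objective_trace"), attr(d2, "objective_trace"))

  tr <- attr(d1, "objective_trace")
  expect_length(tr, 20)
  expect_true(all(is.finite(tr)) && all(tr >= 0))
  expect_true(all(diff(tr) <= 0.01 * tr[-length(tr)]))

  # the 0.03 relative-change stopping rule fires early
  d3 <- learn_dictionary(imgs, K = 16, s = 8, lambda = 0.01,
                         max_iters = 20, tol = 0.03, seed = 3)
  expect_lt(length(attr(d3, "objective_trace")), 20)
  tr3 <- attr(d3, "objective_trace")
  n3 <- length(tr3)
  expect_lt(abs(tr3[n3] - tr3[n3 - 1]) / tr3[n3 - 1], 0.03)

  expect_error(learn_dictionary(list(), K = 2))
  expect_warning(
    dz <- learn_dictionary(list(matrix(0, 16, 16)), K = 2, s = 4, seed = 1),
    "no signal")
  expect_true(attr(dz, "no_signal"))
})

test_that("planted filters are recovered from sparse synthetic data", {
  truth <- init_dictionary(2, 8, seed = 11)
  imgs <- planted_images(truth, n = 64, m = 4, density = 0.02,
                         noise = 0.01, seed = 99)
  dict <- learn_dictionary(imgs, K = 2, s = 8, lambda = 0.1,
                           max_iters = 150, tol = 0, seed = 5)
  cors <- vapply(1:2, function(i) {
    max(vapply(1:2, function(j) {
      best_shift_corr(truth$filters[[i]], dict$filters[[j]])
    }, 0))
  }, 0)
  expect_gte(mean(cors), 0.95)
})

test_that("multi-scale learning concatenates per-scale dictionaries", {
  img_a <- rand_img(32, seed = 31)
  img_b <- rand_img(32, seed = 32)
  pa <- dct_decompose(img_a, 3); pb <- dct_decompose(img_b, 3)
  dicts <- learn_multiscale(pa, pb, K = 4, s = 8, lambda = 0.01,
                            max_iters = 3, tol = 0, seed = 2)
  expect_identical(dicts$d_high$K, 12L)
  expect_length(dicts$d_scales, 3L)
  expect_identical(dicts$d_high$filters[1:4], dicts$d_scales[[1]]$filters)
  for (f in dicts$d_high$filters) expect_equal(sum(f^2), 1, tolerance = 1e-8)

  dicts2 <- learn_multiscale(pa, pb, K = 4, s = 8, lambda = 0.01,
                             max_iters = 3, tol = 0, seed = 2)
  expect_identical(dicts$d_high$filters, dicts2$d_high$filters)

  # constant sources have empty high bands: initialized dictionaries with
  # a no-signal warning
  ca <- dct_decompose(matrix(0.4, 32, 32), 3)
  cb <- dct_decompose(matrix(0.6, 32, 32), 3)
  w <- capture_warnings(
    dc <- learn_multiscale(ca, cb, K = 4, s = 8, max_iters = 2, seed = 2))
  expect_true(any(grepl("no signal", w)))
  expect_true(attr(dc$d_scales[[1]], "no_signal"))
  expect_error(learn_multiscale(pa, dct_decompose(rand_img(40, seed = 1), 3),
                                K = 4))
})
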