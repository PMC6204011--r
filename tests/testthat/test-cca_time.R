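test_that("time regression projects out the spline space exactly", {
  set.seed(1)
  n <- 200
  pma <- runif(n, 25, 90)
  basis <- splines::ns(pma, df = 6)
  # a feature equal to a basis function has ~zero residual
  x <- cbind(f_basis = basis[, 3], f_const = rep(2, n),
             f_noise = rnorm(n))
  r <- regress_out_time(x, pma, df = 6)
  expect_lt(max(abs(r[, "f_basis"])), 1e-8)
  expect_lt(max(abs(r[, "f_const"])), 1e-8)
  # a time-independent feature keeps most of its variance
  expect_gt(var(r[, "f_noise"]) / var(x[, "f_noise"]), 0.9)
  expect_error(regress_out_time(x[1:5, ], pma[1:5], df = 10), "df")
})

test_that("identical matrices give a near-perfect first held-out correlation", {
  set.seed(2)
  n_subj <- 30; per <- 5
  subject <- rep(sprintf("S%02d", 1:n_subj), each = per)
  X <- matrix(rnorm(n_subj * per * 8), ncol = 8)
  cv <- blocked_cv_cca(X, X, subject, folds = 5, n_components = 3)
  expect_gt(cv$heldout_mean[1], 0.99)
  # training correlations non-increasing
  tr <- cv$train[!is.na(cv$train[, 1]), ]
  expect_true(all(apply(tr, 1, function(r) all(diff(na.omit(r)) <= 1e-8))))
})

test_that("folds block by subject and results ignore feature order", {
  set.seed(3)
  n_subj <- 25; per <- 4
  subject <- rep(sprintf("S%02d", 1:n_subj), each = per)
  X <- matrix(rnorm(n_subj * per * 6), ncol = 6)
  Y <- matrix(rnorm(n_subj * per * 6), ncol = 6)
  cv <- blocked_cv_cca(X, Y, subject, folds = 5, n_components = 2, seed = 9)
  # all of a subject's rows share a fold
  expect_equal(length(cv$fold_of), n_subj)
  perm <- sample(6)
  cv2 <- blocked_cv_cca(X[, perm], Y, subject, folds = 5, n_components = 2,
                        seed = 9)
  expect_equal(cv2$heldout_mean, cv$heldout_mean, tolerance = 1e-8)
  expect_error(blocked_cv_cca(X, Y, subject, folds = 30), "folds")
})

test_that("a shared latent factor is detected and noise is not", {
  set.seed(4)
  n_subj <- 60; per <- 5; n <- n_subj * per; p <- 10
  subject <- rep(sprintf("S%02d", 1:n_subj), each = per)
  z <- rnorm(n)
  X <- sapply(1:p, function(j) 0.8 * z + rnorm(n))
  Y <- sapply(1:p, function(j) 0.8 * z + rnorm(n))
  cv <- blocked_cv_cca(X, Y, subject, folds = 10, n_components = 3)
  expect_gt(cv$heldout_mean[1], 0.4)
  # one shared dimension only: the second component is near zero (a small
  # positive leak from the first direction's estimation error remains)
  expect_lt(abs(cv$heldout_mean[2]), 0.15)
  expect_lt(abs(cv$heldout_mean[2]), cv$heldout_mean[1] / 4)
  # independent noise: first component within 0 +/- 2.5 SEM
  Y0 <- matrix(rnorm(n * p), n, p)
  cv0 <- blocked_cv_cca(X, Y0, subject, folds = 10, n_components = 2)
  expect_lt(abs(cv0$heldout_mean[1]), 2.5 * cv0$heldout_2sem[1] / 2)
})

test_that("ridge whitening engages when features outnumber training samples", {
  set.seed(5)
  n_subj <- 12; per <- 2; n <- n_subj * per
  subject <- rep(sprintf("S%02d", 1:n_subj), each = per)
  X <- matrix(rnorm(n * 30), n, 30)
  Y <- matrix(rnorm(n * 30), n, 30)
  expect_warning(cv <- blocked_cv_cca(X, Y, subject, folds = 4,
                                      n_components = 2),
                 "ridge")
  expect_true(cv$ridge_used)
  expect_true(all(abs(na.omit(cv$heldout_mean)) <= 1))
})
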