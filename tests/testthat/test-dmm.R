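test_that("a single-component fit matches a direct optimizer", {
  set.seed(5)
  alpha_true <- c(4, 2, 1, 0.5, 8)
  ct <- make_mixture_counts(matrix(alpha_true, 1), rep(1, 25),
                            depth = 300, seed = 5)
  fit <- dmm(ct, 1, n_restarts = 1, tol = 1e-12, max_iter = 5000)
  # independent oracle: BFGS on the single-component DM likelihood
  neg <- function(l) -dm_loglik_direct(unclass(ct), exp(l))
  opt <- optim(log(rep(1, 5)), neg, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  expect_equal(fit$loglik, -opt$value, tolerance = 1e-6)
  expect_equal(fit$pi, 1)
  expect_equal(sort(fit$alpha[, 1] / sum(fit$alpha[, 1])),
               sort(exp(opt$par) / sum(exp(opt$par))), tolerance = 1e-3)
})

test_that("well-separated groups are recovered with confident posteriors", {
  alpha <- rbind(c(90, 5, 5, rep(0.5, 7)), c(rep(0.5, 7), 5, 5, 90))
  comp <- rep(1:2, each = 20)
  ct <- make_mixture_counts(alpha, comp, depth = 2000, seed = 7)
  fit <- dmm(ct, 2, seed = 1)
  post <- predict(fit, ct)
  expect_true(all(apply(post, 1, max) > 0.99))
  map <- max.col(post)
  expect_equal(ari(map, comp), 1)
  expect_true(all(abs(rowSums(post) - 1) < 1e-10))
})

test_that("the EM log-likelihood is non-decreasing", {
  alpha <- block_alpha(3, 24)
  set.seed(11)
  ct <- make_mixture_counts(alpha, sample(1:3, 90, TRUE), seed = 11)
  fit <- dmm(ct, 3, seed = 2, n_restarts = 1)
  expect_true(fit$monotone)
  expect_true(all(diff(fit$loglik_trace) >
                    -1e-8 * pmax(1, abs(fit$loglik_trace[-1]))))
})

test_that("assignment is invariant to sample order given the fit", {
  alpha <- block_alpha(2, 12)
  set.seed(13)
  comp <- sample(1:2, 40, TRUE)
  ct <- make_mixture_counts(alpha, comp, seed = 13)
  fit <- dmm(ct, 2, seed = 3)
  a1 <- assign_cst(fit, ct)
  perm <- sample(nrow(ct))
  a2 <- assign_cst(fit, ct[perm, ])
  expect_equal(a2$cst, a1$cst[perm])
  expect_equal(a2$posterior, a1$posterior[perm, ])
})

test_that("posterior ties break toward the lowest component index", {
  fit <- structure(list(k = 2,
                        alpha = cbind(c(5, 1), c(1, 5)),
                        pi = c(0.5, 0.5),
                        otu_ids = c("o1", "o2"),
                        n_samples = 2),
                   class = "dmm")
  X <- matrix(c(3L, 3L), 1, 2, dimnames = list("s1", c("o1", "o2")))
  post <- predict(fit, X)
  expect_equal(unname(post[1, ]), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(max.col(post, ties.method = "first"), 1)
})

test_that("frequency relabeling orders CSTs and preserves ties", {
  r <- relabel_by_frequency(c(2, 2, 2, 1))
  expect_equal(r$labels, c(1, 1, 1, 2))
  expect_equal(relabel_by_frequency(c(1, 1, 2))$labels, c(1, 1, 2))
  # tie: both occur twice, original order preserved
  expect_equal(relabel_by_frequency(c(2, 1, 1, 2))$perm, c(1, 2))
  expect_error(relabel_by_frequency(integer(0)), "non-empty")
})

test_that("assign_cst renumbers by frequency and validates the OTU universe", {
  alpha <- block_alpha(2, 12)
  # make component 2 the majority so canonical CST 1 is component 2
  ct <- make_mixture_counts(alpha, rep(c(1, 2), c(10, 30)), seed = 17)
  fit <- dmm(ct, 2, seed = 1)
  asg <- assign_cst(fit, ct)
  tab <- table(asg$cst)
  expect_true(all(diff(as.integer(tab)) <= 0))  # CST 1 most frequent
  bad <- unclass(ct)
  colnames(bad) <- paste0("x", seq_len(ncol(bad)))
  expect_error(assign_cst(fit, bad), "universe")
})

test_that("k validation and the degenerate k_max = 1 path work", {
  ct <- make_mixture_counts(block_alpha(1, 8), rep(1, 12), seed = 19)
  expect_error(dmm(ct, 13), "exceeds")
  ks <- select_k(ct, k_max = 1, reps = 3)
  expect_equal(ks$chosen_k, 1L)
})
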