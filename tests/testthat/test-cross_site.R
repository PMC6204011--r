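# covariates + subjects for mixed-model tests
pair_frame <- function(n_subj = 50, per = 8, seed = 1) {
  set.seed(seed)
  subject <- rep(sprintf("S%02d", seq_len(n_subj)), each = per)
  data.frame(
    subject = subject,
    delivery_mode = rep(sample(c("c-section", "vaginal"), n_subj, TRUE),
                        each = per),
    gab = rep(runif(n_subj, 24, 41), each = per),
    birth_season = rep(sample(c("winter", "spring", "summer", "fall"),
                              n_subj, TRUE), each = per),
    wol = as.numeric(replicate(n_subj, sort(sample(0:60, per)))))
}

test_that("visit pairing matches subjects and weeks and drops illness", {
  samples <- expand.grid(subject_id = c("A", "B", "C"), wol = c(0, 4, 8, 12),
                         site = c("gut", "nasal"), stringsAsFactors = FALSE)
  samples$sample_id <- with(samples, paste(subject_id, site, wol, sep = "."))
  samples$pma <- 30 + samples$wol
  samples$illness_flag <- FALSE
  # remove one nasal sample -> 11 pairs
  samples <- samples[samples$sample_id != "B.nasal.8", ]
  vp <- pair_visits(samples, "gut", "nasal")
  expect_equal(nrow(vp), 11)
  # illness on one gut sample drops its pair too
  samples$illness_flag[samples$sample_id == "A.gut.0"] <- TRUE
  expect_equal(nrow(pair_visits(samples, "gut", "nasal")), 10)
  # subject with gut only contributes nothing
  only_gut <- samples[samples$site == "gut", ]
  expect_error(pair_visits(only_gut, "gut", "nasal"), "present")
})

test_that("co-occurrence chi-squared matches the closed form and is symmetric", {
  la <- rep(1:2, each = 50)
  lb <- rep(1:2, each = 50)
  r <- cooccurrence_chisq(la, lb, simulate = "never")
  expect_equal(r$statistic, 100)
  r2 <- cooccurrence_chisq(lb, la, simulate = "never")
  expect_equal(r2$statistic, r$statistic)
  expect_equal(unname(unclass(r2$table)), t(unname(unclass(r$table))))
  expect_error(cooccurrence_chisq(rep(1, 100), lb), "distinct")
})

test_that("CST probability correlations: self-pairing and degenerate columns", {
  set.seed(2)
  post <- matrix(runif(300), 100, 3)
  post <- post / rowSums(post)
  cm <- cst_probability_correlation(post, post)
  expect_equal(unname(diag(cm)), rep(1, 3))
  post_b <- cbind(post[, 1:2], 0.5)  # zero-variance column
  cm2 <- cst_probability_correlation(post, post_b)
  expect_true(all(is.na(cm2[, 3])))
  expect_false(anyNA(cm2[, 1:2]))
})

test_that("taxon mixed models: deviation coding, F block test, delta-R2", {
  d <- pair_frame(seed = 3)
  n <- nrow(d)
  set.seed(3)
  cst <- factor(sample(1:3, n, TRUE))
  subj_re <- rep(rnorm(50, 0, 0.05), each = 8)
  eff <- c(0.15, 0, -0.15)[as.integer(cst)]
  y_lin <- 0.35 + eff + 0.002 * d$wol + subj_re + rnorm(n, 0, 0.08)
  abund <- pmin(pmax(sin(y_lin)^2, 0), 1)  # invert arcsine-sqrt scale
  rec <- fit_taxon_models(abund, list(cst_remote = cst), d, d$subject,
                          spline_df = 8)
  # sum-to-zero: deviation estimates sum to zero
  expect_lt(abs(sum(rec$wald$estimate)), 1e-8)
  # the shifted CST is detected with the right direction
  w1 <- rec$wald[rec$wald$level == "1", ]
  expect_lt(w1$p_value, 0.05)
  expect_equal(w1$direction, "increase")
  expect_lt(rec$f_tests$cst_remote$p_value, 0.001)
  expect_gt(rec$delta_pseudo_r2, 0)

  # no CST terms: full model == null model, delta-R2 exactly zero
  rec0 <- fit_taxon_models(abund, list(), d, d$subject, spline_df = 8)
  expect_identical(rec0$delta_pseudo_r2, 0)
})

test_that("BH selection keeps monotone q-values and rolls up lineages", {
  rec <- data.frame(taxon = c("Bacteria;F1", "Bacteria;F1;G1",
                              "Bacteria;F2", "Bacteria;F3"),
                    remote_site = "nasal",
                    p_value = c(0.01, 0.02, 0.03, 0.04))
  out <- fdr_and_rollup(rec, fdr = 0.05)
  expect_equal(out$q_value, rep(0.04, nrow(out)))  # BH step-up: all q = 0.04
  # family F1 is dropped in favor of its significant genus G1
  expect_setequal(out$taxon,
                  c("Bacteria;F1;G1", "Bacteria;F2", "Bacteria;F3"))
  # q monotone in p
  rec2 <- data.frame(taxon = paste0("T", 1:6), remote_site = "gut",
                     p_value = c(0.001, 0.01, 0.2, 0.04, 0.6, 0.03))
  r2 <- fdr_and_rollup(rec2, fdr = 1)
  expect_true(all(diff(r2$q_value[order(r2$p_value)]) >= 0))
  # nothing significant -> empty
  rec3 <- data.frame(taxon = "T1", remote_site = "gut", p_value = 0.9)
  expect_equal(nrow(fdr_and_rollup(rec3)), 0)
})

test_that("taxon abundances aggregate counts up the lineage", {
  X <- matrix(c(10L, 30L, 60L,
                50L, 25L, 25L), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("o1", "o2", "o3")))
  tax <- c(o1 = "Bacteria;F1;G1", o2 = "Bacteria;F1;G2", o3 = "Bacteria;F2")
  ta <- taxon_abundances(counts_table(X, taxonomy = tax))
  expect_equal(unname(ta$abund[, "Bacteria"]), c(1, 1))
  expect_equal(unname(ta$abund[, "Bacteria;F1"]), c(0.4, 0.75))
  expect_equal(unname(ta$abund[, "Bacteria;F1;G2"]), c(0.3, 0.25))
})

test_that("shared-OTU residual correlations find shared factors only", {
  set.seed(4)
  n_subj <- 40; per <- 8; n <- n_subj * per
  subject <- rep(sprintf("S%02d", 1:n_subj), each = per)
  pma <- rep(runif(n_subj, 25, 40), each = per) +
    as.numeric(replicate(n_subj, sort(sample(0:60, per))))
  z <- rnorm(n)  # shared latent factor
  mk <- function(load) {
    m <- sapply(1:6, function(j)  # unit total variance: loading^2 + noise^2 = 1
      0.02 * pma + load[j] * z + rnorm(n, 0, sqrt(1 - load[j]^2)))
    colnames(m) <- paste0("OTU", 1:6)
    m
  }
  loads <- c(0.7, 0.7, 0, 0, 0, 0)
  A <- mk(loads); B <- mk(loads)
  colnames(B)[6] <- "OTU_b_only"  # present in one site only
  out <- shared_otu_residual_corr(A, B, pma, subject, spline_df = 6)
  expect_false("OTU_b_only" %in% out$otu_id)
  expect_false("OTU6" %in% out$otu_id)
  expect_gt(out$correlation[out$otu_id == "OTU1"], 0.3)
  expect_gt(out$correlation[out$otu_id == "OTU2"], 0.3)
  expect_lt(max(abs(out$correlation[out$otu_id %in% paste0("OTU", 3:5)])), 0.2)
  # constant OTU skipped
  A2 <- A; A2[, "OTU3"] <- 1
  out2 <- shared_otu_residual_corr(A2, B, pma, subject, spline_df = 6)
  expect_false("OTU3" %in% out2$otu_id)
})
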