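small_cfg <- function(...) {
  synth_config(n_preterm = 4, n_fullterm = 4,
               sites = list(gut = synth_site_spec(k = 3, n_otus = 20),
                            nasal = synth_site_spec(k = 3, n_otus = 20)),
               coupling = data.frame(site = "nasal", source = "gut",
                                     kappa = 0),
               illness_prob = 0, seed = 11, ...)
}

test_that("the generator is deterministic given a seed", {
  a <- simulate_cohort(small_cfg())
  b <- simulate_cohort(small_cfg())
  expect_identical(a, b)
  d <- simulate_cohort(synth_config(n_preterm = 4, n_fullterm = 4,
                                    sites = small_cfg()$sites,
                                    coupling = small_cfg()$coupling,
                                    illness_prob = 0, seed = 12))
  expect_false(identical(a$counts, d$counts))
})

test_that("visit schedules follow the weekly-then-monthly design", {
  sim <- simulate_cohort(small_cfg())
  cfg <- small_cfg()
  for (sid in sim$subjects$subject_id) {
    sub <- sim$subjects[sim$subjects$subject_id == sid, ]
    w <- sort(unique(sim$samples$wol[sim$samples$subject_id == sid]))
    if (sub$term_status == "full") {
      expect_equal(w, seq(0, cfg$fullterm_weeks, by = 4))
    } else {
      in_nicu <- w[sub$ga_birth + w < cfg$discharge_pma]
      expect_true(length(in_nicu) >= 1)      # ga < discharge_pma by design
      expect_equal(in_nicu, seq(0, max(in_nicu)))  # weekly while in NICU
      post <- w[w > max(in_nicu)]
      if (length(post) > 1) expect_true(all(diff(post) == 4))
      expect_true(all(sub$ga_birth + w <= cfg$followup_pma))
    }
  }
  # pma invariant on every record
  expect_equal(sim$samples$pma, sim$samples$ga_birth + sim$samples$wol)
})

test_that("emit_counts respects the multinomial closure and its contract", {
  set.seed(3)
  x <- emit_counts(c(2, 3, 1), 500)
  expect_equal(sum(x), 500)
  expect_error(emit_counts(c(1, -1), 100), "positive")
  expect_error(emit_counts(c(1, 1), 0), "library_size")
  # law of large numbers at alpha = (50, 50)
  draws <- replicate(10000, emit_counts(c(50, 50), 100)[1] / 100)
  expect_lt(abs(mean(draws) - 0.5), 0.02)
})

test_that("a generated cohort round-trips through the TSV dialect", {
  sim <- simulate_cohort(small_cfg())
  dir <- withr::local_tempdir()
  md <- merge(sim$samples,
              sim$subjects[, c("subject_id", "delivery_mode", "birth_season",
                               "sex", "ethnicity")],
              by = "subject_id")
  st <- "gut"
  mds <- md[md$site == st, ]
  mds <- mds[match(rownames(sim$counts[[st]]), mds$sample_id), ]
  write_dataset(sim$counts[[st]], mds, dir)
  back <- load_dataset(file.path(dir, "counts.tsv"),
                       file.path(dir, "metadata.tsv"),
                       file.path(dir, "taxonomy.tsv"))
  expect_equal(unclass(back$counts), unclass(sim$counts[[st]]),
               ignore_attr = TRUE)
  expect_equal(taxonomy(back$counts), taxonomy(sim$counts[[st]]))
  expect_equal(back$samples$pma, back$samples$ga_birth + back$samples$wol)
})

test_that("rank-copy coupling induces detectable cross-site dependence", {
  paired_labels <- function(kappa, seed) {
    cfg <- synth_config(n_preterm = 6, n_fullterm = 6,
                        sites = list(gut = synth_site_spec(k = 3, n_otus = 20),
                                     nasal = synth_site_spec(k = 3, n_otus = 20)),
                        coupling = data.frame(site = "nasal", source = "gut",
                                              kappa = kappa),
                        illness_prob = 0, seed = seed)
    sim <- simulate_cohort(cfg)
    lab <- sim$truth$labels
    g <- lab[lab$site == "gut", ]
    n <- lab[lab$site == "nasal", ]
    merge(g, n, by = c("subject_id", "wol"))
  }
  # strong coupling: dependence detected in every replicate
  ps <- vapply(1:5, function(r) {
    m <- paired_labels(0.9, 300 + r)
    cooccurrence_chisq(m$cst.x, m$cst.y)$p_value
  }, numeric(1))
  expect_true(all(ps < 0.001))
  # no coupling: CST labels across sites still share time structure, so we
  # only check that the coupled statistic dominates the uncoupled one
  m0 <- paired_labels(0, 301)
  m9 <- paired_labels(0.9, 301)
  s0 <- cooccurrence_chisq(m0$cst.x, m0$cst.y)$statistic /
    nrow(m0)
  s9 <- cooccurrence_chisq(m9$cst.x, m9$cst.y)$statistic / nrow(m9)
  expect_gt(s9, s0)
})

test_that("invalid configurations are rejected before generation", {
  expect_error(synth_config(n_preterm = 0), "cohort sizes")
  expect_error(synth_config(coupling = data.frame(site = "gut",
                                                  source = "gut",
                                                  kappa = 0.5)),
               "coupled to itself")
  expect_error(synth_config(coupling = data.frame(site = "throat",
                                                  source = "nasal",
                                                  kappa = 1.5)),
               "kappa")
  expect_error(synth_site_spec(k = 2, n_otus = 4,
                               alpha = matrix(c(1, -1, 1, 1, 1, 1, 1, 1), 2)),
               "positive")
})
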