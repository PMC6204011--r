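#' Per-site specification for the synthetic cohort generator
#'
#' Defines the latent community-state dynamics of one body site: the number
#' of CSTs, a Dirichlet parameter vector per CST, and for each CST a
#' maturity index `a * WOL + b * gaBirth` with a linear predictor
#' `intercept + slope * index` feeding a multinomial-logistic model of CST
#' occurrence.
#'
#' The default composition gives each CST a block of dominant OTUs
#' (pairwise mean total-variation distance well above 0.5), so the mixture
#' components are recoverable; the default dynamics give an early,
#' WOL-driven CST, a constant-baseline CST and a late, PMA-driven CST,
#' echoing the early/transition/late progression seen in infant cohorts.
#'
#' @param k number of CSTs (>= 1).
#' @param n_otus number of OTUs for the site.
#' @param alpha optional k x n_otus matrix of positive Dirichlet parameters;
#'   defaults to block-structured components (dominant block 15, background
#'   0.2).
#' @param a,b numeric length-k index weights per CST (defaults: CST 1 tracks
#'   WOL only, later CSTs track PMA).
#' @param intercept,slope numeric length-k linear-predictor parameters along
#'   each CST's index.
#' @return A `synth_site_spec` list.
#' @export
synth_site_spec <- function(k = 3, n_otus = 30, alpha = NULL,
                            a = NULL, b = NULL,
                            intercept = NULL, slope = NULL) {
  stopifnot(k >= 1, n_otus >= 2)
  if (is.null(alpha)) {
    alpha <- matrix(0.2, k, n_otus)
    block <- max(2L, floor(n_otus / max(k, 2)))
    for (i in seq_len(k)) {
      idx <- (((i - 1) * block) %% n_otus) + seq_len(block)
      idx <- ((idx - 1) %% n_otus) + 1
      alpha[i, idx] <- 15
    }
  }
  alpha <- as.matrix(alpha)
  if (nrow(alpha) != k || ncol(alpha) != n_otus)
    stop("alpha must be k x n_otus")
  if (any(alpha <= 0)) stop("all Dirichlet parameters must be positive")
  if (is.null(a)) a <- rep(1, k)
  if (is.null(b)) b <- if (k == 1) 0 else c(0, rep(1, k - 1))
  if (is.null(intercept)) {
    intercept <- if (k == 1) 0 else c(2, 0, seq(-12, -16, length.out = k - 2))
    intercept <- intercept[seq_len(k)]
  }
  if (is.null(slope)) {
    slope <- if (k == 1) 0 else c(-0.25, 0, rep(0.25, k - 2))
    slope <- slope[seq_len(k)]
  }
  stopifnot(length(a) == k, length(b) == k,
            length(intercept) == k, length(slope) == k)
  structure(list(k = k, n_otus = n_otus, alpha = alpha, a = a, b = b,
                 intercept = intercept, slope = slope),
            class = "synth_site_spec")
}

#' Configuration for the synthetic longitudinal cohort
#'
#' Emulates the study design: pre-term subjects sampled weekly from birth
#' until hospital discharge (PMA `discharge_pma`) and monthly thereafter
#' until PMA `followup_pma`; full-term subjects sampled monthly from birth
#' through `fullterm_weeks` weeks of life. Gestational ages at birth default
#' to uniform over 23-35.9 weeks (pre-term) and normal(39.6, 1.2) truncated
#' to \[37, 42\] (full-term). Per visit and site a latent CST is drawn from a
#' multinomial-logistic model along each CST's maturity index, with
#' probability `kappa` of copying the coupled source site's CST rank.
#'
#' @param n_preterm,n_fullterm subject counts (defaults 38 and 44).
#' @param ga_preterm_range,ga_fullterm_mean,ga_fullterm_sd gestational-age
#'   distribution parameters (weeks).
#' @param discharge_pma PMA at NICU discharge (weeks, default 38).
#' @param followup_pma last pre-term follow-up PMA (weeks, default 92, i.e.
#'   one year of corrected age).
#' @param fullterm_weeks full-term follow-up span in weeks of life (52).
#' @param sites named list of [synth_site_spec()] objects.
#' @param coupling data frame with columns `site`, `source`, `kappa`; each
#'   row makes `site` copy `source`'s CST rank with probability `kappa`.
#' @param library_meanlog,library_sdlog log-normal sequencing-depth
#'   parameters.
#' @param n_shared number of OTUs shared (same identity) across all sites.
#' @param shared_effect_sd standard deviation of the per-visit latent factor
#'   perturbing shared-OTU abundance identically in all sites (0 disables).
#' @param illness_prob per-visit probability of an illness flag.
#' @param seed integer RNG seed.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_preterm = 38, n_fullterm = 44,
                         ga_preterm_range = c(23, 35.9),
                         ga_fullterm_mean = 39.6, ga_fullterm_sd = 1.2,
                         discharge_pma = 38, followup_pma = 92,
                         fullterm_weeks = 52,
                         sites = list(gut = synth_site_spec(),
                                      nasal = synth_site_spec(),
                                      throat = synth_site_spec()),
                         coupling = data.frame(site = "throat",
                                               source = "nasal",
                                               kappa = 0.3),
                         library_meanlog = 8.5, library_sdlog = 0.5,
                         n_shared = 5, shared_effect_sd = 0.4,
                         illness_prob = 0.02, seed = 1L) {
  cfg <- list(n_preterm = n_preterm, n_fullterm = n_fullterm,
              ga_preterm_range = ga_preterm_range,
              ga_fullterm_mean = ga_fullterm_mean,
              ga_fullterm_sd = ga_fullterm_sd,
              discharge_pma = discharge_pma, followup_pma = followup_pma,
              fullterm_weeks = fullterm_weeks, sites = sites,
              coupling = coupling, library_meanlog = library_meanlog,
              library_sdlog = library_sdlog, n_shared = n_shared,
              shared_effect_sd = shared_effect_sd,
              illness_prob = illness_prob, seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$n_preterm < 1 || cfg$n_fullterm < 1)
    stop("cohort sizes must be >= 1")
  if (!length(cfg$sites) || is.null(names(cfg$sites)))
    stop("sites must be a named list of synth_site_spec")
  for (nm in names(cfg$sites)) {
    s <- cfg$sites[[nm]]
    if (!inherits(s, "synth_site_spec")) stop("invalid site spec: ", nm)
    if (any(s$alpha <= 0)) stop("non-positive alpha in site ", nm)
    if (s$k < 1) stop("k must be >= 1 in site ", nm)
  }
  if (nrow(cfg$coupling)) {
    if (any(cfg$coupling$kappa < 0 | cfg$coupling$kappa > 1))
      stop("kappa must lie in [0, 1]")
    bad <- setdiff(c(cfg$coupling$site, cfg$coupling$source), names(cfg$sites))
    if (length(bad)) stop("coupling refers to unknown site(s): ",
                          paste(bad, collapse = ", "))
    if (any(cfg$coupling$site == cfg$coupling$source))
      stop("a site cannot be coupled to itself")
  }
  if (cfg$ga_preterm_range[1] < 20 || cfg$ga_preterm_range[2] >= 37)
    stop("pre-term gestational ages must lie in [20, 37)")
  invisible(cfg)
}

#' Draw one sample's counts from a Dirichlet-multinomial emission
#'
#' Draws proportions from Dirichlet(`alpha`), optionally perturbs a subset
#' of OTUs by a multiplicative factor (the generator's shared latent
#' residual factor), renormalizes, and draws multinomial counts.
#'
#' @param alpha positive Dirichlet parameter vector of the emitting CST.
#' @param library_size total count (>= 1).
#' @param perturb_idx optional integer indices of OTUs to perturb.
#' @param perturb_factor multiplicative factor applied to `perturb_idx`.
#' @return Integer count vector summing to `library_size`.
#' @export
emit_counts <- function(alpha, library_size, perturb_idx = NULL,
                        perturb_factor = 1) {
  if (any(alpha <= 0)) stop("alpha must be positive")
  if (library_size < 1) stop("library_size must be >= 1")
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[] <- 1  # numerical underflow guard for tiny alpha
  p <- g / sum(g)
  if (length(perturb_idx)) {
    p[perturb_idx] <- p[perturb_idx] * perturb_factor
    p <- p / sum(p)
  }
  drop(stats::rmultinom(1, size = library_size, prob = p))
}

subject_schedule <- function(ga, term, cfg) {
  if (term == "pre") {
    weekly <- seq(0, max(0, ceiling(cfg$discharge_pma - ga)), by = 1)
    weekly <- weekly[ga + weekly < cfg$discharge_pma]
    if (!length(weekly)) weekly <- 0
    last <- max(weekly)
    monthly <- seq(last + 4, by = 4,
                   length.out = max(0, floor((cfg$followup_pma - ga - last) / 4)))
    sort(unique(c(weekly, monthly)))
  } else {
    seq(0, cfg$fullterm_weeks, by = 4)
  }
}

synth_taxonomy <- function(site, n_otus, n_shared) {
  ranks <- function(tag, j) {
    sprintf("Bacteria;Phylum_%s;Class_%s;Order_%s;Family_%s_%d;Genus_%s_%d;Species_%s_%d",
            tag, tag, tag, tag, ceiling(j / 10), tag, ceiling(j / 5), tag, j)
  }
  ids <- character(n_otus)
  lin <- character(n_otus)
  for (j in seq_len(n_otus)) {
    if (j <= n_shared) {
      ids[j] <- sprintf("OTU_shared_%03d", j)
      lin[j] <- ranks("shared", j)
    } else {
      ids[j] <- sprintf("OTU_%s_%03d", site, j)
      lin[j] <- ranks(site, j)
    }
  }
  stats::setNames(lin, ids)
}

#' Simulate a synthetic longitudinal multi-site cohort
#'
#' Generates subjects, visit schedules, latent per-site CST sequences, and
#' Dirichlet-multinomial OTU counts, with full ground truth for recovery
#' testing. Reproducible: the global RNG is seeded from `config$seed`.
#'
#' @param config a [synth_config()].
#' @return List with `subjects`, `samples` (one row per sample and site,
#'   `pma` populated), `counts` (named list of [counts_table()] per site)
#'   and `truth` (per-sample CST labels, per-CST index weights, coupling).
#' @export
simulate_cohort <- function(config) {
  validate_synth_config(config)
  set.seed(config$seed)
  cfg <- config
  n_pre <- cfg$n_preterm
  n_full <- cfg$n_fullterm
  ids <- c(sprintf("P%03d", seq_len(n_pre)), sprintf("F%03d", seq_len(n_full)))
  term <- rep(c("pre", "full"), c(n_pre, n_full))
  ga <- numeric(length(ids))
  ga[term == "pre"] <- stats::runif(n_pre, cfg$ga_preterm_range[1],
                                    cfg$ga_preterm_range[2])
  gf <- stats::rnorm(n_full, cfg$ga_fullterm_mean, cfg$ga_fullterm_sd)
  ga[term == "full"] <- pmin(pmax(gf, 37), 42)
  subjects <- data.frame(
    subject_id = ids, ga_birth = round(ga, 2), term_status = term,
    delivery_mode = sample(c("c-section", "vaginal"), length(ids), TRUE,
                           prob = c(0.55, 0.45)),
    birth_season = sample(c("winter", "spring", "summer", "fall"),
                          length(ids), TRUE),
    sex = sample(c("male", "female"), length(ids), TRUE, prob = c(0.58, 0.42)),
    ethnicity = sample(c("hispanic", "non-hispanic", "unknown"),
                       length(ids), TRUE, prob = c(0.15, 0.80, 0.05)),
    stringsAsFactors = FALSE)

  site_names <- names(cfg$sites)
  # order sites so coupling sources are drawn before their dependents
  ord <- site_names
  if (nrow(cfg$coupling))
    ord <- c(setdiff(site_names, cfg$coupling$site),
             cfg$coupling$site[cfg$coupling$source %in% site_names])
  ord <- unique(ord)

  samples <- list()
  counts <- stats::setNames(vector("list", length(site_names)), site_names)
  rows <- stats::setNames(vector("list", length(site_names)), site_names)
  labels <- list()

  for (i in seq_along(ids)) {
    wols <- subject_schedule(subjects$ga_birth[i], term[i], cfg)
    for (w in wols) {
      ill <- stats::runif(1) < cfg$illness_prob
      drawn <- list()
      for (st in ord) {
        sp <- cfg$sites[[st]]
        eta <- sp$intercept + sp$slope * (sp$a * w + sp$b * subjects$ga_birth[i])
        pr <- exp(eta - max(eta))
        cst <- sample.int(sp$k, 1, prob = pr / sum(pr))
        cp <- cfg$coupling[cfg$coupling$site == st, , drop = FALSE]
        if (nrow(cp) && !is.null(drawn[[cp$source[1]]]) &&
            stats::runif(1) < cp$kappa[1]) {
          cst <- min(drawn[[cp$source[1]]], sp$k)
        }
        drawn[[st]] <- cst
      }
      z <- stats::rnorm(1)  # shared latent residual factor for this visit
      for (st in site_names) {
        sp <- cfg$sites[[st]]
        cst <- drawn[[st]]
        lib <- max(50L, as.integer(round(stats::rlnorm(1, cfg$library_meanlog,
                                                       cfg$library_sdlog))))
        ns <- min(cfg$n_shared, sp$n_otus)
        cnt <- emit_counts(
          sp$alpha[cst, ], lib,
          perturb_idx = if (ns > 0 && cfg$shared_effect_sd > 0) seq_len(ns),
          perturb_factor = exp(cfg$shared_effect_sd * z))
        sid <- sprintf("%s.%s.w%03d", ids[i], st, as.integer(w))
        rows[[st]][[length(rows[[st]]) + 1]] <- stats::setNames(list(cnt), sid)
        samples[[length(samples) + 1]] <- data.frame(
          sample_id = sid, subject_id = ids[i], site = st,
          ga_birth = subjects$ga_birth[i], wol = w,
          pma = subjects$ga_birth[i] + w, illness_flag = ill,
          stringsAsFactors = FALSE)
        labels[[length(labels) + 1]] <- data.frame(
          sample_id = sid, subject_id = ids[i], site = st, wol = w,
          cst = cst, stringsAsFactors = FALSE)
      }
    }
  }

  for (st in site_names) {
    sp <- cfg$sites[[st]]
    m <- do.call(rbind, lapply(rows[[st]], function(r) r[[1]]))
    rownames(m) <- vapply(rows[[st]], function(r) names(r)[1], character(1))
    tax <- synth_taxonomy(st, sp$n_otus, min(cfg$n_shared, sp$n_otus))
    colnames(m) <- names(tax)
    counts[[st]] <- counts_table(m, taxonomy = tax)
  }

  truth_weights <- do.call(rbind, lapply(site_names, function(st) {
    sp <- cfg$sites[[st]]
    data.frame(site = st, cst = seq_len(sp$k), a = sp$a, b = sp$b,
               intercept = sp$intercept, slope = sp$slope,
               stringsAsFactors = FALSE)
  }))

  list(subjects = subjects,
       samples = do.call(rbind, samples),
       counts = counts,
       truth = list(labels = do.call(rbind, labels),
                    weights = truth_weights,
                    coupling = cfg$coupling,
                    config = cfg))
}
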