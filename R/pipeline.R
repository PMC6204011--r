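#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()], with any
#' supplied elements overriding the defaults. The default synthetic
#' benchmark uses a reduced cohort (10 pre-term + 12 full-term subjects,
#' three sites of 3 CSTs x 30 OTUs) and `k_max = 4` so that a complete run
#' finishes in a few minutes; `synth` accepts any [synth_config()]
#' arguments for full-scale cohorts.
#'
#' @param ... named overrides (e.g. `seed`, `k_max`, `synth = list(...)`).
#' @return Named list of pipeline parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    synth = list(n_preterm = 10, n_fullterm = 12),
    input = NULL,          # list(counts=, metadata=, taxonomy=) to use real data
    k_max = 4L, reps = 5L, frac = 0.8,
    target_depth = 5000L, min_prev = 0.05,
    spline_df = 14L, fdr = 0.05,
    taxon_models = TRUE,
    cca_folds = 10L, cca_components = 10L, cca_adjust_df = c(14L, 25L),
    grid_n = 61L)
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  for (i in seq_along(over)) cfg[[names(over)[i]]] <- over[[i]]  # later wins
  cfg
}

# Drop bespoke S3 classes so the manifest serializes as plain JSON.
strip_classes <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), strip_classes))
  x
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

pipeline_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf("[cstdyn] %s", sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes, per body site: illness exclusion, prevalence filtering, depth
#' normalization, evidence-based component selection, DMM fitting and CST
#' assignment; then the temporal suite (single-index fits, occurrence
#' tests, pattern classification and sequence summaries), the cross-site
#' suite (co-occurrence chi-squared, CST probability correlations, per-taxon
#' mixed-model associations with FDR roll-up, shared-OTU residual
#' correlations) and the CCA suite (subject-blocked cross-validated
#' canonical correlations, unadjusted and PMA-adjusted). All tables are
#' written as TSV with a JSON manifest of parameters, seeds and file
#' hashes; re-running with the same configuration reproduces byte-identical
#' outputs.
#'
#' @param config a [pipeline_config()] list or path to a YAML file of
#'   overrides.
#' @param outdir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir, quiet = FALSE) {
  if (is.character(config)) config <- pipeline_config(yaml::read_yaml(config))
  if (!all(c("seed", "k_max") %in% names(config)))
    config <- pipeline_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "cstdyn",
                   version = as.character(utils::packageVersion("cstdyn")),
                   config = strip_classes(config[setdiff(names(config), "input")]),
                   files = list(), notes = character(0))
  files <- character(0)
  note <- function(msg) {
    manifest$notes <<- c(manifest$notes, msg)
    pipeline_log(quiet, "note: %s", msg)
  }
  fail <- function(stage, err) {
    manifest$failure <- list(stage = stage, message = conditionMessage(err))
    manifest$files <- as.list(stats::setNames(
      unname(tools::md5sum(files)), basename(files)))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    stop("pipeline halted at stage '", stage, "': ",
         conditionMessage(err), call. = FALSE)
  }

  # ---- data ----
  pipeline_log(quiet, "stage data")
  dat <- tryCatch({
    if (!is.null(config$input)) {
      inp <- config$input
      loaded <- load_dataset(inp$counts, inp$metadata, inp$taxonomy)
      sites <- unique(loaded$samples$site)
      counts <- lapply(stats::setNames(sites, sites), function(st)
        loaded$counts[loaded$samples$sample_id[loaded$samples$site == st], ,
                      drop = FALSE])
      list(subjects = loaded$subjects, samples = loaded$samples,
           counts = counts, truth = NULL)
    } else {
      sc <- do.call(synth_config, c(config$synth,
                                    if (is.null(config$synth$seed))
                                      list(seed = config$seed)))
      simulate_cohort(sc)
    }
  }, error = function(e) fail("data", e))
  site_names <- names(dat$counts)
  files <- c(files,
             write_tsv(dat$subjects, file.path(outdir, "subjects.tsv")),
             write_tsv(dat$samples, file.path(outdir, "samples.tsv")))
  if (!is.null(dat$truth))
    files <- c(files, write_tsv(dat$truth$labels,
                                file.path(outdir, "truth_labels.tsv")))
  cohort <- summarize_cohort(dat$subjects, dat$samples)
  files <- c(files, write_tsv(cohort, file.path(outdir, "cohort_summary.tsv")))

  keep_ids <- dat$samples$sample_id[!dat$samples$illness_flag]
  samples_ok <- dat$samples[!dat$samples$illness_flag, , drop = FALSE]

  # ---- CST inference per site ----
  assignments <- list(); fits <- list(); chosen <- integer(0)
  for (st in site_names) {
    pipeline_log(quiet, "stage cst: %s", st)
    res <- tryCatch({
      ct <- dat$counts[[st]]
      ct <- ct[intersect(rownames(ct), keep_ids), , drop = FALSE]
      ct <- prevalence_filter(ct, min_prev = config$min_prev)
      ctn <- dmm_normalize(ct, target = config$target_depth)
      ks <- select_k(ctn, k_max = config$k_max, reps = config$reps,
                     frac = config$frac, seed = config$seed)
      fit <- dmm(ctn, ks$chosen_k, seed = config$seed)
      asg <- assign_cst(fit, ctn, site = st)
      list(ct = ctn, ks = ks, fit = fit, asg = asg)
    }, error = function(e) fail(paste0("cst:", st), e))
    chosen[st] <- res$ks$chosen_k
    fits[[st]] <- res
    assignments[[st]] <- res$asg
    files <- c(files, write_tsv(
      data.frame(rep = seq_len(nrow(res$ks$scores)), res$ks$scores,
                 check.names = FALSE),
      file.path(outdir, paste0("kselect_", st, ".tsv"))))
    files <- c(files, write_tsv(
      data.frame(sample_id = res$asg$sample_ids, site = st,
                 round(res$asg$posterior, 6), cst = res$asg$cst,
                 check.names = FALSE),
      file.path(outdir, paste0("cst_assignments_", st, ".tsv"))))
    fit_json <- file.path(outdir, paste0("dmm_fit_", st, ".json"))
    jsonlite::write_json(list(k = res$fit$k, pi = res$fit$pi,
                              alpha = res$fit$alpha,
                              loglik = res$fit$loglik,
                              n_iter = res$fit$n_iter,
                              converged = res$fit$converged),
                         fit_json, auto_unbox = TRUE, digits = 8)
    files <- c(files, fit_json)
  }

  # ---- temporal suite ----
  patterns <- list()
  for (st in site_names) {
    asg <- assignments[[st]]
    if (ncol(asg$posterior) < 2) {
      note(sprintf("site %s has a single CST: temporal stage skipped", st))
      next
    }
    pipeline_log(quiet, "stage temporal: %s", st)
    meta <- samples_ok[match(asg$sample_ids, samples_ok$sample_id), ]
    res <- tryCatch({
      out <- list()
      for (cst in seq_len(ncol(asg$posterior))) {
        sif <- single_index(asg$posterior[, cst], meta$wol, meta$ga_birth,
                            meta$subject_id, grid_n = config$grid_n)
        subj_occ <- tapply(asg$cst == cst, meta$subject_id, any)
        subj_gab <- tapply(meta$ga_birth, meta$subject_id, `[`, 1)
        olt <- occurrence_logistic_test(as.logical(subj_occ),
                                        as.numeric(subj_gab))
        pc <- classify_pattern(sif$a, sif$b, olt$p_value)
        pc <- cbind(data.frame(site = st, cst = cst), pc)
        out[[cst]] <- pc
      }
      do.call(rbind, out)
    }, error = function(e) fail(paste0("temporal:", st), e))
    patterns[[st]] <- res
    seq_sum <- sequence_index_summary(asg$cst, meta)
    files <- c(files, write_tsv(seq_sum,
               file.path(outdir, paste0("sequence_summary_", st, ".tsv"))))
  }
  if (length(patterns))
    files <- c(files, write_tsv(do.call(rbind, c(patterns,
                                                 make.row.names = FALSE)),
                                file.path(outdir, "pattern_table.tsv")))

  # ---- cross-site suite ----
  pairs_of_sites <- if (length(site_names) >= 2)
    utils::combn(site_names, 2, simplify = FALSE) else list()
  for (pr in pairs_of_sites) {
    a <- pr[1]; b <- pr[2]
    pipeline_log(quiet, "stage crosssite: %s-%s", a, b)
    vp <- pair_visits(samples_ok, a, b)
    if (!nrow(vp)) { note(sprintf("no paired visits for %s-%s", a, b)); next }
    la <- assignments[[a]]$cst[match(vp$sample_a, assignments[[a]]$sample_ids)]
    lb <- assignments[[b]]$cst[match(vp$sample_b, assignments[[b]]$sample_ids)]
    keep <- !is.na(la) & !is.na(lb)
    vp <- vp[keep, ]; la <- la[keep]; lb <- lb[keep]
    if (length(unique(la)) >= 2 && length(unique(lb)) >= 2) {
      cx <- cooccurrence_chisq(la, lb)
      files <- c(files, write_tsv(
        data.frame(site_a = a, site_b = b, statistic = cx$statistic,
                   p_value = cx$p_value, n_pairs = nrow(vp)),
        file.path(outdir, paste0("cooccurrence_", a, "_", b, ".tsv"))))
    } else {
      note(sprintf("degenerate CST table for %s-%s: chi-squared skipped", a, b))
    }
    pa <- assignments[[a]]$posterior[match(vp$sample_a,
                                           assignments[[a]]$sample_ids), ,
                                     drop = FALSE]
    pb <- assignments[[b]]$posterior[match(vp$sample_b,
                                           assignments[[b]]$sample_ids), ,
                                     drop = FALSE]
    if (nrow(vp) >= 3) {
      cm <- cst_probability_correlation(pa, pb)
      files <- c(files, write_tsv(
        data.frame(cst_a = rownames(cm), round(cm, 6), check.names = FALSE),
        file.path(outdir, paste0("cst_correlation_", a, "_", b, ".tsv"))))
    }
    # shared-OTU residual correlations on raw relative abundances
    cta <- fits[[a]]$ct; ctb <- fits[[b]]$ct
    shared <- intersect(colnames(cta), colnames(ctb))
    if (length(shared) && nrow(vp) >= 20) {
      ra <- sweep(unclass(cta)[vp$sample_a, shared, drop = FALSE], 1,
                  rowSums(cta[vp$sample_a, , drop = FALSE]), "/")
      rb <- sweep(unclass(ctb)[vp$sample_b, shared, drop = FALSE], 1,
                  rowSums(ctb[vp$sample_b, , drop = FALSE]), "/")
      sc <- tryCatch(shared_otu_residual_corr(asin(sqrt(ra)), asin(sqrt(rb)),
                                              vp$pma, vp$subject_id),
                     error = function(e) NULL)
      if (!is.null(sc) && nrow(sc))
        files <- c(files, write_tsv(
          cbind(site_a = a, site_b = b, sc),
          file.path(outdir, paste0("shared_otu_corr_", a, "_", b, ".tsv"))))
    }
  }

  # ---- taxon association models ----
  if (isTRUE(config$taxon_models) && length(site_names) >= 2) {
    assoc_all <- list()
    for (st in site_names) {
      remotes <- setdiff(site_names, st)
      pipeline_log(quiet, "stage taxa: outcome %s", st)
      res <- tryCatch(
        taxon_association_suite(st, remotes, samples_ok, fits, assignments,
                                dat$subjects, config),
        error = function(e) fail(paste0("taxa:", st), e))
      if (!is.null(res)) assoc_all[[st]] <- res
    }
    if (length(assoc_all)) {
      assoc <- do.call(rbind, c(assoc_all, make.row.names = FALSE))
      files <- c(files, write_tsv(assoc,
                                  file.path(outdir, "taxon_associations.tsv")))
      sig <- do.call(rbind, c(lapply(assoc_all, fdr_and_rollup,
                                     fdr = config$fdr),
                              make.row.names = FALSE))
      files <- c(files, write_tsv(sig,
                 file.path(outdir, "taxon_associations_significant.tsv")))
    }
  }

  # ---- CCA suite ----
  for (pr in pairs_of_sites) {
    a <- pr[1]; b <- pr[2]
    pipeline_log(quiet, "stage cca: %s-%s", a, b)
    vp <- pair_visits(samples_ok, a, b)
    if (nrow(vp) < 3 * config$cca_folds) {
      note(sprintf("too few pairs for CCA %s-%s", a, b))
      next
    }
    res <- tryCatch({
      xa <- css_normalize(fits[[a]]$ct[vp$sample_a, , drop = FALSE])
      yb <- css_normalize(fits[[b]]$ct[vp$sample_b, , drop = FALSE])
      rows <- list()
      for (adj in c(0, config$cca_adjust_df)) {
        xu <- if (adj > 0) regress_out_time(xa, vp$pma, df = adj) else xa
        yu <- if (adj > 0) regress_out_time(yb, vp$pma, df = adj) else yb
        cv <- suppressWarnings(
          blocked_cv_cca(xu, yu, vp$subject_id, folds = config$cca_folds,
                         n_components = config$cca_components,
                         seed = config$seed))
        k <- sum(!is.na(cv$heldout_mean))
        rows[[length(rows) + 1]] <- data.frame(
          pair = paste(a, b, sep = "-"), component = seq_len(k),
          adjustment = if (adj == 0) "none" else paste0("pma_ns", adj),
          train_corr = round(cv$train_mean[seq_len(k)], 6),
          heldout_mean = round(cv$heldout_mean[seq_len(k)], 6),
          heldout_2sem = round(cv$heldout_2sem[seq_len(k)], 6))
      }
      do.call(rbind, rows)
    }, error = function(e) fail(paste0("cca:", a, "-", b), e))
    files <- c(files, write_tsv(res,
               file.path(outdir, paste0("cca_", a, "_", b, ".tsv"))))
  }

  manifest$chosen_k <- as.list(chosen)
  manifest$files <- as.list(stats::setNames(
    unname(tools::md5sum(files)), basename(files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  pipeline_log(quiet, "done: %d output files", length(files) + 1)
  invisible(manifest)
}

# Fit the per-taxon mixed models for one outcome site against the CSTs of
# the remote sites observed at the same visits. Returns a long data frame
# (one row per taxon x remote site) or NULL when too few matched visits.
taxon_association_suite <- function(outcome, remotes, samples_ok, fits,
                                    assignments, subjects, config) {
  vp <- pair_visits(samples_ok, outcome, remotes[1])
  names(vp)[names(vp) == "sample_b"] <- paste0("sample_", remotes[1])
  if (length(remotes) > 1) {
    for (r in remotes[-1]) {
      vr <- pair_visits(samples_ok, outcome, r)
      names(vr)[names(vr) == "sample_b"] <- paste0("sample_", r)
      vp <- merge(vp, vr[, c("subject_id", "wol", paste0("sample_", r))],
                  by = c("subject_id", "wol"))
    }
  }
  if (nrow(vp) < 20) return(NULL)
  vp <- vp[order(vp$subject_id, vp$wol), , drop = FALSE]
  ta <- taxon_abundances(fits[[outcome]]$ct[vp$sample_a, , drop = FALSE])
  remote_cst <- lapply(stats::setNames(remotes, paste0("cst_", remotes)),
                       function(r) {
    asg <- assignments[[r]]
    factor(asg$cst[match(vp[[paste0("sample_", r)]], asg$sample_ids)])
  })
  remote_cst <- remote_cst[vapply(remote_cst, nlevels, 1L) >= 2]
  if (!length(remote_cst)) return(NULL)
  covar <- data.frame(
    delivery_mode = subjects$delivery_mode[match(vp$subject_id,
                                                 subjects$subject_id)],
    gab = subjects$ga_birth[match(vp$subject_id, subjects$subject_id)],
    birth_season = subjects$birth_season[match(vp$subject_id,
                                               subjects$subject_id)],
    wol = vp$wol)
  rows <- list()
  for (j in seq_len(ncol(ta$abund))) {
    ab <- pmin(ta$abund[, j], 1)
    if (stats::sd(ab) == 0) next
    rec <- tryCatch(
      fit_taxon_models(ab, remote_cst, covar, vp$subject_id,
                       spline_df = config$spline_df),
      error = function(e) NULL)
    if (is.null(rec)) next
    for (nm in names(rec$f_tests)) {
      rows[[length(rows) + 1]] <- data.frame(
        outcome_site = outcome, taxon = ta$lineage[j],
        remote_site = sub("^cst_", "", nm),
        f_statistic = rec$f_tests[[nm]]$statistic,
        p_value = rec$f_tests[[nm]]$p_value,
        delta_pseudo_r2 = rec$delta_pseudo_r2,
        converged = rec$converged, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}
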