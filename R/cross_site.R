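#' Pair samples from two body sites taken at the same visit
#'
#' One pair per (subject, visit) where both sites were sampled; visits are
#' matched on week of life. Illness-flagged samples are excluded; unmatched
#' samples are dropped.
#'
#' @param samples data frame of visit samples (`sample_id`, `subject_id`,
#'   `site`, `wol`, `pma`, `illness_flag`).
#' @param site_a,site_b the two sites.
#' @return Data frame with `subject_id`, `wol`, `pma`, `sample_a`,
#'   `sample_b`.
#' @export
pair_visits <- function(samples, site_a, site_b) {
  if (!all(c(site_a, site_b) %in% samples$site))
    stop("both sites must be present in the data")
  ok <- !samples$illness_flag
  sa <- samples[ok & samples$site == site_a, , drop = FALSE]
  sb <- samples[ok & samples$site == site_b, , drop = FALSE]
  m <- merge(sa[, c("subject_id", "wol", "pma", "sample_id")],
             sb[, c("subject_id", "wol", "sample_id")],
             by = c("subject_id", "wol"), suffixes = c("_a", "_b"))
  m <- m[order(m$subject_id, m$wol), , drop = FALSE]
  out <- data.frame(subject_id = m$subject_id, wol = m$wol, pma = m$pma,
                    sample_a = m$sample_id_a, sample_b = m$sample_id_b,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Chi-squared test of cross-site CST co-occurrence
#'
#' Pearson chi-squared (no continuity correction) on the contingency table
#' of paired MAP CST labels. When any expected cell count is below 5 and
#' `simulate = "auto"`, a Monte-Carlo p-value is used instead.
#'
#' @param labels_a,labels_b CST labels of the paired samples.
#' @param simulate `"auto"` (default), `"never"` or `"always"`.
#' @param B Monte-Carlo replicates (default 2000).
#' @return List with `statistic`, `p_value`, `table`, `expected`,
#'   `simulated`.
#' @export
cooccurrence_chisq <- function(labels_a, labels_b,
                               simulate = c("auto", "never", "always"),
                               B = 2000) {
  simulate <- match.arg(simulate)
  stopifnot(length(labels_a) == length(labels_b))
  tab <- table(labels_a, labels_b)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need at least 2 distinct CST labels on each side")
  plain <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  use_mc <- simulate == "always" ||
    (simulate == "auto" && any(plain$expected < 5))
  res <- if (use_mc) {
    suppressWarnings(stats::chisq.test(tab, correct = FALSE,
                                       simulate.p.value = TRUE, B = B))
  } else plain
  list(statistic = unname(res$statistic), p_value = res$p.value,
       table = tab, expected = plain$expected, simulated = use_mc)
}

#' Cross-site correlation of CST membership probabilities
#'
#' Entry (i, j) is the Pearson correlation between site-a CST-i membership
#' probability and site-b CST-j membership probability across paired
#' samples. Zero-variance columns give NA entries.
#'
#' @param posterior_a,posterior_b paired posterior matrices (rows aligned).
#' @return Ka x Kb correlation matrix.
#' @export
cst_probability_correlation <- function(posterior_a, posterior_b) {
  stopifnot(nrow(posterior_a) == nrow(posterior_b), nrow(posterior_a) >= 3)
  va <- apply(posterior_a, 2, stats::sd)
  vb <- apply(posterior_b, 2, stats::sd)
  out <- suppressWarnings(stats::cor(posterior_a, posterior_b))
  out[va == 0, ] <- NA_real_
  out[, vb == 0] <- NA_real_
  out
}

# Wald F test of a coefficient block from a fitted lmer model:
# F = b' V^{-1} b / q with residual-based denominator df.
wald_f_block <- function(fit, idx) {
  b <- lme4::fixef(fit)[idx]
  V <- as.matrix(stats::vcov(fit))[idx, idx, drop = FALSE]
  q <- length(idx)
  Fstat <- drop(crossprod(b, solve(V, b))) / q
  n <- stats::nobs(fit)
  df2 <- n - length(lme4::fixef(fit))
  list(statistic = Fstat, df1 = q, df2 = df2,
       p_value = stats::pf(Fstat, q, df2, lower.tail = FALSE))
}

marginal_r2 <- function(fit) {
  X <- lme4::getME(fit, "X")
  var_fixed <- stats::var(drop(X %*% lme4::fixef(fit)))
  vc <- lme4::VarCorr(fit)
  var_rand <- sum(vapply(vc, function(v) sum(diag(v)), numeric(1)))
  var_res <- attr(vc, "sc")^2
  var_fixed / (var_fixed + var_rand + var_res)
}

# Per-level deviation effects (level minus grand mean) with Wald tests,
# from a sum-to-zero coded factor. Returns one row per level.
deviation_wald <- function(fit, prefix, levels) {
  fe <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  idx <- grep(paste0("^", prefix), names(fe))
  K <- length(levels)
  if (length(idx) != K - 1) {  # aliased levels dropped by the fit
    return(data.frame(level = levels, estimate = NA_real_, se = NA_real_,
                      p_value = NA_real_, direction = NA_character_,
                      stringsAsFactors = FALSE))
  }
  n <- stats::nobs(fit)
  df2 <- n - length(fe)
  res <- vector("list", K)
  for (i in seq_len(K)) {
    cvec <- numeric(length(fe))
    if (i < K) cvec[idx[i]] <- 1 else cvec[idx] <- -1
    est <- sum(cvec * fe)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tval <- est / se
    res[[i]] <- data.frame(
      level = levels[i], estimate = est, se = se,
      p_value = 2 * stats::pt(-abs(tval), df2),
      direction = ifelse(est > 0, "increase", "decrease"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Mixed-model association of a taxon with remote-site CSTs
#'
#' Fits, by maximum likelihood, a linear mixed model of the arcsine-sqrt
#' transformed relative abundance of one taxon at the outcome site on the
#' CSTs of the other site(s) (sum-to-zero coded, so coefficients are
#' level-minus-grand-mean deviations), adjusting for delivery mode,
#' gestational age at birth, birth season and a natural spline of week of
#' life, with a subject random intercept. Reports per-CST Wald deviation
#' tests, a Wald-F test per remote site of dropping that site's CST block,
#' and the change in marginal (fixed-effects) pseudo-R2 relative to the
#' null model without any CST terms.
#'
#' @param abund relative abundance of the taxon per visit pair (in
#'   \[0, 1\]); transformed internally.
#' @param remote_cst named list of one or two factors of remote-site CST
#'   labels (one per remote site).
#' @param covariates data frame with `delivery_mode`, `gab`, `birth_season`,
#'   `wol`.
#' @param subject subject identifier per pair.
#' @param spline_df natural-spline degrees of freedom for WOL (default 14).
#' @param compute_delta_r2 fit the null model to obtain the pseudo-R2
#'   change (default TRUE; skip for large calibration runs).
#' @return An `association_record` list: per-site `f_tests`, per-CST
#'   `wald`, `delta_pseudo_r2`, `converged`.
#' @export
fit_taxon_models <- function(abund, remote_cst, covariates, subject,
                             spline_df = 14, compute_delta_r2 = TRUE) {
  stopifnot(is.list(remote_cst))
  n <- length(abund)
  if (n < 20) stop("need at least 20 visit pairs")
  y <- arcsine_sqrt(abund)
  dat <- data.frame(y = y,
                    delivery_mode = factor(covariates$delivery_mode),
                    gab = covariates$gab,
                    birth_season = factor(covariates$birth_season),
                    wol = covariates$wol,
                    subject = factor(subject))
  cst_names <- names(remote_cst)
  for (nm in cst_names) {
    f <- factor(remote_cst[[nm]])
    if (nlevels(f) < 2) stop("remote CSTs must have >= 2 levels present: ", nm)
    stats::contrasts(f) <- stats::contr.sum(nlevels(f))
    dat[[nm]] <- f
  }
  covar_terms <- c(
    if (nlevels(dat$delivery_mode) > 1) "delivery_mode",
    "gab",
    if (nlevels(dat$birth_season) > 1) "birth_season",
    sprintf("splines::ns(wol, df = %d)", spline_df))
  full_rhs <- paste(c(cst_names, covar_terms), collapse = " + ")
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  full <- suppressMessages(suppressWarnings(
    lme4::lmer(stats::as.formula(paste("y ~", full_rhs, "+ (1 | subject)")),
               data = dat, REML = FALSE, control = ctrl)))
  converged <- is.null(full@optinfo$conv$lme4$messages)

  fe_names <- names(lme4::fixef(full))
  f_tests <- list()
  wald <- list()
  for (nm in cst_names) {
    idx <- grep(paste0("^", nm), fe_names)
    f_tests[[nm]] <- wald_f_block(full, idx)
    w <- deviation_wald(full, nm, levels(dat[[nm]]))
    w$remote_site <- nm
    wald[[nm]] <- w
  }
  delta_r2 <- NA_real_
  if (compute_delta_r2) {
    null <- suppressMessages(suppressWarnings(
      lme4::lmer(stats::as.formula(
        paste("y ~", paste(covar_terms, collapse = " + "), "+ (1 | subject)")),
        data = dat, REML = FALSE, control = ctrl)))
    delta_r2 <- marginal_r2(full) - marginal_r2(null)
  }
  structure(list(f_tests = f_tests, wald = do.call(rbind, wald),
                 delta_pseudo_r2 = delta_r2, converged = converged,
                 n = n, fit = full),
            class = "association_record")
}

#' @exportS3Method base::print
print.association_record <- function(x, ...) {
  cat(sprintf("Taxon association record (n = %d pairs%s)\n", x$n,
              if (x$converged) "" else ", convergence flagged"))
  for (nm in names(x$f_tests)) {
    ft <- x$f_tests[[nm]]
    cat(sprintf("  %s: F(%d, %d) = %.2f, p = %.3g\n",
                nm, ft$df1, ft$df2, ft$statistic, ft$p_value))
  }
  cat(sprintf("  delta pseudo-R2 = %s\n", format(x$delta_pseudo_r2, digits = 3)))
  invisible(x)
}

#' Abundances of every taxonomic rank
#'
#' Sums OTU counts up each lineage, producing one row of relative
#' abundances per distinct lineage prefix (all ranks, most specific last).
#'
#' @param ct a [counts_table()] with taxonomy.
#' @return List with `abund` (samples x taxa relative abundances) and
#'   `lineage` (character vector of full lineage prefixes per column).
#' @export
taxon_abundances <- function(ct) {
  tax <- taxonomy(ct)
  if (is.null(tax)) stop("counts table has no taxonomy")
  rs <- rowSums(ct)
  prefixes <- unique(unlist(lapply(strsplit(tax, ";", fixed = TRUE),
                                   function(r) vapply(seq_along(r), function(i)
                                     paste(r[seq_len(i)], collapse = ";"),
                                     character(1)))))
  abund <- matrix(0, nrow(ct), length(prefixes),
                  dimnames = list(rownames(ct), prefixes))
  for (j in seq_along(prefixes)) {
    hit <- startsWith(paste0(tax, ";"), paste0(prefixes[j], ";"))
    abund[, j] <- rowSums(ct[, hit, drop = FALSE]) / rs
  }
  list(abund = abund, lineage = prefixes)
}

#' Benjamini-Hochberg control and most-specific-taxon roll-up
#'
#' Adjusts the F-test p-values of one outcome site across taxa (and remote
#' sites) by Benjamini-Hochberg, keeps records with q <= `fdr`, and within
#' each phylogenetic lineage reports only the most specific significant
#' taxa: an ancestor lineage is dropped when a strictly more specific
#' significant descendant exists.
#'
#' @param records data frame with columns `taxon` (full lineage string),
#'   `remote_site`, `p_value` and any additional columns to carry through.
#' @param fdr FDR level (default 0.05).
#' @return The significant records with a `q_value` column, rolled up.
#' @export
fdr_and_rollup <- function(records, fdr = 0.05) {
  if (!nrow(records)) {
    records$q_value <- numeric(0)
    return(records)
  }
  records$q_value <- stats::p.adjust(records$p_value, method = "BH")
  sig <- records[records$q_value <= fdr, , drop = FALSE]
  if (!nrow(sig)) return(sig)
  taxa <- unique(sig$taxon)
  is_ancestor <- vapply(taxa, function(tx)
    any(startsWith(setdiff(taxa, tx), paste0(tx, ";"))), logical(1))
  out <- sig[!sig$taxon %in% taxa[is_ancestor], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Residual correlation of OTUs shared between two sites
#'
#' For each OTU present in both sites, regresses its (transformed)
#' abundance on a natural spline of PMA with a subject random intercept in
#' each site, then correlates the paired residuals. OTUs constant in either
#' site are skipped.
#'
#' @param abund_a,abund_b paired abundance matrices (pairs x OTUs), columns
#'   named by OTU id.
#' @param pma post-menstrual age per pair (weeks).
#' @param subject subject identifier per pair.
#' @param spline_df spline degrees of freedom (default 10).
#' @return Data frame with `otu_id` and `correlation`.
#' @export
shared_otu_residual_corr <- function(abund_a, abund_b, pma, subject,
                                     spline_df = 10) {
  shared <- intersect(colnames(abund_a), colnames(abund_b))
  if (!length(shared)) stop("no OTU is present in both sites")
  subject <- factor(subject)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  resid_one <- function(y) {
    d <- data.frame(y = y, pma = pma, subject = subject)
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(y ~ splines::ns(pma, df = spline_df) + (1 | subject),
                 data = d, REML = FALSE, control = ctrl)))
    stats::residuals(fit)
  }
  out <- list()
  for (otu in shared) {
    ya <- abund_a[, otu]; yb <- abund_b[, otu]
    if (stats::sd(ya) == 0 || stats::sd(yb) == 0) next
    out[[otu]] <- data.frame(
      otu_id = otu,
      correlation = stats::cor(resid_one(ya), resid_one(yb)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(otu_id = character(0),
                                      correlation = numeric(0))
  rownames(res) <- NULL
  res
}
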