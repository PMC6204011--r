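#' Post-menstrual age
#'
#' PMA is gestational age at birth plus week of life, the study's proxy for
#' innate developmental maturity.
#'
#' @param ga_birth gestational age at birth in weeks, in \[20, 44\].
#' @param wol week of life (weeks since birth), >= 0.
#' @return `ga_birth + wol`, in weeks.
#' @examples
#' compute_pma(29, 10)  # 39
#' @export
compute_pma <- function(ga_birth, wol) {
  if (any(is.na(ga_birth)) || any(is.na(wol)))
    stop("ga_birth and wol must be non-missing")
  if (any(ga_birth < 20 | ga_birth > 44))
    stop("ga_birth outside [20, 44] weeks")
  if (any(wol < 0)) stop("wol must be >= 0")
  ga_birth + wol
}

#' Prevalence filter for one body site
#'
#' Keeps OTUs present (count > 0) in at least `min_prev` of the site's
#' samples; the threshold is inclusive. Samples are never dropped.
#'
#' @param ct a [counts_table()] restricted to one body site.
#' @param min_prev minimum prevalence fraction (default 0.05).
#' @return Filtered `counts_table`.
#' @export
prevalence_filter <- function(ct, min_prev = 0.05) {
  stopifnot(inherits(ct, "counts_table"))
  prev <- colMeans(ct > 0)
  keep <- prev >= min_prev - 1e-12
  if (!any(keep)) stop("no OTU passes the prevalence filter")
  ct[, keep, drop = FALSE]
}

#' Normalize counts to a fixed depth for mixture fitting
#'
#' Per sample, relative abundances are scaled to `target` and floored to
#' integers, so row sums lie in \[target - n_otus + 1, target\].
#'
#' @param ct a [counts_table()].
#' @param target integer depth (default 5000).
#' @return A `counts_table` of normalized integer counts.
#' @export
dmm_normalize <- function(ct, target = 5000L) {
  stopifnot(inherits(ct, "counts_table"))
  rs <- rowSums(ct)
  if (any(rs == 0)) {
    stop(sprintf("sample(s) with all-zero counts: %s",
                 paste(rownames(ct)[rs == 0], collapse = ", ")))
  }
  out <- floor(sweep(unclass(ct), 1, rs, "/") * target)
  counts_table(out, taxonomy = taxonomy(ct))
}

#' Arcsine square-root transform
#'
#' Variance-stabilizing transform for relative abundances.
#'
#' @param x fraction(s) in \[0, 1\].
#' @return `asin(sqrt(x))`, in \[0, pi/2\].
#' @export
arcsine_sqrt <- function(x) {
  if (any(is.na(x)) || any(x < 0) || any(x > 1))
    stop("input must lie in [0, 1]")
  asin(sqrt(x))
}

#' Cumulative-sum-scaling normalization
#'
#' Per sample, the scaling factor is the sum of counts at or below the chosen
#' quantile of that sample's nonzero count distribution; counts are divided
#' by the factor and rescaled by the median factor across samples.
#'
#' @param ct a [counts_table()].
#' @param quantile quantile of the per-sample nonzero count distribution
#'   (default 0.5).
#' @return Numeric matrix of normalized abundances (same dimnames).
#' @export
css_normalize <- function(ct, quantile = 0.5) {
  stopifnot(inherits(ct, "counts_table"), ncol(ct) >= 1, nrow(ct) >= 1)
  X <- unclass(ct)
  factors <- vapply(seq_len(nrow(X)), function(i) {
    xi <- X[i, ]
    nz <- xi[xi > 0]
    if (length(nz) == 0)
      stop(sprintf("sample '%s' has all-zero counts", rownames(X)[i]))
    q <- stats::quantile(nz, probs = quantile, names = FALSE, type = 7)
    sum(xi[xi <= q])
  }, numeric(1))
  out <- sweep(X, 1, factors, "/") * stats::median(factors)
  dimnames(out) <- dimnames(X)
  out
}

round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Cohort summary table
#'
#' Per term-status group: subject counts and percentages (one decimal,
#' rounded half-up) for each categorical covariate, with ethnicity
#' percentages computed over the known-ethnicity denominator, plus per-site
#' sample counts split into hospital and post-discharge periods.
#'
#' @param subjects data frame of subject records (`subject_id`, `ga_birth`,
#'   `term_status`, `delivery_mode`, `birth_season`, and optionally `sex`,
#'   `ethnicity`).
#' @param samples optional data frame of visit samples (`subject_id`, `site`,
#'   `wol`, `pma`); if supplied, per-site sample counts are appended.
#' @param discharge_pma PMA (weeks) separating hospital from post-discharge
#'   samples for pre-term subjects (default 38); full-term samples count as
#'   hospital only at birth (wol 0).
#' @return Long data frame with columns `group`, `variable`, `level`, `n`,
#'   `denominator`, `pct`.
#' @export
summarize_cohort <- function(subjects, samples = NULL, discharge_pma = 38) {
  stopifnot(nrow(subjects) >= 1)
  if (!"term_status" %in% names(subjects))
    subjects$term_status <- ifelse(subjects$ga_birth < 37, "pre", "full")
  rows <- list()
  add <- function(group, variable, level, n, denom) {
    pct <- if (denom > 0) round_half_up(100 * n / denom, 1) else 0
    rows[[length(rows) + 1]] <<- data.frame(
      group = group, variable = variable, level = level,
      n = n, denominator = denom, pct = pct, stringsAsFactors = FALSE)
  }
  for (grp in c("pre", "full")) {
    sub <- subjects[subjects$term_status == grp, , drop = FALSE]
    N <- nrow(sub)
    add(grp, "subjects", "n", N, N)
    for (v in intersect(c("sex", "delivery_mode", "birth_season"), names(subjects))) {
      levs <- sort(unique(as.character(subjects[[v]])))
      for (lv in levs) add(grp, v, lv, sum(sub[[v]] == lv), N)
    }
    if ("ethnicity" %in% names(subjects)) {
      known <- sub[sub$ethnicity != "unknown", , drop = FALSE]
      for (lv in setdiff(sort(unique(as.character(subjects$ethnicity))), "unknown"))
        add(grp, "ethnicity", lv, sum(known$ethnicity == lv), nrow(known))
    }
    if (!is.null(samples)) {
      ss <- merge(samples, sub[, c("subject_id", "ga_birth"), drop = FALSE],
                  by = "subject_id")
      if (nrow(ss)) {
        if (!"pma" %in% names(ss)) ss$pma <- ss$ga_birth + ss$wol
        hospital <- if (grp == "pre") ss$pma < discharge_pma else ss$wol == 0
        for (st in sort(unique(as.character(ss$site)))) {
          in_site <- ss$site == st
          add(grp, "samples_hospital", st, sum(in_site & hospital), sum(in_site))
          add(grp, "samples_postdischarge", st, sum(in_site & !hospital), sum(in_site))
        }
      }
    }
  }
  do.call(rbind, rows)
}

required_metadata_cols <- c("sample_id", "subject_id", "site", "ga_birth",
                            "wol", "delivery_mode", "birth_season", "illness_flag")

#' Load a count table and sample metadata
#'
#' Reads a TSV count table (first column `sample_id`, remaining columns OTU
#' counts), an optional taxonomy sidecar (TSV: `otu_id`, `lineage` with
#' semicolon-delimited ranks), and a TSV metadata table; validates the join
#' and derives PMA.
#'
#' @param counts_path path to the counts TSV (or a BIOM JSON file if
#'   `format = "biom"`).
#' @param metadata_path path to the metadata TSV; required columns:
#'   `sample_id`, `subject_id`, `site`, `ga_birth`, `wol`, `delivery_mode`,
#'   `birth_season`, `illness_flag`.
#' @param taxonomy_path optional taxonomy sidecar TSV.
#' @param format `"tsv"` (default) or `"biom"` (requires the biomformat
#'   package).
#' @return List with `counts` ([counts_table()]), `subjects` (one row per
#'   subject) and `samples` (one row per sample, `pma` populated,
#'   `illness_flag` logical).
#' @export
load_dataset <- function(counts_path, metadata_path, taxonomy_path = NULL,
                         format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(counts_path)) stop("counts file not found: ", counts_path)
  if (!file.exists(metadata_path)) stop("metadata file not found: ", metadata_path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("BIOM input requires the biomformat package")
    b <- biomformat::read_biom(counts_path)
    m <- t(as.matrix(biomformat::biom_data(b)))  # biom stores OTUs x samples
    counts <- m
  } else {
    tab <- utils::read.delim(counts_path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    counts <- as.matrix(tab[, -1, drop = FALSE])
    rownames(counts) <- as.character(tab[[1]])
  }
  tax <- NULL
  if (!is.null(taxonomy_path)) {
    tt <- utils::read.delim(taxonomy_path, stringsAsFactors = FALSE)
    tax <- stats::setNames(as.character(tt$lineage), as.character(tt$otu_id))
  }
  ct <- counts_table(counts, taxonomy = tax)

  md <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required_metadata_cols, names(md))
  if (length(missing_cols))
    stop("metadata missing required column(s): ", paste(missing_cols, collapse = ", "))
  absent <- setdiff(rownames(ct), md$sample_id)
  if (length(absent))
    stop("sample(s) in counts but not metadata: ", paste(absent, collapse = ", "))
  md <- md[match(rownames(ct), md$sample_id), , drop = FALSE]
  md$illness_flag <- as.logical(md$illness_flag)
  md$pma <- compute_pma(md$ga_birth, md$wol)

  subj_cols <- intersect(c("subject_id", "ga_birth", "delivery_mode",
                           "birth_season", "sex", "ethnicity"), names(md))
  subjects <- unique(md[, subj_cols, drop = FALSE])
  if (anyDuplicated(subjects$subject_id))
    stop("inconsistent subject-level covariates across samples")
  subjects$term_status <- ifelse(subjects$ga_birth < 37, "pre", "full")
  rownames(subjects) <- NULL
  samples <- md[, c("sample_id", "subject_id", "site", "ga_birth", "wol",
                    "pma", "illness_flag")]
  rownames(samples) <- NULL
  list(counts = ct, subjects = subjects, samples = samples)
}

#' Write a dataset in the package's TSV dialect
#'
#' Emits `counts.tsv` (sample_id + OTU columns), `metadata.tsv` and, when
#' taxonomy is present, `taxonomy.tsv`, with deterministic column order.
#'
#' @param counts a [counts_table()].
#' @param metadata sample metadata data frame (see [load_dataset()]).
#' @param dir output directory (created if needed).
#' @param prefix filename prefix (default "").
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(counts, metadata, dir, prefix = "") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cpath <- file.path(dir, paste0(prefix, "counts.tsv"))
  mpath <- file.path(dir, paste0(prefix, "metadata.tsv"))
  df <- data.frame(sample_id = rownames(counts), unclass(counts),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, cpath, sep = "\t", quote = FALSE, row.names = FALSE)
  md <- metadata[, intersect(c(required_metadata_cols, "pma", "sex", "ethnicity"),
                             names(metadata)), drop = FALSE]
  utils::write.table(md, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(cpath, mpath)
  tax <- taxonomy(counts)
  if (!is.null(tax)) {
    tpath <- file.path(dir, paste0(prefix, "taxonomy.tsv"))
    utils::write.table(data.frame(otu_id = names(tax), lineage = unname(tax),
                                  stringsAsFactors = FALSE),
                       tpath, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, tpath)
  }
  invisible(paths)
}
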