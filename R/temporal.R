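#' Smooth occurrence surface of one CST over maturity
#'
#' Models the probability of a sample belonging to one CST, on the linear
#' probability scale, as a penalized tensor-product smooth of week of life
#' and gestational age at birth plus a subject random intercept:
#' `P(CST) = f(WOL, gaBirth) + participant + error`, with smoothness chosen
#' by REML.
#'
#' @param p per-sample CST membership probability (posterior column).
#' @param wol week of life per sample (weeks).
#' @param gab gestational age at birth per sample (weeks).
#' @param subject subject identifier per sample.
#' @param k basis dimensions of the tensor product (default `c(10, 10)`,
#'   reduced automatically when the data cannot support them).
#' @return An `occurrence_surface` object wrapping the mgcv fit.
#' @export
fit_occurrence_surface <- function(p, wol, gab, subject, k = c(10, 10)) {
  stopifnot(length(p) == length(wol), length(wol) == length(gab),
            length(gab) == length(subject))
  if (length(p) < 30) stop("need at least 30 samples")
  if (length(unique(wol)) < 5) stop("need at least 5 distinct WOL values")
  dat <- data.frame(p = p, wol = wol, gab = gab,
                    subject = factor(subject))
  if (stats::sd(p) < 1e-12) {  # constant outcome: the flat surface is exact
    return(structure(list(gam = NULL, k = k, single_subject = TRUE,
                          constant = p[1]),
                     class = "occurrence_surface"))
  }
  k <- c(min(k[1], length(unique(wol))), min(k[2], length(unique(gab))))
  single_subject <- nlevels(dat$subject) < 2
  form <- if (single_subject) {
    p ~ te(wol, gab, k = k)
  } else {
    p ~ te(wol, gab, k = k) + s(subject, bs = "re")
  }
  g <- mgcv::gam(form, data = dat, method = "REML")
  structure(list(gam = g, k = k, single_subject = single_subject),
            class = "occurrence_surface")
}

#' Predict an occurrence surface on a grid
#'
#' Population-level predictions (random intercept excluded). Fitting is on
#' the linear probability scale; set `clip = TRUE` to clip reported values
#' to \[0, 1\].
#'
#' @param object an [fit_occurrence_surface()] result.
#' @param newdata data frame with `wol` and `gab`.
#' @param clip clip predictions to \[0, 1\] for reporting (default FALSE).
#' @param ... unused.
#' @export
predict.occurrence_surface <- function(object, newdata, clip = FALSE, ...) {
  if (!is.null(object$constant)) return(rep(object$constant, nrow(newdata)))
  nd <- newdata
  nd$subject <- factor(object$gam$model$subject[1])
  pr <- as.numeric(mgcv::predict.gam(
    object$gam, newdata = nd,
    exclude = if (!object$single_subject) "s(subject)" else NULL,
    newdata.guaranteed = TRUE))
  if (clip) pr <- pmin(pmax(pr, 0), 1)
  pr
}

#' @exportS3Method base::print
print.occurrence_surface <- function(x, ...) {
  cat("CST occurrence surface: te(wol, gab), k =",
      paste(x$k, collapse = " x "), "\n")
  print(summary(x$gam)$s.table)
  invisible(x)
}

si_criterion <- function(theta, dat, k_index, single_subject) {
  a <- cos(theta); b <- sin(theta)
  dat$index <- a * dat$wol + b * dat$gab
  ku <- min(k_index, length(unique(dat$index)))
  form <- if (single_subject) p ~ s(index, k = ku)
          else p ~ s(index, k = ku) + s(subject, bs = "re")
  g <- try(mgcv::gam(form, data = dat, method = "REML"), silent = TRUE)
  if (inherits(g, "try-error")) return(list(score = Inf, gam = NULL))
  list(score = as.numeric(g$gcv.ubre), gam = g)
}

#' Single-index model of CST occurrence
#'
#' Restricts the occurrence surface to a common "time" axis: the CST
#' probability is a smooth function of one learned index
#' `a * WOL + b * gaBirth` (plus a subject random intercept). The index is
#' normalized to `a^2 + b^2 = 1` with `a >= 0`; only the ratio `b/a`
#' matters. The angle `theta = atan2(b, a)` is profiled on a grid over
#' (-pi/2, pi/2) with the REML score of the 1-D penalized smooth as the
#' criterion, then refined by local optimization around the best grid cell
#' (the profile can be multimodal, hence grid first).
#'
#' `log2(b/a)` near 0 means prenatal and postnatal weeks contribute equally
#' (the index is PMA-like); strongly negative values mean occurrence tracks
#' week of life alone.
#'
#' @inheritParams fit_occurrence_surface
#' @param grid_n number of grid angles (default 61).
#' @param k_index basis dimension of the index smooth (default 10).
#' @param flat_tol criterion range below which the profile is declared flat
#'   and the ratio indeterminate (default 1e-6).
#' @return A `single_index` object: `a`, `b`, `theta`, `log2_ratio`,
#'   `criterion`, `profile` (grid), `gam` (fit at the optimum),
#'   `indeterminate`.
#' @export
single_index <- function(p, wol, gab, subject, grid_n = 61, k_index = 10,
                         flat_tol = 1e-6) {
  stopifnot(length(p) == length(wol), length(wol) == length(gab),
            length(gab) == length(subject))
  if (length(p) < 30) stop("need at least 30 samples")
  if (length(unique(wol)) < 5) stop("need at least 5 distinct WOL values")
  dat <- data.frame(p = p, wol = wol, gab = gab, subject = factor(subject))
  if (stats::sd(p) < 1e-12)
    stop("outcome is constant: the index is unidentifiable")
  single_subject <- nlevels(dat$subject) < 2
  eps <- pi / (2 * (grid_n + 1))
  grid <- seq(-pi / 2 + eps, pi / 2 - eps, length.out = grid_n)
  scores <- vapply(grid, function(th)
    si_criterion(th, dat, k_index, single_subject)$score, numeric(1))
  ib <- which.min(scores)
  lo <- grid[max(1, ib - 1)]; hi <- grid[min(grid_n, ib + 1)]
  opt <- stats::optimize(function(th)
    si_criterion(th, dat, k_index, single_subject)$score,
    interval = c(lo, hi))
  theta <- if (opt$objective < scores[ib]) opt$minimum else grid[ib]
  best <- si_criterion(theta, dat, k_index, single_subject)
  a <- cos(theta); b <- sin(theta)
  indeterminate <- (max(scores[is.finite(scores)]) -
                      min(scores[is.finite(scores)])) < flat_tol
  log2_ratio <- if (indeterminate) NA_real_
                else if (a > 0 && b > 0) log2(b / a)
                else if (a > 0) -Inf  # b <= 0: prenatal time does not advance the CST
                else Inf
  structure(list(a = a, b = b, theta = theta, log2_ratio = log2_ratio,
                 criterion = best$score, gam = best$gam,
                 profile = data.frame(theta = grid, score = scores),
                 indeterminate = indeterminate, k_index = k_index),
            class = "single_index")
}

#' @exportS3Method base::print
print.single_index <- function(x, ...) {
  cat(sprintf("Single-index fit: a = %.3f (WOL), b = %.3f (gaBirth), theta = %.1f deg\n",
              x$a, x$b, 180 * x$theta / pi))
  cat(sprintf("  log2(b/a) = %s%s, REML criterion %.4f\n",
              format(x$log2_ratio, digits = 3),
              if (x$indeterminate) " (indeterminate: flat profile)" else "",
              x$criterion))
  invisible(x)
}

#' @export
coef.single_index <- function(object, ...) {
  c(a = object$a, b = object$b)
}

#' @export
predict.single_index <- function(object, newdata, clip = FALSE, ...) {
  nd <- data.frame(index = object$a * newdata$wol + object$b * newdata$gab)
  nd$subject <- factor(object$gam$model$subject[1])
  has_re <- any(grepl("s(subject)", rownames(summary(object$gam)$s.table),
                      fixed = TRUE))
  pr <- as.numeric(mgcv::predict.gam(
    object$gam, newdata = nd,
    exclude = if (has_re) "s(subject)" else NULL,
    newdata.guaranteed = TRUE))
  if (clip) pr <- pmin(pmax(pr, 0), 1)
  pr
}

#' Logistic test of any-occurrence against gestational age at birth
#'
#' One observation per subject: did the CST ever occur. Returns the Wald
#' p-value for the gestational-age coefficient. Complete separation is
#' flagged and reported as p < 1e-6 (significant); no outcome variation
#' yields p = 1 by convention.
#'
#' @param occurred logical per subject.
#' @param gab gestational age at birth per subject (weeks).
#' @return List with `p_value`, `separation`, `degenerate`.
#' @export
occurrence_logistic_test <- function(occurred, gab) {
  stopifnot(length(occurred) == length(gab))
  occurred <- as.logical(occurred)
  if (all(occurred) || all(!occurred))
    return(list(p_value = 1, separation = FALSE, degenerate = TRUE))
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(occurred ~ gab, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  if (!sep && abs(co["gab", "Estimate"]) > 15) sep <- TRUE
  p <- if (sep) 1e-7 else co["gab", "Pr(>|z|)"]
  list(p_value = p, separation = sep, degenerate = FALSE)
}

#' Classify a CST's occurrence pattern
#'
#' Bins the log2 ratio of the single-index weights: `|log2(b/a)| < 1` is
#' *convergent* (prenatal and postnatal time trade off near one-to-one, a
#' PMA-like index); `log2(b/a) < -1` (including `b <= 0`) with a
#' non-significant gestational-age occurrence test is *chronological*
#' (driven by week of life alone); everything else is *idiosyncratic to
#' maturity at birth*.
#'
#' @param a,b single-index weights, `a >= 0`.
#' @param occurrence_p p-value from [occurrence_logistic_test()].
#' @param ratio_threshold log2-ratio bin half-width (default 1).
#' @param alpha significance level for the occurrence test (default 0.05).
#' @return A one-row data frame: `a`, `b`, `log2_ratio`, `occurrence_p`,
#'   `class`.
#' @export
classify_pattern <- function(a, b, occurrence_p, ratio_threshold = 1,
                             alpha = 0.05) {
  if (a < 0) stop("orientation convention requires a >= 0")
  if (a == 0 && b == 0) stop("no time dependence: a and b both zero")
  lr <- if (a > 0 && b > 0) log2(b / a) else if (a > 0) -Inf else Inf
  cls <- if (a > 0 && b > 0 && abs(lr) < ratio_threshold) {
    "convergent"
  } else if (a > 0 && (b <= 0 || lr < -ratio_threshold) &&
             occurrence_p >= alpha) {
    "chronological"
  } else {
    "idiosyncratic"
  }
  data.frame(a = a, b = b, log2_ratio = lr, occurrence_p = occurrence_p,
             class = cls, stringsAsFactors = FALSE)
}

#' Per-subject weekly CST sequences
#'
#' Quantizes each observation to the whole week of post-menstrual age
#' (rounded down) and fills the interval between consecutive observations
#' by splitting it at the midpoint, each half carrying its neighbor's CST
#' (weeks at or past the midpoint take the later CST). Weeks before the
#' first and after the last observation are absent from the output.
#'
#' @param labels integer CST label per sample.
#' @param samples data frame with `sample_id`, `subject_id`, `site`, `pma`
#'   aligned with `labels`.
#' @return Long data frame: `subject_id`, `site`, `pma_week`, `cst`.
#' @export
sequence_index_summary <- function(labels, samples) {
  stopifnot(length(labels) == nrow(samples))
  d <- data.frame(subject_id = samples$subject_id, site = samples$site,
                  week = floor(samples$pma), cst = labels,
                  ord = seq_along(labels), stringsAsFactors = FALSE)
  out <- list()
  for (key in unique(paste(d$subject_id, d$site, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    di <- d[d$subject_id == parts[1] & d$site == parts[2], , drop = FALSE]
    di <- di[order(di$week, di$ord), , drop = FALSE]
    if (anyDuplicated(di$week)) {
      warning(sprintf("duplicate week(s) for subject %s site %s: later sample wins",
                      parts[1], parts[2]))
      di <- di[!duplicated(di$week, fromLast = TRUE), , drop = FALSE]
    }
    weeks <- seq(min(di$week), max(di$week))
    cst <- integer(length(weeks))
    for (w_i in seq_along(weeks)) {
      w <- weeks[w_i]
      nxt <- which(di$week >= w)[1]
      if (di$week[nxt] == w || nxt == 1) {
        cst[w_i] <- di$cst[nxt]
      } else {
        midpoint <- (di$week[nxt - 1] + di$week[nxt]) / 2
        cst[w_i] <- if (w < midpoint) di$cst[nxt - 1] else di$cst[nxt]
      }
    }
    out[[key]] <- data.frame(subject_id = parts[1], site = parts[2],
                             pma_week = weeks, cst = cst,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
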