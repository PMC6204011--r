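#' Remove temporal structure from a feature matrix
#'
#' Replaces each feature by its residuals from a natural-spline regression
#' on post-menstrual age. Residuals are orthogonal to the spline basis;
#' constant features become identically zero.
#'
#' @param x samples x features numeric matrix.
#' @param pma post-menstrual age per sample (weeks).
#' @param df spline degrees of freedom (the analyses use 14 and 25).
#' @return Residual matrix of the same shape.
#' @export
regress_out_time <- function(x, pma, df = 14) {
  x <- as.matrix(x)
  if (df >= nrow(x)) stop("spline df must be smaller than the sample count")
  basis <- cbind(1, splines::ns(pma, df = df))
  qr_b <- qr(basis)
  res <- x - basis %*% qr.coef(qr_b, x)
  dimnames(res) <- dimnames(x)
  res
}

#' Cross-validated canonical correlations with subject-blocked folds
#'
#' Estimates canonical correlations between two paired feature matrices
#' (one per body site). Subjects are partitioned into folds (all of a
#' subject's visits stay together); canonical weights are estimated on the
#' training subjects via whitening and SVD, and held-out subspace
#' correlations are the Pearson correlations of the projected withheld
#' samples, reported as mean +/- 2 SEM across folds per component. When a
#' site has at least as many features as training samples (or a singular
#' covariance), a small ridge is added to the whitening step with a
#' warning.
#'
#' @param x,y paired matrices (rows aligned across sites).
#' @param subject subject identifier per row (blocks the folds).
#' @param folds number of folds (default 10).
#' @param n_components components to report (default 10, capped by the
#'   data).
#' @param ridge ridge fraction of the mean covariance diagonal used when
#'   regularization is needed (default 1e-3).
#' @param seed fold-assignment seed (default 1).
#' @return A `cca_cv` object: `heldout_mean`, `heldout_2sem`, `train_mean`,
#'   per-fold matrices, `n_components`, `ridge_used`.
#' @export
blocked_cv_cca <- function(x, y, subject, folds = 10, n_components = 10,
                           ridge = 1e-3, seed = 1L) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y), nrow(x) == length(subject))
  subj <- unique(as.character(subject))
  if (length(subj) < folds) stop("need at least as many subjects as folds")
  set.seed(as.integer(seed))
  fold_of <- sample(rep_len(seq_len(folds), length(subj)))
  names(fold_of) <- subj
  row_fold <- fold_of[as.character(subject)]

  ridge_used <- FALSE
  heldout <- matrix(NA_real_, folds, n_components)
  train <- matrix(NA_real_, folds, n_components)
  for (f in seq_len(folds)) {
    tr <- row_fold != f; te <- !tr
    if (sum(te) < 3 || sum(tr) < 4) next
    mx <- colMeans(x[tr, , drop = FALSE])
    my <- colMeans(y[tr, , drop = FALSE])
    Xc <- sweep(x[tr, , drop = FALSE], 2, mx)
    Yc <- sweep(y[tr, , drop = FALSE], 2, my)
    n_tr <- sum(tr)
    Sxx <- crossprod(Xc) / (n_tr - 1)
    Syy <- crossprod(Yc) / (n_tr - 1)
    Sxy <- crossprod(Xc, Yc) / (n_tr - 1)
    need_ridge <- ncol(x) >= n_tr || ncol(y) >= n_tr
    wx <- whiten_inv_sqrt(Sxx, if (need_ridge) ridge else 0)
    wy <- whiten_inv_sqrt(Syy, if (need_ridge) ridge else 0)
    if (is.null(wx) || is.null(wy)) {  # singular: retry with ridge
      wx <- whiten_inv_sqrt(Sxx, ridge)
      wy <- whiten_inv_sqrt(Syy, ridge)
      need_ridge <- TRUE
    }
    if (need_ridge && !ridge_used) {
      ridge_used <- TRUE
      warning("ridge-regularized whitening applied (p >= n or singular covariance)")
    }
    sv <- svd(wx %*% Sxy %*% wy)
    nc <- min(n_components, length(sv$d), n_tr - 1)
    A <- wx %*% sv$u[, seq_len(nc), drop = FALSE]
    B <- wy %*% sv$v[, seq_len(nc), drop = FALSE]
    train[f, seq_len(nc)] <- sv$d[seq_len(nc)]
    Xt <- sweep(x[te, , drop = FALSE], 2, mx) %*% A
    Yt <- sweep(y[te, , drop = FALSE], 2, my) %*% B
    for (cc in seq_len(nc)) {
      if (stats::sd(Xt[, cc]) > 0 && stats::sd(Yt[, cc]) > 0)
        heldout[f, cc] <- stats::cor(Xt[, cc], Yt[, cc])
    }
  }
  hm <- colMeans(heldout, na.rm = TRUE)
  n_ok <- colSums(!is.na(heldout))
  hsem <- apply(heldout, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(n_ok, 1))
  structure(list(heldout_mean = hm, heldout_2sem = 2 * hsem,
                 train_mean = colMeans(train, na.rm = TRUE),
                 heldout = heldout, train = train,
                 n_components = n_components, folds = folds,
                 ridge_used = ridge_used, fold_of = fold_of),
            class = "cca_cv")
}

whiten_inv_sqrt <- function(S, ridge) {
  p <- nrow(S)
  if (ridge > 0) S <- S + diag(ridge * mean(diag(S)), p)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) <= 1e-10 * max(e$values)) return(NULL)
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' @exportS3Method base::print
print.cca_cv <- function(x, ...) {
  cat(sprintf("Subject-blocked %d-fold CV canonical correlations%s\n",
              x$folds, if (x$ridge_used) " (ridge whitening)" else ""))
  k <- sum(!is.na(x$heldout_mean))
  tab <- data.frame(component = seq_len(k),
                    train = round(x$train_mean[seq_len(k)], 3),
                    heldout = round(x$heldout_mean[seq_len(k)], 3),
                    pm2sem = round(x$heldout_2sem[seq_len(k)], 3))
  print(tab, row.names = FALSE)
  invisible(x)
}
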