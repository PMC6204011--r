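#' Fit a Dirichlet-Multinomial mixture model
#'
#' Clusters normalized OTU count vectors into community state types (CSTs)
#' by maximum-likelihood EM on a K-component Dirichlet-multinomial mixture:
#' each component is a Dirichlet prior over multinomial proportions. The
#' E-step computes component responsibilities from log-sum-exp-stabilized
#' Dirichlet-multinomial log-likelihoods; the M-step updates mixture weights
#' by posterior means and the Dirichlet parameters by a fixed-point
#' iteration that cannot decrease the weighted likelihood, so the total
#' log-likelihood is non-decreasing across iterations.
#'
#' Components are initialized from k-means on relative abundances (centers
#' scaled to a concentration of 10); `n_restarts` randomized restarts are
#' run and the best likelihood kept.
#'
#' @param counts a [counts_table()] (or integer matrix) of normalized
#'   counts, every row sum positive; see [dmm_normalize()].
#' @param k number of Dirichlet components (>= 1, <= number of samples).
#' @param seed integer seed controlling initialization.
#' @param n_restarts randomized restarts (default 3).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter maximum EM iterations per restart (default 500).
#' @param inner_iter fixed-point passes per M-step (default 3).
#' @return An object of class `dmm`: `k`, `alpha` (OTUs x k), `pi`,
#'   `loglik`, `loglik_trace`, `n_iter`, `converged`, `monotone`.
#' @seealso [laplace_evidence()], [select_k()], [assign_cst()]
#' @export
dmm <- function(counts, k, seed = 1L, n_restarts = 3L, tol = 1e-6,
                max_iter = 500L, inner_iter = 3L) {
  X <- as.matrix(counts)
  if (any(X < 0)) stop("counts must be non-negative")
  storage.mode(X) <- "integer"
  n <- nrow(X)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k exceeds the number of samples")
  if (any(rowSums(X) == 0)) stop("every sample must have positive total count")

  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(as.integer(seed) + 1000L * (r - 1L))
    fit <- dmm_em_once(X, k, jitter = (r > 1), tol = tol,
                       max_iter = max_iter, inner_iter = inner_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best$otu_ids <- colnames(X)
  best$n_samples <- n
  best$call <- match.call()
  class(best) <- "dmm"
  best
}

dmm_em_once <- function(X, k, jitter, tol, max_iter, inner_iter) {
  n <- nrow(X); S <- ncol(X)
  ra <- X / rowSums(X)
  if (k == 1) {
    centers <- matrix(colMeans(ra), 1)
  } else {
    km <- tryCatch(stats::kmeans(ra, centers = k, nstart = 5, iter.max = 25),
                   error = function(e) NULL)
    centers <- if (is.null(km)) ra[sample.int(n, k), , drop = FALSE] else km$centers
  }
  alpha <- t(pmax(centers, 1e-4) * 10)  # S x k, concentration 10
  if (jitter) alpha <- alpha * exp(matrix(stats::rnorm(S * k, 0, 0.3), S, k))
  pi_k <- rep(1 / k, k)

  ll_prev <- -Inf
  trace <- numeric(0)
  monotone <- TRUE
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    L <- dm_logliks_cpp(X, alpha)
    Lp <- sweep(L, 2, log(pi_k), "+")
    m <- apply(Lp, 1, max)
    W <- exp(Lp - m)
    rs <- rowSums(W)
    ll <- sum(m + log(rs))
    r <- W / rs
    trace <- c(trace, ll)
    if (ll < ll_prev - 1e-8 * max(1, abs(ll_prev))) monotone <- FALSE
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * max(1, abs(ll_prev))) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_prev <- ll
    pi_k <- pmax(colMeans(r), 1e-10)
    pi_k <- pi_k / sum(pi_k)
    for (kk in seq_len(k))
      alpha[, kk] <- dm_alpha_update_cpp(X, r[, kk], alpha[, kk],
                                         inner_iter, 1e-8)
  }
  list(k = k, alpha = alpha, pi = pi_k, loglik = ll, loglik_trace = trace,
       n_iter = iter, converged = converged, monotone = monotone)
}

#' @exportS3Method base::print
print.dmm <- function(x, ...) {
  cat(sprintf("Dirichlet-multinomial mixture: k = %d, %d OTUs, n = %d\n",
              x$k, nrow(x$alpha), x$n_samples))
  cat(sprintf("  log-likelihood %.3f after %d EM iterations (%s)\n",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  cat("  mixture weights:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  invisible(x)
}

#' @exportS3Method base::summary
summary.dmm <- function(object, n_top = 5, ...) {
  print(object)
  means <- sweep(object$alpha, 2, colSums(object$alpha), "/")
  for (kk in seq_len(object$k)) {
    top <- order(means[, kk], decreasing = TRUE)[seq_len(min(n_top, nrow(means)))]
    cat(sprintf("  component %d top OTUs: %s\n", kk,
                paste(sprintf("%s (%.2f)", object$otu_ids[top], means[top, kk]),
                      collapse = ", ")))
  }
  invisible(object)
}

#' @export
coef.dmm <- function(object, ...) object$alpha

#' @export
logLik.dmm <- function(object, ...) {
  structure(object$loglik,
            df = object$k * nrow(object$alpha) + object$k - 1,
            class = "logLik")
}

#' Posterior component membership for (new) samples
#'
#' @param object a fitted [dmm()] model.
#' @param newdata counts over the same OTU universe as the fit.
#' @param ... unused.
#' @return n x k matrix of posterior probabilities (rows sum to 1).
#' @export
predict.dmm <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(colnames(X)) && !is.null(object$otu_ids)) {
    if (!identical(colnames(X), object$otu_ids)) {
      if (!setequal(colnames(X), object$otu_ids))
        stop("OTU universe of newdata does not match the fit")
      X <- X[, object$otu_ids, drop = FALSE]
    }
  } else if (ncol(X) != nrow(object$alpha)) {
    stop("OTU universe of newdata does not match the fit")
  }
  storage.mode(X) <- "integer"
  L <- dm_logliks_cpp(X, object$alpha)
  Lp <- sweep(L, 2, log(object$pi), "+")
  m <- apply(Lp, 1, max)
  W <- exp(Lp - m)
  post <- W / rowSums(W)
  rownames(post) <- rownames(X)
  colnames(post) <- paste0("comp", seq_len(object$k))
  post
}

#' Simulate samples from a fitted mixture
#'
#' @param object a fitted [dmm()] model.
#' @param nsim number of samples.
#' @param seed optional seed.
#' @param library_size total count per sample (scalar or vector).
#' @param ... unused.
#' @return List with `counts` (nsim x OTUs) and `component` labels.
#' @export
simulate.dmm <- function(object, nsim = 1, seed = NULL,
                         library_size = 5000, ...) {
  if (!is.null(seed)) set.seed(seed)
  lib <- rep_len(library_size, nsim)
  comp <- sample.int(object$k, nsim, replace = TRUE, prob = object$pi)
  counts <- t(vapply(seq_len(nsim), function(i)
    emit_counts(object$alpha[, comp[i]], lib[i]),
    numeric(nrow(object$alpha))))
  colnames(counts) <- object$otu_ids
  list(counts = counts, component = comp)
}

#' Laplace approximation to the negative log model evidence
#'
#' Scores a fitted mixture by the Laplace approximation at the
#' maximum-likelihood plug-in: `-loglik - (d/2) log(2*pi) + (1/2) log|H|`,
#' where `H` is the Hessian of the negative log-likelihood at the fitted
#' parameters and `d` the number of free parameters (`k` Dirichlet vectors
#' on the log scale plus `k - 1` mixture weights). The Dirichlet blocks are
#' responsibility-weighted diagonal-plus-rank-one matrices; the weight block
#' is the observed information of the mixture weights. A singular Hessian is
#' ridge-stabilized with a warning.
#'
#' @param fit a fitted [dmm()] model.
#' @param counts the counts the model was fitted on.
#' @return The negative log evidence (finite scalar); smaller is better.
#' @export
laplace_evidence <- function(fit, counts) {
  X <- as.matrix(counts)
  storage.mode(X) <- "integer"
  if (ncol(X) != nrow(fit$alpha))
    stop("counts do not match the fitted OTU universe")
  post <- predict(fit, X)
  logdet <- 0
  for (kk in seq_len(fit$k)) {
    a <- fit$alpha[, kk]
    tm <- dm_laplace_terms_cpp(X, post[, kk], a)
    # Hessian of the log-likelihood wrt log(alpha):
    #   H = c * a a' + diag(a^2 * d + a * g); we need logdet(-H)
    Hn <- -(tm$c * tcrossprod(a)) - diag(a^2 * tm$d + a * tm$g,
                                         nrow = length(a))
    logdet <- logdet + safe_logdet(Hn)
  }
  if (fit$k > 1) {
    p <- fit$pi
    K <- fit$k
    h <- sweep(post[, -K, drop = FALSE], 2, p[-K], "/") - post[, K] / p[K]
    Hn_pi <- crossprod(h)
    logdet <- logdet + safe_logdet(Hn_pi)
  }
  d <- fit$k * nrow(fit$alpha) + (fit$k - 1)
  -fit$loglik - (d / 2) * log(2 * pi) + 0.5 * logdet
}

safe_logdet <- function(M) {
  for (ridge in c(0, 10^seq(-8, 2))) {
    Mr <- M + diag(ridge * mean(abs(diag(M))), nrow(M))
    ch <- tryCatch(chol(Mr), error = function(e) NULL)
    if (!is.null(ch)) {
      if (ridge > 0)
        warning("singular Hessian: ridge-stabilized log-determinant")
      return(2 * sum(log(diag(ch))))
    }
  }
  stop("Hessian could not be stabilized")
}

#' Choose the number of mixture components by subsampled evidence
#'
#' For each of `reps` random subsamples of `frac` of the samples (without
#' replacement), fits mixtures with 1..`k_max` components and records the
#' Laplace negative log evidence. The default `"one_se"` rule picks the
#' smallest k whose mean score is within one standard error of the best
#' mean; `"min_minus_sem"` picks the k minimizing mean minus SEM.
#'
#' @param counts normalized counts (see [dmm_normalize()]).
#' @param k_max largest k considered (default 10).
#' @param reps number of subsamples (default 10).
#' @param frac subsample fraction (default 0.8).
#' @param seed integer seed.
#' @param rule selection rule (see above).
#' @param ... passed to [dmm()] (e.g. `n_restarts`, `max_iter`).
#' @return A `dmm_kselect` object: `scores` (reps x k), `mean`, `sem`,
#'   `chosen_k`.
#' @export
select_k <- function(counts, k_max = 10L, reps = 10L, frac = 0.8, seed = 1L,
                     rule = c("one_se", "min_minus_sem"),
                     n_restarts = 1L, ...) {
  rule <- match.arg(rule)
  X <- as.matrix(counts)
  n <- nrow(X)
  m <- floor(frac * n)
  if (m < k_max) stop("too few samples: frac * n must be >= k_max")
  scores <- matrix(NA_real_, reps, k_max,
                   dimnames = list(NULL, paste0("k", seq_len(k_max))))
  for (r in seq_len(reps)) {
    set.seed(as.integer(seed) + r)
    idx <- sample.int(n, m)
    Xs <- X[idx, , drop = FALSE]
    keep <- rowSums(Xs) > 0
    Xs <- Xs[keep, , drop = FALSE]
    for (k in seq_len(k_max)) {
      scores[r, k] <- tryCatch({
        fit <- dmm(Xs, k, seed = as.integer(seed) + 100L * r + k,
                   n_restarts = n_restarts, ...)
        laplace_evidence(fit, Xs)
      }, error = function(e) NA_real_)
    }
  }
  n_ok <- colSums(!is.na(scores))
  usable <- n_ok > reps / 2
  mu <- ifelse(usable, colMeans(scores, na.rm = TRUE), NA_real_)
  sem <- ifelse(usable,
                apply(scores, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(n_ok, 1)),
                NA_real_)
  ks <- which(usable)
  if (!length(ks)) stop("no k produced a usable score")
  kbest <- ks[which.min(mu[ks])]
  chosen <- if (rule == "one_se") {
    thresh <- mu[kbest] + sem[kbest]
    min(ks[mu[ks] <= thresh])
  } else {
    ks[which.min(mu[ks] - sem[ks])]
  }
  structure(list(scores = scores, mean = mu, sem = sem,
                 chosen_k = as.integer(chosen), rule = rule,
                 k_max = as.integer(k_max), reps = as.integer(reps),
                 frac = frac),
            class = "dmm_kselect")
}

#' @exportS3Method base::print
print.dmm_kselect <- function(x, ...) {
  cat(sprintf("Component selection over k = 1..%d (%d subsamples of %.0f%%)\n",
              x$k_max, x$reps, 100 * x$frac))
  tab <- rbind(mean = x$mean, sem = x$sem)
  print(round(tab, 2))
  cat(sprintf("chosen k = %d (%s rule)\n", x$chosen_k, x$rule))
  invisible(x)
}

#' Renumber CST labels by occurrence frequency
#'
#' CST 1 becomes the most frequent state; ties keep the original fit order.
#'
#' @param labels integer component labels (1..k).
#' @param k number of components (default `max(labels)`).
#' @return List with `labels` (canonical) and `perm` where
#'   `perm[old] = new`.
#' @export
relabel_by_frequency <- function(labels, k = max(labels)) {
  if (!length(labels)) stop("labels must be non-empty")
  counts <- tabulate(labels, nbins = k)
  ord <- order(-counts, seq_len(k))  # stable: ties keep fit order
  perm <- integer(k)
  perm[ord] <- seq_len(k)
  list(labels = perm[labels], perm = perm)
}

#' Assign samples to canonically numbered CSTs
#'
#' Computes posterior responsibilities under a fitted mixture, takes MAP
#' labels (ties toward the lowest component index) and renumbers components
#' so CST 1 is the most frequent.
#'
#' @param fit a fitted [dmm()] model.
#' @param counts counts over the fit's OTU universe.
#' @param site optional body-site tag carried into the output.
#' @return A `cst_assignment`: `posterior` (columns in canonical CST order),
#'   `cst` (canonical MAP labels), `canonical_map` (fit order -> CST
#'   number), `site`.
#' @export
assign_cst <- function(fit, counts, site = NULL) {
  post <- predict(fit, counts)
  map <- max.col(post, ties.method = "first")
  rel <- relabel_by_frequency(map, k = fit$k)
  ord <- order(rel$perm)  # columns of posterior in canonical order
  posterior <- post[, ord, drop = FALSE]
  colnames(posterior) <- paste0("CST", seq_len(fit$k))
  structure(list(posterior = posterior, cst = rel$labels,
                 canonical_map = rel$perm, site = site,
                 sample_ids = rownames(post)),
            class = "cst_assignment")
}

#' @exportS3Method base::print
print.cst_assignment <- function(x, ...) {
  cat(sprintf("CST assignment%s: %d samples, %d CSTs\n",
              if (is.null(x$site)) "" else paste0(" (", x$site, ")"),
              length(x$cst), ncol(x$posterior)))
  print(table(CST = x$cst))
  invisible(x)
}
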