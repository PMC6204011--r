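# Fixture builders shared across test files. Everything is generated in
# code; no data files are read.

# Counts drawn from a mixture of Dirichlet-multinomial components.
# alpha: k x S matrix; comp: component label per sample.
make_mixture_counts <- function(alpha, comp, depth = 5000, seed = 1) {
  set.seed(seed)
  X <- t(vapply(comp, function(k) emit_counts(alpha[k, ], depth),
                numeric(ncol(alpha))))
  rownames(X) <- sprintf("s%03d", seq_along(comp))
  colnames(X) <- sprintf("o%03d", seq_len(ncol(alpha)))
  counts_table(X)
}

# Well-separated block-structured components.
block_alpha <- function(k, S, hi = 15, lo = 0.2) {
  a <- matrix(lo, k, S)
  block <- floor(S / k)
  for (i in seq_len(k)) a[i, (i - 1) * block + seq_len(block)] <- hi
  a
}

# Direct single-component Dirichlet-multinomial log-likelihood, written
# independently of the package internals (oracle for K = 1 fits).
dm_loglik_direct <- function(X, alpha) {
  A <- sum(alpha)
  sum(apply(X, 1, function(x)
    lgamma(A) - lgamma(A + sum(x)) + sum(lgamma(alpha + x) - lgamma(alpha))))
}

# Adjusted Rand index between two labelings (closed form).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# A small on-disk dataset in the package's TSV dialect.
write_toy_dataset <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  counts <- data.frame(sample_id = c("a1", "a2", "a3"),
                       OTU1 = c(5L, 0L, 2L), OTU2 = c(1L, 3L, 4L))
  write.table(counts, file.path(dir, "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  md <- data.frame(sample_id = c("a1", "a2", "a3"),
                   subject_id = c("P1", "P1", "F1"),
                   site = "gut", ga_birth = c(29, 29, 39.61),
                   wol = c(0, 10, 0),
                   delivery_mode = c("c-section", "c-section", "vaginal"),
                   birth_season = c("winter", "winter", "fall"),
                   illness_flag = c(FALSE, FALSE, TRUE))
  write.table(md, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tax <- data.frame(otu_id = c("OTU1", "OTU2"),
                    lineage = c("Bacteria;Firmicutes;Bacilli",
                                "Bacteria;Bacteroidetes"))
  write.table(tax, file.path(dir, "taxonomy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  dir
}
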