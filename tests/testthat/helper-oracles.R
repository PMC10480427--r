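# Independent reference implementations used as test oracles. These are
# deliberately naive (substring scans, direct formula transliterations)
# and share no code with the package's vectorized paths.

# count k-mers by scanning every window and looking its substring up
naive_kmer_counts <- function(s, k) {
  kn <- kmer_names(c("uni", "bi", "tri")[k])
  out <- stats::setNames(integer(length(kn)), kn)
  N <- nchar(s)
  if (N >= k) {
    for (i in 1:(N - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (w %in% names(out)) out[w] <- out[w] + 1L
    }
  }
  out
}

# direct scalar transliteration of the directed average-variance formula:
# sd of class-a values around the mean over a of class-b's sample sd
oracle_avg_var_scalar <- function(xa, xb) {
  m <- length(xa)
  n <- length(xb)
  inner <- sum(vapply(seq_len(m), function(i) {
    sqrt(sum((xb - sum(xb) / n)^2) / (n - 1))
  }, numeric(1))) / m
  sqrt(sum((xa - inner)^2) / (m - 1))
}

oracle_avg_var_matrix <- function(A, B) {
  mean(vapply(seq_len(ncol(A)), function(j) {
    oracle_avg_var_scalar(A[, j], B[, j])
  }, numeric(1)))
}

# random peptide over the standard alphabet
random_peptide <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

# small labeled set with an optional planted dipeptide in positives
small_signal_set <- function(n_pos, n_neg, lengths = c(10L, 16L),
                             kmer = "WH", weight = 2, noise = 0, seed = 1L) {
  sk <- if (is.null(kmer)) NULL else
    data.frame(kmer = kmer, class = 1, weight = weight)
  generate_peptides(synthetic_spec(n_pos, n_neg, length_range = lengths,
                                   signal_kmers = sk, noise = noise,
                                   seed = seed))
}

# wrap a plain matrix + labels as a feature_table (for GA tests on
# low-dimensional toy features)
toy_feature_table <- function(X, labels) {
  structure(list(features = X, labels = as.integer(labels),
                 ids = paste0("row_", seq_len(nrow(X)))),
            class = "feature_table")
}

as_peptide_subset <- function(seqs, idx) {
  out <- seqs[idx, , drop = FALSE]
  class(out) <- c("peptide_set", "data.frame")
  out
}
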