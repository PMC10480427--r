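# Encoding and k-mer counting over the fixed 20-letter alphabet.
#
# All extractors share one convention: a window (of length 1, 2 or 3) is
# counted only if every position holds a standard residue. Under the
# default "skip" policy, windows touching a nonstandard symbol (X, B, Z,
# U, O, J, *) are silently excluded from the counts and a warning reports
# how many sequences were affected.

encode_residues <- function(residues) {
  chars <- strsplit(residues, "", fixed = TRUE)
  lens <- nchar(residues)
  list(
    code = match(unlist(chars, use.names = FALSE), AA_ALPHABET),
    seq_id = rep(seq_along(residues), lens),
    lens = lens
  )
}

# count k-mer windows for one integer-coded sequence; NA codes invalidate
# any window that covers them
count_kmer_windows <- function(code, k) {
  n <- length(code)
  nbins <- 20L^k
  if (n < k) return(integer(nbins))
  idx <- code[seq_len(n - k + 1L)] - 1L
  ok <- !is.na(code[seq_len(n - k + 1L)])
  if (k >= 2L) {
    for (d in 1L:(k - 1L)) {
      nxt <- code[seq_len(n - k + 1L) + d]
      ok <- ok & !is.na(nxt)
      idx <- idx * 20L + (nxt - 1L)
    }
  }
  tabulate(idx[ok] + 1L, nbins = nbins)
}

resolve_one_seq <- function(seq) {
  if (inherits(seq, "peptide_set")) {
    stopifnot(nrow(seq) == 1L)
    seq$residues
  } else {
    toupper(as.character(seq))
  }
}

apply_residue_policy <- function(code, policy) {
  if (policy == "error" && anyNA(code)) {
    stop("nonstandard residue encountered (policy = 'error')")
  }
  code
}

#' Amino-acid composition (unigram counts)
#'
#' Counts occurrences of each of the 20 standard amino acids. For a fully
#' standard sequence of length N the counts sum to N.
#'
#' @param seq A sequence string or a single-row [peptide_set()].
#' @param residue_policy `"skip"` (default) excludes windows containing
#'   nonstandard symbols; `"error"` aborts on them.
#' @return Named integer vector of length 20.
#' @examples
#' extract_unigram("ACAC") # A = 2, C = 2
#' @export
extract_unigram <- function(seq, residue_policy = c("skip", "error")) {
  residue_policy <- match.arg(residue_policy)
  code <- apply_residue_policy(
    match(strsplit(resolve_one_seq(seq), "")[[1]], AA_ALPHABET), residue_policy)
  stats::setNames(count_kmer_windows(code, 1L), kmer_names("uni"))
}

#' Dipeptide composition (bigram counts)
#'
#' Counts each ordered residue pair over a sliding window of width 2,
#' flattened row-major to 400 values. For a fully standard sequence of
#' length N >= 1 the counts sum to N - 1.
#'
#' @inheritParams extract_unigram
#' @return Named integer vector of length 400.
#' @examples
#' extract_bigram("ACAC")[c("AC", "CA")] # 2, 1
#' @export
extract_bigram <- function(seq, residue_policy = c("skip", "error")) {
  residue_policy <- match.arg(residue_policy)
  code <- apply_residue_policy(
    match(strsplit(resolve_one_seq(seq), "")[[1]], AA_ALPHABET), residue_policy)
  stats::setNames(count_kmer_windows(code, 2L), kmer_names("bi"))
}

#' Tripeptide composition (trigram counts)
#'
#' Counts each ordered residue triple over a sliding window of width 3,
#' flattened row-major to 8000 values. For a fully standard sequence of
#' length N >= 2 the counts sum to N - 2.
#'
#' @inheritParams extract_unigram
#' @return Named integer vector of length 8000.
#' @export
extract_trigram <- function(seq, residue_policy = c("skip", "error")) {
  residue_policy <- match.arg(residue_policy)
  code <- apply_residue_policy(
    match(strsplit(resolve_one_seq(seq), "")[[1]], AA_ALPHABET), residue_policy)
  stats::setNames(count_kmer_windows(code, 3L), kmer_names("tri"))
}

#' Build the full composition feature table
#'
#' Converts a peptide set into the concatenated unigram + bigram + trigram
#' count matrix (8420 columns, in [kmer_names()] order) with aligned ids
#' and 0/1 labels; together with the label each row carries 8421 values.
#' Row order matches input order.
#'
#' @param seqs A [peptide_set()].
#' @param residue_policy How to treat nonstandard residues: `"skip"`
#'   (exclude affected windows, warn), `"error"`, or `"drop-sequence"`
#'   (remove any sequence containing one, warn).
#' @return A list of class `feature_table` with elements `features`
#'   (numeric matrix, n x 8420), `labels` (integer), `ids` (character).
#' @export
build_feature_table <- function(seqs,
                                residue_policy = c("skip", "error", "drop-sequence")) {
  residue_policy <- match.arg(residue_policy)
  stopifnot(inherits(seqs, "peptide_set"))
  if (nrow(seqs) == 0L) stop("empty peptide set")
  enc <- encode_residues(seqs$residues)
  if (anyNA(enc$code)) {
    affected <- unique(enc$seq_id[is.na(enc$code)])
    if (residue_policy == "error") {
      stop("nonstandard residues in ", length(affected),
           " sequence(s) (policy = 'error'); first: ", seqs$id[affected[1]])
    }
    if (residue_policy == "drop-sequence") {
      warning("dropping ", length(affected),
              " sequence(s) containing nonstandard residues")
      seqs <- seqs[-affected, , drop = FALSE]
      class(seqs) <- c("peptide_set", "data.frame")
      if (nrow(seqs) == 0L) stop("all sequences dropped by residue policy")
      enc <- encode_residues(seqs$residues)
    } else {
      warning(length(affected), " sequence(s) contain nonstandard residues; ",
              "windows covering them are not counted")
    }
  }
  n <- nrow(seqs)
  code <- enc$code
  seq_id <- enc$seq_id
  total <- length(code)

  block <- function(k) {
    nbins <- 20L^k
    if (total < k) {
      return(matrix(0, n, nbins))
    }
    t0 <- seq_len(total - k + 1L)
    same <- seq_id[t0] == seq_id[t0 + (k - 1L)]
    idx <- code[t0] - 1L
    ok <- !is.na(code[t0])
    if (k >= 2L) {
      for (d in 1L:(k - 1L)) {
        nxt <- code[t0 + d]
        ok <- ok & !is.na(nxt)
        idx <- idx * 20L + (nxt - 1L)
      }
    }
    keep <- same & ok
    as.matrix(Matrix::sparseMatrix(
      i = seq_id[t0][keep], j = idx[keep] + 1L, x = 1,
      dims = c(n, nbins)))
  }

  feats <- cbind(block(1L), block(2L), block(3L))
  dimnames(feats) <- list(seqs$id, kmer_names("all"))
  structure(
    list(features = feats, labels = seqs$label, ids = seqs$id),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$features), "sequences x", ncol(x$features),
      "k-mer counts; labels:", paste(table(x$labels), collapse = "/"),
      "(0/1)\n")
  invisible(x)
}

#' Full labeled feature matrix (8421 columns)
#'
#' @param table A [build_feature_table()] result.
#' @return Numeric matrix with the 8420 k-mer columns plus a final
#'   `label` column.
#' @export
labeled_feature_matrix <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  cbind(table$features, label = table$labels)
}

# row subset keeping class
ft_rows <- function(table, idx) {
  structure(
    list(features = table$features[idx, , drop = FALSE],
         labels = table$labels[idx], ids = table$ids[idx]),
    class = "feature_table"
  )
}

#' Write / read a feature table as CSV
#'
#' The CSV carries an `id` column, the 8420 k-mer columns (named), and a
#' final `label` column; `read_feature_table()` round-trips losslessly.
#'
#' @param table A `feature_table`.
#' @param path CSV file path.
#' @return `path` invisibly (writer); a `feature_table` (reader).
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(id = table$ids, table$features, label = table$labels,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  expected <- c("id", kmer_names("all"), "label")
  if (!identical(names(df), expected)) {
    stop("not a feature-table CSV: column names do not match the k-mer layout")
  }
  feats <- as.matrix(df[, kmer_names("all"), drop = FALSE])
  rownames(feats) <- df$id
  structure(
    list(features = feats, labels = as.integer(df$label), ids = df$id),
    class = "feature_table"
  )
}
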