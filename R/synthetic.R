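# Seeded synthetic peptide generator. Sequences are drawn residue by
# residue from a background frequency vector; positive-class sequences
# get a planted k-mer written over a random window, so the compositional
# effect size per sequence is explicit. This emulates the statistical
# structure of binary linear B-cell epitope data (class-dependent
# composition bias, variable lengths, class imbalance) without any claim
# to real epitope biology.

#' Specification of a synthetic peptide dataset
#'
#' @param n_pos,n_neg Number of positive / negative sequences.
#' @param length_range Integer pair `(Lmin, Lmax)`; lengths are drawn
#'   uniformly. The default 15--30 covers typical linear epitope lengths.
#' @param signal_kmers Data frame with columns `kmer` (string over the
#'   standard alphabet), `class` (0 or 1) and `weight` (mean copies
#'   planted per sequence of that class), or `NULL` for no signal.
#' @param background Length-20 residue frequency vector (normalized
#'   internally); default uniform.
#' @param noise Label-flip probability in \[0, 1\].
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pos, n_neg, length_range = c(15L, 30L),
                           signal_kmers = NULL,
                           background = rep(1 / 20, 20L),
                           noise = 0, seed = 1L) {
  if (n_pos < 0 || n_neg < 0 || n_pos + n_neg < 1) {
    stop("need at least one sequence")
  }
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || length_range[1] < 1L ||
      length_range[1] > length_range[2]) {
    stop("length_range must be (Lmin, Lmax) with 1 <= Lmin <= Lmax")
  }
  if (length(background) != 20L || any(background < 0) || sum(background) <= 0) {
    stop("background must be 20 non-negative frequencies")
  }
  if (noise < 0 || noise > 1) stop("noise must lie in [0, 1]")
  if (!is.null(signal_kmers)) {
    stopifnot(is.data.frame(signal_kmers),
              all(c("kmer", "class", "weight") %in% names(signal_kmers)))
    if (any(grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"),
                  signal_kmers$kmer))) {
      stop("signal k-mers must use the standard alphabet")
    }
    if (!all(signal_kmers$class %in% c(0, 1)) || any(signal_kmers$weight < 0)) {
      stop("signal k-mer classes must be 0/1 and weights non-negative")
    }
    if (any(nchar(signal_kmers$kmer) > length_range[1])) {
      stop("signal k-mers longer than Lmin cannot always be planted")
    }
  }
  structure(
    list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
         length_range = length_range, signal_kmers = signal_kmers,
         background = background / sum(background), noise = noise,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a labeled synthetic peptide set
#'
#' Residues are sampled i.i.d. from the background frequencies. For each
#' sequence whose class matches a signal k-mer row, `floor(weight)` plus
#' a Bernoulli(`weight - floor(weight)`) copies of the k-mer overwrite
#' random windows. Finally each label is flipped independently with
#' probability `noise`. Identical seeds give identical datasets.
#'
#' @param spec A [synthetic_spec()].
#' @return A [peptide_set()] with ids `synth_1 ... synth_n`; positives
#'   first, then negatives.
#' @export
generate_peptides <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_pos + spec$n_neg
  true_class <- rep(c(1L, 0L), c(spec$n_pos, spec$n_neg))
  withr::with_seed(spec$seed, {
    lens <- sample(spec$length_range[1]:spec$length_range[2], n, replace = TRUE)
    residues <- vapply(lens, function(L)
      paste(sample(AA_ALPHABET, L, replace = TRUE, prob = spec$background),
            collapse = ""), "")
    if (!is.null(spec$signal_kmers)) {
      for (r in seq_len(nrow(spec$signal_kmers))) {
        km <- spec$signal_kmers$kmer[r]
        cl <- spec$signal_kmers$class[r]
        w <- spec$signal_kmers$weight[r]
        klen <- nchar(km)
        for (i in which(true_class == cl)) {
          copies <- floor(w) + stats::rbinom(1L, 1L, w - floor(w))
          for (cp in seq_len(copies)) {
            start <- sample.int(lens[i] - klen + 1L, 1L)
            substr(residues[i], start, start + klen - 1L) <- km
          }
        }
      }
    }
    label <- true_class
    if (spec$noise > 0) {
      flip <- stats::runif(n) < spec$noise
      label[flip] <- 1L - label[flip]
    }
    peptide_set(residues, label, id = paste0("synth_", seq_len(n)))
  })
}

#' Fixed fixture datasets
#'
#' Small named datasets with documented seeds, used throughout the test
#' suite and reproducible byte-for-byte:
#' \describe{
#'   \item{separable}{500 + 500 sequences, three copies of the dipeptide
#'     `WH` planted in every positive, no label noise (seed 101).}
#'   \item{random}{100 + 100 sequences, no signal: the best achievable
#'     accuracy is chance (seed 102).}
#'   \item{imbalanced}{100 positives vs 400 negatives with the planted
#'     signal (seed 103).}
#'   \item{short_seqs}{50 + 50 sequences of length 1--5 (seed 104).}
#' }
#'
#' @param which Fixture name, or `"all"` for the full named list.
#' @return A [peptide_set()], or a named list of them.
#' @export
make_fixture_suite <- function(which = c("all", "separable", "random",
                                         "imbalanced", "short_seqs")) {
  which <- match.arg(which)
  signal <- data.frame(kmer = "WH", class = 1, weight = 3)
  specs <- list(
    separable = synthetic_spec(500, 500, signal_kmers = signal,
                               noise = 0, seed = 101L),
    random = synthetic_spec(100, 100, seed = 102L),
    imbalanced = synthetic_spec(100, 400, signal_kmers = signal,
                                noise = 0, seed = 103L),
    short_seqs = synthetic_spec(50, 50, length_range = c(1L, 5L),
                                signal_kmers = NULL, seed = 104L)
  )
  if (which == "all") {
    lapply(specs, generate_peptides)
  } else {
    generate_peptides(specs[[which]])
  }
}

#' Write a synthetic dataset plus its spec sidecar
#'
#' Writes FASTA (`>synth_i label=b`), TSV, and the generating spec as a
#' JSON sidecar.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- generate_peptides(spec)
  write_labeled_sequences(seqs, file.path(dir, "sequences.fasta"), "fasta")
  write_labeled_sequences(seqs, file.path(dir, "sequences.tsv"), "tsv")
  jsonlite::write_json(unclass(spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(dir)
}
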