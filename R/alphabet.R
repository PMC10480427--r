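#' The 20-letter amino-acid alphabet
#'
#' Fixed alphabetical ordering of the 20 standard amino-acid one-letter
#' codes. All k-mer feature columns are indexed against this ordering.
#'
#' @format A character vector of length 20.
#' @export
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# symbols occasionally seen in real peptide data that are not part of the
# standard alphabet; windows containing them are handled by `residue_policy`
NONSTANDARD_RESIDUES <- c("X", "B", "Z", "U", "O", "J", "*")

#' k-mer column names of the composition feature space
#'
#' Returns the column names of the unigram (20), bigram (400) or trigram
#' (8000) blocks, or of the full concatenated 8420-column feature space.
#' Flattening is row-major: the first residue of the k-mer varies slowest,
#' so column `(i-1)*20 + j` of the bigram block is `AA[i] AA[j]`.
#'
#' @param which One of `"uni"`, `"bi"`, `"tri"` or `"all"`.
#' @return Character vector of k-mer names.
#' @examples
#' kmer_names("uni")[1:3]
#' kmer_names("bi")[21] # "CA": second row of the 20 x 20 grid
#' @export
kmer_names <- function(which = c("all", "uni", "bi", "tri")) {
  which <- match.arg(which)
  a <- AA_ALPHABET
  uni <- a
  bi <- paste0(rep(a, each = 20L), a)
  tri <- paste0(rep(a, each = 400L), rep(rep(a, each = 20L), times = 20L),
                rep(a, times = 400L))
  switch(which,
    uni = uni, bi = bi, tri = tri,
    all = c(uni, bi, tri))
}

# deterministic derived seed for a pipeline stage, kept below 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
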