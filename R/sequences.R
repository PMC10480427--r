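#' Construct a set of labeled peptide sequences
#'
#' A peptide set is a data frame with columns `id`, `residues` and `label`
#' (1 = linear B-cell epitope present, 0 = absent). Residues are upper-cased
#' on construction; the standard alphabet is `ACDEFGHIKLMNPQRSTVWY`.
#' Nonstandard symbols (X, B, Z, U, O, J, *) are tolerated here and handled
#' at featurization time by the residue policy.
#'
#' @param residues Character vector of peptide sequences (length >= 1 each).
#' @param label Integer/numeric vector of 0/1 class labels.
#' @param id Optional character identifiers; defaults to `seq_1 ... seq_n`.
#' @return A data frame of class `peptide_set`.
#' @examples
#' peptide_set(c("ACDK", "wwyh"), c(1, 0))
#' @export
peptide_set <- function(residues, label, id = NULL) {
  if (length(residues) == 0L) stop("empty peptide set")
  residues <- toupper(as.character(residues))
  if (anyNA(residues) || any(!nzchar(residues))) {
    stop("all sequences must be non-empty strings")
  }
  bad <- grepl("[^A-Z*]", residues)
  if (any(bad)) {
    stop("sequence ", which(bad)[1], " contains characters outside A-Z/*")
  }
  label <- suppressWarnings(as.integer(label))
  if (length(label) != length(residues) || anyNA(label) ||
      !all(label %in% c(0L, 1L))) {
    stop("labels must be 0 or 1, one per sequence")
  }
  id <- if (is.null(id)) paste0("seq_", seq_along(residues)) else as.character(id)
  stopifnot(length(id) == length(residues))
  structure(
    data.frame(id = id, residues = residues, label = label,
               stringsAsFactors = FALSE),
    class = c("peptide_set", "data.frame")
  )
}

#' Read labeled peptide sequences from FASTA or TSV
#'
#' FASTA headers must carry a binary label, either as `>id label=0` /
#' `>id label=1` or as the dialect `>id|0` / `>id|1`. TSV files have two
#' columns, `sequence<TAB>label`, with an optional header row. File order
#' is preserved and residues are upper-cased.
#'
#' @param path Path to the input file.
#' @param format `"fasta"`, `"tsv"`, or `"auto"` (by file extension;
#'   `.fa/.fasta/.faa` read as FASTA, anything else as TSV).
#' @return A [peptide_set()].
#' @export
read_labeled_sequences <- function(path, format = c("auto", "fasta", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|faa)$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  }
  if (format == "fasta") read_fasta_labeled(path) else read_tsv_labeled(path)
}

read_fasta_labeled <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("unparseable FASTA: ", conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  lab <- rep(NA_integer_, length(set))
  ids <- character(length(set))
  m <- regmatches(headers, regexec("^(\\S+).*label=(\\S+)", headers))
  for (i in seq_along(set)) {
    h <- headers[i]
    if (length(m[[i]]) == 3L) {
      ids[i] <- m[[i]][2]
      tok <- m[[i]][3]
    } else if (grepl("\\|[^|]*$", h)) {
      ids[i] <- sub("\\|[^|]*$", "", h)
      tok <- sub("^.*\\|", "", h)
    } else {
      stop("record ", i, ": no label token in header '", h, "'")
    }
    if (!tok %in% c("0", "1")) {
      stop("record ", i, ": invalid label token '", tok, "'")
    }
    lab[i] <- as.integer(tok)
  }
  peptide_set(as.character(set), lab, id = ids)
}

read_tsv_labeled <- function(path) {
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0L) stop("empty file: ", path)
  parts <- strsplit(raw, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) stop("record ", bad[1], ": expected sequence<TAB>label")
  seqs <- vapply(parts, `[`, "", 1L)
  labs <- vapply(parts, `[`, "", 2L)
  # optional header row
  if (tolower(seqs[1]) %in% c("sequence", "seq", "residues")) {
    seqs <- seqs[-1]; labs <- labs[-1]
    if (length(seqs) == 0L) stop("no data rows in ", path)
  }
  if (!all(labs %in% c("0", "1"))) {
    i <- which(!labs %in% c("0", "1"))[1]
    stop("record ", i, ": invalid label token '", labs[i], "'")
  }
  peptide_set(seqs, as.integer(labs))
}

#' Write a peptide set to FASTA (`>id label=b`) or TSV
#'
#' @param seqs A [peptide_set()].
#' @param path Output file path.
#' @param format `"fasta"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_labeled_sequences <- function(seqs, path, format = c("fasta", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(seqs, "peptide_set"))
  if (format == "fasta") {
    lines <- as.vector(rbind(paste0(">", seqs$id, " label=", seqs$label),
                             seqs$residues))
  } else {
    lines <- paste0(seqs$residues, "\t", seqs$label)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Truncate every sequence to its first `SLsel` residues
#'
#' Sequences shorter than `SLsel` pass through unchanged; labels, ids and
#' order are preserved. Truncation is idempotent: truncating twice at the
#' same length equals truncating once.
#'
#' @param seqs A [peptide_set()].
#' @param SLsel Positive integer truncation length.
#' @return A [peptide_set()] of prefixes.
#' @export
truncate_sequences <- function(seqs, SLsel) {
  stopifnot(inherits(seqs, "peptide_set"))
  if (!is.numeric(SLsel) || length(SLsel) != 1L || SLsel < 1) {
    stop("SLsel must be a single integer >= 1")
  }
  out <- seqs
  out$residues <- substr(seqs$residues, 1L, as.integer(SLsel))
  out
}
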