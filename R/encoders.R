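# Sequence encodings consumed by the random forests.
#
# One-hot: 40 positions x 4 channels in the order A, G, C, T (A -> 1000,
# G -> 0100, C -> 0010, T -> 0001; N -> 0000), position-major. Positions are
# labelled -39 ... 0 relative to the TSS, position 0 being the base adjacent
# to the TSS.
#
# Tetra-frequency: counts of the 256 overlapping 4-mers (lexicographic over
# A < C < G < T) divided by the number of valid 4-mer windows; windows
# containing N are excluded from numerator and denominator.

ONE_HOT_BASES <- c("A", "G", "C", "T")

one_hot_feature_names <- function(width = 40L) {
  pos <- seq_len(width) - width  # -39 ... 0 for width 40
  as.vector(t(outer(pos, ONE_HOT_BASES,
                    function(p, b) sprintf("pos%d:%s", p, b))))
}

tetra_feature_names <- function() {
  b <- c("A", "C", "G", "T")
  paste0(rep(b, each = 64L), rep(rep(b, each = 16L), 4L),
         rep(rep(b, each = 4L), 16L), rep(b, 64L))
}

seq_char_matrix <- function(seqs, width) {
  if (any(nchar(seqs) != width))
    stop("all sequences must have length ", width, " (found length ",
         nchar(seqs)[nchar(seqs) != width][1], ")")
  if (any(grepl("[^ACGTN]", seqs)))
    stop("sequence contains characters outside {A, C, G, T, N}")
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), byrow = TRUE)
}

#' One-hot encode 40-nt sequences
#'
#' Each base becomes a 4-bit indicator in channel order A, G, C, T
#' (`A -> 1000`, `G -> 0100`, `C -> 0010`, `T -> 0001`); `N` yields an
#' all-zero block. Blocks are concatenated position-major, giving 160
#' features named `pos-39:A` ... `pos0:T` (position 0 adjacent to the TSS).
#'
#' @param seqs Character vector of sequences, each of length `width`.
#' @param width Sequence length (default 40).
#' @return Integer matrix, one row per sequence, `4 * width` columns.
#' @examples
#' encode_one_hot("GAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA")[1, 1:4]
#' @export
encode_one_hot <- function(seqs, width = 40L) {
  nm <- one_hot_feature_names(width)
  if (length(seqs) == 0L)
    return(matrix(integer(0), 0L, 4L * width, dimnames = list(NULL, nm)))
  m <- seq_char_matrix(seqs, width)
  x <- matrix(0L, length(seqs), 4L * width, dimnames = list(NULL, nm))
  for (b in 1:4)
    x[, (seq_len(width) - 1L) * 4L + b] <- (m == ONE_HOT_BASES[b]) + 0L
  x
}

#' Decode a one-hot matrix back to sequences
#'
#' Inverse of [encode_one_hot()] for N-free input; all-zero blocks decode to
#' `N`.
#'
#' @param x One-hot matrix with `4 * width` columns.
#' @param width Sequence length (default 40).
#' @return Character vector of sequences.
#' @export
decode_one_hot <- function(x, width = 40L) {
  if (ncol(x) != 4L * width)
    stop("expected ", 4L * width, " columns, got ", ncol(x))
  if (nrow(x) == 0L) return(character(0))
  apply(x, 1L, function(row) {
    blocks <- matrix(row, nrow = 4L)
    paste(vapply(seq_len(width), function(j) {
      hit <- which(blocks[, j] == 1L)
      if (length(hit) == 1L) ONE_HOT_BASES[hit] else "N"
    }, ""), collapse = "")
  })
}

#' Tetra-nucleotide frequency encoding
#'
#' Counts every overlapping 4-mer (step 1) and divides by the number of
#' valid 4-mer windows; windows containing `N` are excluded from both the
#' numerator and the denominator. For an N-free 40-mer the denominator is
#' 37 and each row sums to 1. Columns are the 256 4-mers in lexicographic
#' order (A < C < G < T).
#'
#' @param seqs Character vector of sequences (each length >= 4). All must
#'   share a common length.
#' @return Numeric matrix, one row per sequence, 256 columns.
#' @examples
#' encode_tetra_freq("ACGTACGT")[1, c("ACGT", "CGTA")]
#' @export
encode_tetra_freq <- function(seqs) {
  nm <- tetra_feature_names()
  if (length(seqs) == 0L)
    return(matrix(numeric(0), 0L, 256L, dimnames = list(NULL, nm)))
  width <- nchar(seqs[1])
  if (width < 4L) stop("sequences must have length >= 4 for 4-mer counting")
  m <- seq_char_matrix(seqs, width)
  code <- matrix(match(m, c("A", "C", "G", "T")), nrow = nrow(m))  # N -> NA
  w <- width - 3L
  idx <- 64L * (code[, 1:w, drop = FALSE] - 1L) +
    16L * (code[, 2:(w + 1L), drop = FALSE] - 1L) +
    4L * (code[, 3:(w + 2L), drop = FALSE] - 1L) +
    (code[, 4:(w + 3L), drop = FALSE] - 1L) + 1L
  x <- matrix(0, length(seqs), 256L, dimnames = list(NULL, nm))
  for (i in seq_len(nrow(x))) {
    ki <- idx[i, ]
    ki <- ki[!is.na(ki)]
    if (length(ki)) x[i, ] <- tabulate(ki, 256L) / length(ki)
  }
  x
}

#' Encode a labelled set (or bare sequences) into a feature matrix
#'
#' Dispatches on the encoder tag used throughout the package: `"hot"` for
#' the 160-dimensional positional one-hot encoding, `"tetra"` for the
#' 256-dimensional 4-mer frequency encoding.
#'
#' @param x Character vector of sequences, or a labelled set with a
#'   `sequence` column.
#' @param encoder `"hot"` or `"tetra"`.
#' @return Feature matrix with named columns, rows aligned to the input.
#' @export
encode_sequences <- function(x, encoder = c("hot", "tetra")) {
  encoder <- match.arg(encoder)
  seqs <- if (is.data.frame(x)) x$sequence else x
  switch(encoder, hot = encode_one_hot(seqs), tetra = encode_tetra_freq(seqs))
}
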