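#' Validate a genome sequence object
#'
#' A genome is a named character vector: one uppercase nucleotide string per
#' contig over the alphabet `{A, C, G, T, N}`. Lowercase (softmasked) input is
#' folded to uppercase.
#'
#' @param x Named character vector of contig sequences.
#' @return The validated, uppercased genome.
#' @export
genome_sequence <- function(x) {
  if (!is.character(x) || is.null(names(x)) || any(!nzchar(names(x))))
    stop("a genome is a named character vector of contig sequences")
  if (anyDuplicated(names(x)))
    stop("duplicated contig identifiers: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  x <- toupper(x)
  if (any(!nzchar(x)))
    stop("empty contig sequence: ", names(x)[!nzchar(x)][1])
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    off <- regmatches(x[bad][1], regexpr("[^ACGTN]", x[bad][1]))
    stop("contig ", names(x)[bad][1], " contains invalid character '",
         off, "' (alphabet is A, C, G, T, N)")
  }
  x
}

#' Total genome length in bp
#' @param genome Genome from [genome_sequence()] or [read_fasta()].
#' @return Integer, sum of contig lengths.
#' @export
genome_length <- function(genome) sum(nchar(genome))

#' Read a genome from FASTA
#'
#' One entry per record, contig order preserved, sequence uppercased.
#' Characters outside `{A, C, G, T, N}` are rejected.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of contig sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("failed to parse FASTA file ",
                                           path, ": ", conditionMessage(e)))
  if (length(set) == 0L)
    stop("FASTA file ", path, " contains no sequence records")
  x <- as.character(set)
  # keep only the identifier part of each header
  names(x) <- vapply(strsplit(names(set), "[ \t]"), `[`, "", 1L)
  genome_sequence(x)
}

#' Write a genome to FASTA
#' @param genome Named character vector of contig sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(genome, path) {
  genome <- genome_sequence(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Reverse complement
#'
#' Standard complement with `N -> N`, then reversal. Vectorised over input
#' strings.
#'
#' @param seq Character vector of nucleotide strings over `{A, C, G, T, N}`.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("AAGN")  # "NCTT"
#' @export
reverse_complement <- function(seq) {
  if (length(seq) == 0L) return(character(0))
  if (any(grepl("[^ACGTN]", seq)))
    stop("reverse_complement: sequence contains characters outside ",
         "{A, C, G, T, N}")
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), "",
         USE.NAMES = FALSE)
}

#' Extract strand-resolved sequences for intervals
#'
#' Returns the forward-strand slice for `+` intervals and its reverse
#' complement for `-` intervals, so the result always reads 5'->3' on the
#' annotated strand.
#'
#' @param genome Named character vector of contig sequences.
#' @param iv Interval data frame (see [genomic_intervals()]).
#' @return Character vector of sequences, one per interval row.
#' @export
fetch_sequence <- function(genome, iv) {
  validate_intervals(iv)
  if (nrow(iv) == 0L) return(character(0))
  unknown <- setdiff(unique(iv$chrom), names(genome))
  if (length(unknown))
    stop("interval on unknown contig: ", unknown[1])
  len <- nchar(genome)[iv$chrom]
  if (any(iv$end > len))
    stop("interval out of contig bounds: ", iv$chrom[iv$end > len][1],
         ":[", iv$start[iv$end > len][1], ",", iv$end[iv$end > len][1], ")")
  out <- substring(genome[iv$chrom], iv$start + 1L, iv$end)
  neg <- iv$strand == "-"
  if (any(neg)) out[neg] <- reverse_complement(out[neg])
  unname(out)
}
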