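#' Construct a table of genomic intervals
#'
#' Intervals are the coordinate currency of the package: plain data frames in
#' BED column order (`chrom`, `start`, `end`, `name`, `score`, `strand`) with
#' 0-based half-open coordinates. A transcription start site (TSS) is an
#' interval of width 1 covering the TSS base.
#'
#' @param chrom Character vector of contig identifiers.
#' @param start Integer vector, 0-based inclusive start positions.
#' @param end Integer vector, exclusive end positions (`end > start`).
#' @param strand Character vector over `"+"`/`"-"`.
#' @param name Optional feature names (default `"."`).
#' @param score Optional numeric scores; for prediction tracks this column
#'   carries the promoter probability.
#' @return A data frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @examples
#' genomic_intervals("c1", 960, 1000, "+")
#' @export
genomic_intervals <- function(chrom, start, end, strand,
                              name = ".", score = 0) {
  n <- length(start)
  iv <- data.frame(chrom  = as.character(chrom),
                   start  = as.integer(start),
                   end    = as.integer(end),
                   name   = rep_len(as.character(name), n),
                   score  = rep_len(as.numeric(score), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  validate_intervals(iv)
  iv
}

validate_intervals <- function(iv, what = "interval") {
  stopifnot(is.data.frame(iv))
  need <- c("chrom", "start", "end", "strand")
  miss <- setdiff(need, names(iv))
  if (length(miss))
    stop(what, " table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(iv) == 0L) return(invisible(iv))
  if (any(iv$start < 0L))
    stop(what, " with negative start (coordinates are 0-based)")
  if (any(iv$end <= iv$start))
    stop(what, " with end <= start (intervals are half-open, end exclusive)")
  bad <- !iv$strand %in% c("+", "-")
  if (any(bad))
    stop(what, " with unknown strand symbol '", iv$strand[which(bad)[1]],
         "' (must be '+' or '-')")
  invisible(iv)
}

#' Read a strand-aware BED6 file
#'
#' Requires at least six columns (chrom, start, end, name, score, strand);
#' coordinates are 0-based half-open per the BED convention. The score column
#' is retained and, for prediction tracks, holds the promoter probability.
#'
#' @param path Path to a BED file.
#' @return Interval data frame as from [genomic_intervals()], in file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = "character", quote = "",
                      comment.char = ""),
    error = function(e) stop("failed to parse BED file ", path, ": ",
                             conditionMessage(e)))
  if (ncol(tab) < 6L)
    stop("BED file ", path, " has ", ncol(tab),
         " column(s); 6 columns (chrom, start, end, name, score, strand) ",
         "are required")
  iv <- data.frame(chrom  = tab[[1]],
                   start  = as.integer(tab[[2]]),
                   end    = as.integer(tab[[3]]),
                   name   = tab[[4]],
                   score  = as.numeric(tab[[5]]),
                   strand = tab[[6]],
                   stringsAsFactors = FALSE)
  validate_intervals(iv, what = paste0("BED record in ", path))
  iv
}

#' Write intervals to BED6
#'
#' Round-trips losslessly through [read_bed()]; scores are serialised with six
#' decimals so that prediction probabilities survive the trip.
#'
#' @param iv Interval data frame.
#' @param path Output path.
#' @param scores Optional numeric vector in `[0, 1]` overriding the score
#'   column (one per interval).
#' @return Invisibly, `path`.
#' @export
write_bed <- function(iv, path, scores = NULL) {
  validate_intervals(iv)
  if (!is.null(scores)) {
    if (length(scores) != nrow(iv))
      stop("length(scores) [", length(scores), "] != number of intervals [",
           nrow(iv), "]")
    if (length(scores) && (any(scores < 0) || any(scores > 1)))
      stop("scores must lie in [0, 1]")
    iv$score <- scores
  }
  if (nrow(iv) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  name <- if ("name" %in% names(iv)) iv$name else "."
  score <- if ("score" %in% names(iv)) iv$score else 0
  lines <- sprintf("%s\t%d\t%d\t%s\t%.6f\t%s",
                   iv$chrom, iv$start, iv$end, name, score, iv$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Collapse exact-duplicate intervals
#'
#' Intervals identical in (chrom, start, end, strand) are collapsed to their
#' first occurrence; order of first occurrences is preserved. Used to
#' deduplicate promoter records derived from redundant TSS maps.
#'
#' @param iv Interval data frame.
#' @return Deduplicated interval data frame.
#' @export
deduplicate_intervals <- function(iv) {
  validate_intervals(iv)
  if (nrow(iv) == 0L) return(iv)
  key <- paste(iv$chrom, iv$start, iv$end, iv$strand, sep = "\r")
  out <- iv[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# bp shared between one interval and each row of a table (same contig only;
# strand is the caller's business)
overlap_bp <- function(iv, chrom, start, end) {
  same <- iv$chrom == chrom
  ov <- pmin(iv$end, end) - pmax(iv$start, start)
  ov[!same] <- 0L
  pmax(ov, 0L)
}
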