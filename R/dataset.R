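#' Promoter intervals upstream of TSS coordinates
#'
#' The promoter is operationalised as the `width` bp immediately upstream of
#' the TSS on its own strand: for a `+` TSS at base `p` the interval is
#' `[p - width, p)`; for a `-` TSS it is `[p + 1, p + 1 + width)` on the `-`
#' strand. In both cases the extracted sequence reads 5'->3' toward the TSS
#' and covers positions `-width ... -1` relative to it. Intervals that would
#' extend past a contig boundary are dropped with a warning.
#'
#' @param tss Interval data frame of width-1 TSS records.
#' @param genome Genome (needed for contig bounds).
#' @param width Promoter width in bp (default 40).
#' @return Interval data frame of promoters (possibly fewer rows than `tss`).
#' @export
promoter_intervals <- function(tss, genome, width = 40L) {
  validate_intervals(tss, what = "TSS record")
  stopifnot(width >= 1L)
  if (nrow(tss) && any(tss$end - tss$start != 1L))
    stop("TSS records must have width 1 (the TSS base)")
  p <- tss$start
  plus <- tss$strand == "+"
  start <- ifelse(plus, p - width, p + 1L)
  end <- start + width
  len <- nchar(genome)[tss$chrom]
  if (any(is.na(len)))
    stop("TSS on unknown contig: ", tss$chrom[is.na(len)][1])
  keep <- start >= 0L & end <= len
  if (any(!keep))
    warning(sum(!keep), " TSS record(s) dropped: promoter window extends ",
            "past a contig boundary")
  out <- data.frame(chrom = tss$chrom, start = as.integer(start),
                    end = as.integer(end),
                    name = if ("name" %in% names(tss)) tss$name else ".",
                    score = 0, strand = tss$strand,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample random negative intervals avoiding known promoters
#'
#' Draws `n` fixed-length intervals with the start uniform over valid
#' positions (contigs weighted by their number of valid starts) and the
#' strand uniform over `{+, -}`. Draws sharing at least 1 bp with any
#' `exclude` interval are rejected regardless of strand. Deterministic for a
#' fixed seed; gives up with an error after a retry budget of `1000 * n`
#' candidate draws.
#'
#' @param genome Genome.
#' @param n Number of intervals to return.
#' @param width Interval length in bp (default 40).
#' @param exclude Interval data frame to avoid (typically the positives).
#' @param seed Integer seed.
#' @return Interval data frame with `n` rows.
#' @export
sample_negative_intervals <- function(genome, n, width = 40L,
                                      exclude = NULL, seed = 1L) {
  stopifnot(n >= 0L, width >= 1L)
  if (n == 0L)
    return(genomic_intervals(character(0), integer(0), integer(0),
                             character(0)))
  set.seed(seed)
  nvalid <- pmax(nchar(genome) - width + 1L, 0L)
  if (sum(nvalid) == 0L)
    stop("no contig is long enough for intervals of width ", width)
  contigs <- names(genome)
  acc_chrom <- character(0); acc_start <- integer(0); acc_strand <- character(0)
  budget <- 1000 * n
  drawn <- 0L
  while (length(acc_start) < n) {
    m <- min(max(2L * (n - length(acc_start)), 100L), budget - drawn)
    if (m <= 0L)
      stop("negative sampling exhausted its retry budget (", budget,
           " draws); the genome is too crowded -- request fewer intervals")
    drawn <- drawn + m
    ci <- sample.int(length(contigs), m, replace = TRUE, prob = nvalid)
    st <- floor(stats::runif(m) * nvalid[ci])
    sd_ <- sample(c("+", "-"), m, replace = TRUE)
    ok <- rep(TRUE, m)
    if (!is.null(exclude) && nrow(exclude)) {
      for (i in seq_len(nrow(exclude))) {
        hit <- contigs[ci] == exclude$chrom[i] &
          st < exclude$end[i] & st + width > exclude$start[i]
        ok <- ok & !hit
      }
    }
    acc_chrom <- c(acc_chrom, contigs[ci][ok])
    acc_start <- c(acc_start, as.integer(st[ok]))
    acc_strand <- c(acc_strand, sd_[ok])
  }
  keep <- seq_len(n)
  genomic_intervals(acc_chrom[keep], acc_start[keep],
                    acc_start[keep] + width, acc_strand[keep],
                    name = sprintf("neg%d", keep))
}

#' Build a labelled promoter / non-promoter sequence set
#'
#' Positives are the deduplicated, in-bounds promoter windows upstream of the
#' supplied TSS records; negatives are `neg_per_pos` times as many random
#' windows that share no base with any positive. Records are shuffled with
#' the seed. The paper-faithful training regime uses `neg_per_pos = 10`
#' (1:10, emulating the rarity of promoters in a genome); validation sets
#' use `neg_per_pos = 1` (balanced).
#'
#' @param genome Genome.
#' @param tss TSS interval data frame (width-1 records).
#' @param neg_per_pos Negatives per positive (default 10).
#' @param width Promoter width in bp (default 40).
#' @param seed Integer seed driving negative sampling and shuffling.
#' @return A data frame with columns `sequence`, `label` (1 promoter /
#'   0 non-promoter), `chrom`, `start`, `end`, `strand`; attribute
#'   `neg_per_pos` records the declared ratio.
#' @export
build_dataset <- function(genome, tss, neg_per_pos = 10L, width = 40L,
                          seed = 1L) {
  neg_per_pos <- as.integer(neg_per_pos)
  stopifnot(neg_per_pos >= 1L)
  if (nrow(tss) == 0L) stop("no TSS records supplied")
  pos <- deduplicate_intervals(promoter_intervals(tss, genome, width))
  if (nrow(pos) == 0L)
    stop("all TSS records were dropped at contig boundaries; ",
         "cannot build a dataset without positives")
  neg <- sample_negative_intervals(genome, neg_per_pos * nrow(pos), width,
                                   exclude = pos, seed = seed)
  iv <- rbind(pos, neg)
  ds <- data.frame(sequence = fetch_sequence(genome, iv),
                   label = rep(c(1L, 0L), c(nrow(pos), nrow(neg))),
                   chrom = iv$chrom, start = iv$start, end = iv$end,
                   strand = iv$strand, stringsAsFactors = FALSE)
  set.seed(seed + 1L)
  ds <- ds[sample.int(nrow(ds)), , drop = FALSE]
  rownames(ds) <- NULL
  attr(ds, "neg_per_pos") <- neg_per_pos
  ds
}

#' Stratified train/test split
#'
#' Splits a labelled set so that both parts preserve the positive:negative
#' ratio within rounding; the parts are disjoint and their union is the
#' input. The model-selection protocol holds out 25%.
#'
#' @param ds Labelled set from [build_dataset()].
#' @param test_fraction Proportion held out (default 0.25).
#' @param seed Integer seed.
#' @return List with elements `train` and `test`.
#' @export
split_train_test <- function(ds, test_fraction = 0.25, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  tab <- table(ds$label)
  if (any(tab < 2L))
    stop("each class needs at least 2 records to stratify (have ",
         paste(tab, collapse = "/"), ")")
  set.seed(seed)
  test_idx <- unlist(lapply(split(seq_len(nrow(ds)), ds$label), function(ix) {
    sample(ix, round(length(ix) * test_fraction))
  }), use.names = FALSE)
  test <- ds[sort(test_idx), , drop = FALSE]
  train <- ds[-sort(test_idx), , drop = FALSE]
  rownames(test) <- rownames(train) <- NULL
  attr(train, "neg_per_pos") <- attr(ds, "neg_per_pos")
  attr(test, "neg_per_pos") <- attr(ds, "neg_per_pos")
  list(train = train, test = test)
}

#' Write / read a labelled sequence set as TSV
#'
#' Six tab-separated columns with a header: sequence, label, chrom, start,
#' end, strand.
#'
#' @param ds Labelled set.
#' @param path File path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns
#'   the data frame.
#' @export
write_dataset <- function(ds, path) {
  utils::write.table(ds, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  ds <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("sequence", "label") %in% names(ds)))
    stop("dataset TSV must have 'sequence' and 'label' columns")
  ds
}
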