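#' Enumerate sliding windows over a genome
#'
#' Per contig of length `L`: `floor((L - window) / step) + 1` plus-strand
#' windows starting at 0, `step`, `2*step`, ..., then the same coordinates
#' on the minus strand. Contigs shorter than the window contribute no
#' windows. Windows never span contig boundaries and circular genomes are
#' treated as linear.
#'
#' @param genome Genome.
#' @param window Window size in bp (default 40).
#' @param step Step size in bp (default 1).
#' @return Interval data frame, per contig all `+` windows then all `-`.
#' @export
sliding_windows <- function(genome, window = 40L, step = 1L) {
  window <- as.integer(window)
  step <- as.integer(step)
  stopifnot(window >= 1L, step >= 1L)
  parts <- lapply(names(genome), function(ct) {
    L <- nchar(genome[[ct]])
    if (L < window) return(NULL)
    starts <- seq.int(0L, L - window, by = step)
    data.frame(chrom = ct,
               start = rep(starts, 2L),
               end = rep(starts + window, 2L),
               name = ".", score = 0,
               strand = rep(c("+", "-"), each = length(starts)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- genomic_intervals(character(0), integer(0), integer(0),
                             character(0))
  rownames(out) <- NULL
  out
}

#' Scan a genome for promoters with a sliding window
#'
#' Slides a 40-nt window over every contig with the given step and scores
#' each window on both strands: a `+` window is scored on the forward slice,
#' a `-` window on its reverse complement (the backwards-strand
#' configuration). Windows are encoded and scored in batches so that at no
#' point are all encoded windows held in memory. Increasing the step speeds
#' the scan roughly proportionally at the cost of positional resolution.
#'
#' @param model Fitted [promoter_rf()] model.
#' @param genome Genome.
#' @param step Step size in bp (default 1, paper-faithful).
#' @param batch Number of windows encoded and scored per batch.
#' @param num_threads Threads for prediction.
#' @return Prediction track: interval data frame sorted by
#'   (contig, start, strand) whose `score` column is the promoter
#'   probability of each 40-nt window.
#' @export
scan_genome <- function(model, genome, step = 1L, batch = 20000L,
                        num_threads = 1L) {
  step <- as.integer(step)
  batch <- as.integer(batch)
  stopifnot(inherits(model, "promoter_rf"), step >= 1L, batch >= 1L)
  window <- 40L
  parts <- list()
  for (ct in names(genome)) {
    L <- nchar(genome[[ct]])
    if (L < window) {
      message("contig ", ct, " (", L, " bp) is shorter than the ", window,
              "-nt window; skipped")
      next
    }
    starts <- seq.int(0L, L - window, by = step)
    for (sd_ in c("+", "-")) {
      probs <- numeric(length(starts))
      for (lo in seq.int(1L, length(starts), by = batch)) {
        hi <- min(lo + batch - 1L, length(starts))
        seqs <- substring(genome[[ct]], starts[lo:hi] + 1L,
                          starts[lo:hi] + window)
        if (sd_ == "-") seqs <- reverse_complement(seqs)
        x <- encode_sequences(seqs, model$encoder)
        probs[lo:hi] <- predict_proba_matrix(model, x, num_threads)
      }
      parts[[paste(ct, sd_)]] <- data.frame(
        chrom = ct, start = starts, end = starts + window,
        name = ".", score = probs, strand = sd_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(parts))
    return(genomic_intervals(character(0), integer(0), integer(0),
                             character(0)))
  out <- do.call(rbind, parts)
  out <- out[order(out$chrom, out$start, match(out$strand, c("+", "-"))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep predictions at or above a probability cutoff
#'
#' @param predictions Prediction track from [scan_genome()].
#' @param tau Probability threshold in `[0, 1]`.
#' @return The subset with `score >= tau`, order preserved.
#' @export
threshold_predictions <- function(predictions, tau) {
  stopifnot(tau >= 0, tau <= 1)
  out <- predictions[predictions$score >= tau, , drop = FALSE]
  rownames(out) <- NULL
  out
}
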