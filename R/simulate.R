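#' Simulate a bacterial genome with planted promoters
#'
#' Generates a single-contig genome of i.i.d. bases at the requested GC
#' content and plants `n_promoters` non-overlapping 40-nt promoters, each
#' carrying a (possibly degenerate) Pribnow-box-like motif at a fixed
#' offset relative to its TSS. Strands alternate +/- along the genome so
#' both strand code paths are exercised. Each motif base is independently
#' randomised (uniformly over A, C, G, T) with probability
#' `mutation_rate`, which keeps classifiers from being trivially perfect
#' and gives PR curves shape. Fully deterministic per seed.
#'
#' Position convention: promoter positions are labelled -39 ... 0 relative
#' to the TSS, position 0 adjacent to the TSS; the default
#' `motif_offset = -12` places `TATAAT` at positions -12 ... -7, i.e. at
#' 1-based offset 28 ... 33 of the 40-mer -- the canonical sigma-70 -10
#' element.
#'
#' @param length Genome length in bp (default 1e6). Must exceed
#'   `200 * n_promoters` so placement stays feasible.
#' @param gc GC content of the background, in (0, 1) (default 0.5).
#' @param n_promoters Number of planted promoters (default 500).
#' @param motif Motif string planted in each promoter (default `"TATAAT"`).
#' @param motif_offset Position label of the motif's first base
#'   (default -12).
#' @param mutation_rate Per-base probability that a motif base is
#'   randomised (default 0.15).
#' @param seed Integer seed.
#' @param contig Contig identifier (default `"chr"`).
#' @return List with `genome` (named character vector), `tss` (width-1
#'   interval data frame) and `truth` (the 40-nt promoter intervals).
#' @export
simulate_genome <- function(length = 1e6, gc = 0.5, n_promoters = 500L,
                            motif = "TATAAT", motif_offset = -12L,
                            mutation_rate = 0.15, seed = 1L,
                            contig = "chr") {
  stopifnot(gc > 0, gc < 1, length >= 100, n_promoters >= 1L,
            mutation_rate >= 0, mutation_rate <= 1)
  if (n_promoters * 200 >= length)
    stop("placement infeasible: need length > 200 * n_promoters")
  width <- 40L
  mstart <- motif_offset + width  # 1-based offset within the 40-mer
  if (mstart < 1L || mstart + nchar(motif) - 1L > width)
    stop("motif does not fit inside the ", width,
         "-nt promoter at offset ", motif_offset)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  bg_prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  g <- sample(bases, length, replace = TRUE, prob = bg_prob)

  # promoter window starts: rejection-filter random draws to >= 40 bp apart
  valid_max <- length - width - 1L
  starts <- integer(0)
  tries <- 0L
  while (base::length(starts) < n_promoters) {
    tries <- tries + 1L
    if (tries > 200L)
      stop("promoter placement exhausted its retry budget; ",
           "reduce n_promoters or enlarge the genome")
    cand <- sort(unique(c(starts, sample.int(valid_max, 2L * n_promoters))))
    keep <- integer(0)
    last_end <- -1L
    for (s in cand) {
      if (s > last_end) {
        keep <- c(keep, s)
        last_end <- s + width - 1L
      }
    }
    starts <- if (base::length(keep) >= n_promoters)
      keep[sort(sample.int(base::length(keep), n_promoters))] else keep
  }
  strand <- rep_len(c("+", "-"), n_promoters)

  mot <- strsplit(motif, "")[[1]]
  for (i in seq_len(n_promoters)) {
    s <- starts[i]
    promo <- sample(bases, width, replace = TRUE, prob = bg_prob)
    mut <- stats::runif(base::length(mot)) < mutation_rate
    planted <- ifelse(mut, sample(bases, base::length(mot), replace = TRUE),
                      mot)
    promo[mstart:(mstart + base::length(mot) - 1L)] <- planted
    if (strand[i] == "-")
      promo <- rev(chartr("ACGT", "TGCA", promo))
    g[(s + 1L):(s + width)] <- promo
  }
  genome <- structure(paste(g, collapse = ""), names = contig)

  tss_pos <- ifelse(strand == "+", starts + width, starts - 1L)
  tss <- genomic_intervals(contig, tss_pos, tss_pos + 1L, strand,
                           name = sprintf("tss%d", seq_len(n_promoters)))
  truth <- genomic_intervals(contig, starts, starts + width, strand,
                             name = sprintf("prom%d", seq_len(n_promoters)))
  list(genome = genome, tss = tss, truth = truth)
}

#' Canonical synthetic benchmark bundle
#'
#' The fixture used throughout the test-suite and worked examples: a 1 Mbp
#' genome at GC 0.5 with 500 planted promoters (motif mutation rate 0.15),
#' its TSS map split in half into a training and a validation set of 250
#' TSS each, with labelled sequence sets at the 1:10 (training) and 1:1
#' (validation) class ratios. Negative sampling excludes every planted
#' promoter, so neither set carries label noise.
#'
#' @param seed Integer seed (default 42).
#' @return List with `genome`, `tss`, `truth`, `train` (250 positives +
#'   2500 negatives) and `validation` (250 positives + 250 negatives).
#' @export
default_benchmark <- function(seed = 42L) {
  sim <- simulate_genome(length = 1e6, gc = 0.5, n_promoters = 500L,
                         mutation_rate = 0.15, seed = seed)
  n <- nrow(sim$tss)
  train_ix <- seq_len(n) %% 2L == 1L  # alternate, so both halves span the genome
  build_half <- function(ix, ratio, sub_seed) {
    pos <- deduplicate_intervals(promoter_intervals(sim$tss[ix, ],
                                                    sim$genome))
    neg <- sample_negative_intervals(sim$genome, ratio * nrow(pos),
                                     exclude = sim$truth, seed = sub_seed)
    iv <- rbind(pos, neg)
    ds <- data.frame(sequence = fetch_sequence(sim$genome, iv),
                     label = rep(c(1L, 0L), c(nrow(pos), nrow(neg))),
                     chrom = iv$chrom, start = iv$start, end = iv$end,
                     strand = iv$strand, stringsAsFactors = FALSE)
    set.seed(sub_seed + 1L)
    ds <- ds[sample.int(nrow(ds)), , drop = FALSE]
    rownames(ds) <- NULL
    attr(ds, "neg_per_pos") <- ratio
    ds
  }
  list(genome = sim$genome, tss = sim$tss, truth = sim$truth,
       train = build_half(train_ix, 10L, seed + 1L),
       validation = build_half(!train_ix, 1L, seed + 2L))
}
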