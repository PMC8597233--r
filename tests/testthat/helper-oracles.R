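# Brute-force reference implementations used as independent oracles.
# They are deliberately naive (all-pairs loops, dictionary counting,
# exhaustive threshold enumeration) and share no code with the package
# internals they check.

oracle_overlap <- function(windows, truth, min_frac = 0.1) {
  out <- logical(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    wlen <- windows$end[i] - windows$start[i]
    need <- ceiling(min_frac * wlen)
    for (j in seq_len(nrow(truth))) {
      if (windows$chrom[i] != truth$chrom[j]) next
      if (windows$strand[i] != truth$strand[j]) next
      ov <- min(windows$end[i], truth$end[j]) -
        max(windows$start[i], truth$start[j])
      if (ov >= need) { out[i] <- TRUE; break }
    }
  }
  out
}

oracle_distance <- function(s1, e1, s2, e2) {
  ov <- min(e1, e2) - max(s1, s2)
  if (ov > 0) 0L else 1L - ov
}

oracle_cluster <- function(pred, truth, max_dist = 100L, k = 5L) {
  tp <- logical(nrow(pred))
  for (j in seq_len(nrow(truth))) {
    d <- rep(Inf, nrow(pred))
    for (i in seq_len(nrow(pred))) {
      if (pred$chrom[i] != truth$chrom[j]) next
      d[i] <- oracle_distance(pred$start[i], pred$end[i],
                              truth$start[j], truth$end[j])
    }
    ord <- order(d, pred$start)
    near <- ord[d[ord] < max_dist]
    tp[head(near, k)] <- TRUE
  }
  tp
}

oracle_tetra <- function(seq) {
  b <- c("A", "C", "G", "T")
  kmers <- paste0(rep(b, each = 64), rep(rep(b, each = 16), 4),
                  rep(rep(b, each = 4), 16), rep(b, 64))
  counts <- setNames(numeric(256), kmers)
  n_valid <- 0L
  for (i in seq_len(nchar(seq) - 3L)) {
    w <- substr(seq, i, i + 3L)
    if (grepl("N", w, fixed = TRUE)) next
    counts[w] <- counts[w] + 1
    n_valid <- n_valid + 1L
  }
  if (n_valid > 0L) counts <- counts / n_valid
  counts
}

# Exhaustive threshold enumeration: one confusion matrix per candidate
# threshold, PR area by step integration over recall increments, ROC area
# by trapezoids.
oracle_pr_roc <- function(labels, scores) {
  taus <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1); N <- sum(labels == 0)
  rec <- prec <- fpr <- numeric(length(taus))
  for (t in seq_along(taus)) {
    pos <- scores >= taus[t]
    tp <- sum(pos & labels == 1)
    fp <- sum(pos & labels == 0)
    prec[t] <- tp / max(tp + fp, 1)
    rec[t] <- tp / P
    fpr[t] <- fp / N
  }
  auprc <- sum(diff(c(0, rec)) * prec)
  xs <- c(0, fpr); ys <- c(0, rec)
  auroc <- sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
  list(auprc = auprc, auroc = auroc)
}

random_sequences <- function(n, len = 40L, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""), "")
}

random_interval_set <- function(n, span = 2000L, width_range = c(20L, 60L),
                                chroms = c("c1", "c2")) {
  w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  s <- sample.int(span, n, replace = TRUE) - 1L
  genomic_intervals(sample(chroms, n, replace = TRUE), s, s + w,
                    sample(c("+", "-"), n, replace = TRUE),
                    score = runif(n))
}

# Small trained model shared across scanner/importance tests (fit once per
# test run).
toy_model_cache <- new.env(parent = emptyenv())
toy_separable_model <- function() {
  if (!is.null(toy_model_cache$m)) return(toy_model_cache$m)
  set.seed(11)
  pos <- strrep("A", 40)
  neg <- strrep("T", 40)
  ds <- data.frame(sequence = rep(c(pos, neg), each = 25),
                   label = rep(c(1L, 0L), each = 25),
                   stringsAsFactors = FALSE)
  toy_model_cache$m <- promoter_rf(ds, "hot", trees = 30L,
                                   mtry_rule = "log2", tune = FALSE,
                                   seed = 4L)
  toy_model_cache$m
}

small_sim_cache <- new.env(parent = emptyenv())
small_sim_model <- function() {
  if (!is.null(small_sim_cache$v)) return(small_sim_cache$v)
  sim <- simulate_genome(length = 60000, n_promoters = 40, seed = 7)
  ds <- build_dataset(sim$genome, sim$tss, neg_per_pos = 5, seed = 3)
  m <- promoter_rf(ds, "hot", trees = 50L, mtry_rule = "log2",
                   tune = FALSE, seed = 5)
  small_sim_cache$v <- list(sim = sim, ds = ds, model = m)
  small_sim_cache$v
}
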