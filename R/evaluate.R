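# The three assessment schemes: overlap-based genome-wide labelling
# (>= 10% of the predicted window shared with a same-strand true promoter),
# cluster-based labelling (the k = 5 predictions nearest each true promoter
# and closer than 100 nt are true positives), and balanced-set evaluation
# (AUPRC/AUROC plus MCC and accuracy at probability 0.5).

#' Label windows by overlap with true promoters
#'
#' A window is positive iff some true promoter on the same contig and strand
#' shares at least `ceiling(min_frac * window_length)` bp with it (the
#' semantics of `bedtools intersect -s -f 0.1` with the window as query).
#'
#' @param windows Interval data frame of predicted/scanned windows.
#' @param truth Interval data frame of true promoter spans.
#' @param min_frac Minimum overlap as a fraction of the window length
#'   (default 0.1).
#' @return Logical vector, one element per window row.
#' @export
label_by_overlap <- function(windows, truth, min_frac = 0.1) {
  stopifnot(min_frac > 0, min_frac <= 1)
  validate_intervals(windows, "window")
  validate_intervals(truth, "truth interval")
  n <- nrow(windows)
  lab <- logical(n)
  if (n == 0L || nrow(truth) == 0L) return(lab)
  wlen <- windows$end - windows$start
  thr <- as.integer(ceiling(min_frac * wlen))
  grp_w <- paste(windows$chrom, windows$strand)
  grp_t <- paste(truth$chrom, truth$strand)
  for (g in intersect(unique(grp_w), unique(grp_t))) {
    wi <- which(grp_w == g)
    ti <- which(grp_t == g)
    ord <- wi[order(windows$start[wi])]
    ws <- windows$start[ord]
    we <- windows$end[ord]
    thro <- thr[ord]
    maxw <- max(we - ws)
    for (j in ti) {
      ts <- truth$start[j]; te <- truth$end[j]
      lo <- findInterval(ts - maxw, ws) + 1L
      hi <- findInterval(te - 1L, ws)
      if (hi < lo) next
      cand <- lo:hi
      ov <- pmin(we[cand], te) - pmax(ws[cand], ts)
      hit <- cand[ov >= thro[cand]]
      lab[ord[hit]] <- TRUE
    }
  }
  lab
}

# Gap distance between half-open intervals on the same contig: 0 when they
# share a base, 1 when bookended, else the number of bases separating them
# plus one (bedtools closest -d reporting).
interval_distance <- function(s1, e1, s2, e2) {
  ov <- pmin(e1, e2) - pmax(s1, s2)
  ifelse(ov > 0L, 0L, 1L - ov)
}

# For every truth row, the predictions within max_dist (strand-blind),
# ordered by (distance, start). Returns a list of data.frames (idx, dist).
cluster_candidates <- function(predictions, truth, max_dist) {
  out <- vector("list", nrow(truth))
  if (nrow(predictions) == 0L) {
    out[] <- list(data.frame(idx = integer(0), dist = integer(0)))
    return(out)
  }
  plen_max <- max(predictions$end - predictions$start)
  for (ct in unique(truth$chrom)) {
    pi <- which(predictions$chrom == ct)
    ord <- pi[order(predictions$start[pi])]
    ps <- predictions$start[ord]; pe <- predictions$end[ord]
    for (j in which(truth$chrom == ct)) {
      ts <- truth$start[j]; te <- truth$end[j]
      lo <- findInterval(ts - max_dist - plen_max, ps) + 1L
      hi <- findInterval(te + max_dist, ps)
      if (hi < lo) {
        out[[j]] <- data.frame(idx = integer(0), dist = integer(0))
        next
      }
      cand <- lo:hi
      d <- interval_distance(ps[cand], pe[cand], ts, te)
      keep <- d < max_dist
      cand <- cand[keep]; d <- d[keep]
      o <- order(d, ps[cand])
      out[[j]] <- data.frame(idx = ord[cand][o], dist = d[o])
    }
  }
  for (j in seq_along(out))
    if (is.null(out[[j]]))
      out[[j]] <- data.frame(idx = integer(0), dist = integer(0))
  out
}

#' Label predictions by the cluster criterion
#'
#' For each true promoter, its `k` nearest predictions (gap distance;
#' overlapping intervals have distance 0; ties broken by leftmost start)
#' that lie strictly closer than `max_dist` nt are true positives. A
#' prediction marked by any truth counts once; all other predictions are
#' false positives. Matching is strand-blind.
#'
#' @param predictions Prediction track (interval data frame).
#' @param truth True promoter intervals.
#' @param max_dist Distance cutoff in nt (default 100, strict).
#' @param k Nearest predictions considered per truth (default 5).
#' @return Logical vector: `TRUE` for TP predictions, `FALSE` for FP.
#' @export
label_by_cluster <- function(predictions, truth, max_dist = 100L, k = 5L) {
  stopifnot(max_dist >= 0L, k >= 1L)
  validate_intervals(predictions, "prediction")
  validate_intervals(truth, "truth interval")
  tp <- logical(nrow(predictions))
  if (nrow(predictions) == 0L || nrow(truth) == 0L) return(tp)
  cand <- cluster_candidates(predictions, truth, max_dist)
  for (cc in cand)
    if (nrow(cc)) tp[utils::head(cc$idx, k)] <- TRUE
  tp
}

#' Precision-recall and ROC curves with their areas
#'
#' Sweeps every distinct score as a threshold (descending). The PR area is
#' the step-wise integral `sum((R_i - R_{i-1}) * P_i)` (right-constant
#' precision); the ROC area is the trapezoidal integral.
#'
#' @param labels Binary vector (1 positive, 0 negative); both classes must
#'   be present.
#' @param scores Numeric scores aligned with `labels`.
#' @param mode Tag recorded on the result (`"overlap"`, `"cluster"`,
#'   `"balanced"`, or the default `"scores"`).
#' @return A `prom_eval` object: list with `pr` (recall, precision), `roc`
#'   (fpr, tpr), `auprc`, `auroc`, `n_pos`, `n_total`, `mode`.
#' @export
pr_roc <- function(labels, scores, mode = "scores") {
  labels <- as.integer(labels)
  if (length(labels) != length(scores))
    stop("labels and scores must have the same length")
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0L || N == 0L)
    stop("both classes must be present to compute PR/ROC curves")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  last <- c(which(diff(s) != 0), length(s))  # end of each tie block
  tp <- cumsum(l)[last]
  fp <- cumsum(1L - l)[last]
  precision <- tp / (tp + fp)
  recall <- tp / P
  fpr <- fp / N
  auprc <- sum(diff(c(0, recall)) * precision)
  xs <- c(0, fpr); ys <- c(0, recall)
  auroc <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  structure(list(mode = mode,
                 pr = data.frame(recall = recall, precision = precision),
                 roc = data.frame(fpr = fpr, tpr = recall),
                 auprc = auprc, auroc = auroc,
                 n_pos = P, n_total = P + N),
            class = "prom_eval")
}

#' @export
print.prom_eval <- function(x, ...) {
  cat(sprintf("Promoter evaluation [%s]: AUPRC %.4f, AUROC %.4f (%d/%d positives)\n",
              x$mode, x$auprc, x$auroc, x$n_pos, x$n_total))
  if (!is.null(x$mcc))
    cat(sprintf("  at p >= 0.5: MCC %.4f, accuracy %.4f\n",
                x$mcc, x$accuracy))
  invisible(x)
}

#' Genome-wide evaluation of a prediction track
#'
#' `mode = "overlap"`: every scanned window is labelled by
#' [label_by_overlap()] and the PR/ROC curves come from a full threshold
#' sweep of the window probabilities. `mode = "cluster"`: for each threshold
#' on a quantile grid of the scores, the retained predictions are
#' re-matched with [label_by_cluster()]; precision is TP predictions over
#' retained predictions, recall is the fraction of true promoters with at
#' least one TP among their `k` nearest retained predictions, and the
#' false-positive rate denominator is the number of windows minus the
#' number of true promoters.
#'
#' @param predictions Prediction track from [scan_genome()].
#' @param truth True promoter intervals.
#' @param mode `"overlap"` or `"cluster"`.
#' @param min_frac Overlap fraction for overlap mode (default 0.1).
#' @param max_dist,k Cluster-mode matching parameters (defaults 100 nt, 5).
#' @param n_thresholds Size of the cluster-mode threshold grid (default 200).
#' @return A `prom_eval` object.
#' @export
evaluate_genome_wide <- function(predictions, truth,
                                 mode = c("overlap", "cluster"),
                                 min_frac = 0.1, max_dist = 100L, k = 5L,
                                 n_thresholds = 200L) {
  mode <- match.arg(mode)
  if (nrow(truth) == 0L) stop("truth set is empty; nothing to evaluate")
  if (mode == "overlap") {
    lab <- label_by_overlap(predictions, truth, min_frac)
    return(pr_roc(as.integer(lab), predictions$score, mode = "overlap"))
  }
  cand <- cluster_candidates(predictions, truth, max_dist)
  taus <- sort(unique(stats::quantile(
    predictions$score, probs = seq(0, 1, length.out = n_thresholds),
    names = FALSE, type = 1)), decreasing = TRUE)
  n_truth <- nrow(truth)
  neg_denom <- max(nrow(predictions) - n_truth, 1L)
  precision <- recall <- fpr <- numeric(length(taus))
  score <- predictions$score
  for (t in seq_along(taus)) {
    tau <- taus[t]
    n_ret <- sum(score >= tau)
    tp_idx <- integer(0); matched <- 0L
    for (cc in cand) {
      sel <- utils::head(cc$idx[score[cc$idx] >= tau], k)
      if (length(sel)) {
        matched <- matched + 1L
        tp_idx <- c(tp_idx, sel)
      }
    }
    n_tp <- length(unique(tp_idx))
    precision[t] <- if (n_ret > 0L) n_tp / n_ret else 1
    recall[t] <- matched / n_truth
    fpr[t] <- min((n_ret - n_tp) / neg_denom, 1)
  }
  auprc <- sum(diff(c(0, recall)) * precision)
  xs <- c(0, fpr, 1); ys <- c(0, recall, 1)
  o <- order(xs, ys)
  xs <- xs[o]; ys <- ys[o]
  auroc <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  structure(list(mode = "cluster",
                 pr = data.frame(recall = recall, precision = precision),
                 roc = data.frame(fpr = fpr, tpr = recall),
                 auprc = auprc, auroc = auroc,
                 n_pos = n_truth, n_total = nrow(predictions)),
            class = "prom_eval")
}

#' Balanced-set evaluation of a fitted model
#'
#' Scores each labelled sequence, computes PR/ROC curves with areas, and
#' adds the Matthews correlation coefficient and accuracy at a probability
#' threshold of 0.5 (MCC defined as 0 when its denominator vanishes).
#'
#' @param model Fitted [promoter_rf()] model.
#' @param ds Labelled set with `sequence` and `label` columns.
#' @param threshold Classification threshold (default 0.5).
#' @return A `prom_eval` object with extra fields `mcc` and `accuracy`.
#' @export
evaluate_balanced <- function(model, ds, threshold = 0.5) {
  probs <- predict(model, ds)
  ev <- pr_roc(ds$label, probs, mode = "balanced")
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1L & ds$label == 1L)
  tn <- sum(pred == 0L & ds$label == 0L)
  fp <- sum(pred == 1L & ds$label == 0L)
  fn <- sum(pred == 0L & ds$label == 1L)
  denom <- sqrt(prod(as.numeric(c(tp + fp, tp + fn, tn + fp, tn + fn))))
  ev$mcc <- if (denom == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / denom
  ev$accuracy <- (tp + tn) / length(probs)
  ev$threshold <- threshold
  ev
}

#' Expected AUPRC of a random classifier
#'
#' Equals the positive prevalence: with `n_pos` true promoters among
#' `n_total` candidate windows, random scoring attains an AUPRC of
#' `n_pos / n_total` in expectation -- the baseline against which
#' genome-wide AUPRC values must be read.
#'
#' @param n_pos Number of positives.
#' @param n_total Total number of instances.
#' @return The prevalence `n_pos / n_total`.
#' @export
baseline_auprc <- function(n_pos, n_total) {
  stopifnot(n_pos >= 0, n_total > 0, n_pos <= n_total)
  n_pos / n_total
}
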