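# Model interpretation: impurity-based (mean decrease in Gini) and
# permutation-based (mean decrease in accuracy) feature importance, and the
# per-position / per-nucleotide profile that makes the learned Pribnow box
# visible.

new_importance_ranking <- function(feature, mean, sd, method,
                                   n_repeats = NA_integer_) {
  o <- order(-mean)
  structure(data.frame(feature = feature[o], mean = mean[o], sd = sd[o],
                       stringsAsFactors = FALSE),
            method = method, n_repeats = n_repeats,
            class = c("importance_ranking", "data.frame"))
}

#' @export
print.importance_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("Feature importance (%s), top %d of %d:\n",
              attr(x, "method"), min(n, nrow(x)), nrow(x)))
  top <- utils::head(x, n)
  cat(sprintf("  %2d. %-10s %.4f +/- %.4f\n", seq_len(nrow(top)),
              top$feature, top$mean, top$sd), sep = "")
  invisible(x)
}

#' Impurity-based feature importance with across-tree spread
#'
#' Computes, for every tree of the fitted forest, the class-weighted Gini
#' impurity decrease attributable to each feature by routing the tree's
#' in-bag samples through its stored splits; each tree's vector is
#' normalised to sum 1 and the ranking reports the mean and standard
#' deviation across trees (so the means again sum to 1). This is the
#' normalised mean-decrease-in-impurity convention; the package's aggregate
#' agrees in ranking with the ensemble's own impurity importance.
#'
#' @param model Fitted [promoter_rf()] model.
#' @return An `importance_ranking`: data frame (`feature`, `mean`, `sd`)
#'   sorted by decreasing mean.
#' @export
impurity_importance <- function(model) {
  stopifnot(inherits(model, "promoter_rf"))
  x <- model$train$x
  y1 <- model$train$y == "1"
  cwv <- ifelse(y1, model$class_weights[["1"]], model$class_weights[["0"]])
  p <- ncol(x)
  ntree <- model$forest$num.trees
  per_tree <- matrix(0, ntree, p)
  for (b in seq_len(ntree)) {
    ti <- ranger::treeInfo(model$forest, b)
    w <- model$forest$inbag.counts[[b]] * cwv
    wpos <- w * y1
    imp <- numeric(p)
    rowsets <- vector("list", nrow(ti))
    rowsets[[1]] <- which(w > 0)
    for (nd in seq_len(nrow(ti))) {
      if (ti$terminal[nd]) next
      idx <- rowsets[[nd]]
      rowsets[nd] <- list(NULL)
      li <- ti$leftChild[nd] + 1L
      ri <- ti$rightChild[nd] + 1L
      if (length(idx) == 0L) {
        rowsets[[li]] <- integer(0); rowsets[[ri]] <- integer(0)
        next
      }
      sv <- ti$splitvarID[nd] + 1L
      left <- x[idx, sv] <= ti$splitval[nd]
      idx_l <- idx[left]; idx_r <- idx[!left]
      rowsets[[li]] <- idx_l; rowsets[[ri]] <- idx_r
      gini_w <- function(ix) {
        N <- sum(w[ix])
        if (N == 0) return(c(0, 0))
        n1 <- sum(wpos[ix])
        c(N, N * (1 - ((n1 / N)^2 + ((N - n1) / N)^2)))
      }
      gp <- gini_w(idx); gl <- gini_w(idx_l); gr <- gini_w(idx_r)
      imp[sv] <- imp[sv] + (gp[2] - gl[2] - gr[2])
    }
    tot <- sum(imp)
    if (tot > 0) per_tree[b, ] <- imp / tot
  }
  new_importance_ranking(colnames(x), colMeans(per_tree),
                         apply(per_tree, 2L, stats::sd),
                         method = "impurity")
}

#' Permutation-based feature importance (mean decrease in accuracy)
#'
#' Shuffles one feature column at a time (`n_repeats` independent
#' permutations each), re-scores the evaluation set, and reports the mean
#' and standard deviation of the accuracy drop at probability threshold
#' 0.5. A feature carrying no label information scores 0 in expectation.
#'
#' @param model Fitted [promoter_rf()] model.
#' @param data Evaluation set: labelled data frame (`sequence`, `label`) or
#'   list with `x` (encoded matrix) and `y` (0/1 labels). Typically the
#'   held-out split, not the training data.
#' @param n_repeats Permutations per feature (default 5).
#' @param seed Integer seed.
#' @param num_threads Threads for prediction.
#' @return An `importance_ranking` sorted by decreasing mean accuracy drop.
#' @export
permutation_importance <- function(model, data, n_repeats = 5L, seed = 1L,
                                   num_threads = 1L) {
  stopifnot(inherits(model, "promoter_rf"))
  n_repeats <- as.integer(n_repeats)
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  if (is.data.frame(data)) {
    x <- encode_sequences(data, model$encoder)
    y <- as.integer(data$label)
  } else {
    x <- data$x
    y <- as.integer(data$y)
  }
  if (length(unique(y)) < 2L)
    stop("evaluation set must contain both classes")
  acc <- function(m) mean((predict_proba_matrix(model, m, num_threads) >=
                             0.5) == (y == 1L))
  base <- acc(x)
  p <- ncol(x)
  set.seed(seed)
  drops <- matrix(0, n_repeats, p)
  for (j in seq_len(p)) {
    if (length(unique(x[, j])) == 1L) next  # constant column: no information
    for (r in seq_len(n_repeats)) {
      xp <- x
      xp[, j] <- x[sample.int(nrow(x)), j]
      drops[r, j] <- base - acc(xp)
    }
  }
  new_importance_ranking(colnames(x), colMeans(drops),
                         apply(drops, 2L, stats::sd),
                         method = "permutation", n_repeats = n_repeats)
}

#' Per-position, per-nucleotide importance profile
#'
#' Reshapes a 160-feature ranking from an RF-HOT model into a 40 x 4 matrix
#' (positions -39 ... 0 relative to the TSS, position 0 adjacent to the
#' TSS; channels A, G, C, T). Total score is conserved.
#'
#' @param ranking An `importance_ranking` over the one-hot features.
#' @return Numeric 40 x 4 matrix with position row names and nucleotide
#'   column names.
#' @export
position_profile <- function(ranking) {
  m <- regmatches(ranking$feature,
                  regexec("^pos(-?[0-9]+):([AGCT])$", ranking$feature))
  if (nrow(ranking) != 160L || any(lengths(m) != 3L))
    stop("position_profile needs the 160 positional one-hot features ",
         "(an RF-HOT ranking)")
  pos <- vapply(m, function(z) as.integer(z[2]), 0L)
  base <- vapply(m, function(z) z[3], "")
  out <- matrix(0, 40L, 4L,
                dimnames = list(as.character(-39:0), ONE_HOT_BASES))
  out[cbind(as.character(pos), base)] <- ranking$mean
  out
}

#' Plot the positional importance profile of an RF-HOT model
#'
#' Stacked bars of impurity importance per promoter position (-39 ... 0
#' relative to the TSS), split by nucleotide channel. For a model trained
#' on genuine promoters the A/T channels dominate around positions -12 to
#' -7, the Pribnow box.
#'
#' @param x Fitted [promoter_rf()] model with `encoder = "hot"`.
#' @param ranking Optional precomputed `importance_ranking`; defaults to
#'   [impurity_importance()] of the model.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the 40 x 4 profile matrix.
#' @export
plot.promoter_rf <- function(x, ranking = NULL, ...) {
  if (x$encoder != "hot")
    stop("positional profiles are defined for RF-HOT models only")
  if (is.null(ranking)) ranking <- impurity_importance(x)
  prof <- position_profile(ranking)
  graphics::barplot(t(prof), beside = FALSE,
                    col = c("#1b9e77", "#d95f02", "#7570b3", "#e7298a"),
                    border = NA, las = 2, cex.names = 0.6,
                    xlab = "position relative to TSS",
                    ylab = "impurity importance",
                    legend.text = colnames(prof), ...)
  invisible(prof)
}
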