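#' Rank genes by random-forest importance for the subtype labels
#'
#' Fits an ensemble of randomized CART trees (Gini splits, per-split random
#' feature subsets of size `mtry`, bootstrap bagging) to predict the
#' subtype labels, and scores every gene by permutation importance: the
#' mean out-of-bag accuracy decrease when that gene's values are permuted
#' among the out-of-bag samples. Impurity (total Gini decrease) importance
#' is available as an alternative.
#'
#' @param expr_scaled genes x samples matrix (z-scored by convention).
#' @param labels per-sample class labels (2+ classes, >= 2 samples each),
#'   named by sample id or in column order.
#' @param n_trees ensemble size.
#' @param seed integer RNG seed; the ranking is deterministic given it.
#' @param mtry features tried per split (default `floor(sqrt(p))`).
#' @param max_depth maximum tree depth.
#' @param min_node minimum samples in a splittable node.
#' @param importance `"permutation"` (OOB accuracy decrease) or
#'   `"impurity"` (total Gini decrease).
#' @return data frame `gene`, `importance`, `rank` (1 = most important),
#'   sorted by rank; ties broken by gene id.
#' @export
rank_importance <- function(expr_scaled, labels, n_trees = 500, seed = 1,
                            mtry = NULL, max_depth = 8, min_node = 5,
                            importance = c("permutation", "impurity")) {
  importance <- match.arg(importance)
  stopifnot(is.matrix(expr_scaled))
  if (!is.null(names(labels))) labels <- labels[colnames(expr_scaled)]
  y <- factor(as.character(labels))
  if (nlevels(y) < 2) stop("labels must contain at least 2 classes")
  if (any(table(y) < 2)) stop("need >= 2 samples per class")
  X <- t(expr_scaled)
  n <- nrow(X); p <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  set.seed(as.integer(seed))
  yi <- as.integer(y)
  K <- nlevels(y)
  imp <- numeric(p)
  gini_acc <- numeric(p)
  trees_scored <- 0L
  for (t in seq_len(n_trees)) {
    boot <- sample.int(n, n, replace = TRUE)
    oob <- which(!(seq_len(n) %in% boot))
    tree <- grow_cart(X[boot, , drop = FALSE], yi[boot], K, mtry,
                      max_depth, min_node)
    gini_acc[tree$feat_gini$feature] <-
      gini_acc[tree$feat_gini$feature] + tree$feat_gini$decrease
    if (importance == "permutation" && length(oob) > 0) {
      trees_scored <- trees_scored + 1L
      Xo <- X[oob, , drop = FALSE]
      acc0 <- mean(predict_cart(tree, Xo) == yi[oob])
      for (f in unique(tree$feat_gini$feature)) {
        Xp <- Xo
        Xp[, f] <- Xp[sample.int(length(oob)), f]
        imp[f] <- imp[f] + (acc0 - mean(predict_cart(tree, Xp) == yi[oob]))
      }
    }
  }
  score <- if (importance == "permutation") {
    if (trees_scored == 0L) stop("no out-of-bag samples in any tree")
    imp / trees_scored
  } else {
    gini_acc / n_trees
  }
  genes <- colnames(X)
  ord <- order(-score, genes)
  data.frame(gene = genes[ord], importance = score[ord],
             rank = seq_len(p), stringsAsFactors = FALSE)
}

# Grow one CART tree. X: numeric matrix (rows = samples), yi: integer class
# codes in 1..K. Nodes are stored in parallel vectors; feature/threshold
# NA marks a leaf.
grow_cart <- function(X, yi, K, mtry, max_depth, min_node) {
  feature <- integer(0); threshold <- numeric(0)
  left <- integer(0); right <- integer(0); pred <- integer(0)
  gini_feat <- integer(0); gini_dec <- numeric(0)
  new_node <- function() {
    feature[length(feature) + 1L] <<- NA_integer_
    threshold[length(threshold) + 1L] <<- NA_real_
    left[length(left) + 1L] <<- 0L
    right[length(right) + 1L] <<- 0L
    pred[length(pred) + 1L] <<- 0L
    length(feature)
  }
  p <- ncol(X)
  build <- function(idx, depth) {
    node <- new_node()
    yn <- yi[idx]
    counts <- tabulate(yn, K)
    pred[node] <<- which.max(counts)     # ties: lowest class code
    if (depth >= max_depth || length(idx) < min_node ||
        max(counts) == length(idx))
      return(node)
    feats <- sample.int(p, min(mtry, p))
    best <- best_gini_split(X[idx, feats, drop = FALSE], yn, K)
    if (is.null(best)) return(node)
    f <- feats[best$feature]
    feature[node] <<- f
    threshold[node] <<- best$threshold
    gini_feat[length(gini_feat) + 1L] <<- f
    gini_dec[length(gini_dec) + 1L] <<- best$decrease
    go_left <- X[idx, f] <= best$threshold
    left[node] <<- build(idx[go_left], depth + 1L)
    right[node] <<- build(idx[!go_left], depth + 1L)
    node
  }
  root <- build(seq_along(yi), 0L)
  list(feature = feature, threshold = threshold, left = left,
       right = right, pred = pred, root = root,
       feat_gini = data.frame(feature = gini_feat, decrease = gini_dec))
}

# Best Gini split over the columns of Xs for integer classes yn (1..K).
# Returns NULL when no column admits a split that separates the data.
best_gini_split <- function(Xs, yn, K) {
  n <- length(yn)
  parent_gini <- 1 - sum((tabulate(yn, K) / n)^2)
  best <- NULL
  best_dec <- 1e-12
  for (j in seq_len(ncol(Xs))) {
    x <- Xs[, j]
    ord <- order(x)
    xs <- x[ord]; ys <- yn[ord]
    valid <- which(xs[-n] < xs[-1])    # split between distinct values
    if (!length(valid)) next
    cum <- vapply(seq_len(K), function(k) cumsum(ys == k), numeric(n))
    if (is.null(dim(cum))) cum <- matrix(cum, nrow = n)
    nl <- valid
    left_counts <- cum[valid, , drop = FALSE]
    right_counts <- matrix(tabulate(yn, K), nrow = length(valid),
                           ncol = K, byrow = TRUE) - left_counts
    gl <- 1 - rowSums((left_counts / nl)^2)
    gr <- 1 - rowSums((right_counts / (n - nl))^2)
    dec <- parent_gini - (nl * gl + (n - nl) * gr) / n
    i <- which.max(dec)
    if (dec[i] > best_dec) {
      best_dec <- dec[i]
      best <- list(feature = j,
                   threshold = (xs[valid[i]] + xs[valid[i] + 1L]) / 2,
                   decrease = dec[i])
    }
  }
  best
}

# Predict integer class codes for the rows of X.
predict_cart <- function(tree, X) {
  vapply(seq_len(nrow(X)), function(i) {
    node <- tree$root
    while (!is.na(tree$feature[node])) {
      node <- if (X[i, tree$feature[node]] <= tree$threshold[node])
        tree$left[node] else tree$right[node]
    }
    tree$pred[node]
  }, integer(1))
}
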