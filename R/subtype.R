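#' Z-score each gene across samples
#'
#' Subtracts the per-gene mean and divides by the per-gene SD (sample SD,
#' denominator n-1). Constant genes cannot be scaled and are dropped with a
#' warning.
#'
#' @param expr genes x samples matrix.
#' @return the scaled matrix (possibly with fewer rows).
#' @export
zscore_genes <- function(expr) {
  stopifnot(is.matrix(expr))
  sds <- apply(expr, 1, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) dropped before scaling")
    expr <- expr[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (expr - rowMeans(expr)) / sds
}

#' Consensus clustering of samples into expression subtypes
#'
#' Monti-style consensus clustering: `n_reps` rounds subsample
#' `item_frac` of the samples (without replacement) and cluster them by PAM
#' (k medoids) on a 1 - Pearson-correlation distance between sample
#' profiles; the consensus matrix is the co-clustering count divided by the
#' co-sampling count. Final labels come from average-linkage hierarchical
#' clustering of 1 - consensus cut at `k`. When a clinical table is
#' supplied (and `k = 2`), clusters are relabelled so C1 is the
#' worse-prognosis cluster (log-rank observed > expected deaths; ties
#' broken by smaller mean survival time).
#'
#' @param expr_scaled genes x samples matrix, typically [zscore_genes()]
#'   output.
#' @param k number of clusters (>= 2; need >= 3k samples).
#' @param n_reps subsampling rounds.
#' @param item_frac fraction of samples drawn per round.
#' @param seed integer RNG seed.
#' @param clin optional clinical table for the C1/C2 prognosis labelling
#'   and the log-rank statistic.
#' @param distance `"pearson"` (1 - correlation between sample profiles)
#'   or `"euclidean"`.
#' @return object of class `"subtype_result"`: `labels` (named character,
#'   `"C1"`/`"C2"`/...), `consensus` matrix, `cluster_sizes`, and when
#'   `clin` is given `logrank_p` / `logrank_chi2`.
#' @export
consensus_cluster <- function(expr_scaled, k = 2, n_reps = 100,
                              item_frac = 0.8, seed = 1, clin = NULL,
                              distance = c("pearson", "euclidean")) {
  distance <- match.arg(distance)
  stopifnot(is.matrix(expr_scaled))
  n <- ncol(expr_scaled)
  if (k < 2) stop("k must be >= 2")
  if (n < 3 * k) stop("need at least 3k samples")
  samples <- colnames(expr_scaled)
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(n))
  D <- if (distance == "pearson") 1 - cor(expr_scaled)
       else as.matrix(dist(t(expr_scaled)))
  set.seed(as.integer(seed))
  co_cluster <- matrix(0, n, n)
  co_sample <- matrix(0, n, n)
  m <- max(floor(item_frac * n), k)
  for (rep in seq_len(n_reps)) {
    idx <- sort(sample.int(n, m))
    cl <- cluster::pam(D[idx, idx], k, diss = TRUE, cluster.only = TRUE,
                       pamonce = 6)
    co_sample[idx, idx] <- co_sample[idx, idx] + 1
    for (g in seq_len(k)) {
      members <- idx[cl == g]
      co_cluster[members, members] <- co_cluster[members, members] + 1
    }
  }
  if (any(co_sample == 0 & upper.tri(co_sample)))
    warning("some sample pairs were never co-sampled; consensus set to 0")
  consensus <- ifelse(co_sample > 0, co_cluster / co_sample, 0)
  diag(consensus) <- 1
  dimnames(consensus) <- list(samples, samples)
  hc <- hclust(as.dist(1 - consensus), method = "average")
  raw <- cutree(hc, k)
  labels <- setNames(paste0("C", raw), samples)
  res <- list(labels = labels, consensus = consensus,
              cluster_sizes = as.integer(table(raw)),
              logrank_p = NA_real_, logrank_chi2 = NA_real_)
  if (!is.null(clin)) {
    cg <- compare_groups(clin, labels)
    res$logrank_p <- cg$logrank_p
    res$logrank_chi2 <- cg$logrank_chi2
    if (k == 2) {
      # worse prognosis first: more observed than expected deaths
      excess <- cg$observed - cg$expected
      worse <- names(cg$km)[which.max(excess)]
      if (abs(diff(excess)) < sqrt(.Machine$double.eps)) {
        mean_time <- tapply(clin$time, labels[clin$sample], mean)
        worse <- names(which.min(mean_time))
      }
      if (worse != "C1") {
        labels <- setNames(ifelse(labels == "C1", "C2", "C1"), names(labels))
        res$labels <- labels
        res$cluster_sizes <- as.integer(table(labels))
      }
    }
  }
  class(res) <- "subtype_result"
  res
}

#' @export
print.subtype_result <- function(x, ...) {
  cat("subtype_result:", length(x$labels), "samples; sizes",
      paste(x$cluster_sizes, collapse = "/"),
      if (!is.na(x$logrank_p)) sprintf("; log-rank p = %.3g", x$logrank_p),
      "\n")
  invisible(x)
}

#' Random-gene-set null distribution of the subtype log-rank statistic
#'
#' Repeats the clustering with randomly drawn gene sets: per repetition,
#' `n_genes` genes are sampled uniformly without replacement from the
#' (zero-filtered) genome-wide matrix, z-scored, consensus-clustered into
#' k = 2 subtypes, and the two-group log-rank p is recorded as -log10(p).
#' The observed statistic from the master-gene clustering is judged against
#' this distribution.
#'
#' @param expr_full genes x samples matrix to resample genes from.
#' @param clin clinical table (`sample`, `time`, `event`).
#' @param n_genes genes per repetition (the master-gene count, by default
#'   convention of the callers).
#' @param n_reps repetitions.
#' @param seed integer RNG seed; per-repetition seeds are derived from it.
#' @param consensus_reps subsampling rounds inside each consensus run
#'   (reduce for speed; the null only needs the final labels).
#' @param item_frac subsample fraction inside each consensus run.
#' @param distance sample-profile distance handed to [consensus_cluster()].
#' @return object of class `"null_distribution"`: `neglog10_p` vector,
#'   `n_reps`, `genes_per_rep`.
#' @export
random_gene_null <- function(expr_full, clin, n_genes, n_reps = 100,
                             seed = 1, consensus_reps = 100,
                             item_frac = 0.8,
                             distance = c("pearson", "euclidean")) {
  distance <- match.arg(distance)
  stopifnot(is.matrix(expr_full))
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (nrow(expr_full) < n_genes) stop("not enough genes to sample from")
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  neglog <- vapply(seq_len(n_reps), function(r) {
    set.seed(rep_seeds[r])
    genes <- sample(rownames(expr_full), n_genes)
    sub <- suppressWarnings(zscore_genes(expr_full[genes, , drop = FALSE]))
    res <- consensus_cluster(sub, k = 2, n_reps = consensus_reps,
                             item_frac = item_frac, seed = rep_seeds[r],
                             clin = clin, distance = distance)
    -log10(res$logrank_p)
  }, numeric(1))
  structure(list(neglog10_p = neglog, n_reps = n_reps,
                 genes_per_rep = n_genes),
            class = "null_distribution")
}

#' Empirical null p-value of an observed statistic
#'
#' `(1 + #{null >= observed}) / (n + 1)`; always in (0, 1].
#'
#' @param observed observed -log10 p (or any statistic, larger = stronger).
#' @param null a [random_gene_null()] result or numeric vector.
#' @return scalar empirical p-value.
#' @export
empirical_null_p <- function(observed, null) {
  v <- if (inherits(null, "null_distribution")) null$neglog10_p else null
  (1 + sum(v >= observed)) / (length(v) + 1)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement; 1 for identical partitions, ~0 for random.
#'
#' @param a,b label vectors of equal length (names ignored; order aligned).
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  denom <- (ai + bj) / 2 - expected
  if (denom == 0) return(0)
  (nij - expected) / denom
}
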