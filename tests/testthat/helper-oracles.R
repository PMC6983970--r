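# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (except trivially shared primitives) so that
# estimator and oracle can disagree.

# ---- graphs -------------------------------------------------------------

oracle_is_acyclic <- function(amat) {
  # repeated leaf removal, independent of topological_order()
  A <- amat != 0
  repeat {
    if (nrow(A) == 0L) return(TRUE)
    sinks <- which(rowSums(A) == 0)
    if (length(sinks) == 0L) return(FALSE)
    A <- A[-sinks, -sinks, drop = FALSE]
  }
}

# v-structures of a DAG as a sorted character key "i<k>j" with i < j
oracle_vstructs <- function(amat) {
  A <- amat != 0
  out <- character()
  p <- nrow(A)
  for (k in seq_len(p)) {
    pa <- which(A[, k])
    if (length(pa) < 2) next
    for (a in seq_along(pa)) for (b in seq_along(pa)) {
      if (b <= a) next
      i <- pa[a]; j <- pa[b]
      if (!A[i, j] && !A[j, i])
        out <- c(out, paste(i, k, j, sep = "<"))
    }
  }
  sort(out)
}

oracle_skeleton_key <- function(amat) {
  S <- (amat != 0) | t(amat != 0)
  paste(which(S[upper.tri(S)]), collapse = ",")
}

# Brute-force CPDAG of a DAG: enumerate every orientation of its skeleton,
# keep the acyclic ones with identical v-structures, and take the union of
# orientations (edges directed the same way in all members stay directed).
oracle_cpdag_amat <- function(dag_amat) {
  p <- nrow(dag_amat)
  S <- (dag_amat != 0) | t(dag_amat != 0)
  edges <- which(S & upper.tri(S), arr.ind = TRUE)
  ne <- nrow(edges)
  stopifnot(ne <= 14)                  # 2^14 orientations max
  target_v <- oracle_vstructs(dag_amat)
  members <- list()
  for (code in 0:(2^ne - 1)) {
    bits <- as.logical(bitwAnd(code, 2^(seq_len(ne) - 1)))
    A <- matrix(0L, p, p)
    for (e in seq_len(ne)) {
      if (bits[e]) A[edges[e, 1], edges[e, 2]] <- 1L
      else A[edges[e, 2], edges[e, 1]] <- 1L
    }
    if (!oracle_is_acyclic(A)) next
    if (!identical(oracle_vstructs(A), target_v)) next
    members[[length(members) + 1L]] <- A
  }
  stopifnot(length(members) >= 1)
  out <- matrix(0L, p, p)
  for (e in seq_len(ne)) {
    i <- edges[e, 1]; j <- edges[e, 2]
    fwd <- all(vapply(members, function(A) A[i, j] == 1L, logical(1)))
    bwd <- all(vapply(members, function(A) A[j, i] == 1L, logical(1)))
    if (fwd) out[i, j] <- 1L
    else if (bwd) out[j, i] <- 1L
    else { out[i, j] <- 1L; out[j, i] <- 1L }
  }
  out
}

# All labeled DAGs on n nodes as 0/1 adjacency matrices (n <= 4 practical;
# for n = 5 use enumerate_dag_classes below).
enumerate_all_dags <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  np <- nrow(pairs)
  out <- list()
  for (code in 0:(3^np - 1)) {
    states <- integer(np)
    c0 <- code
    for (e in seq_len(np)) { states[e] <- c0 %% 3; c0 <- c0 %/% 3 }
    A <- matrix(0L, n, n)
    for (e in seq_len(np)) {
      if (states[e] == 1L) A[pairs[e, 1], pairs[e, 2]] <- 1L
      if (states[e] == 2L) A[pairs[e, 2], pairs[e, 1]] <- 1L
    }
    if (oracle_is_acyclic(A)) out[[length(out) + 1L]] <- A
  }
  out
}

# One representative DAG per Markov-equivalence class (skeleton +
# v-structures) over all labeled DAGs on n nodes.
enumerate_dag_classes <- function(n) {
  reps <- list()
  seen <- new.env(hash = TRUE)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  np <- nrow(pairs)
  for (code in 0:(3^np - 1)) {
    states <- integer(np)
    c0 <- code
    for (e in seq_len(np)) { states[e] <- c0 %% 3; c0 <- c0 %/% 3 }
    A <- matrix(0L, n, n)
    for (e in seq_len(np)) {
      if (states[e] == 1L) A[pairs[e, 1], pairs[e, 2]] <- 1L
      if (states[e] == 2L) A[pairs[e, 2], pairs[e, 1]] <- 1L
    }
    if (!oracle_is_acyclic(A)) next
    key <- paste(oracle_skeleton_key(A), "|",
                 paste(oracle_vstructs(A), collapse = ";"))
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      reps[[length(reps) + 1L]] <- A
    }
  }
  reps
}

# Random sparse DAG on n nodes with at most max_edges edges (edges respect
# a random topological order, so acyclicity is guaranteed).
random_dag <- function(n, max_edges) {
  ord <- sample.int(n)
  A <- matrix(0L, n, n)
  cand <- which(upper.tri(A), arr.ind = TRUE)
  take <- sample.int(nrow(cand), min(max_edges, nrow(cand)))
  for (e in take) A[ord[cand[e, 1]], ord[cand[e, 2]]] <- 1L
  A
}

cpdag_amat_of <- function(g) {
  a <- g$amat
  dimnames(a) <- NULL
  a
}

# ---- bicor --------------------------------------------------------------

# Direct transcription of the biweight-midcorrelation formula.
oracle_bicor <- function(x, y) {
  wt <- function(v) {
    med <- median(v)
    m <- median(abs(v - med))
    if (m == 0) return(v - mean(v))
    u <- (v - med) / (9 * m)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    (v - med) * w
  }
  a <- wt(x); b <- wt(y)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# ---- exact tests --------------------------------------------------------

# Upper-tail hypergeometric probability by direct enumeration.
oracle_hyper_tail <- function(overlap, pw_size, universe, draw) {
  ks <- overlap:min(pw_size, draw)
  sum(choose(pw_size, ks) * choose(universe - pw_size, draw - ks)) /
    choose(universe, draw)
}

# Two-sided Fisher exact p by enumerating all tables with the observed
# margins, summing probabilities <= the observed table's.
oracle_fisher_two_sided <- function(a, b, c_, d) {
  m <- a + c_; n <- b + d; k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    choose(m, x) * choose(n, k - x) / choose(m + n, k), numeric(1))
  obs <- probs[a - lo + 1]
  sum(probs[probs <= obs * (1 + 1e-7)])
}
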