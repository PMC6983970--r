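#' CPDAG objects
#'
#' The PC algorithm returns the Markov equivalence class of DAGs as a
#' completed partially directed acyclic graph (CPDAG). Internally a CPDAG is
#' an integer mark matrix `amat` with `amat[u, v] = 1` when the edge mark
#' `u -> v` is present: `u -> v` is directed iff `amat[u, v] == 1` and
#' `amat[v, u] == 0`; the pair is undirected iff both marks are set.
#'
#' @param amat square 0/1 mark matrix with node names as dimnames.
#' @return an object of class `"cpdag"`.
#' @export
cpdag <- function(amat) {
  stopifnot(is.matrix(amat), nrow(amat) == ncol(amat))
  if (is.null(rownames(amat))) {
    nodes <- sprintf("V%d", seq_len(nrow(amat)))
    dimnames(amat) <- list(nodes, nodes)
  }
  storage.mode(amat) <- "integer"
  if (any(diag(amat) != 0)) stop("self loops are not allowed")
  if (!all(amat %in% c(0L, 1L))) stop("amat must be 0/1")
  structure(list(nodes = rownames(amat), amat = amat), class = "cpdag")
}

#' @export
print.cpdag <- function(x, ...) {
  de <- directed_edges(x); ue <- undirected_edges(x)
  cat("cpdag:", length(x$nodes), "nodes,", nrow(de), "directed and",
      nrow(ue), "undirected edges\n")
  invisible(x)
}

#' @rdname cpdag
#' @param g a `cpdag`.
#' @return `directed_edges`/`undirected_edges`: data frame with columns
#'   `source`, `target` (for undirected edges, source < target).
#' @export
directed_edges <- function(g) {
  a <- g$amat
  idx <- which(a == 1L & t(a) == 0L, arr.ind = TRUE)
  data.frame(source = g$nodes[idx[, 1]], target = g$nodes[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' @rdname cpdag
#' @export
undirected_edges <- function(g) {
  a <- g$amat
  idx <- which(a == 1L & t(a) == 1L & upper.tri(a), arr.ind = TRUE)
  data.frame(source = g$nodes[idx[, 1]], target = g$nodes[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' @rdname cpdag
#' @param path TSV path; columns `source`, `target`,
#'   `type` (`directed`/`undirected`).
#' @export
write_cpdag <- function(g, path) {
  de <- directed_edges(g); ue <- undirected_edges(g)
  df <- rbind(
    if (nrow(de)) cbind(de, type = "directed"),
    if (nrow(ue)) cbind(ue, type = "undirected"))
  if (is.null(df))
    df <- data.frame(source = character(), target = character(),
                     type = character())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- PC machinery -------------------------------------------------------

# Stable-PC skeleton from a conditional-independence test.
# ci_test(i, j, S) returns TRUE when i and j are independent given S
# (indices into `nodes`). Returns list(adj = logical matrix, sepset).
pc_skeleton <- function(nodes, ci_test, max_cond_size = Inf) {
  p <- length(nodes)
  adj <- matrix(TRUE, p, p); diag(adj) <- FALSE
  sepset <- vector("list", p * p)
  sep_idx <- function(i, j) (i - 1L) * p + j
  l <- 0L
  repeat {
    adj_fixed <- lapply(seq_len(p), function(i) which(adj[i, ]))
    any_tested <- FALSE
    for (i in seq_len(p)) {
      for (j in adj_fixed[[i]]) {
        if (!adj[i, j]) next            # removed earlier this level
        cand <- setdiff(adj_fixed[[i]], j)
        if (length(cand) < l) next
        any_tested <- TRUE
        subsets <- if (l == 0L) list(integer()) else
          lapply(combn(seq_along(cand), l, simplify = FALSE),
                 function(ix) cand[ix])   # guard: combn(n, l) on scalar n
        for (S in subsets) {
          if (ci_test(i, j, S)) {
            adj[i, j] <- adj[j, i] <- FALSE
            sepset[[sep_idx(i, j)]] <- S
            sepset[[sep_idx(j, i)]] <- S
            break
          }
        }
      }
    }
    l <- l + 1L
    if (!any_tested || l > max_cond_size) break
  }
  list(adj = adj, sepset = sepset, sep_idx = sep_idx)
}

# Orient v-structures from separation sets; conflicting arrow demands leave
# the edge undirected. Returns the 0/1 mark matrix.
orient_v_structures <- function(skel) {
  adj <- skel$adj
  p <- nrow(adj)
  amat <- matrix(as.integer(adj), p, p)
  demand <- matrix(FALSE, p, p)        # demand[a, b]: arrow a -> b requested
  for (k in seq_len(p)) {
    nb <- which(adj[k, ])
    if (length(nb) < 2) next
    for (ii in seq_along(nb)) {
      for (jj in seq_along(nb)) {
        if (jj <= ii) next
        i <- nb[ii]; j <- nb[jj]
        if (adj[i, j]) next            # shielded
        S <- skel$sepset[[skel$sep_idx(i, j)]]
        if (is.null(S)) S <- integer() # pair never separated: no sepset info
        if (!(k %in% S)) {
          demand[i, k] <- TRUE
          demand[j, k] <- TRUE
        }
      }
    }
  }
  one_way <- demand & !t(demand)
  amat[t(one_way)] <- 0L               # demanded a->b: drop the b->a mark
  amat
}

# Meek orientation rules R1-R4, applied to closure. amat is the mark matrix.
meek_rules <- function(amat) {
  p <- nrow(amat)
  repeat {
    changed <- FALSE
    D <- amat == 1L & t(amat) == 0L    # directed
    Un <- amat == 1L & t(amat) == 1L   # undirected
    Adj <- (amat + t(amat)) > 0
    diag(Adj) <- TRUE                  # blocks a == c cases below
    und_idx <- which(Un, arr.ind = TRUE)
    for (r in seq_len(nrow(und_idx))) {
      a <- und_idx[r, 1]; b <- und_idx[r, 2]
      if (!(amat[a, b] == 1L && amat[b, a] == 1L)) next  # already oriented
      orient <- FALSE
      # R1: c -> a, c not adjacent to b  =>  a -> b
      if (any(D[, a] & !Adj[, b])) orient <- TRUE
      # R2: a -> c -> b with a - b  =>  a -> b
      if (!orient && any(D[a, ] & D[, b])) orient <- TRUE
      if (!orient) {
        # R3: a - c, a - d, c -> b, d -> b, c and d nonadjacent => a -> b
        cand <- which(Un[a, ] & D[, b])
        if (length(cand) >= 2) {
          for (ci in seq_along(cand)) {
            for (di in seq_along(cand)) {
              if (di <= ci) next
              if (!Adj[cand[ci], cand[di]]) { orient <- TRUE; break }
            }
            if (orient) break
          }
        }
      }
      if (!orient) {
        # R4: a - c, c -> d, d -> b, c and b nonadjacent, a and d adjacent
        for (cc in which(Un[a, ])) {
          if (Adj[cc, b]) next
          dd <- which(D[cc, ] & D[, b] & Adj[a, ])
          if (length(dd)) { orient <- TRUE; break }
        }
      }
      if (orient) {
        amat[b, a] <- 0L
        changed <- TRUE
        D <- amat == 1L & t(amat) == 0L
        Un <- amat == 1L & t(amat) == 1L
      }
    }
    if (!changed) break
  }
  amat
}

# Shared back-end: skeleton + v-structures + Meek closure.
pc_core <- function(nodes, ci_test, max_cond_size = Inf) {
  skel <- pc_skeleton(nodes, ci_test, max_cond_size)
  amat <- orient_v_structures(skel)
  amat <- meek_rules(amat)
  dimnames(amat) <- list(nodes, nodes)
  cpdag(amat)
}

#' Estimate a CPDAG with the PC algorithm (Fisher-z tests)
#'
#' Runs the order-independent (stable) PC skeleton phase with Fisher-z tests
#' of partial correlations derived from the supplied correlation matrix,
#' orients v-structures from the recorded separation sets (conflicts leave
#' the edge undirected) and closes under the Meek rules.
#'
#' @param corr symmetric correlation matrix with unit diagonal (typically
#'   from [bicor_matrix()]), treated as a Pearson matrix.
#' @param n_samples sample size behind `corr`.
#' @param alpha significance level of the conditional-independence tests; an
#'   edge survives when every test rejects independence (p < alpha).
#' @param max_cond_size cap on the conditioning-set size (default unbounded;
#'   always capped at `n_samples - 4` so the z statistic is defined).
#' @param engine `"cpp"` (compiled skeleton loop, the default) or `"r"`
#'   (pure-R reference path); both share the orientation code and must
#'   agree — a property the test suite checks.
#' @return a [cpdag()] over the genes of `corr`.
#' @export
pc_estimate <- function(corr, n_samples, alpha = 0.01, max_cond_size = Inf,
                        engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (max(abs(corr - t(corr))) > 1e-8) stop("corr must be symmetric")
  if (any(abs(diag(corr) - 1) > 1e-8)) stop("corr must have unit diagonal")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (is.finite(max_cond_size) && n_samples <= max_cond_size + 3)
    stop("n_samples must exceed max_cond_size + 3")
  corr <- (corr + t(corr)) / 2
  ev <- eigen(corr, symmetric = TRUE)
  if (min(ev$values) < 1e-10) {
    warning("correlation matrix not positive definite; eigenvalues clipped")
    v <- pmax(ev$values, 1e-10)
    corr <- ev$vectors %*% (v * t(ev$vectors))
    d <- sqrt(diag(corr))
    corr <- corr / tcrossprod(d)
    diag(corr) <- 1
  }
  nodes <- rownames(corr)
  if (is.null(nodes)) nodes <- sprintf("V%d", seq_len(nrow(corr)))
  dimnames(corr) <- NULL               # keep submatrix copies cheap
  max_cond <- min(max_cond_size, n_samples - 4)
  z_crit <- qnorm(1 - alpha / 2)       # reject independence iff p < alpha
  if (engine == "cpp") {
    p <- nrow(corr)
    skel <- .pc_skeleton_gauss(corr, as.integer(n_samples), z_crit,
                               as.integer(min(max_cond, p - 2L)))
    skel$sep_idx <- function(i, j) (i - 1L) * p + j
    amat <- meek_rules(orient_v_structures(skel))
    dimnames(amat) <- list(nodes, nodes)
    return(cpdag(amat))
  }
  ci_test <- function(i, j, S) {
    l <- length(S)
    r <- if (l == 0L) {
      corr[i, j]
    } else if (l == 1L) {
      ci <- corr[i, S]; cj <- corr[j, S]
      (corr[i, j] - ci * cj) / sqrt((1 - ci^2) * (1 - cj^2))
    } else {
      ci <- corr[S, i]; cj <- corr[S, j]
      B <- tryCatch(solve(corr[S, S], cbind(ci, cj)),
                    error = function(e) NULL)
      if (is.null(B)) NA_real_         # non-invertible: non-significant
      else (corr[i, j] - sum(ci * B[, 2L])) /
        sqrt((1 - sum(ci * B[, 1L])) * (1 - sum(cj * B[, 2L])))
    }
    if (!is.finite(r)) return(TRUE)
    r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
    sqrt(n_samples - l - 3) * abs(atanh(r)) < z_crit
  }
  pc_core(nodes, ci_test, max_cond)
}

#' PC with a d-separation oracle
#'
#' Runs the identical PC machinery, but answers every conditional
#' independence query exactly by d-separation in a known DAG. On faithful
#' input this returns the true CPDAG; used for algorithm validation.
#'
#' @param dag square 0/1 adjacency matrix of a DAG (`dag[u, v] = 1` for
#'   `u -> v`).
#' @param max_cond_size cap on conditioning-set size.
#' @return a [cpdag()].
#' @export
pc_oracle <- function(dag, max_cond_size = Inf) {
  stopifnot(is.matrix(dag), nrow(dag) == ncol(dag))
  A <- dag != 0
  if (is.null(topological_order(A))) stop("dag is cyclic")
  nodes <- rownames(dag)
  if (is.null(nodes)) nodes <- sprintf("V%d", seq_len(nrow(dag)))
  pc_core(nodes, function(i, j, S) dsep(A, i, j, S), max_cond_size)
}

#' Test d-separation in a DAG
#'
#' Classic moralized-ancestral-graph criterion: restrict to the ancestors of
#' `{x, y} \\u222a S`, moralize (marry parents, drop directions), delete `S`,
#' and check whether `x` and `y` are disconnected.
#'
#' @param dag logical/0-1 adjacency matrix (`dag[u, v]` = edge `u -> v`).
#' @param x,y node indices.
#' @param S integer vector of conditioning node indices.
#' @return TRUE when `x` and `y` are d-separated given `S`.
#' @export
dsep <- function(dag, x, y, S = integer()) {
  A <- dag != 0
  p <- nrow(A)
  # ancestors of x, y and S (including themselves), by reverse reachability
  anc <- rep(FALSE, p)
  frontier <- unique(c(x, y, S))
  while (length(frontier)) {
    anc[frontier] <- TRUE
    parents <- which(rowSums(A[, frontier, drop = FALSE]) > 0)
    frontier <- parents[!anc[parents]]
  }
  keep <- which(anc)
  Asub <- A[keep, keep, drop = FALSE]
  M <- Asub | t(Asub)
  for (v in seq_along(keep)) {        # marry parents of each node
    pa <- which(Asub[, v])
    if (length(pa) > 1) M[pa, pa] <- TRUE
  }
  diag(M) <- FALSE
  Smap <- match(S, keep)
  if (length(Smap)) {
    M[Smap, ] <- FALSE
    M[, Smap] <- FALSE
  }
  xi <- match(x, keep); yi <- match(y, keep)
  seen <- rep(FALSE, length(keep))
  frontier <- xi
  seen[xi] <- TRUE
  while (length(frontier)) {
    nxt <- which(rowSums(M[, frontier, drop = FALSE]) > 0)
    nxt <- nxt[!seen[nxt]]
    if (yi %in% nxt) return(FALSE)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  TRUE
}

#' CPDAG of a known DAG
#'
#' Builds the Markov-equivalence-class representative of a DAG directly:
#' skeleton plus the DAG's unshielded colliders, closed under the Meek
#' rules. Used to express planted ground-truth networks on the same footing
#' as PC estimates.
#'
#' @param dag square 0/1 adjacency matrix of a DAG.
#' @return a [cpdag()].
#' @export
dag_to_cpdag <- function(dag) {
  A <- dag != 0
  if (is.null(topological_order(A))) stop("dag is cyclic")
  p <- nrow(A)
  nodes <- rownames(dag)
  if (is.null(nodes)) nodes <- sprintf("V%d", seq_len(p))
  skel <- A | t(A)
  amat <- matrix(as.integer(skel), p, p)
  for (k in seq_len(p)) {
    pa <- which(A[, k])
    if (length(pa) < 2) next
    for (ii in seq_along(pa)) {
      for (jj in seq_along(pa)) {
        if (jj <= ii) next
        i <- pa[ii]; j <- pa[jj]
        if (!skel[i, j]) {            # unshielded collider i -> k <- j
          amat[k, i] <- 0L
          amat[k, j] <- 0L
        }
      }
    }
  }
  amat <- meek_rules(amat)
  dimnames(amat) <- list(nodes, nodes)
  cpdag(amat)
}
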