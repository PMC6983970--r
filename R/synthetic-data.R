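#' Ground truth for the synthetic-data generator
#'
#' Bundles everything the generator needs and everything the recovery tests
#' check against: a weighted DAG over gene identifiers, the designated hub
#' ("master") genes, per-sample subtype labels, the additive expression shift
#' master genes receive in subtype C1, per-gene Cox log-hazard coefficients,
#' the significantly-mutated-gene (SMG) panel with its baseline mutation rate
#' and the C1-vs-C2 mutation odds ratio, and the structural noise SD.
#'
#' @param dag square numeric matrix with identical row/column gene names;
#'   `dag[u, v] != 0` plants the edge `u -> v` with that linear weight. Must
#'   be acyclic.
#' @param master_genes character vector of designated hub genes (must be DAG
#'   nodes).
#' @param subtype_labels character/factor vector of `"C1"`/`"C2"` per sample,
#'   named by sample id.
#' @param subtype_effect additive expression shift (in noise-SD units when
#'   `noise_sd = 1`) applied to the shifted master genes in C1 samples at
#'   generation time, so the shift propagates to downstream genes. Either a
#'   scalar or a named vector over `shifted_masters` (mixed signs mimic
#'   subtypes with both up- and down-regulated marker genes).
#' @param shifted_masters subset of `master_genes` receiving the subtype
#'   shift (default: all of them). A handful of strongly shifted driver
#'   masters mimics subtype biology while leaving most of the causal
#'   network unconfounded by the latent subtype.
#' @param cox_betas named numeric vector of log-hazard coefficients per
#'   expression unit; genes absent from the vector have coefficient 0.
#' @param smg_genes character vector of SMG identifiers (disjoint from
#'   expression genes; they index the mutation matrix).
#' @param mutation_rate baseline per-sample mutation probability in C2.
#' @param mutation_cluster_or odds ratio of mutation in C1 vs C2.
#' @param noise_sd SD of the Gaussian structural noise, > 0.
#'
#' @return an object of class `"ground_truth"`.
#' @export
ground_truth <- function(dag,
                         master_genes = character(),
                         subtype_labels,
                         subtype_effect = 0,
                         shifted_masters = master_genes,
                         cox_betas = NULL,
                         smg_genes = character(),
                         mutation_rate = 0.15,
                         mutation_cluster_or = 1,
                         noise_sd = 1) {
  stopifnot(is.matrix(dag), nrow(dag) == ncol(dag))
  if (is.null(rownames(dag)) || is.null(colnames(dag)))
    stop("dag must carry gene names as dimnames")
  if (!identical(rownames(dag), colnames(dag)))
    stop("dag row and column names must match")
  if (is.null(topological_order(dag != 0)))
    stop("dag is cyclic")
  if (!all(master_genes %in% rownames(dag)))
    stop("master_genes must all be dag nodes")
  if (!all(shifted_masters %in% master_genes))
    stop("shifted_masters must be master genes")
  if (length(subtype_effect) > 1) {
    if (is.null(names(subtype_effect)) ||
        !setequal(names(subtype_effect), shifted_masters))
      stop("vector subtype_effect must be named by the shifted masters")
  }
  if (is.null(names(subtype_labels)))
    stop("subtype_labels must be named by sample id")
  subtype_labels <- setNames(as.character(subtype_labels),
                             names(subtype_labels))
  if (!all(subtype_labels %in% c("C1", "C2")))
    stop("subtype_labels must be 'C1' or 'C2'")
  if (!is.null(cox_betas)) {
    if (is.null(names(cox_betas))) stop("cox_betas must be named by gene")
    if (any(!is.finite(cox_betas))) stop("cox_betas must be finite")
  }
  if (!(is.numeric(noise_sd) && length(noise_sd) == 1L && noise_sd > 0))
    stop("noise_sd must be a positive scalar")
  if (mutation_rate < 0 || mutation_rate > 1)
    stop("mutation_rate must lie in [0, 1]")
  if (mutation_cluster_or < 0) stop("mutation_cluster_or must be >= 0")
  structure(
    list(dag = dag,
         master_genes = master_genes,
         subtype_labels = subtype_labels,
         subtype_effect = subtype_effect,
         shifted_masters = shifted_masters,
         cox_betas = if (is.null(cox_betas)) numeric() else cox_betas,
         smg_genes = smg_genes,
         mutation_rate = mutation_rate,
         mutation_cluster_or = mutation_cluster_or,
         noise_sd = noise_sd),
    class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:", nrow(x$dag), "network genes,",
      sum(x$dag != 0), "edges,", length(x$master_genes), "masters,",
      length(x$subtype_labels), "samples,",
      length(x$smg_genes), "SMGs\n")
  invisible(x)
}

# Kahn topological order of a logical/0-1 adjacency matrix; NULL if cyclic.
topological_order <- function(amat) {
  amat <- amat != 0
  n <- nrow(amat)
  if (n == 0L) return(integer())
  indeg <- colSums(amat)
  order <- integer(0)
  active <- rep(TRUE, n)
  repeat {
    leaves <- which(active & indeg == 0)
    if (length(leaves) == 0L) break
    order <- c(order, leaves)
    active[leaves] <- FALSE
    if (length(leaves) == 1L) {
      indeg <- indeg - amat[leaves, ]
    } else {
      indeg <- indeg - colSums(amat[leaves, , drop = FALSE])
    }
  }
  if (length(order) < n) NULL else order
}

#' Simulate log-scale expression from a linear-Gaussian structural model
#'
#' Each gene is generated in topological order as the weighted sum of its
#' parents plus Gaussian noise with SD `noise_sd`. Master genes additionally
#' receive the `subtype_effect` shift in C1 samples at generation time, so
#' their descendants inherit an attenuated shift — the subtype acts as a
#' latent upstream cause, as in real tumor cohorts. Optional pure-noise
#' background genes (prefix `BG`) are appended.
#'
#' @param truth a [ground_truth()] object.
#' @param n_samples number of samples; the truth's `subtype_labels` are
#'   recycled/cropped to this length if needed (>= 4 required).
#' @param n_background count of i.i.d. Gaussian background genes to append.
#' @param seed integer RNG seed; identical inputs give bit-identical output.
#' @return numeric matrix, genes x samples, with gene and sample dimnames.
#' @export
simulate_expression <- function(truth, n_samples = length(truth$subtype_labels),
                                n_background = 0, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  if (n_samples < 4) stop("n_samples must be >= 4")
  labels <- truth$subtype_labels
  if (length(labels) != n_samples)
    stop("n_samples must match length(truth$subtype_labels)")
  ord <- topological_order(truth$dag)
  if (is.null(ord)) stop("dag is cyclic")
  genes <- rownames(truth$dag)
  p <- length(genes)
  set.seed(as.integer(seed))
  expr <- matrix(0, nrow = p, ncol = n_samples,
                 dimnames = list(genes, names(labels)))
  in_c1 <- labels == "C1"
  effect <- truth$subtype_effect
  if (length(effect) == 1L)
    effect <- setNames(rep(effect, length(truth$shifted_masters)),
                       truth$shifted_masters)
  for (g in ord) {
    parents <- which(truth$dag[, g] != 0)
    val <- rnorm(n_samples, 0, truth$noise_sd)
    if (length(parents))
      val <- val + drop(truth$dag[parents, g] %*% expr[parents, , drop = FALSE])
    if (genes[g] %in% truth$shifted_masters)
      val[in_c1] <- val[in_c1] + effect[[genes[g]]]
    expr[g, ] <- val
  }
  if (n_background > 0) {
    bg <- matrix(rnorm(n_background * n_samples, 0, truth$noise_sd),
                 nrow = n_background,
                 dimnames = list(sprintf("BG%04d", seq_len(n_background)),
                                 names(labels)))
    expr <- rbind(expr, bg)
  }
  expr
}

#' Simulate survival under a Weibull-baseline proportional-hazards model
#'
#' Event times follow \eqn{T = b (-\log U / e^{\eta})^{1/s}} with linear
#' predictor \eqn{\eta = \sum_g \beta_g x_{g}} over the genes named in
#' `truth$cox_betas`, Weibull scale `baseline_scale` and shape `shape`
#' (shape 1 = exponential baseline). Censoring is independent
#' Uniform(0, tau), with tau calibrated against the realized event-time
#' distribution so the expected censored fraction equals `censor_rate`.
#'
#' @param expr genes x samples expression matrix (samples must match
#'   `truth$subtype_labels`).
#' @param truth a [ground_truth()] object.
#' @param baseline_scale Weibull scale of the baseline (e.g. days), > 0.
#' @param censor_rate target fraction of censored samples in `[0, 1]`.
#' @param seed integer RNG seed.
#' @param shape Weibull shape of the baseline hazard.
#' @return data frame with columns `sample`, `time` (> 0), `event` (0/1).
#' @export
simulate_survival <- function(expr, truth, baseline_scale = 1000,
                              censor_rate = 0.3, seed = 1, shape = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  if (baseline_scale <= 0) stop("baseline_scale must be positive")
  if (censor_rate < 0 || censor_rate > 1) stop("censor_rate must lie in [0,1]")
  samples <- colnames(expr)
  if (!all(samples %in% names(truth$subtype_labels)))
    stop("expr samples do not match truth$subtype_labels")
  betas <- truth$cox_betas[names(truth$cox_betas) %in% rownames(expr)]
  set.seed(as.integer(seed))
  n <- length(samples)
  eta <- rep(0, n)
  if (length(betas))
    eta <- drop(betas %*% expr[names(betas), samples, drop = FALSE])
  u <- runif(n)
  t_event <- baseline_scale * (-log(u) / exp(eta))^(1 / shape)
  time <- t_event
  event <- rep(1L, n)
  if (censor_rate > 0) {
    if (censor_rate >= 1) {
      tau <- min(t_event) / 2
    } else {
      # P(censored) = mean(min(T/tau, 1)) for C ~ U(0, tau); monotone in tau.
      f <- function(log_tau) mean(pmin(t_event / exp(log_tau), 1)) - censor_rate
      lo <- log(min(t_event)) - 20
      hi <- log(max(t_event)) + 20
      tau <- exp(uniroot(f, c(lo, hi))$root)
    }
    cens <- runif(n, 0, tau)
    censored <- cens < t_event
    time[censored] <- cens[censored]
    event[censored] <- 0L
  }
  time <- pmax(time, .Machine$double.eps)
  data.frame(sample = unname(samples), time = unname(time), event = event,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate a binary SMG mutation matrix with subtype-enriched mutations
#'
#' Every SMG in `truth$smg_genes` is mutated with probability
#' `truth$mutation_rate` in C2 samples and with the probability implied by
#' `truth$mutation_cluster_or` on the odds scale in C1 samples.
#'
#' @param truth a [ground_truth()] object.
#' @param samples sample ids (must be labelled in the truth).
#' @param seed integer RNG seed.
#' @return binary integer matrix, SMGs x samples.
#' @export
simulate_mutations <- function(truth, samples = names(truth$subtype_labels),
                               seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  if (length(samples) == 0L) stop("samples must be nonempty")
  if (!all(samples %in% names(truth$subtype_labels)))
    stop("unknown sample ids: ",
         paste(setdiff(samples, names(truth$subtype_labels)), collapse = ", "))
  p2 <- truth$mutation_rate
  odds1 <- truth$mutation_cluster_or * p2 / (1 - p2)
  p1 <- if (is.finite(odds1)) odds1 / (1 + odds1) else 1
  if (p2 == 0) p1 <- if (truth$mutation_cluster_or == 0) 0 else p1
  prob <- ifelse(truth$subtype_labels[samples] == "C1", p1, p2)
  set.seed(as.integer(seed))
  m <- length(truth$smg_genes)
  mut <- matrix(0L, nrow = m, ncol = length(samples),
                dimnames = list(truth$smg_genes, samples))
  for (i in seq_len(m)) mut[i, ] <- rbinom(length(samples), 1L, prob)
  mut
}

#' Construct the default synthetic cohort truth
#'
#' Builds the demo world as a two-layer regulatory cascade. `n_hubs` hub
#' genes are the DAG roots. The first layer holds
#' `n_hubs * children_per_hub / 2` collider genes, each drawing two
#' distinct hub parents (balanced so every hub emits exactly
#' `children_per_hub` edges): unshielded colliders are what lets the PC
#' algorithm orient hub edges outward. The remaining network genes form a
#' second, downstream layer with one first-layer parent each (oriented by
#' orientation propagation). Hubs carry Cox effects `+hub_beta`
#' (unfavourable, `n_unfav_hubs` of them) or `-hub_beta` (favourable);
#' downstream genes carry `child_beta` times the sign-sum of their parents'
#' effects — the indirect prognosis relevance the network stage is meant to
#' strip away. All hubs are masters; the first `n_shifted_masters` of them
#' are shifted by `subtype_effect` in C1 — by default uniformly upward, a
#' proliferation-like program over-expressed in the aggressive subtype
#' (`shift_sign = "alternating"` gives a sign-mixed marker panel instead).
#' With the default hub effect signs the net C1 log-hazard shift is
#' positive, so C1 is the worse-prognosis subtype.
#'
#' @param n_samples cohort size.
#' @param n_hubs planted hub count.
#' @param n_children non-hub network genes across both layers.
#' @param children_per_hub out-degree of every hub (must keep
#'   `n_hubs * children_per_hub / 2` integral and `<= n_children`).
#' @param n_smgs SMG panel size.
#' @param subtype_effect C1 shift on the driver masters, in noise SDs.
#' @param n_shifted_masters how many masters drive the subtype.
#' @param shift_sign `"uniform"` (all drivers up in C1) or `"alternating"`
#'   (sign-mixed marker panel).
#' @param edge_weight linear weight of every hub -> child edge.
#' @param chain_weight linear weight of layer-1 -> layer-2 edges.
#' @param hub_beta absolute Cox log-hazard of hub genes.
#' @param n_unfav_hubs hubs with positive (unfavourable) sign.
#' @param child_beta per-parent-sign Cox log-hazard of downstream genes.
#' @param mutation_rate baseline C2 mutation probability.
#' @param mutation_cluster_or mutation odds ratio C1 vs C2.
#' @param noise_sd structural noise SD.
#' @param seed integer RNG seed (parent assignment + subtype labels).
#' @return a [ground_truth()] object.
#' @export
make_demo_truth <- function(n_samples = 500, n_hubs = 8, n_children = 52,
                            children_per_hub = 13, n_smgs = 6,
                            subtype_effect = 2, n_shifted_masters = n_hubs,
                            shift_sign = c("uniform", "alternating"),
                            edge_weight = 0.6,
                            chain_weight = 0.7, hub_beta = 0.5,
                            n_unfav_hubs = 5, child_beta = 0.15,
                            mutation_rate = 0.2, mutation_cluster_or = 4,
                            noise_sd = 1, seed = 1) {
  stopifnot(n_hubs >= 2, n_children >= 0, n_unfav_hubs <= n_hubs,
            (n_hubs * children_per_hub) %% 2 == 0)
  n_layer1 <- n_hubs * children_per_hub / 2
  stopifnot(n_layer1 <= max(n_children, 0) || n_children == 0)
  set.seed(as.integer(seed))
  hubs <- sprintf("HUB%02d", seq_len(n_hubs))
  children <- if (n_children > 0) sprintf("G%03d", seq_len(n_children)) else character()
  layer1 <- head(children, n_layer1)
  layer2 <- children[-seq_len(n_layer1)]
  genes <- c(hubs, children)
  dag <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  if (length(layer1)) {
    # balanced hub pairing: shuffle hub slots into pairs, no self-pairs
    repeat {
      slots <- sample(rep(hubs, children_per_hub))
      pairs <- matrix(slots, nrow = 2)
      if (all(pairs[1, ] != pairs[2, ])) break
    }
    for (ii in seq_along(layer1))
      dag[pairs[, ii], layer1[ii]] <- edge_weight
  }
  for (ch in layer2)
    dag[sample(layer1, 1L), ch] <- chain_weight
  hub_sign <- c(rep(1, n_unfav_hubs), rep(-1, n_hubs - n_unfav_hubs))
  betas <- setNames(hub_sign * hub_beta, hubs)
  for (ch in children) {                # children are in topological order
    pa <- rownames(dag)[dag[, ch] != 0]
    betas[ch] <- child_beta * sum(sign(betas[pa]))
  }
  labels <- setNames(sample(c("C1", "C2"), n_samples, replace = TRUE),
                     sprintf("S%04d", seq_len(n_samples)))
  shift_sign <- match.arg(shift_sign)
  shifted <- head(hubs, min(n_shifted_masters, n_hubs))
  shift_vec <- if (length(subtype_effect) == 1L) {
    sgn <- if (shift_sign == "uniform") rep(1, length(shifted))
           else (-1)^(seq_along(shifted) + 1)
    setNames(subtype_effect * sgn, shifted)
  } else subtype_effect
  ground_truth(dag = dag, master_genes = hubs, subtype_labels = labels,
               subtype_effect = shift_vec,
               shifted_masters = shifted,
               cox_betas = betas,
               smg_genes = if (n_smgs > 0) sprintf("SMG%02d", seq_len(n_smgs)) else character(),
               mutation_rate = mutation_rate,
               mutation_cluster_or = mutation_cluster_or,
               noise_sd = noise_sd)
}
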