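#' Hypergeometric pathway enrichment of a top gene set
#'
#' Upper-tail hypergeometric test per pathway: the probability of drawing at
#' least the observed overlap when `|top_genes|` genes are drawn from the
#' universe and the pathway contributes its universe intersection.
#' Benjamini-Hochberg FDR across pathways. Pathways with an empty universe
#' intersection are skipped.
#'
#' @param top_genes character set of selected genes (must lie in `universe`).
#' @param pathways named list of gene-id vectors (e.g. [read_gmt()] output).
#' @param universe character set of testable genes.
#' @return data frame `pathway`, `overlap`, `pathway_size` (in-universe),
#'   `universe_size`, `draw_size`, `p`, `fdr`, sorted by p.
#' @export
hypergeom_enrich <- function(top_genes, pathways, universe) {
  top_genes <- unique(top_genes)
  universe <- unique(universe)
  if (!all(top_genes %in% universe))
    stop("top_genes must be a subset of the universe")
  rows <- lapply(names(pathways), function(nm) {
    pw <- intersect(pathways[[nm]], universe)
    if (length(pw) == 0L) return(NULL)
    ov <- length(intersect(top_genes, pw))
    p <- phyper(ov - 1, length(pw), length(universe) - length(pw),
                length(top_genes), lower.tail = FALSE)
    data.frame(pathway = nm, overlap = ov, pathway_size = length(pw),
               universe_size = length(universe),
               draw_size = length(top_genes), p = p,
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0)
    message(skipped, " pathway(s) with no universe overlap skipped")
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(pathway = character(), overlap = integer(),
                      pathway_size = integer(), universe_size = integer(),
                      draw_size = integer(), p = numeric(), fdr = numeric()))
  out$fdr <- p.adjust(out$p, "BH")
  out[order(out$p, out$pathway), , drop = FALSE]
}

#' Differential expression between mutated and wild-type samples of an SMG
#'
#' For one significantly mutated gene, splits samples by its mutation
#' status and tests every expression gene with a two-sided two-sample test
#' (unpaired t-test by default; Wilcoxon rank-sum by flag). Fold change is
#' the mutated/wild mean ratio on the linear scale, anti-logging the input
#' per `scale`. BH FDR across genes; `significant` flags `fdr < fdr_max`.
#'
#' @param expr genes x samples matrix.
#' @param mut binary SMG x samples mutation matrix.
#' @param smg SMG row name of `mut` to split on.
#' @param test `"t"` or `"wilcoxon"`.
#' @param scale input expression scale: `"log2"`, `"ln"` or `"linear"`.
#' @param fdr_max FDR threshold for the `significant` flag.
#' @return data frame `smg`, `gene`, `fold_change`, `p`, `fdr`,
#'   `significant`, in gene order of `expr`.
#' @export
mutation_expression_assoc <- function(expr, mut, smg,
                                      test = c("t", "wilcoxon"),
                                      scale = c("log2", "ln", "linear"),
                                      fdr_max = 0.1) {
  test <- match.arg(test)
  scale <- match.arg(scale)
  if (!smg %in% rownames(mut)) stop("unknown SMG: ", smg)
  common <- intersect(colnames(expr), colnames(mut))
  status <- mut[smg, common]
  mutated <- common[status == 1]
  wild <- common[status == 0]
  if (length(mutated) == 0L || length(wild) == 0L)
    stop("both mutated and wild-type groups must be nonempty for ", smg)
  unlog <- switch(scale, log2 = function(x) 2^x, ln = exp,
                  linear = identity)
  res <- lapply(rownames(expr), function(g) {
    xm <- expr[g, mutated]; xw <- expr[g, wild]
    if (length(xm) < 2 || length(xw) < 2 || (sd(xm) == 0 && sd(xw) == 0)) {
      warning("gene ", g, " skipped (degenerate groups)")
      return(NULL)
    }
    p <- if (test == "t") t.test(xm, xw)$p.value
         else suppressWarnings(wilcox.test(xm, xw)$p.value)
    fc <- mean(unlog(xm)) / mean(unlog(xw))
    data.frame(smg = smg, gene = g, fold_change = fc, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no testable genes")
  out$fdr <- p.adjust(out$p, "BH")
  out$significant <- out$fdr < fdr_max
  rownames(out) <- NULL
  out
}

#' Mutation enrichment of SMGs in the expression subtypes
#'
#' Per SMG, a 2x2 table of mutation status by cluster, two-sided Fisher
#' exact p, sample odds ratio of mutation in C1 vs C2 (Haldane 0.5
#' correction when any cell is zero), and BH FDR across SMGs.
#'
#' @param mut binary SMG x samples matrix.
#' @param labels per-sample cluster labels (`"C1"`/`"C2"`), named by sample.
#' @return data frame `smg`, `odds_ratio`, `p`, `fdr`.
#' @export
smg_cluster_enrichment <- function(mut, labels) {
  common <- intersect(colnames(mut), names(labels))
  lab <- factor(as.character(labels[common]), levels = c("C1", "C2"))
  if (any(is.na(lab)) || nlevels(droplevels(lab)) < 2)
    stop("need both clusters among the mutated cohort samples")
  res <- lapply(rownames(mut), function(g) {
    m <- mut[g, common]
    a <- sum(m == 1 & lab == "C1"); b <- sum(m == 1 & lab == "C2")
    c_ <- sum(m == 0 & lab == "C1"); d <- sum(m == 0 & lab == "C2")
    tab <- matrix(c(a, c_, b, d), 2)
    p <- fisher.test(tab)$p.value
    if (any(tab == 0)) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
    data.frame(smg = g, odds_ratio = (a * d) / (b * c_), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}
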