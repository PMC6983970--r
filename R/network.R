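#' Summarized degrees and master-gene calls
#'
#' For every node of a CPDAG, counts out-going and in-coming directed edges
#' (undirected edges contribute to neither: they add equally to "out" and
#' "in" under any resolution, so they cancel in the difference) and scores
#' the node by summarized degree = out-degree - in-degree. Nodes with
#' `|summarized degree| > hub_threshold` (strict) are flagged as master
#' prognosis-impacting genes.
#'
#' @param g a [cpdag()].
#' @param hub_threshold strict absolute cutoff on the summarized degree.
#' @return data frame with columns `gene`, `out_degree`, `in_degree`,
#'   `summarized_degree`, `is_master`, in node order.
#' @export
summarize_degrees <- function(g, hub_threshold = 5) {
  stopifnot(inherits(g, "cpdag"))
  a <- g$amat
  dir_mat <- (a == 1L) & (t(a) == 0L)
  out_deg <- rowSums(dir_mat)
  in_deg <- colSums(dir_mat)
  sdeg <- out_deg - in_deg
  data.frame(gene = g$nodes,
             out_degree = as.integer(out_deg),
             in_degree = as.integer(in_deg),
             summarized_degree = as.integer(sdeg),
             is_master = abs(sdeg) > hub_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select master genes from degree summaries
#'
#' @param summaries data frame from [summarize_degrees()].
#' @return master gene ids ordered by decreasing `|summarized_degree|`,
#'   ties broken lexicographically.
#' @export
select_masters <- function(summaries) {
  stopifnot(nrow(summaries) > 0)
  m <- summaries[summaries$is_master, , drop = FALSE]
  m$gene[order(-abs(m$summarized_degree), m$gene)]
}
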