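#' Drop genes dominated by zero values
#'
#' Genome-wide screening starts by removing genes whose expression is zero in
#' more than `max_zero_frac` of samples (genes with a zero fraction exactly
#' at the threshold are retained — the cut is "more than").
#'
#' @param expr genes x samples matrix.
#' @param max_zero_frac maximum tolerated zero fraction, in `[0, 1]`.
#' @return the filtered matrix, sample order unchanged.
#' @export
filter_zero_heavy <- function(expr, max_zero_frac = 0.7) {
  stopifnot(is.matrix(expr))
  if (max_zero_frac < 0 || max_zero_frac > 1)
    stop("max_zero_frac must lie in [0, 1]")
  frac0 <- rowMeans(expr == 0)
  keep <- frac0 <= max_zero_frac
  if (!any(keep)) warning("all genes removed by the zero filter")
  expr[keep, , drop = FALSE]
}

# Align expression columns with a clinical table; extra expression samples
# are dropped with a warning, samples missing expression are an error.
align_samples <- function(expr, clin) {
  missing_expr <- setdiff(clin$sample, colnames(expr))
  if (length(missing_expr))
    clin <- clin[clin$sample %in% colnames(expr), , drop = FALSE]
  extra <- setdiff(colnames(expr), clin$sample)
  if (length(extra))
    warning(length(extra), " sample(s) in expression but not in clinical table; dropped")
  expr <- expr[, clin$sample, drop = FALSE]
  list(expr = expr, clin = clin)
}

#' Univariate Cox screening of every gene
#'
#' Fits one proportional-hazards model per gene (partial likelihood, Efron
#' tie handling, Wald p-value) and classifies genes as unfavourable
#' (significant with positive coefficient: higher expression, worse
#' survival), favourable (negative coefficient) or none.
#'
#' @param expr genes x samples matrix.
#' @param clin clinical data frame (`sample`, `time`, `event`), >= 2 events.
#' @param p_sig significance threshold for the direction call.
#' @param standardize z-score each gene before fitting (off by default; the
#'   coefficient cutoff downstream is scale-dependent).
#' @return data frame with one row per gene: `gene`, `coef`, `hr`, `p`,
#'   `direction` (`favourable`/`unfavourable`/`none`), `flagged` (constant
#'   gene or non-converged fit).
#' @export
cox_screen <- function(expr, clin, p_sig = 0.05, standardize = FALSE) {
  al <- align_samples(expr, clin)
  expr <- al$expr; clin <- al$clin
  if (sum(clin$event) < 2) stop("need at least 2 events")
  surv_obj <- Surv(clin$time, clin$event)
  res <- lapply(rownames(expr), function(g) {
    x <- expr[g, ]
    if (standardize) {
      s <- sd(x)
      if (s > 0) x <- (x - mean(x)) / s
    }
    if (sd(x) == 0)
      return(data.frame(gene = g, coef = 0, hr = 1, p = 1,
                        direction = "none", flagged = TRUE,
                        stringsAsFactors = FALSE))
    fit <- tryCatch(coxph(surv_obj ~ x, ties = "efron"),
                    error = function(e) NULL,
                    warning = function(w) {
                      # retry capturing the fit; flag non-convergence
                      f <- suppressWarnings(coxph(surv_obj ~ x, ties = "efron"))
                      attr(f, "prognet_flag") <- TRUE
                      f
                    })
    if (is.null(fit))
      return(data.frame(gene = g, coef = 0, hr = 1, p = 1,
                        direction = "none", flagged = TRUE,
                        stringsAsFactors = FALSE))
    sm <- summary(fit)$coefficients
    cf <- unname(sm[1, "coef"])
    p <- unname(sm[1, "Pr(>|z|)"])
    if (!is.finite(cf) || !is.finite(p)) {
      cf <- 0; p <- 1
    }
    dir <- if (p < p_sig && cf > 0) "unfavourable"
           else if (p < p_sig && cf < 0) "favourable" else "none"
    data.frame(gene = g, coef = cf, hr = exp(cf), p = p, direction = dir,
               flagged = isTRUE(attr(fit, "prognet_flag")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Select prognosis-relevant genes for the causal network
#'
#' Keeps genes with Cox p-value strictly below `p_max` and absolute
#' coefficient strictly above `min_abs_coef`, preserving input order.
#'
#' @param results data frame from [cox_screen()].
#' @param p_max p-value cutoff.
#' @param min_abs_coef absolute-coefficient cutoff.
#' @return character vector of gene ids.
#' @export
select_network_genes <- function(results, p_max = 0.01, min_abs_coef = 0.2) {
  stopifnot(nrow(results) > 0)
  results$gene[results$p < p_max & abs(results$coef) > min_abs_coef]
}

#' Compare survival between groups (log-rank + Kaplan-Meier)
#'
#' @param clin clinical data frame (`sample`, `time`, `event`).
#' @param labels per-sample group labels, named by sample id (or in `clin`
#'   row order); >= 2 groups, each with >= 1 event.
#' @return list with `logrank_chi2`, `logrank_p`, and `km`: one data frame
#'   per group with columns `time`, `surv` (right-continuous step function
#'   starting at 1).
#' @export
compare_groups <- function(clin, labels) {
  if (!is.null(names(labels))) {
    if (!all(clin$sample %in% names(labels)))
      stop("labels missing for some samples")
    labels <- labels[clin$sample]
  } else if (length(labels) != nrow(clin)) {
    stop("labels must be named or match clin row order")
  }
  grp <- factor(as.character(labels))
  if (nlevels(grp) < 2) stop("need at least 2 groups")
  ev_per_group <- tapply(clin$event, grp, sum)
  if (any(ev_per_group < 1)) stop("every group needs at least one event")
  sd_fit <- survdiff(Surv(clin$time, clin$event) ~ grp)
  chi2 <- sd_fit$chisq
  p <- pchisq(chi2, df = nlevels(grp) - 1, lower.tail = FALSE)
  sf <- survfit(Surv(clin$time, clin$event) ~ grp)
  strata <- rep(names(sf$strata), sf$strata)
  km <- lapply(levels(grp), function(lv) {
    idx <- strata == paste0("grp=", lv)
    data.frame(time = sf$time[idx], surv = sf$surv[idx])
  })
  names(km) <- levels(grp)
  list(logrank_chi2 = unname(chi2), logrank_p = unname(p), km = km,
       observed = sd_fit$obs, expected = sd_fit$exp)
}
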