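#' Fit an elastic-net logistic subtype predictor
#'
#' Penalized logistic regression (glmnet coordinate descent) of the subtype
#' label on the z-scored expression of the selected genes. The elastic-net
#' mixing `alpha` and penalty `lambda` are chosen by internal
#' cross-validated misclassification over the supplied grids (fold
#' assignment derived from `seed`, so selection is deterministic). C1 is
#' encoded as the positive class, so positive coefficients mark C1-up
#' genes.
#'
#' @param expr genes x samples matrix (training cohort).
#' @param labels per-sample `"C1"`/`"C2"` labels, named by sample id.
#' @param gene_ids genes to use (e.g. top-10 by importance); all must be
#'   present in `expr`.
#' @param alpha_grid candidate elastic-net mixing values in `[0, 1]`.
#' @param lambda_grid candidate penalties (decreasing order recommended).
#' @param seed integer RNG seed for the cross-validation folds.
#' @param nfolds internal CV folds.
#' @return object of class `"subtype_predictor"`: `gene_ids`,
#'   `coefficients` (named), `intercept`, `alpha`, `lambda`,
#'   `training_scaling` (per-gene mean/sd), `cv_misclass`.
#' @export
fit_predictor <- function(expr, labels, gene_ids,
                          alpha_grid = c(0.25, 0.5, 0.75, 1),
                          lambda_grid = exp(seq(log(1), log(1e-4),
                                                length.out = 50)),
                          seed = 1, nfolds = 10) {
  missing_genes <- setdiff(gene_ids, rownames(expr))
  if (length(missing_genes))
    stop("genes missing from expression matrix: ",
         paste(missing_genes, collapse = ", "))
  if (!is.null(names(labels))) labels <- labels[colnames(expr)]
  y <- factor(as.character(labels), levels = c("C2", "C1"))
  if (any(is.na(y)) || nlevels(droplevels(y)) < 2)
    stop("both classes must be present")
  X <- t(expr[gene_ids, , drop = FALSE])
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  sdev[sdev == 0] <- 1
  Xs <- scale(X, center = mu, scale = sdev)
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  nfolds <- min(nfolds, min(table(y)))
  set.seed(as.integer(seed))
  foldid <- sample(rep_len(seq_len(nfolds), length(y)))
  best <- NULL
  for (al in alpha_grid) {
    cv <- glmnet::cv.glmnet(Xs, y, family = "binomial", alpha = al,
                            lambda = lambda_grid, type.measure = "class",
                            foldid = foldid, standardize = FALSE)
    i <- which.min(cv$cvm)
    # ties: prefer the sparser (larger) lambda, then larger alpha
    if (is.null(best) || cv$cvm[i] < best$cvm - 1e-12 ||
        (abs(cv$cvm[i] - best$cvm) <= 1e-12 && al > best$alpha)) {
      best <- list(cvm = cv$cvm[i], alpha = al, lambda = cv$lambda[i])
    }
  }
  fit <- glmnet::glmnet(Xs, y, family = "binomial", alpha = best$alpha,
                        lambda = lambda_grid, standardize = FALSE)
  cf <- coef(fit, s = best$lambda)
  beta <- setNames(as.numeric(cf)[-1], rownames(cf)[-1])
  structure(
    list(gene_ids = gene_ids,
         coefficients = beta[gene_ids],
         intercept = as.numeric(cf)[1],
         alpha = best$alpha,
         lambda = best$lambda,
         training_scaling = data.frame(gene = gene_ids, mean = unname(mu),
                                       sd = unname(sdev),
                                       stringsAsFactors = FALSE),
         cv_misclass = best$cvm),
    class = "subtype_predictor")
}

#' @export
print.subtype_predictor <- function(x, ...) {
  cat(sprintf(
    "subtype_predictor: %d genes, alpha = %.2f, lambda = %.3g, CV misclass = %.3f\n",
    length(x$gene_ids), x$alpha, x$lambda, x$cv_misclass))
  invisible(x)
}

#' Leave-one-out cross-validated accuracy of the subtype predictor
#'
#' Each sample is held out in turn; the full [fit_predictor()] procedure
#' (scaling and grid selection recomputed on the remaining n - 1 samples)
#' predicts its label. A fold that loses one class entirely predicts the
#' remaining class. Returns the fraction of correct predictions.
#'
#' @inheritParams fit_predictor
#' @return scalar accuracy in `[0, 1]`.
#' @export
loocv_accuracy <- function(expr, labels, gene_ids,
                           alpha_grid = c(0.25, 0.5, 0.75, 1),
                           lambda_grid = exp(seq(log(1), log(1e-4),
                                                 length.out = 50)),
                           seed = 1, nfolds = 5) {
  if (!is.null(names(labels))) labels <- labels[colnames(expr)]
  labels <- as.character(labels)
  n <- ncol(expr)
  if (n < 10) stop("need at least 10 samples for LOOCV")
  correct <- logical(n)
  for (i in seq_len(n)) {
    tr_expr <- expr[, -i, drop = FALSE]
    tr_lab <- labels[-i]
    if (length(unique(tr_lab)) < 2) {
      message("fold ", i, " lost one class; predicting the remaining class")
      correct[i] <- unique(tr_lab) == labels[i]
      next
    }
    fit <- fit_predictor(tr_expr, setNames(tr_lab, colnames(tr_expr)),
                         gene_ids, alpha_grid, lambda_grid,
                         seed = seed + i, nfolds = nfolds)
    pred <- transfer_labels(fit, expr[, i, drop = FALSE],
                            rescale = "training")
    correct[i] <- pred$label == labels[i]
  }
  mean(correct)
}

#' Transfer subtype labels to an external cohort
#'
#' Applies the trained predictor to a new expression matrix. By default the
#' external cohort is re-z-scored per gene within itself (the sensible mode
#' when transferring across platforms, e.g. RNA-seq to microarray);
#' `rescale = "training"` applies the training means/SDs instead. Scores
#' above probability 0.5 are called C1; exact ties go to C2.
#'
#' @param predictor a [fit_predictor()] object.
#' @param expr_external genes x samples matrix containing every predictor
#'   gene (case-insensitive match on gene symbol).
#' @param rescale `"cohort"` or `"training"`.
#' @return data frame `sample`, `prob_c1`, `label`.
#' @export
transfer_labels <- function(predictor, expr_external,
                            rescale = c("cohort", "training")) {
  rescale <- match.arg(rescale)
  stopifnot(inherits(predictor, "subtype_predictor"))
  idx <- match(tolower(predictor$gene_ids), tolower(rownames(expr_external)))
  if (any(is.na(idx)))
    stop("genes missing from external cohort: ",
         paste(predictor$gene_ids[is.na(idx)], collapse = ", "))
  X <- t(expr_external[idx, , drop = FALSE])
  if (rescale == "cohort" && nrow(X) > 1) {
    mu <- colMeans(X)
    sdev <- apply(X, 2, sd)
    sdev[sdev == 0] <- 1
  } else {
    mu <- predictor$training_scaling$mean
    sdev <- predictor$training_scaling$sd
  }
  Xs <- scale(X, center = mu, scale = sdev)
  eta <- drop(Xs %*% predictor$coefficients) + predictor$intercept
  prob <- plogis(eta)
  data.frame(sample = colnames(expr_external), prob_c1 = unname(prob),
             label = ifelse(prob > 0.5, "C1", "C2"),
             stringsAsFactors = FALSE)
}

#' Serialize / restore a subtype predictor as JSON
#'
#' @param predictor a [fit_predictor()] object.
#' @param path JSON file path.
#' @return `write_predictor`: the path, invisibly; `read_predictor`: the
#'   restored `"subtype_predictor"`.
#' @export
write_predictor <- function(predictor, path) {
  jsonlite::write_json(
    list(gene_ids = predictor$gene_ids,
         coefficients = unname(predictor$coefficients),
         intercept = predictor$intercept,
         alpha = predictor$alpha,
         lambda = predictor$lambda,
         scaling_mean = predictor$training_scaling$mean,
         scaling_sd = predictor$training_scaling$sd),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_predictor
#' @export
read_predictor <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(gene_ids = j$gene_ids,
         coefficients = setNames(j$coefficients, j$gene_ids),
         intercept = j$intercept,
         alpha = j$alpha,
         lambda = j$lambda,
         training_scaling = data.frame(gene = j$gene_ids,
                                       mean = j$scaling_mean,
                                       sd = j$scaling_sd,
                                       stringsAsFactors = FALSE),
         cv_misclass = NA_real_),
    class = "subtype_predictor")
}

# Penalized logistic objective at given coefficients (used by the
# local-optimality tests): mean negative log-likelihood + elastic-net term.
elnet_objective <- function(Xs, y01, beta, intercept, alpha, lambda) {
  eta <- drop(Xs %*% beta) + intercept
  nll <- mean(log1p(exp(eta)) - y01 * eta)
  pen <- lambda * sum((1 - alpha) / 2 * beta^2 + alpha * abs(beta))
  nll + pen
}
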