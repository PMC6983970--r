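make_sep_data <- function(n = 80, p = 6, seed = 1) {
  set.seed(seed)
  labels <- setNames(rep(c("C1", "C2"), each = n / 2), paste0("S", 1:n))
  expr <- matrix(rnorm(p * n), p, n,
                 dimnames = list(paste0("g", 1:p), names(labels)))
  expr["g1", ] <- ifelse(labels == "C1", 1.5, -1.5) + rnorm(n, 0, 0.5)
  list(expr = expr, labels = labels)
}

test_that("lasso keeps the separating gene and shrinks the rest", {
  d <- make_sep_data()
  fit <- fit_predictor(d$expr, d$labels, paste0("g", 1:6),
                       alpha_grid = 1, seed = 3)
  expect_gt(fit$coefficients["g1"], 0)    # C1 encoded as positive class
  expect_lte(sum(abs(fit$coefficients[-1]) > 0.3), 1)
  expect_true(fit$lambda >= 0 && fit$alpha == 1)
})

test_that("an overwhelming penalty empties the model", {
  d <- make_sep_data()
  fit <- fit_predictor(d$expr, d$labels, paste0("g", 1:6),
                       alpha_grid = 1, lambda_grid = c(50, 100), seed = 3)
  expect_true(all(abs(fit$coefficients) < 1e-8))
  pred <- transfer_labels(fit, d$expr)
  expect_identical(length(unique(pred$label)), 1L)  # majority class only
})

test_that("flipping labels flips the coefficient signs", {
  d <- make_sep_data(seed = 5)
  grids <- list(alpha_grid = 0.5, lambda_grid = c(0.05, 0.04))
  f1 <- fit_predictor(d$expr, d$labels, paste0("g", 1:6),
                      alpha_grid = grids$alpha_grid,
                      lambda_grid = grids$lambda_grid, seed = 3)
  flipped <- setNames(ifelse(d$labels == "C1", "C2", "C1"), names(d$labels))
  f2 <- fit_predictor(d$expr, flipped, paste0("g", 1:6),
                      alpha_grid = grids$alpha_grid,
                      lambda_grid = grids$lambda_grid, seed = 3)
  expect_equal(unname(f2$coefficients), -unname(f1$coefficients),
               tolerance = 1e-5)
})

test_that("fitted coefficients are a local optimum of the penalized objective", {
  d <- make_sep_data(seed = 7)
  fit <- fit_predictor(d$expr, d$labels, paste0("g", 1:6),
                       alpha_grid = 0.5, seed = 2)
  X <- t(d$expr)
  Xs <- scale(X, fit$training_scaling$mean, fit$training_scaling$sd)
  y01 <- as.numeric(d$labels == "C1")
  obj0 <- prognet:::elnet_objective(Xs, y01, fit$coefficients,
                                    fit$intercept, fit$alpha, fit$lambda)
  set.seed(11)
  for (i in 1:25) {
    pert <- fit$coefficients + rnorm(6, 0, 0.05)
    obj <- prognet:::elnet_objective(Xs, y01, pert, fit$intercept,
                                     fit$alpha, fit$lambda)
    expect_gte(obj, obj0 - 1e-4)
  }
})

test_that("coefficient paths are continuous in lambda", {
  d <- make_sep_data(seed = 9)
  lam <- 0.05
  f1 <- fit_predictor(d$expr, d$labels, paste0("g", 1:6),
                      alpha_grid = 1, lambda_grid = c(lam, lam * 0.9), seed = 1)
  f2 <- fit_predictor(d$expr, d$labels, paste0("g", 1:6),
                      alpha_grid = 1, lambda_grid = c(lam * 1.02, lam * 0.9),
                      seed = 1)
  expect_lt(max(abs(coef_at <- f1$coefficients - f2$coefficients)), 0.2)
})

test_that("LOOCV reaches 0.9 on separable subtypes and chance on noise", {
  co <- flat_subtype_cohort(60, n_masters = 10, effect = 2, seed = 41)
  acc <- loocv_accuracy(co$expr, co$truth$subtype_labels,
                        rownames(co$expr), alpha_grid = c(0.5, 1),
                        seed = 2)
  expect_gte(acc, 0.9)
  set.seed(42)
  null_labels <- setNames(sample(c("C1", "C2"), 60, TRUE),
                          colnames(co$expr))
  acc0 <- loocv_accuracy(co$expr, null_labels, rownames(co$expr),
                         alpha_grid = 1, seed = 3)
  expect_lt(acc0, max(mean(null_labels == "C1"),
                      mean(null_labels == "C2")) + 0.15)
  expect_error(loocv_accuracy(co$expr[, 1:5],
                              co$truth$subtype_labels[1:5],
                              rownames(co$expr)), "10 samples")
})

test_that("transfer is consistent in-sample and handles degenerate input", {
  d <- make_sep_data(seed = 13)
  fit <- fit_predictor(d$expr, d$labels, paste0("g", 1:6),
                       alpha_grid = 1, seed = 1)
  pred <- transfer_labels(fit, d$expr)
  expect_true(all(pred$prob_c1 > 0 & pred$prob_c1 < 1))
  expect_gte(mean(pred$label == d$labels[pred$sample]), 0.9)
  # constant expression scales to zero: probability = plogis(intercept)
  flat <- matrix(5, 6, 3, dimnames = list(paste0("g", 1:6), paste0("X", 1:3)))
  pf <- transfer_labels(fit, flat)
  expect_equal(pf$prob_c1, rep(plogis(fit$intercept), 3))
  expect_error(transfer_labels(fit, d$expr[1:3, ]), "g4")
  # case-insensitive gene matching
  up <- d$expr
  rownames(up) <- toupper(rownames(up))
  expect_silent(transfer_labels(fit, up))
})

test_that("predictor JSON serialization round-trips", {
  d <- make_sep_data(seed = 15)
  fit <- fit_predictor(d$expr, d$labels, paste0("g", 1:6),
                       alpha_grid = 0.75, seed = 1)
  path <- tempfile(fileext = ".json")
  write_predictor(fit, path)
  back <- read_predictor(path)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(back$intercept, fit$intercept)
  p1 <- transfer_labels(fit, d$expr)
  p2 <- transfer_labels(back, d$expr)
  expect_equal(p1, p2)
})
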