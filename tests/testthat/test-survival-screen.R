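test_that("filter_zero_heavy applies a strict 'more than' cut", {
  m <- rbind(zero7 = c(rep(0, 7), 1, 2, 3),
             zero8 = c(rep(0, 8), 1, 2),
             dense = rnorm(10),
             allzero = rep(0, 10))
  out <- filter_zero_heavy(m, 0.7)
  expect_identical(rownames(out), c("zero7", "dense"))  # 0.7 kept, 0.8 gone
  expect_identical(filter_zero_heavy(m, 1), m)
  expect_warning(filter_zero_heavy(m[4, , drop = FALSE], 0.5), "removed")
})

test_that("cox_screen recovers a planted effect and classifies direction", {
  # one prognostic gene per cohort: a univariate marginal fit of a correctly
  # specified model (omitting a second effect would attenuate the HR --
  # Cox models are non-collapsible)
  one_gene_cohort <- function(beta, seed) {
    dag <- matrix(0, 1, 1, dimnames = list("g", "g"))
    labs <- setNames(rep(c("C1", "C2"), 1000), sprintf("S%04d", 1:2000))
    truth <- ground_truth(dag, subtype_labels = labs,
                          cox_betas = c(g = beta))
    expr <- simulate_expression(truth, seed = seed)
    list(expr = expr,
         clin = simulate_survival(expr, truth, censor_rate = 0.2,
                                  seed = seed + 1))
  }
  up <- one_gene_cohort(1, 31)
  res_up <- cox_screen(up$expr, up$clin)
  expect_equal(res_up$coef, 1, tolerance = 0.1)
  expect_identical(res_up$direction, "unfavourable")
  expect_equal(res_up$hr, exp(res_up$coef))
  down <- one_gene_cohort(-0.8, 41)
  res_down <- cox_screen(down$expr, down$clin)
  expect_equal(res_down$coef, -0.8, tolerance = 0.1)
  expect_identical(res_down$direction, "favourable")
})

test_that("cox_screen handles duplicates, constants and alignment", {
  co <- flat_subtype_cohort(120, seed = 8)
  expr <- co$expr
  expr <- rbind(expr, dup = expr["M01", ], flat = rep(3, ncol(expr)))
  res <- cox_screen(expr, co$clin)
  r1 <- res[res$gene == "M01", -1]; r2 <- res[res$gene == "dup", -1]
  rownames(r1) <- rownames(r2) <- NULL
  expect_equal(r1, r2)
  flat_row <- res[res$gene == "flat", ]
  expect_identical(flat_row$direction, "none")
  expect_true(flat_row$flagged)
  expect_equal(flat_row$p, 1)
  # extra expression samples are dropped with a warning
  expr2 <- cbind(expr, EXTRA = rnorm(nrow(expr)))
  expect_warning(cox_screen(expr2, co$clin), "dropped")
})

test_that("cox coefficients transform correctly under rescaling", {
  co <- flat_subtype_cohort(200, seed = 12)
  res <- cox_screen(co$expr, co$clin)
  # time unit change: coefficients and p-values unchanged
  clin_days <- co$clin
  clin_days$time <- clin_days$time * 365.25
  res_days <- cox_screen(co$expr, clin_days)
  expect_equal(res$coef, res_days$coef, tolerance = 1e-6)
  expect_equal(res$p, res_days$p, tolerance = 1e-6)
  # expression scaled by c: coef' = coef / c
  res_scaled <- cox_screen(co$expr * 4, co$clin)
  expect_equal(res_scaled$coef, res$coef / 4, tolerance = 1e-6)
})

test_that("select_network_genes uses strict inequalities and keeps order", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    coef = c(0.2, 0.5, -0.6, 0.5),
                    p = c(0.001, 0.005, 0.009, 0.01))
  expect_identical(select_network_genes(res), c("b", "c"))  # a: |coef| not > 0.2; d: p not < 0.01
  expect_identical(select_network_genes(data.frame(gene = "x", coef = 1,
                                                   p = 0.5)), character(0))
})

test_that("compare_groups matches the empirical survival function without censoring", {
  clin <- data.frame(sample = paste0("S", 1:6),
                     time = c(1, 2, 3, 4, 5, 6), event = 1L)
  labels <- setNames(rep(c("A", "B"), each = 3), clin$sample)
  cg <- compare_groups(clin, labels)
  # group A died at 1, 2, 3: KM = empirical survival 2/3, 1/3, 0
  expect_equal(cg$km$A$surv, c(2, 1, 0) / 3)
  expect_true(all(diff(cg$km$B$surv) <= 0))
  expect_true(all(cg$km$B$surv <= 1))
  expect_error(compare_groups(clin, setNames(rep("A", 6), clin$sample)),
               "2 groups")
  labels0 <- setNames(c("A", "A", "A", "A", "A", "B"), clin$sample)
  clin0 <- clin; clin0$event[6] <- 0L
  expect_error(compare_groups(clin0, labels0), "at least one event")
})

test_that("log-rank p is calibrated under label permutation", {
  set.seed(99)
  n <- 80
  clin <- data.frame(sample = paste0("S", 1:n),
                     time = rexp(n), event = rbinom(n, 1, 0.8))
  ps <- replicate(400, {
    labels <- setNames(sample(rep(c("A", "B"), n / 2)), clin$sample)
    compare_groups(clin, labels)$logrank_p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.035)
})

test_that("Wald, score and log-rank tests agree for a binary covariate", {
  set.seed(4)
  n <- 300
  grp <- rep(0:1, each = n / 2)
  time <- rexp(n, exp(0.6 * grp))
  clin <- data.frame(sample = paste0("S", 1:n), time = time, event = 1L)
  expr <- matrix(grp, 1, n, dimnames = list("g", clin$sample))
  wald_p <- cox_screen(expr, clin)$p
  lr_p <- compare_groups(clin, setNames(grp, clin$sample))$logrank_p
  expect_equal(wald_p, lr_p, tolerance = 0.25 * lr_p + 0.002)
})
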