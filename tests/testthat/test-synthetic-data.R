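test_that("ground_truth validates its invariants", {
  g2 <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  labs <- setNames(c("C1", "C2", "C1", "C2"), paste0("S", 1:4))
  expect_s3_class(ground_truth(g2, subtype_labels = labs), "ground_truth")

  cyc <- g2; cyc["A", "B"] <- 1; cyc["B", "A"] <- 1
  expect_error(ground_truth(cyc, subtype_labels = labs), "cyclic")
  expect_error(ground_truth(g2, subtype_labels = unname(labs)), "named")
  expect_error(ground_truth(g2, master_genes = "Z", subtype_labels = labs),
               "dag nodes")
  expect_error(ground_truth(g2, subtype_labels = labs, noise_sd = 0),
               "positive")
  expect_error(ground_truth(g2, subtype_labels = labs,
                            cox_betas = c(A = Inf)), "finite")
})

test_that("empty DAG gives i.i.d. Gaussian genes with the stated moments", {
  n <- 5000
  truth <- flat_subtype_truth(n, n_masters = 6, effect = 0, beta = 0)
  expr <- simulate_expression(truth, seed = 7)
  se_mean <- 1 / sqrt(n)
  se_sd <- 1 / sqrt(2 * n)
  expect_true(all(abs(rowMeans(expr)) < 3 * se_mean))
  expect_true(all(abs(apply(expr, 1, sd) - 1) < 3 * se_sd))
  cc <- cor(t(expr))
  expect_lt(max(abs(cc[upper.tri(cc)])), 4 / sqrt(n))
})

test_that("a single unit-weight edge gives corr w/sqrt(w^2+1) = 1/sqrt(2)", {
  genes <- c("A", "B")
  dag <- matrix(0, 2, 2, dimnames = list(genes, genes))
  dag["A", "B"] <- 1
  labs <- setNames(rep(c("C1", "C2"), 5000), sprintf("S%05d", 1:10000))
  truth <- ground_truth(dag, subtype_labels = labs)
  expr <- simulate_expression(truth, seed = 11)
  expect_equal(cor(expr["A", ], expr["B", ]), 1 / sqrt(2), tolerance = 0.02)
})

test_that("expression generation is deterministic under seed and validates input", {
  truth <- make_demo_truth(n_samples = 50, seed = 3)
  e1 <- simulate_expression(truth, n_background = 5, seed = 9)
  e2 <- simulate_expression(truth, n_background = 5, seed = 9)
  expect_identical(e1, e2)
  e3 <- simulate_expression(truth, n_background = 5, seed = 10)
  expect_false(identical(e1, e3))
  labs3 <- setNames(c("C1", "C2", "C1"), paste0("S", 1:3))
  g1 <- matrix(0, 1, 1, dimnames = list("A", "A"))
  tiny <- ground_truth(g1, subtype_labels = labs3)
  expect_error(simulate_expression(tiny), ">= 4")
})

test_that("faithfulness hook: planted |weight| >= 0.5 gives |corr| >= 0.3 at n = 500", {
  for (w in c(0.5, -0.7, 1)) {
    genes <- c("A", "B")
    dag <- matrix(0, 2, 2, dimnames = list(genes, genes))
    dag["A", "B"] <- w
    labs <- setNames(rep(c("C1", "C2"), 250), sprintf("S%03d", 1:500))
    truth <- ground_truth(dag, subtype_labels = labs)
    for (seed in 1:5) {
      expr <- simulate_expression(truth, seed = seed)
      expect_gte(abs(cor(expr["A", ], expr["B", ])), 0.3)
    }
  }
})

test_that("survival honours degenerate censoring and the PH model", {
  co <- flat_subtype_cohort(300, effect = 0, seed = 5, censor_rate = 0)
  expect_true(all(co$clin$event == 1))
  expect_true(all(co$clin$time > 0))
  clin_all_cens <- simulate_survival(co$expr, co$truth, censor_rate = 1,
                                     seed = 2)
  expect_true(all(clin_all_cens$event == 0))
  expect_true(all(clin_all_cens$time > 0))
  clin_mid <- simulate_survival(co$expr, co$truth, censor_rate = 0.4,
                                seed = 2)
  expect_equal(mean(clin_mid$event == 0), 0.4, tolerance = 0.08)
  expect_error(simulate_survival(co$expr, co$truth, baseline_scale = -1),
               "positive")
})

test_that("planted Cox beta = 1 is recovered within 0.1 at n = 2000", {
  genes <- "A"
  dag <- matrix(0, 1, 1, dimnames = list(genes, genes))
  labs <- setNames(rep(c("C1", "C2"), 1000), sprintf("S%04d", 1:2000))
  truth <- ground_truth(dag, subtype_labels = labs,
                        cox_betas = c(A = 1))
  expr <- simulate_expression(truth, seed = 21)
  clin <- simulate_survival(expr, truth, censor_rate = 0.2, seed = 22)
  fit <- survival::coxph(survival::Surv(clin$time, clin$event) ~ expr["A", ])
  expect_equal(unname(coef(fit)), 1, tolerance = 0.1)
})

test_that("mutation generator realizes the cluster odds ratio", {
  truth <- make_demo_truth(n_samples = 5000, n_smgs = 4,
                           mutation_cluster_or = 1, seed = 2)
  mut <- simulate_mutations(truth, seed = 3)
  expect_identical(mut, simulate_mutations(truth, seed = 3))
  lab <- truth$subtype_labels[colnames(mut)]
  ors <- apply(mut, 1, function(m) {
    (sum(m == 1 & lab == "C1") * sum(m == 0 & lab == "C2")) /
      (sum(m == 1 & lab == "C2") * sum(m == 0 & lab == "C1"))
  })
  expect_true(all(abs(log(ors)) < 0.35))  # ~3 binomial SEs around log OR 0

  or4 <- make_demo_truth(n_samples = 5000, n_smgs = 4,
                         mutation_cluster_or = 4, seed = 2)
  mut4 <- simulate_mutations(or4, seed = 3)
  lab4 <- or4$subtype_labels[colnames(mut4)]
  ors4 <- apply(mut4, 1, function(m) {
    (sum(m == 1 & lab4 == "C1") * sum(m == 0 & lab4 == "C2")) /
      (sum(m == 1 & lab4 == "C2") * sum(m == 0 & lab4 == "C1"))
  })
  expect_true(all(abs(log(ors4) - log(4)) < 0.4))

  none <- make_demo_truth(n_samples = 100, n_smgs = 3, mutation_rate = 0,
                          mutation_cluster_or = 0, seed = 2)
  expect_true(all(simulate_mutations(none, seed = 1) == 0))
  expect_error(simulate_mutations(truth, samples = c("NOPE")), "unknown")
})

test_that("the subtype shift propagates from masters to their children", {
  truth <- make_demo_truth(n_samples = 2000, seed = 4)
  expr <- simulate_expression(truth, seed = 5)
  lab <- truth$subtype_labels
  child <- setdiff(rownames(truth$dag), truth$master_genes)[1]
  w <- sum(truth$dag[, child])
  shift <- mean(expr[child, lab == "C1"]) - mean(expr[child, lab == "C2"])
  expect_equal(shift, w * 2, tolerance = 0.25)  # both parents shifted by +2
})
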