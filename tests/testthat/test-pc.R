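test_that("cpdag objects validate and expose their edges", {
  a <- matrix(0L, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  a["A", "B"] <- 1L                      # directed A -> B
  a["B", "C"] <- 1L; a["C", "B"] <- 1L   # undirected B - C
  g <- cpdag(a)
  expect_identical(directed_edges(g),
                   data.frame(source = "A", target = "B",
                              stringsAsFactors = FALSE))
  expect_identical(undirected_edges(g)$source, "B")
  bad <- a; diag(bad) <- 1L
  expect_error(cpdag(bad), "self loops")
})

test_that("d-separation answers the canonical motifs", {
  # chain A -> B -> C
  chain <- matrix(0, 3, 3); chain[1, 2] <- chain[2, 3] <- 1
  expect_false(dsep(chain, 1, 3))
  expect_true(dsep(chain, 1, 3, 2))
  # fork A <- B -> C
  fork <- matrix(0, 3, 3); fork[2, 1] <- fork[2, 3] <- 1
  expect_false(dsep(fork, 1, 3))
  expect_true(dsep(fork, 1, 3, 2))
  # collider A -> B <- C: marginally independent, dependent given B
  # or given a descendant D of B
  coll <- matrix(0, 4, 4); coll[1, 2] <- coll[3, 2] <- 1; coll[2, 4] <- 1
  expect_true(dsep(coll, 1, 3))
  expect_false(dsep(coll, 1, 3, 2))
  expect_false(dsep(coll, 1, 3, 4))
})

test_that("a diagonal correlation matrix yields an empty graph", {
  corr <- diag(5)
  dimnames(corr) <- list(letters[1:5], letters[1:5])
  g <- pc_estimate(corr, 100, alpha = 0.3)
  expect_identical(nrow(directed_edges(g)), 0L)
  expect_identical(nrow(undirected_edges(g)), 0L)
  expect_error(pc_estimate(corr, 10, max_cond_size = 8), "exceed")
  expect_error(pc_estimate(corr, 100, alpha = 2), "alpha")
})

test_that("PC recovers the chain skeleton and the collider orientation", {
  genes <- c("A", "B", "C")
  chain <- matrix(0, 3, 3, dimnames = list(genes, genes))
  chain["A", "B"] <- 0.8; chain["B", "C"] <- 0.8
  labs <- setNames(rep(c("C1", "C2"), 2500), sprintf("S%04d", 1:5000))
  truth <- ground_truth(chain, subtype_labels = labs)
  expr <- simulate_expression(truth, seed = 55)
  g <- pc_estimate(bicor_matrix(expr), 5000)
  ue <- undirected_edges(g)
  expect_setequal(paste(ue$source, ue$target), c("A B", "B C"))
  expect_identical(nrow(directed_edges(g)), 0L)

  coll <- matrix(0, 3, 3, dimnames = list(genes, genes))
  coll["A", "C"] <- 0.8; coll["B", "C"] <- 0.8
  truth2 <- ground_truth(coll, subtype_labels = labs)
  expr2 <- simulate_expression(truth2, seed = 56)
  g2 <- pc_estimate(bicor_matrix(expr2), 5000)
  de <- directed_edges(g2)
  expect_setequal(paste(de$source, de$target), c("A C", "B C"))
})

test_that("both engines produce identical CPDAGs", {
  set.seed(17)
  for (rep in 1:6) {
    p <- sample(5:8, 1)
    A <- random_dag(p, max_edges = p + 2)
    w <- A * matrix(runif(p * p, 0.5, 1), p)
    dimnames(w) <- list(paste0("g", 1:p), paste0("g", 1:p))
    labs <- setNames(rep(c("C1", "C2"), 400), sprintf("S%03d", 1:800))
    truth <- ground_truth(w, subtype_labels = labs)
    expr <- simulate_expression(truth, seed = rep)
    corr <- bicor_matrix(expr)
    g_cpp <- pc_estimate(corr, 800, engine = "cpp")
    g_r <- pc_estimate(corr, 800, engine = "r")
    expect_identical(g_cpp$amat, g_r$amat)
  }
})

test_that("the stable-PC skeleton is invariant to gene input order", {
  truth <- make_demo_truth(n_samples = 400, n_children = 12,
                           children_per_hub = 3, subtype_effect = 0, seed = 2)
  expr <- simulate_expression(truth, seed = 3)
  corr <- bicor_matrix(expr)
  g1 <- pc_estimate(corr, 400)
  set.seed(71)
  perm <- sample(nrow(corr))
  g2 <- pc_estimate(corr[perm, perm], 400)
  back <- match(g1$nodes, g2$nodes)
  skel1 <- (g1$amat + t(g1$amat)) > 0
  skel2 <- (g2$amat + t(g2$amat)) > 0
  expect_identical(unname(skel1), unname(skel2[back, back]))
})

test_that("Meek rules close hand-constructed patterns", {
  # R1: A -> B, B - C, A and C nonadjacent  =>  B -> C
  a <- matrix(0L, 3, 3)
  a[1, 2] <- 1L
  a[2, 3] <- a[3, 2] <- 1L
  m <- prognet:::meek_rules(a)
  expect_identical(m[2, 3], 1L); expect_identical(m[3, 2], 0L)
  # R2: A -> B -> C with A - C  =>  A -> C
  a2 <- matrix(0L, 3, 3)
  a2[1, 2] <- 1L; a2[2, 3] <- 1L
  a2[1, 3] <- a2[3, 1] <- 1L
  m2 <- prognet:::meek_rules(a2)
  expect_identical(m2[1, 3], 1L); expect_identical(m2[3, 1], 0L)
  # R3: a - b, a - c, a - d, c -> b, d -> b, c/d nonadjacent  =>  a -> b
  a3 <- matrix(0L, 4, 4)
  a3[1, 2] <- a3[2, 1] <- 1L
  a3[1, 3] <- a3[3, 1] <- 1L
  a3[1, 4] <- a3[4, 1] <- 1L
  a3[3, 2] <- 1L; a3[4, 2] <- 1L
  m3 <- prognet:::meek_rules(a3)
  expect_identical(m3[1, 2], 1L); expect_identical(m3[2, 1], 0L)
})

test_that("dag_to_cpdag equals the enumeration oracle on random DAGs", {
  set.seed(23)
  for (rep in 1:30) {
    n <- sample(3:7, 1)
    A <- random_dag(n, max_edges = min(9, n * (n - 1) / 2))
    expect_identical(unname(cpdag_amat_of(dag_to_cpdag(A))),
                     oracle_cpdag_amat(A))
  }
})

test_that("rank-deficient correlation matrices are repaired with a warning", {
  set.seed(9)
  x <- matrix(rnorm(5 * 30), 5)
  x <- rbind(x, x[1, ])                 # exact duplicate gene
  rownames(x) <- paste0("g", 1:6)
  corr <- suppressWarnings(bicor_matrix(x))
  expect_warning(g <- pc_estimate(corr, 30), "positive definite")
  expect_s3_class(g, "cpdag")
})
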