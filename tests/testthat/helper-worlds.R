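# Small fixture worlds shared across test files.

# Flat world: k master genes on an empty DAG, sign-mixed C1 shift, Cox
# effects aligned so C1 has worse survival. The standard subtype fixture.
flat_subtype_truth <- function(n_samples, n_masters = 8, effect = 2,
                               beta = 0.3, seed = 1) {
  genes <- sprintf("M%02d", seq_len(n_masters))
  dag <- matrix(0, n_masters, n_masters, dimnames = list(genes, genes))
  sgn <- (-1)^(seq_len(n_masters) + 1)
  set.seed(seed)
  labels <- setNames(sample(c("C1", "C2"), n_samples, replace = TRUE),
                     sprintf("S%04d", seq_len(n_samples)))
  ground_truth(dag = dag, master_genes = genes, subtype_labels = labels,
               subtype_effect = setNames(effect * sgn, genes),
               cox_betas = setNames(beta * sgn, genes),
               noise_sd = 1)
}

# Expression + clinical for a flat subtype world in one call.
flat_subtype_cohort <- function(n_samples, n_masters = 8, effect = 2,
                                n_background = 0, censor_rate = 0.2,
                                seed = 1, beta = 0.3) {
  truth <- flat_subtype_truth(n_samples, n_masters, effect, beta, seed)
  expr <- simulate_expression(truth, n_background = n_background,
                              seed = seed + 1)
  clin <- simulate_survival(expr, truth, censor_rate = censor_rate,
                            seed = seed + 2)
  list(truth = truth, expr = expr, clin = clin)
}
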