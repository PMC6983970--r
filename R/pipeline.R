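#' Assemble a pipeline configuration
#'
#' Collects input paths and the stage thresholds (defaults are the
#' pipeline's standard operating point: zero filter 0.7, screen p 0.05,
#' network selection p 0.01 with |coef| 0.2, PC alpha 0.01, hub threshold
#' 5, k = 2 subtypes, 100 random-gene null repetitions, top-50 genes for
#' enrichment, top-10 for the predictor, association FDR 0.1).
#'
#' @param expr,clinical required input TSV paths.
#' @param mutations,pathways,smg_list optional input paths (mutation TSV /
#'   MAF-lite, GMT, one SMG id per line).
#' @param out_dir output directory (created if needed).
#' @param seed integer seed driving every stochastic stage.
#' @param scale expression scale (`"log2"`, `"ln"`, `"linear"`), used for
#'   fold changes.
#' @param thresholds named list overriding any default threshold.
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(expr, clinical, mutations = NULL,
                            pathways = NULL, smg_list = NULL,
                            out_dir, seed = 1, scale = "log2",
                            thresholds = list()) {
  defaults <- list(zero_frac = 0.7, screen_p = 0.05, network_p = 0.01,
                   min_abs_coef = 0.2, pc_alpha = 0.01, hub_threshold = 5,
                   k = 2, consensus_reps = 100, item_frac = 0.8,
                   null_reps = 100, null_consensus_reps = 30,
                   top_n_importance = 50, top_n_predictor = 10,
                   n_trees = 500, assoc_fdr = 0.1, max_cond_size = Inf,
                   cluster_distance = "pearson")
  unknown <- setdiff(names(thresholds), names(defaults))
  if (length(unknown)) stop("unknown thresholds: ", paste(unknown, collapse = ", "))
  th <- modifyList(defaults, thresholds)
  stopifnot(th$zero_frac >= 0, th$zero_frac <= 1,
            th$screen_p > 0, th$screen_p < 1,
            th$network_p > 0, th$network_p < 1,
            th$pc_alpha > 0, th$pc_alpha < 1,
            th$k >= 2, th$null_reps >= 1)
  structure(list(paths = list(expr = expr, clinical = clinical,
                              mutations = mutations, pathways = pathways,
                              smg_list = smg_list, out_dir = out_dir),
                 thresholds = th, seed = as.integer(seed), scale = scale),
            class = "pipeline_config")
}

# Hash of the analytic configuration (thresholds, seed, scale). Paths are
# deliberately excluded so the same analysis in a different directory is
# recognized as the same run.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(list(thresholds = config$thresholds,
                            seed = config$seed, scale = config$scale),
                       tmp, auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

# TSV writer that stamps the config hash as a leading comment line.
write_stage_table <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes screen -> network -> subtype (+ random-gene null) ->
#' characterize -> predictor on the configured inputs, writing every
#' intermediate artifact (stamped with the config hash) plus a JSON run
#' manifest to the output directory. Identical config + seed reproduce
#' identical outputs. A stage failure aborts with the stage name; earlier
#' outputs are retained.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (list), invisibly written to `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  th <- config$thresholds
  out <- config$paths$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  manifest <- list(package_version = as.character(utils::packageVersion("prognet")),
                   config_hash = hash, seed = config$seed,
                   config = unclass(config), stages = list())
  log_path <- file.path(out, "run.log")
  logf <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    secs <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    logf(name, " done in ", sprintf("%.1fs", secs))
    manifest$stages[[name]] <<- c(res, list(seconds = round(secs, 2)))
    res
  }

  # stage results shared across closures (assigned with <<- inside stages)
  expr_f <- NULL; screen_res <- NULL; masters <- NULL
  subtype_res <- NULL; null_res <- NULL; ranking_res <- NULL

  expr <- read_expression(config$paths$expr)
  clin <- read_clinical(config$paths$clinical)
  al <- align_samples(expr, clin)
  expr <- al$expr; clin <- al$clin
  logf("loaded ", nrow(expr), " genes x ", ncol(expr), " samples")

  screen <- stage("screen", function() {
    expr_f <<- filter_zero_heavy(expr, th$zero_frac)
    res <- cox_screen(expr_f, clin, p_sig = th$screen_p)
    write_stage_table(res, file.path(out, "screen.tsv"), hash)
    screen_res <<- res
    list(genes_after_zero_filter = nrow(expr_f),
         prognosis_relevant = sum(res$direction != "none"),
         favourable = sum(res$direction == "favourable"),
         unfavourable = sum(res$direction == "unfavourable"))
  })

  network <- stage("network", function() {
    genes <- select_network_genes(screen_res, th$network_p, th$min_abs_coef)
    if (length(genes) < 2)
      stop("fewer than 2 genes pass the network thresholds")
    corr <- bicor_matrix(expr_f[genes, , drop = FALSE])
    g <- pc_estimate(corr, n_samples = ncol(expr_f), alpha = th$pc_alpha,
                     max_cond_size = th$max_cond_size)
    write_cpdag(g, file.path(out, "network_edges.tsv"))
    deg <- summarize_degrees(g, th$hub_threshold)
    write_stage_table(deg, file.path(out, "degrees.tsv"), hash)
    masters <<- select_masters(deg)
    writeLines(masters, file.path(out, "masters.txt"))
    list(network_genes = length(genes),
         directed_edges = nrow(directed_edges(g)),
         undirected_edges = nrow(undirected_edges(g)),
         masters = length(masters))
  })

  subtype <- stage("subtype", function() {
    if (length(masters) == 0)
      stop("no master genes; cannot derive subtypes")
    scaled <- zscore_genes(expr_f[masters, , drop = FALSE])
    res <- consensus_cluster(scaled, k = th$k, n_reps = th$consensus_reps,
                             item_frac = th$item_frac, seed = config$seed,
                             clin = clin, distance = th$cluster_distance)
    subtype_res <<- res
    write_stage_table(data.frame(sample = names(res$labels),
                                 cluster = unname(res$labels)),
                      file.path(out, "subtype_labels.tsv"), hash)
    write_stage_table(data.frame(sample = rownames(res$consensus),
                                 res$consensus, check.names = FALSE),
                      file.path(out, "consensus_matrix.tsv"), hash)
    null <- random_gene_null(expr_f, clin, n_genes = length(masters),
                             n_reps = th$null_reps, seed = config$seed,
                             consensus_reps = th$null_consensus_reps,
                             item_frac = th$item_frac,
                             distance = th$cluster_distance)
    null_res <<- null
    observed <- -log10(res$logrank_p)
    write_stage_table(data.frame(rep = seq_len(null$n_reps),
                                 neglog10_p = null$neglog10_p),
                      file.path(out, "null_distribution.tsv"), hash)
    list(cluster_sizes = res$cluster_sizes, logrank_p = res$logrank_p,
         observed_neglog10_p = observed,
         null_p95 = unname(quantile(null$neglog10_p, 0.95)),
         empirical_null_p = empirical_null_p(observed, null))
  })

  characterize <- stage("characterize", function() {
    scaled <- zscore_genes(expr_f[masters, , drop = FALSE])
    ranking <- rank_importance(scaled, subtype_res$labels,
                               n_trees = th$n_trees, seed = config$seed)
    ranking_res <<- ranking
    write_stage_table(ranking, file.path(out, "importance_ranking.tsv"), hash)
    counts <- list(ranked_genes = nrow(ranking))
    if (!is.null(config$paths$pathways)) {
      pathways <- read_gmt(config$paths$pathways)
      universe <- intersect(rownames(expr_f), unique(unlist(pathways)))
      top <- intersect(head(ranking$gene, th$top_n_importance), universe)
      enr <- hypergeom_enrich(top, pathways, universe)
      write_stage_table(enr, file.path(out, "pathway_enrichment.tsv"), hash)
      counts$enriched_pathways <- sum(enr$fdr < th$assoc_fdr)
    }
    if (!is.null(config$paths$mutations)) {
      mut <- read_mutations(config$paths$mutations)
      smgs <- if (!is.null(config$paths$smg_list))
        intersect(readLines(config$paths$smg_list), rownames(mut))
      else rownames(mut)
      mut <- mut[smgs, , drop = FALSE]
      enr2 <- smg_cluster_enrichment(mut, subtype_res$labels)
      write_stage_table(enr2, file.path(out, "smg_cluster_enrichment.tsv"),
                        hash)
      assoc <- do.call(rbind, lapply(smgs, function(s)
        tryCatch(mutation_expression_assoc(expr_f, mut, s,
                                           scale = config$scale,
                                           fdr_max = th$assoc_fdr),
                 error = function(e) NULL)))
      if (!is.null(assoc))
        write_stage_table(assoc, file.path(out, "smg_expression_assoc.tsv"),
                          hash)
      counts$smgs_enriched_in_cluster <- sum(enr2$fdr < th$assoc_fdr)
      counts$smg_gene_associations <-
        if (is.null(assoc)) 0L else sum(assoc$significant)
    }
    counts
  })

  predictor <- stage("predictor", function() {
    top <- head(ranking_res$gene, th$top_n_predictor)
    acc <- loocv_accuracy(expr_f, subtype_res$labels, top,
                          seed = config$seed)
    fit <- fit_predictor(expr_f, subtype_res$labels, top,
                         seed = config$seed)
    write_predictor(fit, file.path(out, "subtype_predictor.json"))
    list(predictor_genes = length(top), loocv_accuracy = acc,
         alpha = fit$alpha, lambda = fit$lambda)
  })

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE, pretty = TRUE)
  logf("pipeline complete; manifest written")
  invisible(manifest)
}

#' Simulate a full synthetic cohort to disk
#'
#' Generates expression, clinical, mutation and pathway files (plus the
#' ground truth as JSON) for a [make_demo_truth()] world, ready for
#' [run_pipeline()].
#'
#' @param out_dir directory to write into.
#' @param seed integer seed.
#' @param n_samples,n_background,... forwarded to [make_demo_truth()] /
#'   [simulate_expression()].
#' @param censor_rate fraction of censored samples.
#' @return list of file paths plus the `truth` object.
#' @export
simulate_cohort <- function(out_dir, seed = 1, n_samples = 500,
                            n_background = 1000, censor_rate = 0.3, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- make_demo_truth(n_samples = n_samples, seed = seed, ...)
  expr <- simulate_expression(truth, n_background = n_background,
                              seed = seed + 1L)
  clin <- simulate_survival(expr, truth, censor_rate = censor_rate,
                            seed = seed + 2L)
  mut <- simulate_mutations(truth, seed = seed + 3L)
  # pathway fixture: one set holding the planted network, plus random decoys
  set.seed(seed + 4L)
  network_genes <- rownames(truth$dag)
  decoy_pool <- setdiff(rownames(expr), network_genes)
  pathways <- c(list(PLANTED_NETWORK = network_genes),
                setNames(lapply(1:9, function(i) sample(decoy_pool, 40)),
                         sprintf("DECOY_%02d", 1:9)))
  paths <- list(
    expr = file.path(out_dir, "expression.tsv"),
    clinical = file.path(out_dir, "clinical.tsv"),
    mutations = file.path(out_dir, "mutations.tsv"),
    pathways = file.path(out_dir, "pathways.gmt"),
    smg_list = file.path(out_dir, "smg_list.txt"),
    dag = file.path(out_dir, "true_dag.tsv"),
    truth_json = file.path(out_dir, "ground_truth.json"))
  write_expression(expr, paths$expr)
  write_clinical(clin, paths$clinical)
  write_mutations(mut, paths$mutations)
  write_gmt(pathways, paths$pathways)
  writeLines(truth$smg_genes, paths$smg_list)
  edges <- which(truth$dag != 0, arr.ind = TRUE)
  write.table(data.frame(source = rownames(truth$dag)[edges[, 1]],
                         target = colnames(truth$dag)[edges[, 2]],
                         weight = truth$dag[edges]),
              paths$dag, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(master_genes = truth$master_genes,
         shifted_masters = truth$shifted_masters,
         subtype_labels = as.list(truth$subtype_labels),
         subtype_effect = truth$subtype_effect,
         cox_betas = as.list(truth$cox_betas),
         smg_genes = truth$smg_genes,
         mutation_rate = truth$mutation_rate,
         mutation_cluster_or = truth$mutation_cluster_or,
         noise_sd = truth$noise_sd),
    paths$truth_json, auto_unbox = TRUE, digits = NA)
  c(paths, list(truth = truth))
}

#' One-command synthetic demo
#'
#' Simulates the default synthetic cohort (500 samples — the scale of the
#' TCGA-LUAD cohort —, 60 network genes with 8 planted hubs, 1000
#' background genes, 6 SMGs), runs the full pipeline on it, and evaluates
#' a self-check against the planted truth: hub recall of the master stage,
#' adjusted Rand index of the subtypes, and whether the observed subtype
#' -log10 log-rank p exceeds the random-gene null's 95th percentile.
#'
#' The demo configuration caps PC conditioning sets at 3 and clusters with
#' the Euclidean distance: the planted subtype program shifts all master
#' genes in the same direction, which a profile-correlation distance is
#' mathematically blind to (it removes per-sample profile means).
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param quick smaller, faster world (250 samples, 300 background genes,
#'   20 null repetitions, 200 trees) for smoke tests; the self-check is
#'   reported but not expected to clear its thresholds at that size.
#' @return the pipeline manifest with an added `self_check` entry.
#' @export
run_demo <- function(out_dir = tempfile("prognet_demo_"), seed = 1,
                     quick = FALSE) {
  sim_dir <- file.path(out_dir, "input")
  sim <- if (quick)
    simulate_cohort(sim_dir, seed = seed, n_samples = 250,
                    n_background = 300)
  else simulate_cohort(sim_dir, seed = seed)
  th <- list(max_cond_size = 3, cluster_distance = "euclidean")
  if (quick) th <- c(th, list(null_reps = 20, n_trees = 200))
  config <- pipeline_config(expr = sim$expr, clinical = sim$clinical,
                            mutations = sim$mutations,
                            pathways = sim$pathways,
                            smg_list = sim$smg_list,
                            out_dir = file.path(out_dir, "results"),
                            seed = seed, thresholds = th)
  manifest <- run_pipeline(config)
  truth <- sim$truth
  masters_found <- readLines(file.path(out_dir, "results", "masters.txt"))
  recall <- mean(truth$master_genes %in% masters_found)
  lab_df <- read.delim(file.path(out_dir, "results", "subtype_labels.tsv"),
                       comment.char = "#", stringsAsFactors = FALSE)
  ari <- adjusted_rand_index(truth$subtype_labels[lab_df$sample],
                             lab_df$cluster)
  st <- manifest$stages$subtype
  manifest$self_check <- list(
    hub_recall = recall,
    subtype_ari = ari,
    observed_above_null_p95 = st$observed_neglog10_p > st$null_p95,
    pass = recall >= 0.75 && ari >= 0.9 &&
      st$observed_neglog10_p > st$null_p95)
  jsonlite::write_json(manifest,
                       file.path(out_dir, "results", "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE, pretty = TRUE)
  invisible(manifest)
}
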