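# Shared simulated fixtures. All are built in code at test time; nothing is
# stored on disk.

# default desk-scale fixture: 40 TFs, 10 modules x 20 genes, 2 conditions x 3
# replicates (the study's six-sample design)
default_sim <- function(seed = 1) {
  net <- simulate_network(40, 10, seed = seed)
  simulate_expression(net, n_conditions = 2, n_replicates = 3,
                      genes_per_module = 20, seed = seed)
}

# wide fixture: same truth scale, 30 conditions x 2 replicates, so network
# inference has enough columns to be statistically meaningful
wide_sim <- function(seed = 1) {
  net <- simulate_network(40, 10, seed = seed)
  simulate_expression(net, n_conditions = 30, n_replicates = 2,
                      genes_per_module = 20, seed = seed)
}

# low-noise module-recovery fixture: 10 modules each driven by its own TF
# with equal |weight|, enough conditions that each module's realized signal
# variance is comparable (see the methods vignette for why equal signals are
# required for K identifiability under pooled-variance BIC)
recovery_truth <- function(seed = 1) {
  net <- simulate_network(10, 10, edge_density = 0, seed = seed)
  net$edges <- tibble::tibble(tf = net$tf_ids, module = net$module_ids,
                              weight = rep(c(1, -1), length.out = 10))
  net
}

recovery_sim <- function(seed = 1) {
  simulate_expression(recovery_truth(seed), n_conditions = 12,
                      n_replicates = 2, genes_per_module = 20,
                      module_noise_sd = 0.05, gene_noise_sd = 0.1,
                      nb_dispersion = 0.02, libsize_cv = 0.05,
                      base_log_mean = log(500), seed = seed)
}

# module assignment fixed to the generator's true membership
true_assignment <- function(sim) {
  mods <- unique(sim$module_membership$module)
  structure(list(labels = stats::setNames(match(sim$module_membership$module, mods),
                                          sim$module_membership$gene),
                 k = length(mods)),
            class = "module_assignment")
}

# condition-averaged log2(FPKM + 1), the clustering input
log_fpkm_avg <- function(sim) {
  fl <- fpkm(sim$counts, sim$gene_lengths, log2 = TRUE)
  average_replicates(fl, sim$sample_sheet)
}

# row-standardized recovery clustering input (module genes only)
recovery_X <- function(sim) {
  X <- log_fpkm_avg(sim)[sim$module_membership$gene, ]
  t(scale(t(X)))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# one wide-fixture evaluation: method scores on the true module structure,
# plus consensus precision and sign metrics against the planted network.
# Cached because several test files and the acceptance suite reuse seeds.
.wide_cache <- new.env(parent = emptyenv())

wide_metrics <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.wide_cache[[key]])) return(.wide_cache[[key]])
  net <- simulate_network(40, 10, seed = seed)
  sim <- simulate_expression(net, n_conditions = 30, n_replicates = 2,
                             genes_per_module = 20, seed = seed)
  fl <- fpkm(sim$counts, sim$gene_lengths, log2 = TRUE)
  prof <- module_profiles(true_assignment(sim), fl)
  im <- build_inference_matrix(prof, fl[sim$tf_ids, ], sim$tf_ids)
  scores <- suppressWarnings(
    run_all_methods(im, n_resamples = 100, seed = seed))
  truth_key <- paste(net$edges$tf, net$edges$module)
  is_true <- function(tf, module) paste(tf, module) %in% truth_key

  # per-method rank dominance of true pairs over null pairs (AUROC) and the
  # raw medians
  per_method <- lapply(scores, function(s) {
    v <- as.vector(unclass(s))
    truth <- is_true(rep(rownames(s), times = ncol(s)),
                     rep(colnames(s), each = nrow(s)))
    r <- rank(v, ties.method = "average")
    auroc <- (mean(r[truth]) - (sum(truth) + 1) / 2) / sum(!truth)
    c(auroc = auroc, med_true = stats::median(v[truth]),
      med_null = stats::median(v[!truth]))
  })

  precision_at <- function(ms) {
    cn <- build_consensus_network(scores, im, min_support = ms)
    e <- cn$edges
    if (!nrow(e)) return(c(precision = NA_real_, n = 0))
    c(precision = mean(is_true(e$tf, e$module)), n = nrow(e))
  }
  p4 <- precision_at(4); p2 <- precision_at(2)

  cn4 <- build_consensus_network(scores, im, min_support = 4)
  et <- dplyr::inner_join(cn4$edges, net$edges, by = c("tf", "module"))
  res <- list(per_method = per_method,
              precision4 = p4[["precision"]], n4 = p4[["n"]],
              precision2 = p2[["precision"]], n2 = p2[["n"]],
              true_retained = nrow(et),
              sign_correct = sum(sign(et$score) == sign(et$weight)))
  .wide_cache[[key]] <- res
  res
}

# random inference matrix for method-surface tests
toy_infmat <- function(n_modules, n_tfs, n_cols, seed = 1) {
  withr::with_seed(seed, {
    prof <- matrix(stats::rnorm(n_modules * n_cols), n_modules, n_cols,
                   dimnames = list(sprintf("module_%02d", seq_len(n_modules)),
                                   sprintf("L%02d", seq_len(n_cols))))
    tfx <- matrix(stats::rnorm(n_tfs * n_cols), n_tfs, n_cols,
                  dimnames = list(sprintf("TF%03d", seq_len(n_tfs)),
                                  sprintf("L%02d", seq_len(n_cols))))
    build_inference_matrix(prof, tfx, rownames(tfx))
  })
}

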