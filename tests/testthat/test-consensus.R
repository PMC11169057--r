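score_mat <- function(values, n_tfs, n_modules) {
  matrix(values, n_tfs, n_modules,
         dimnames = list(sprintf("TF%03d", seq_len(n_tfs)),
                         sprintf("module_%02d", seq_len(n_modules))))
}

test_that("per-method calls honour the top fraction and are monotone", {
  s <- score_mat(1:100, 10, 10)
  expect_true(all(call_edges(s, top_fraction = 1)))
  expect_identical(sum(call_edges(s, top_fraction = 0.02)), 2L)
  expect_true(all(call_edges(s, 0.02)[s >= 99]))

  # raising the fraction never removes a call
  c1 <- call_edges(s, 0.05); c2 <- call_edges(s, 0.2)
  expect_true(all(c2[c1]))

  expect_error(call_edges(s, 0), "proportion")
})

test_that("consensus voting counts support and is monotone in min_support", {
  calls <- list(
    a = score_mat(c(TRUE, TRUE, TRUE, FALSE), 2, 2),
    b = score_mat(c(TRUE, TRUE, FALSE, FALSE), 2, 2),
    c = score_mat(c(TRUE, TRUE, TRUE, FALSE), 2, 2),
    d = score_mat(c(TRUE, FALSE, TRUE, FALSE), 2, 2))
  cs4 <- consensus_support(calls, 4)
  expect_identical(nrow(cs4), 1L)  # only TF001/module_01 called by all four
  expect_identical(cs4$support, 4L)
  # a 3-of-4 pair is dropped at min_support 4 but kept at 3
  cs3 <- consensus_support(calls, 3)
  expect_setequal(paste(cs3$tf, cs3$module),
                  c("TF001 module_01", "TF002 module_01", "TF001 module_02"))
  # retained set shrinks as min_support grows
  sizes <- vapply(0:4, function(k) nrow(consensus_support(calls, k)), integer(1))
  expect_true(all(diff(sizes) <= 0))

  expect_warning(empty <- consensus_support(calls, 5), "exceeds")
  expect_identical(nrow(empty), 0L)
})

test_that("consensus score: maximal agreement, antisymmetry, zero variance", {
  # all TFs correlate positively with module_01 so every pair's Spearman
  # sign is +1 and the top-ranked pair is unambiguously maximal
  im <- withr::with_seed(70, {
    base <- stats::rnorm(12)
    tfx <- rbind(TF001 = base + stats::rnorm(12, 0, 0.05),
                 TF002 = base + stats::rnorm(12, 0, 0.6),
                 TF003 = base + stats::rnorm(12, 0, 0.6))
    colnames(tfx) <- sprintf("L%02d", 1:12)
    prof <- rbind(module_01 = base + stats::rnorm(12, 0, 0.05),
                  module_02 = base + stats::rnorm(12, 0, 0.6))
    colnames(prof) <- colnames(tfx)
    build_inference_matrix(prof, tfx, rownames(tfx))
  })
  # TF001/module_01 at the top rank of every method with positive Spearman:
  # S equals the sum of the maximal z and is the maximum over pairs
  scores <- list(m1 = score_mat(c(6, 1, 2, 3, 4, 5), 3, 2),
                 m2 = score_mat(c(60, 10, 20, 30, 40, 50), 3, 2),
                 m3 = score_mat(c(0.9, 0.1, 0.2, 0.3, 0.4, 0.5), 3, 2),
                 m4 = score_mat(c(10, 3, 5, 7, 8, 9), 3, 2))
  S <- consensus_score(scores, im)
  zmax <- stats::qnorm(6 / 7)
  expect_equal(S["TF001", "module_01"], 4 * zmax)
  expect_identical(which.max(S), which(rownames(S) == "TF001"))

  # negating the module profile negates S for its pairs
  im_neg <- im
  im_neg["module_01", ] <- -im_neg["module_01", ]
  S_neg <- consensus_score(scores, im_neg)
  expect_equal(S_neg[, "module_01"], -S[, "module_01"])
  expect_equal(S_neg[, "module_02"], S[, "module_02"])

  # zero-variance module profile -> sign 0 -> S 0, with warning
  im_flat <- im
  im_flat["module_02", ] <- 1
  expect_warning(S_flat <- consensus_score(scores, im_flat), "zero-variance")
  expect_true(all(S_flat[, "module_02"] == 0))
})

test_that("edge classification follows the +/-5 and +/-10 thresholds", {
  expect_identical(classify_edges(12), "highly_significant_activator")
  expect_identical(classify_edges(-12), "highly_significant_suppressor")
  expect_identical(classify_edges(3), "unclassified")
  expect_identical(classify_edges(7), "activator")
  expect_identical(classify_edges(-7), "suppressor")
  # boundaries: |S| <= sig unclassified; S >= high highly significant
  expect_identical(classify_edges(c(5, -5, 10, -10)),
                   c("unclassified", "unclassified",
                     "highly_significant_activator",
                     "highly_significant_suppressor"))

  # partition: every S gets exactly one label; inversion maps activator
  # classes onto suppressor classes
  S <- withr::with_seed(71, stats::rnorm(200, 0, 8))
  lab <- classify_edges(S)
  expect_identical(length(lab), 200L)
  expect_true(all(lab %in% c("highly_significant_activator", "activator",
                             "suppressor", "highly_significant_suppressor",
                             "unclassified")))
  flipped <- classify_edges(-S)
  map <- c(highly_significant_activator = "highly_significant_suppressor",
           activator = "suppressor",
           suppressor = "activator",
           highly_significant_suppressor = "highly_significant_activator",
           unclassified = "unclassified")
  expect_identical(unname(map[lab]), flipped)

  expect_error(classify_edges(1, sig = 10, high = 5), "sig")
})

test_that("network stats: star degrees and bipartite conservation", {
  im <- toy_infmat(5, 3, 10, seed = 72)
  edges <- tibble::tibble(
    tf = c(rep("TF001", 5), "TF002"),
    module = c(sprintf("module_%02d", 1:5), "module_01"),
    support = 4L, score = 6, sign = "+", class = "activator")
  net <- structure(list(edges = edges,
                        nodes = tibble::tibble(
                          id = c(sprintf("TF%03d", 1:3), sprintf("module_%02d", 1:5)),
                          kind = c(rep("tf", 3), rep("module", 5))),
                        n_methods = 4L,
                        params = list(min_support = 4L)),
                   class = "consensus_network")
  st <- network_stats(net)
  expect_identical(st$degree$degree[st$degree$id == "TF001"], 5L)
  expect_identical(st$hubs$id[st$hubs$kind == "tf"], "TF001")
  expect_identical(st$hubs$id[st$hubs$kind == "module"], "module_01")
  tf_deg <- sum(st$degree$degree[st$degree$kind == "tf"])
  mod_deg <- sum(st$degree$degree[st$degree$kind == "module"])
  expect_identical(tf_deg, nrow(edges))
  expect_identical(mod_deg, nrow(edges))

  empty <- structure(list(edges = edges[0, ], nodes = net$nodes,
                          n_methods = 4L, params = list(min_support = 4L)),
                     class = "consensus_network")
  st0 <- network_stats(empty)
  expect_identical(nrow(st0$degree), 0L)
})

test_that("network export round-trips TSV and writes valid SIF/GraphML", {
  im <- toy_infmat(4, 8, 20, seed = 73)
  scores <- suppressWarnings(run_all_methods(im, n_resamples = 20, seed = 73))
  net <- build_consensus_network(scores, im, top_fraction = 0.3, min_support = 2)
  expect_gt(nrow(net$edges), 0)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tsv, "tsv")
  back <- read_network_tsv(tsv)
  expect_identical(back$tf, net$edges$tf)
  expect_identical(back$module, net$edges$module)
  expect_identical(back$support, net$edges$support)
  expect_identical(back$class, net$edges$class)
  expect_equal(back$score, net$edges$score, tolerance = 1e-12)

  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  lines <- readLines(sif)
  expect_identical(length(lines), nrow(net$edges))
  expect_true(all(grepl("^\\S+\tregulates\t\\S+$", lines)))

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  expect_no_error(xml2::read_xml(gml))  # well-formed XML
  g <- igraph::read_graph(gml, format = "graphml")
  expect_identical(igraph::ecount(g), as.numeric(nrow(net$edges)))
  expect_true(all(c("support", "score", "class") %in%
                    igraph::edge_attr_names(g)))
  expect_true("kind" %in% igraph::vertex_attr_names(g))

  # empty network -> header-only TSV
  empty_net <- build_consensus_network(scores, im, top_fraction = 0.01,
                                       min_support = 4)
  if (nrow(empty_net$edges) == 0) {
    tsv0 <- withr::local_tempfile(fileext = ".tsv")
    export_network(empty_net, tsv0, "tsv")
    expect_identical(readLines(tsv0), "tf\tmodule\tsupport\tscore\tclass")
  }

  expect_error(export_network(net, tsv, "gexf"), "arg")
})

test_that("consensus on the wide fixture is precise and correctly signed", {
  mets <- lapply(1:20, wide_metrics)
  p4 <- vapply(mets, `[[`, numeric(1), "precision4")
  p2 <- vapply(mets, `[[`, numeric(1), "precision2")
  # median precision at min_support 4 over 20 seeds
  expect_gte(stats::median(p4, na.rm = TRUE), 0.7)
  # stricter support never hurts precision (medians)
  expect_gte(stats::median(p4, na.rm = TRUE), stats::median(p2, na.rm = TRUE))
  # planted activators get S > 0, suppressors S < 0 for >= 90% of the
  # retained true edges (pooled over seeds)
  retained <- sum(vapply(mets, `[[`, numeric(1), "true_retained"))
  correct <- sum(vapply(mets, `[[`, numeric(1), "sign_correct"))
  expect_gt(retained, 0)
  expect_gte(correct / retained, 0.9)
})
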