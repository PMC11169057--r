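#' Median-of-ratios size factors
#'
#' Per-sample normalization constants: each sample's factor is the median,
#' over reference genes, of the ratio of its count to the gene's geometric
#' mean across samples. Genes with a zero count in any sample are excluded
#' from the reference set. Factors are rescaled to geometric mean 1 so they
#' are identifiable.
#'
#' @param counts Gene x sample count matrix with dimnames.
#' @return Named positive numeric vector, one factor per sample, geometric
#'   mean exactly 1.
#' @examples
#' m <- matrix(c(10, 100, 5, 20, 200, 10), 3,
#'             dimnames = list(paste0("g", 1:3), c("A", "B")))
#' size_factors(m)  # c(1/sqrt(2), sqrt(2))
#' @export
size_factors <- function(counts) {
  check_count_matrix(counts)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    abort("degenerate input: no gene has a nonzero count in every sample")
  }
  logc <- log(counts[ref, , drop = FALSE])
  log_geo <- rowMeans(logc)
  raw <- apply(logc - log_geo, 2, stats::median)
  f <- exp(raw - mean(raw))  # rescale to geometric mean 1
  stats::setNames(f, colnames(counts))
}

#' FPKM expression matrix
#'
#' Fragments per kilobase per million, computed on normalized counts:
#' `FPKM_gs = (count_gs / factor_s) / ((length_g / 1000) * (N_s / 1e6))`
#' where `N_s = sum_g count_gs / factor_s` is the normalized library size.
#' Using the normalized library size as the per-million denominator means
#' scaling one sample's counts leaves its FPKM column unchanged.
#'
#' @param counts Gene x sample count matrix.
#' @param gene_lengths Named vector of gene lengths in bp; must cover every
#'   gene in `counts`.
#' @param factors Per-sample size factors; computed by [size_factors()] if
#'   omitted.
#' @param log2 If `TRUE`, return `log2(FPKM + 1)`.
#' @return Numeric matrix of the same shape as `counts` with attributes
#'   `scale` (`"linear"` or `"log2"`) and `size_factors`.
#' @export
fpkm <- function(counts, gene_lengths, factors = NULL, log2 = FALSE) {
  check_count_matrix(counts)
  missing <- setdiff(rownames(counts), names(gene_lengths))
  if (length(missing)) {
    abort(sprintf("missing gene lengths for: %s%s",
                  paste(head(missing, 5), collapse = ", "),
                  if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5) else ""))
  }
  len <- gene_lengths[rownames(counts)]
  if (any(len <= 0)) abort("gene lengths must be positive")
  if (is.null(factors)) factors <- size_factors(counts)
  norm <- sweep(counts, 2, factors, "/")
  n_s <- colSums(norm)
  out <- sweep(norm / (len / 1000), 2, n_s / 1e6, "/")
  if (log2) out <- log2(out + 1)
  attr(out, "scale") <- if (log2) "log2" else "linear"
  attr(out, "size_factors") <- factors
  out
}

# Vectorized Welch two-sample test on rows; returns two-sided p-values.
# When both group variances are zero: p = 1 if the means agree, 0 otherwise.
welch_rows <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1, stats::var); vb <- apply(xb, 1, stats::var)
  se2 <- va / na + vb / nb
  tstat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  zero_se <- se2 == 0
  p[zero_se & abs(mb - ma) < .Machine$double.eps^0.5] <- 1
  p[zero_se & abs(mb - ma) >= .Machine$double.eps^0.5] <- 0
  p
}

#' Two-group differential-expression test
#'
#' Computes, per gene, the mean normalized count, the pseudocounted log2 fold
#' change `log2((mean_B + c) / (mean_A + c))` (positive = higher in the
#' treatment group B), and a two-sided Welch t p-value on
#' `log2(normalized count + 1)`. The Welch test is a deliberately simple
#' p-value engine; a p-value column computed elsewhere can be supplied via
#' `p_override` and the fold-change/filter machinery is unchanged.
#'
#' @param counts Gene x sample count matrix.
#' @param group_a,group_b Character vectors of sample IDs (control and
#'   treatment); disjoint, each of size >= 2.
#' @param factors Size factors; computed from the full matrix if omitted.
#' @param pseudocount Pseudocount `c` for the fold change (default 1).
#' @param lfc_min,p_max Thresholds used for the `call` column (see
#'   [filter_degs()]).
#' @param p_override Optional named numeric vector of p-values replacing the
#'   Welch p (names = gene IDs).
#' @return Tibble with columns `gene`, `base_mean`, `log2fc`, `p_value`,
#'   `call` (`"up"`, `"down"` or `"ns"`).
#' @export
deg_test <- function(counts, group_a, group_b, factors = NULL,
                     pseudocount = 1, lfc_min = 1, p_max = 0.05,
                     p_override = NULL) {
  check_count_matrix(counts)
  if (length(intersect(group_a, group_b))) {
    abort(sprintf("groups overlap: %s",
                  paste(intersect(group_a, group_b), collapse = ", ")))
  }
  missing <- setdiff(c(group_a, group_b), colnames(counts))
  if (length(missing)) {
    abort(sprintf("unknown sample IDs: %s", paste(missing, collapse = ", ")))
  }
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 samples")
  }
  if (is.null(factors)) factors <- size_factors(counts)
  norm <- sweep(counts, 2, factors[colnames(counts)], "/")
  na_mat <- norm[, group_a, drop = FALSE]
  nb_mat <- norm[, group_b, drop = FALSE]
  mean_a <- rowMeans(na_mat)
  mean_b <- rowMeans(nb_mat)
  log2fc <- log2((mean_b + pseudocount) / (mean_a + pseudocount))
  p <- welch_rows(log2(na_mat + 1), log2(nb_mat + 1))
  if (!is.null(p_override)) {
    idx <- match(rownames(counts), names(p_override))
    if (anyNA(idx)) abort("`p_override` must name every gene in `counts`")
    p <- unname(p_override[idx])
  }
  tibble::tibble(
    gene = rownames(counts),
    base_mean = rowMeans(norm[, c(group_a, group_b), drop = FALSE]),
    log2fc = unname(log2fc),
    p_value = unname(p),
    call = dplyr::case_when(
      log2fc >= lfc_min & p < p_max ~ "up",
      log2fc <= -lfc_min & p < p_max ~ "down",
      TRUE ~ "ns"
    )
  )
}

#' Filter a DEG table into up/down/all gene sets
#'
#' Applies the fold-change and p-value rule: a gene is differentially
#' expressed iff `|log2fc| >= lfc_min` (inclusive) and `p < p_max` (strict).
#'
#' @param deg_table Tibble from [deg_test()] (columns `gene`, `log2fc`,
#'   `p_value`).
#' @param lfc_min Minimum absolute log2 fold change (inclusive), > 0.
#' @param p_max p-value ceiling (strict), > 0.
#' @return List with character vectors `up`, `down`, and `all_de = up | down`.
#' @export
filter_degs <- function(deg_table, lfc_min = 1, p_max = 0.05) {
  check_positive(lfc_min, "lfc_min")
  check_positive(p_max, "p_max")
  sig <- deg_table$p_value < p_max
  up <- deg_table$gene[sig & deg_table$log2fc >= lfc_min]
  down <- deg_table$gene[sig & deg_table$log2fc <= -lfc_min]
  list(up = up, down = down, all_de = c(up, down))
}

#' Sample quality control: correlation matrix and PCoA
#'
#' Pairwise Pearson correlation between sample columns and classical
#' multidimensional scaling (principal coordinates) on the distance
#' `d = 1 - r`. Zero-variance samples are flagged, excluded from the PCoA
#' with a warning, and listed in the result.
#'
#' @param expr Gene x sample expression matrix (FPKM or log2 FPKM).
#' @param sample_sheet Optional tibble with `sample` and `condition` columns;
#'   if given, conditions are attached to the PCoA coordinates (handy for
#'   plotting).
#' @return A `sample_qc` object: list with `correlation` (symmetric matrix,
#'   unit diagonal), `pcoa` (tibble: sample, axis1, axis2, and condition if
#'   supplied), `eig` (MDS eigenvalues), `excluded` (character).
#' @export
sample_qc <- function(expr, sample_sheet = NULL) {
  if (ncol(expr) < 3) abort("sample_qc needs at least 3 samples")
  sds <- apply(expr, 2, stats::sd)
  excluded <- colnames(expr)[sds == 0]
  if (length(excluded)) {
    warn(sprintf("zero-variance sample(s) excluded from PCoA: %s",
                 paste(excluded, collapse = ", ")))
  }
  keep <- setdiff(colnames(expr), excluded)
  r <- suppressWarnings(stats::cor(expr))
  diag(r) <- 1
  rk <- r[keep, keep, drop = FALSE]
  d <- stats::as.dist(1 - rk)
  k <- min(2L, length(keep) - 1L)
  mds <- stats::cmdscale(d, k = k, eig = TRUE)
  coords <- mds$points
  if (ncol(coords) < 2) coords <- cbind(coords, 0)
  pcoa <- tibble::tibble(sample = keep,
                         axis1 = coords[, 1], axis2 = coords[, 2])
  if (!is.null(sample_sheet)) {
    pcoa <- dplyr::left_join(pcoa,
                             dplyr::select(sample_sheet, "sample", "condition"),
                             by = "sample")
  }
  structure(list(correlation = r, pcoa = pcoa, eig = mds$eig,
                 excluded = excluded),
            class = "sample_qc")
}

#' @export
print.sample_qc <- function(x, ...) {
  cat(sprintf("<sample_qc> %d samples; mean off-diagonal correlation %.3f\n",
              ncol(x$correlation),
              mean(x$correlation[upper.tri(x$correlation)])))
  invisible(x)
}

#' MA-plot data from a DEG table
#'
#' @param deg_table Tibble from [deg_test()].
#' @param p_max Significance flag rule: `significant = p_value < p_max`.
#' @return Tibble with `gene`, `mean_expr` (normalized mean), `log2fc`,
#'   `significant`.
#' @export
ma_data <- function(deg_table, p_max = 0.05) {
  if (!nrow(deg_table)) abort("`deg_table` is empty")
  tibble::tibble(gene = deg_table$gene,
                 mean_expr = deg_table$base_mean,
                 log2fc = deg_table$log2fc,
                 significant = deg_table$p_value < p_max)
}

#' Average expression over replicates, per condition
#'
#' @param expr Gene x sample matrix.
#' @param sample_sheet Tibble with `sample` and `condition`; must cover every
#'   column of `expr`.
#' @return Gene x condition matrix (arithmetic mean of member samples);
#'   condition order follows first appearance in the sheet.
#' @export
average_replicates <- function(expr, sample_sheet) {
  unmapped <- setdiff(colnames(expr), sample_sheet$sample)
  if (length(unmapped)) {
    abort(sprintf("sample(s) missing from sample sheet: %s",
                  paste(unmapped, collapse = ", ")))
  }
  cond <- sample_sheet$condition[match(colnames(expr), sample_sheet$sample)]
  levels <- unique(sample_sheet$condition)
  out <- vapply(levels, function(cc) {
    rowMeans(expr[, cond == cc, drop = FALSE])
  }, numeric(nrow(expr)))
  dimnames(out) <- list(rownames(expr), levels)
  out
}
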