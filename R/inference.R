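#' Stack module profiles and regulator profiles into one inference matrix
#'
#' Rows are the module mean profiles followed by the differentially expressed
#' TF profiles; columns are the experimental lines. Only TFs listed in
#' `de_tf_ids` are retained.
#'
#' @param profiles Module x line matrix.
#' @param tf_expr TF x line matrix (same columns, same order).
#' @param de_tf_ids TF gene IDs to keep (the differentially expressed ones).
#' @return Numeric matrix with attribute `row_kind` (`"module"` or `"tf"`
#'   per row), class `inference_matrix`.
#' @export
build_inference_matrix <- function(profiles, tf_expr, de_tf_ids) {
  if (!identical(colnames(profiles), colnames(tf_expr))) {
    diff <- union(setdiff(colnames(profiles), colnames(tf_expr)),
                  setdiff(colnames(tf_expr), colnames(profiles)))
    abort(sprintf("column (line) sets differ or are ordered differently: %s",
                  paste(if (length(diff)) diff else colnames(profiles),
                        collapse = ", ")))
  }
  keep <- intersect(rownames(tf_expr), de_tf_ids)
  if (!length(keep)) {
    warn("no differentially expressed TFs retained; inference cannot run on a module-only matrix")
  }
  tf_rows <- tf_expr[keep, , drop = FALSE]
  if (length(intersect(rownames(profiles), rownames(tf_rows)))) {
    abort("module and TF row IDs overlap")
  }
  m <- rbind(profiles, tf_rows)
  attr(m, "row_kind") <- c(rep("module", nrow(profiles)), rep("tf", nrow(tf_rows)))
  class(m) <- c("inference_matrix", class(m))
  m
}

row_kind <- function(mat) {
  rk <- attr(mat, "row_kind")
  if (is.null(rk)) abort("matrix lacks a `row_kind` attribute; build it with build_inference_matrix()")
  rk
}

#' Mutual information between two vectors
#'
#' Two estimators: `"gauss_copula"` computes `-0.5 * log(1 - rho^2)` nats with
#' `rho` the Pearson correlation of rank-normal scores (robust at small n,
#' invariant under monotone transforms); `"binned"` is the plug-in estimate on
#' an equal-frequency discretization with `bins` bins per margin.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param estimator `"gauss_copula"` (default) or `"binned"`.
#' @param bins Bins per margin for the binned estimator (default
#'   `floor(sqrt(n))`).
#' @return Mutual information in nats (>= 0). A constant input gives 0 with a
#'   warning.
#' @export
mutual_information <- function(x, y, estimator = c("gauss_copula", "binned"),
                               bins = NULL) {
  estimator <- match.arg(estimator)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 4) abort("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warn("constant vector: mutual information set to 0")
    return(0)
  }
  if (estimator == "gauss_copula") {
    rho <- stats::cor(rank_inverse_normal(x), rank_inverse_normal(y))
    rho <- max(min(rho, 1 - 1e-12), -1 + 1e-12)
    -0.5 * log(1 - rho^2)
  } else {
    n <- length(x)
    if (is.null(bins)) bins <- max(2L, floor(sqrt(n)))
    bx <- ceiling(rank(x, ties.method = "first") * bins / n)
    by <- ceiling(rank(y, ties.method = "first") * bins / n)
    tab <- table(bx, by) / n
    px <- rowSums(tab); py <- colSums(tab)
    nz <- tab > 0
    sum(tab[nz] * log(tab[nz] / outer(px, py)[nz]))
  }
}

#' Pairwise mutual-information matrix over the rows of a matrix
#'
#' @param mat Row-variable matrix (e.g. an `inference_matrix`).
#' @inheritParams mutual_information
#' @return Symmetric non-negative matrix, zero diagonal. Constant rows give
#'   zero MI against everything (one warning).
#' @export
mi_matrix <- function(mat, estimator = c("gauss_copula", "binned"), bins = NULL) {
  estimator <- match.arg(estimator)
  flat <- apply(mat, 1, stats::sd) == 0
  if (any(flat)) {
    warn(sprintf("%d constant row(s): MI set to 0 against all partners", sum(flat)))
  }
  if (estimator == "gauss_copula") {
    z <- t(apply(mat, 1, function(r) if (stats::sd(r) == 0) r * 0 else rank_inverse_normal(r)))
    rho <- suppressWarnings(stats::cor(t(z)))
    rho[!is.finite(rho)] <- 0
    rho <- pmax(pmin(rho, 1 - 1e-12), -1 + 1e-12)
    mi <- -0.5 * log(1 - rho^2)
  } else {
    n <- nrow(mat)
    mi <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (flat[i] || flat[j]) next
        mi[i, j] <- mi[j, i] <- mutual_information(mat[i, ], mat[j, ],
                                                   estimator = "binned",
                                                   bins = bins)
      }
    }
  }
  mi[flat, ] <- 0
  mi[, flat] <- 0
  diag(mi) <- 0
  dimnames(mi) <- list(rownames(mat), rownames(mat))
  mi
}

#' ARACNE data-processing-inequality pruning
#'
#' Removes every edge that is the weakest of some triangle: edge `(i, j)` is
#' pruned iff some third node `k` has
#' `MI_ij < min(MI_ik, MI_jk) - dpi_tolerance`. Surviving edges keep their MI
#' as score; pruned edges score 0.
#'
#' @param mi Symmetric non-negative MI matrix (zero diagonal).
#' @param dpi_tolerance Non-negative slack in the DPI rule; 0 is the strict
#'   rule, a tolerance >= max(mi) prunes nothing.
#' @return Matrix of the same shape: MI where the edge survives, 0 where
#'   pruned.
#' @export
aracne <- function(mi, dpi_tolerance = 0) {
  check_nonneg(dpi_tolerance, "dpi_tolerance")
  if (!isSymmetric(unname(mi))) abort("`mi` must be symmetric")
  if (any(mi < 0)) abort("`mi` must be non-negative")
  n <- nrow(mi)
  keep <- matrix(TRUE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      third <- pmin(mi[i, ], mi[j, ])
      third[c(i, j)] <- -Inf
      if (any(third - dpi_tolerance > mi[i, j])) {
        keep[i, j] <- keep[j, i] <- FALSE
      }
    }
  }
  out <- mi * keep
  dimnames(out) <- dimnames(mi)
  out
}

#' CLR background-corrected association scores
#'
#' Context likelihood of relatedness: each node's MI values are z-scored
#' against that node's own background (mean and sd of its off-diagonal MI),
#' negatives clipped to 0, and the two per-node z's combined as
#' `sqrt(z_i(j)^2 + z_j(i)^2)`.
#'
#' @param mi Symmetric non-negative MI matrix (zero diagonal).
#' @return Symmetric non-negative score matrix. A node whose background sd is
#'   0 contributes 0 for all partners (warning).
#' @export
clr <- function(mi) {
  if (!isSymmetric(unname(mi))) abort("`mi` must be symmetric")
  n <- nrow(mi)
  z <- matrix(0, n, n)
  off <- !diag(n)
  mu <- rowSums(mi * off) / (n - 1)
  sdv <- vapply(seq_len(n), function(i) stats::sd(mi[i, -i]), numeric(1))
  if (any(sdv == 0)) {
    warn(sprintf("%d node(s) with constant MI background: z contribution 0", sum(sdv == 0)))
  }
  for (i in seq_len(n)) {
    if (sdv[i] > 0) z[i, ] <- pmax(0, (mi[i, ] - mu[i]) / sdv[i])
  }
  out <- sqrt(z^2 + t(z)^2)
  diag(out) <- 0
  dimnames(out) <- dimnames(mi)
  out
}

# Least-angle regression: order in which predictors enter the path.
# X: n x p (columns standardized by the caller), y centered. Returns the
# column indices entered within n_steps steps, in entry order.
lars_enter_order <- function(X, y, n_steps) {
  n <- nrow(X); p <- ncol(X)
  n_steps <- min(n_steps, p, n - 1)
  mu <- rep(0, n)
  active <- integer(0)
  for (step in seq_len(n_steps)) {
    cvec <- drop(crossprod(X, y - mu))
    inactive <- setdiff(seq_len(p), active)
    if (!length(inactive)) break
    C <- max(abs(cvec[inactive]))
    if (C < 1e-10) break
    j <- inactive[which.max(abs(cvec[inactive]))]
    active <- c(active, j)
    s <- sign(cvec[active]); s[s == 0] <- 1
    Xa <- sweep(X[, active, drop = FALSE], 2, s, "*")
    G <- crossprod(Xa)
    ginv1 <- tryCatch(solve(G, rep(1, length(active))), error = function(e) NULL)
    if (is.null(ginv1) || any(ginv1 <= 0)) break  # collinear active set
    A <- 1 / sqrt(sum(ginv1))
    u <- drop(Xa %*% (A * ginv1))
    a <- drop(crossprod(X, u))
    inactive <- setdiff(seq_len(p), active)
    if (!length(inactive)) break
    gam <- c((C - cvec[inactive]) / (A - a[inactive]),
             (C + cvec[inactive]) / (A + a[inactive]))
    gam <- gam[is.finite(gam) & gam > 1e-12]
    gamma <- if (length(gam)) min(gam) else C / A
    mu <- mu + gamma * u
  }
  active
}

#' LARS stability-selection scores for one target module
#'
#' TIGRESS-style stability selection: the target module profile is regressed
#' on all TF rows with least-angle regression; over `n_resamples` random
#' column subsamples, a TF's score is the fraction of resamples in which it
#' enters the LARS path within `n_steps` steps.
#'
#' @param mat An `inference_matrix` (modules + TFs over lines).
#' @param target Module row ID to explain.
#' @param n_resamples Number of column subsamples.
#' @param n_steps LARS steps per fit (capped at the number of TFs with a
#'   warning).
#' @param subsample_fraction Fraction of columns drawn (without replacement)
#'   per resample.
#' @param seed Integer seed.
#' @return Named numeric vector of selection frequencies in `[0, 1]`, one per
#'   TF row (zero-variance TFs score 0).
#' @export
lars_stability <- function(mat, target, n_resamples = 200, n_steps = 3,
                           subsample_fraction = 0.8, seed = 1) {
  rk <- row_kind(mat)
  if (ncol(mat) < 4) abort("need at least 4 columns (lines)")
  if (!(target %in% rownames(mat)[rk == "module"])) {
    abort(sprintf("`target` must be a module row; got '%s'", target))
  }
  tf_ids <- rownames(mat)[rk == "tf"]
  withr::with_seed(seed, {
    subs <- lapply(seq_len(n_resamples), function(i) {
      sort(sample.int(ncol(mat), max(4L, floor(subsample_fraction * ncol(mat)))))
    })
    lars_stability_fixed(mat, target, subs, n_steps)
  })
}

# shared worker: frequencies over a fixed list of column subsamples
lars_stability_fixed <- function(mat, target, subsamples, n_steps) {
  rk <- row_kind(mat)
  tf_ids <- rownames(mat)[rk == "tf"]
  if (n_steps >= length(tf_ids)) {
    warn(sprintf("n_steps capped at %d (number of TFs)", length(tf_ids)))
    n_steps <- length(tf_ids)
  }
  hits <- stats::setNames(numeric(length(tf_ids)), tf_ids)
  for (cols in subsamples) {
    Xfull <- t(mat[tf_ids, cols, drop = FALSE])
    y <- mat[target, cols]
    y <- y - mean(y)
    sds <- apply(Xfull, 2, stats::sd)
    usable <- sds > 0
    if (!any(usable)) next
    X <- scale(Xfull[, usable, drop = FALSE])
    entered <- lars_enter_order(X, y, n_steps)
    hits[tf_ids[usable][entered]] <- hits[tf_ids[usable][entered]] + 1
  }
  hits / length(subsamples)
}

#' Shrinkage partial correlations over the rows of a matrix
#'
#' Shrinks the sample correlation matrix of the rows toward the identity with
#' the analytic intensity
#' `lambda* = clip(sum Var(r_ij) / sum r_ij^2, 0, 1)` (off-diagonal sums),
#' then reads partial correlations off the standardized inverse:
#' `pcor_ij = -P_ij / sqrt(P_ii P_jj)` with `P` the inverse of the shrunk
#' correlation matrix. With `lambda = 0` and more observations than
#' variables this is classical partial correlation.
#'
#' @param mat Row-variable matrix with >= 3 columns (observations); all
#'   values finite.
#' @param lambda Optional fixed shrinkage intensity in `[0, 1]`; estimated
#'   analytically if `NULL`.
#' @return Symmetric matrix of partial correlations (unit diagonal) with
#'   attribute `lambda`.
#' @export
shrinkage_pcor <- function(mat, lambda = NULL) {
  if (!all(is.finite(mat))) abort("`mat` must be finite")
  if (ncol(mat) < 3) abort("need at least 3 columns (observations)")
  X <- t(mat)  # n observations x p variables
  n <- nrow(X); p <- ncol(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warn(sprintf("%d zero-variance row(s): partial correlations set to 0", sum(sds == 0)))
  }
  Xs <- scale(X)
  Xs[, sds == 0] <- 0
  r <- crossprod(Xs) / (n - 1)
  diag(r) <- 1
  if (is.null(lambda)) {
    # Schafer-Strimmer analytic intensity from the empirical variance of r_ij
    num <- 0; den <- 0
    for (i in seq_len(p - 1)) {
      w <- Xs[, i] * Xs[, (i + 1):p, drop = FALSE]
      vr <- n / (n - 1)^3 * colSums((w - matrix(colMeans(w), n, ncol(w), byrow = TRUE))^2)
      num <- num + sum(vr)
      den <- den + sum(r[i, (i + 1):p]^2)
    }
    lambda <- if (den > 0) max(0, min(1, num / den)) else 1
  } else {
    check_proportion(lambda, "lambda")
  }
  rs <- (1 - lambda) * r
  diag(rs) <- 1
  prec <- solve(rs)
  d <- sqrt(diag(prec))
  pc <- -prec / outer(d, d)
  diag(pc) <- 1
  dimnames(pc) <- list(rownames(mat), rownames(mat))
  attr(pc, "lambda") <- lambda
  pc
}

#' Score every TF-module pair with the enabled inference methods
#'
#' Runs the enabled algorithms on the stacked inference matrix and returns,
#' per method, a TF x module score matrix (orientation: higher = stronger).
#' MI-based methods (`aracne`, `clr`) use the full matrix (TF-TF and
#' module-module MI feed the DPI rule and the CLR background) but only
#' TF-module cells are emitted. The optional fifth method `spearman` scores
#' pairs by absolute Spearman correlation.
#'
#' @param mat An `inference_matrix`.
#' @param methods Subset of `c("aracne", "clr", "lars", "pcor", "spearman")`.
#' @param mi_estimator,bins Passed to [mi_matrix()].
#' @param dpi_tolerance Passed to [aracne()].
#' @param n_resamples,n_steps,subsample_fraction Passed to [lars_stability()].
#' @param seed Integer seed (drives the LARS subsampling).
#' @return Named list of `score_matrix` objects (TF x module numeric matrices
#'   with attributes `method` and `orientation = "higher_stronger"`).
#' @export
run_all_methods <- function(mat,
                            methods = c("aracne", "clr", "lars", "pcor"),
                            mi_estimator = "gauss_copula", bins = NULL,
                            dpi_tolerance = 0,
                            n_resamples = 200, n_steps = 3,
                            subsample_fraction = 0.8,
                            seed = 1) {
  known <- c("aracne", "clr", "lars", "pcor", "spearman")
  bad <- setdiff(methods, known)
  if (length(bad)) abort(sprintf("unknown method(s): %s", paste(bad, collapse = ", ")))
  if (!length(methods)) abort("at least one method must be enabled")
  rk <- row_kind(mat)
  tf_ids <- rownames(mat)[rk == "tf"]
  mod_ids <- rownames(mat)[rk == "module"]
  if (!length(tf_ids)) abort("inference matrix has no TF rows")

  slice <- function(full) full[tf_ids, mod_ids, drop = FALSE]
  as_score <- function(m, method) {
    structure(m, method = method, orientation = "higher_stronger",
              class = c("score_matrix", class(m)))
  }

  mi <- NULL
  if (any(c("aracne", "clr") %in% methods)) {
    mi <- mi_matrix(mat, estimator = mi_estimator, bins = bins)
  }
  out <- list()
  for (m in methods) {
    t0 <- Sys.time()
    s <- switch(m,
      aracne = slice(aracne(mi, dpi_tolerance = dpi_tolerance)),
      clr = slice(clr(mi)),
      lars = {
        freq <- vapply(mod_ids, function(mod) {
          lars_stability(mat, mod, n_resamples = n_resamples,
                         n_steps = n_steps,
                         subsample_fraction = subsample_fraction,
                         seed = seed + match(mod, mod_ids))
        }, numeric(length(tf_ids)))
        dimnames(freq) <- list(tf_ids, mod_ids)
        freq
      },
      pcor = abs(slice(shrinkage_pcor(mat))),
      spearman = {
        rho <- suppressWarnings(
          stats::cor(t(mat[tf_ids, , drop = FALSE]),
                     t(mat[mod_ids, , drop = FALSE]), method = "spearman"))
        rho[!is.finite(rho)] <- 0
        abs(rho)
      })
    out[[m]] <- as_score(s, m)
    attr(out[[m]], "runtime_s") <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }
  out
}

#' Long-format tidy table of method scores
#'
#' @param scores Named list of score matrices from [run_all_methods()].
#' @return Tibble with `tf`, `module`, `method`, `score`, and `rank`
#'   (within-method, average ties, higher = stronger).
#' @export
tidy_scores <- function(scores) {
  purrr::map_dfr(names(scores), function(m) {
    s <- scores[[m]]
    tibble::tibble(
      tf = rep(rownames(s), times = ncol(s)),
      module = rep(colnames(s), each = nrow(s)),
      method = m,
      score = as.vector(unclass(s))
    ) |>
      dplyr::mutate(rank = rank(.data$score, ties.method = "average"))
  })
}
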