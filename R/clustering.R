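# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, then
# points with probability proportional to squared distance to the nearest
# chosen center. Points coinciding with a chosen center have probability 0,
# so centers are distinct whenever k <= number of distinct rows.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  idx <- sample.int(n, 1)
  centers[1, ] <- X[idx, ]
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      abort("fewer distinct rows than requested clusters")
    }
    idx <- sample.int(n, 1, prob = d2)
    centers[j + 1, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums((X - matrix(centers[j + 1, ], n, ncol(X), byrow = TRUE))^2))
  }
  centers
}

# best-of-n_init K-means with k-means++ starts; uses the caller's RNG stream
fit_kmeans <- function(X, k, n_init) {
  best <- NULL
  for (i in seq_len(n_init)) {
    centers <- kmeanspp_centers(X, k)
    # Lloyd can abandon a start if a cluster empties; just move to the next
    km <- tryCatch(
      suppressWarnings(
        stats::kmeans(X, centers = centers, iter.max = 100, algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) abort(sprintf("all %d K-means starts failed at k = %d", n_init, k))
  best
}

# Spherical-Gaussian BIC of a fitted K-means solution:
#   sigma2 = W / (n d)            (pooled MLE variance, W = total within-SS)
#   LL     = sum_k n_k log(n_k/n) - (n d / 2) (log(2 pi sigma2) + 1)
#   BIC    = -2 LL + q log(n),    q = K d + K (centroids + mixing weights)
# Lower is better.
kmeans_bic <- function(km, n, d) {
  sigma2 <- max(km$tot.withinss / (n * d), 1e-12)
  nk <- km$size
  ll <- sum(nk * log(nk / n)) - (n * d / 2) * (log(2 * pi * sigma2) + 1)
  -2 * ll + (km$centers |> nrow()) * (d + 1) * log(n)
}

#' Sweep K-means over a grid of K and select K by minimum BIC
#'
#' For each candidate K, fits K-means (squared Euclidean, k-means++
#' initialization, best of `n_init` restarts) and scores the solution with a
#' spherical-Gaussian BIC (see Details). The selected K minimizes BIC; ties
#' go to the smaller K.
#'
#' @details The BIC used is the X-means-style spherical-Gaussian score
#'   `BIC(K) = -2 LL(K) + (K d + K) log(n)` with
#'   `LL = sum_k n_k log(n_k / n) - (n d / 2)(log(2 pi sigma2) + 1)` and
#'   `sigma2 = W / (n d)`, `W` the total within-cluster sum of squares over
#'   `n` rows in `d` dimensions. Any monotone variant of this score shifts
#'   the curve but the argmin-based tests in this package are written against
#'   exactly this formula.
#'
#' @param X Numeric row-observation matrix (genes x conditions), finite.
#' @param k_min,k_max,k_step Sweep grid (defaults 10..100 step 5). Candidates
#'   exceeding `nrow(X)` are dropped with a warning.
#' @param n_init Number of k-means++ restarts per K.
#' @param seed Integer seed; identical seeds give identical curves.
#' @return A `bic_sweep` object: list with `bic_curve` (tibble: k, bic,
#'   inertia), `best_k`, and the call parameters.
#' @export
kmeans_bic_sweep <- function(X, k_min = 10, k_max = 100, k_step = 5,
                             n_init = 10, seed = 1) {
  k_min <- check_count(k_min, "k_min")
  k_max <- check_count(k_max, "k_max")
  k_step <- check_count(k_step, "k_step")
  if (k_min > k_max) abort("`k_min` must be <= `k_max`")
  if (!all(is.finite(X))) abort("`X` must be finite")
  ks <- seq(k_min, k_max, by = k_step)
  if (any(ks > nrow(X))) {
    warn(sprintf("sweep truncated: %d candidate K exceed nrow(X) = %d",
                 sum(ks > nrow(X)), nrow(X)))
    ks <- ks[ks <= nrow(X)]
  }
  if (!length(ks)) abort("no feasible K in the sweep")
  n <- nrow(X); d <- ncol(X)
  fits <- withr::with_seed(seed, lapply(ks, function(k) fit_kmeans(X, k, n_init)))
  bic <- vapply(fits, kmeans_bic, numeric(1), n = n, d = d)
  inertia <- vapply(fits, function(f) f$tot.withinss, numeric(1))
  structure(
    list(bic_curve = tibble::tibble(k = ks, bic = bic, inertia = inertia),
         best_k = ks[which.min(bic)],  # which.min -> first minimum -> smaller K
         n_init = n_init, seed = seed),
    class = "bic_sweep"
  )
}

#' @export
print.bic_sweep <- function(x, ...) {
  cat(sprintf("<bic_sweep> %d candidates, best K = %d (BIC %.1f)\n",
              nrow(x$bic_curve), x$best_k,
              min(x$bic_curve$bic)))
  invisible(x)
}

#' Assign genes to K co-expression modules
#'
#' K-means at a fixed K (k-means++ init, best of `n_init` restarts).
#'
#' @param X Numeric gene x condition matrix with rownames.
#' @param k Number of modules.
#' @param n_init Restarts.
#' @param seed Integer seed.
#' @return A `module_assignment`: list with `labels` (named integer vector
#'   gene -> module), `centroids` (K x d), `k`, `sizes` (named integer),
#'   `inertia`.
#' @export
assign_modules <- function(X, k, n_init = 10, seed = 1) {
  k <- check_count(k, "k")
  if (k > nrow(X)) abort(sprintf("k = %d exceeds number of rows (%d)", k, nrow(X)))
  if (is.null(rownames(X))) abort("`X` must carry gene rownames")
  km <- withr::with_seed(seed, fit_kmeans(X, k, n_init))
  labels <- stats::setNames(km$cluster, rownames(X))
  structure(
    list(labels = labels,
         centroids = km$centers,
         k = k,
         sizes = stats::setNames(as.integer(km$size), seq_len(k)),
         inertia = km$tot.withinss),
    class = "module_assignment"
  )
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("<module_assignment> %d genes in %d modules (sizes %d..%d)\n",
              length(x$labels), x$k, min(x$sizes), max(x$sizes)))
  invisible(x)
}

#' Module mean expression profiles
#'
#' Row `m` is the arithmetic mean of the expression rows of module `m`'s
#' member genes.
#'
#' @param assignment A `module_assignment`.
#' @param expr Gene x condition matrix containing every labelled gene.
#' @return Module x condition matrix with rownames `module_01`, ...
#' @export
module_profiles <- function(assignment, expr) {
  missing <- setdiff(names(assignment$labels), rownames(expr))
  if (length(missing)) {
    abort(sprintf("labelled gene(s) absent from `expr`: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  out <- t(vapply(seq_len(assignment$k), function(m) {
    members <- names(assignment$labels)[assignment$labels == m]
    if (!length(members)) abort(sprintf("module %d is empty", m))
    colMeans(expr[members, , drop = FALSE])
  }, numeric(ncol(expr))))
  dimnames(out) <- list(sprintf("module_%02d", seq_len(assignment$k)),
                        colnames(expr))
  out
}

#' Central gene of each module
#'
#' The member gene closest (Euclidean) to the module centroid; ties broken by
#' lexicographically smallest gene ID.
#'
#' @param assignment A `module_assignment` fitted on `X`.
#' @param X The matrix the assignment was fitted on.
#' @return Tibble with `module`, `gene`, `distance`.
#' @export
central_genes <- function(assignment, X) {
  purrr::map_dfr(seq_len(assignment$k), function(m) {
    members <- sort(names(assignment$labels)[assignment$labels == m])
    d <- sqrt(rowSums((X[members, , drop = FALSE] -
                         matrix(assignment$centroids[m, ], length(members),
                                ncol(X), byrow = TRUE))^2))
    i <- which.min(d)  # first minimum; members sorted -> lexicographic ties
    tibble::tibble(module = sprintf("module_%02d", m),
                   gene = members[i], distance = d[[i]])
  })
}

#' Row-standardized, hierarchically ordered heatmap matrix
#'
#' Z-scores each module profile (mean 0, population sd 1 across conditions;
#' zero-variance rows become all-zero with a warning) and orders rows by the
#' leaf order of average-linkage hierarchical clustering on Euclidean
#' distance.
#'
#' @param profiles Module x condition matrix with >= 2 conditions.
#' @return A `heatmap_matrix`: list with `matrix` (z-scored, rows in leaf
#'   order), `row_order` (character), `hclust` (the tree).
#' @export
heatmap_matrix <- function(profiles) {
  if (ncol(profiles) < 2) abort("heatmap needs at least 2 conditions")
  mu <- rowMeans(profiles)
  # population sd (divisor n): row (1,2,3) maps to (-1.2247, 0, 1.2247)
  sdev <- sqrt(rowMeans((profiles - mu)^2))
  flat <- sdev == 0
  if (any(flat)) {
    warn(sprintf("%d zero-variance row(s) set to 0: %s", sum(flat),
                 paste(rownames(profiles)[flat], collapse = ", ")))
    sdev[flat] <- 1
  }
  z <- (profiles - mu) / sdev
  hc <- stats::hclust(stats::dist(z), method = "average")
  ord <- rownames(z)[hc$order]
  structure(list(matrix = z[ord, , drop = FALSE], row_order = ord, hclust = hc),
            class = "heatmap_matrix")
}
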