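test_that("inference matrix stacking, filtering and column checks", {
  prof <- matrix(1:6, 2, 3, dimnames = list(c("module_01", "module_02"),
                                            c("a", "b", "c")))
  tfx <- matrix(1:9, 3, 3, dimnames = list(c("TF001", "TF002", "TF003"),
                                           c("a", "b", "c")))
  im <- build_inference_matrix(prof, tfx, c("TF001", "TF003"))
  expect_identical(nrow(im), 4L)  # 2 modules + 2 retained TFs
  expect_identical(attr(im, "row_kind"), c("module", "module", "tf", "tf"))
  expect_identical(rownames(im), c("module_01", "module_02", "TF001", "TF003"))

  # no DE TFs -> module-only matrix with warning
  expect_warning(im0 <- build_inference_matrix(prof, tfx, character(0)),
                 "no differentially expressed TFs")
  expect_identical(nrow(im0), 2L)

  bad <- tfx; colnames(bad) <- c("a", "b", "z")
  expect_error(build_inference_matrix(prof, bad, "TF001"), "z")
})

test_that("mutual information: independence, self, binned plug-in, invariance", {
  # independent vectors: median MI over 50 reps below 0.05 nats
  mis <- withr::with_seed(5, vapply(1:50, function(i) {
    mutual_information(stats::rnorm(200), stats::rnorm(200))
  }, numeric(1)))
  expect_lt(stats::median(mis), 0.05)
  expect_true(all(mis >= 0))

  # y = x reaches the estimator's clipped finite maximum
  x <- withr::with_seed(6, stats::rnorm(30))
  expect_equal(mutual_information(x, x),
               -0.5 * log(1 - (1 - 1e-12)^2))

  # binned plug-in: 2x2 balanced perfect association -> ln 2 nats
  expect_equal(mutual_information(c(1, 2, 3, 4), c(10, 20, 30, 40),
                                  estimator = "binned", bins = 2), log(2))
  # and a hand-computed non-degenerate table: x splits 1..6 into two bins,
  # y = (1,1,2,1,2,2) pattern -> joint (2/6,1/6;1/6,2/6),
  # MI = 4*(1/3)ln(4/3)... computed by the plug-in formula by hand:
  xx <- 1:6; yy <- c(1, 2, 3, 10, 11, 12)[c(1, 2, 4, 3, 5, 6)]
  joint <- matrix(c(2, 1, 1, 2) / 6, 2)
  hand <- sum(joint * log(joint / outer(rowSums(joint), colSums(joint))))
  expect_equal(mutual_information(xx, yy, estimator = "binned", bins = 2), hand)

  # symmetry and invariance under strictly monotone transforms
  y <- withr::with_seed(7, stats::rnorm(30) + x)
  expect_equal(mutual_information(x, y), mutual_information(y, x))
  expect_equal(mutual_information(x, y), mutual_information(exp(x), y))
  expect_equal(mutual_information(x, y), mutual_information(x, y^3 + 5 * y))

  expect_warning(mi0 <- mutual_information(rep(1, 10), stats::rnorm(10)),
                 "constant")
  expect_identical(mi0, 0)
  expect_error(mutual_information(1:3, 1:3), "4 observations")
})

test_that("ARACNE: forced triangle, tolerance, brute-force oracle", {
  mi <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  mi["A", "B"] <- mi["B", "A"] <- 0.9
  mi["B", "C"] <- mi["C", "B"] <- 0.8
  mi["A", "C"] <- mi["C", "A"] <- 0.3
  pr <- aracne(mi)
  expect_identical(pr["A", "C"], 0)       # weakest edge of the triangle
  expect_identical(pr["A", "B"], 0.9)
  expect_identical(pr["B", "C"], 0.8)

  # tolerance at least max(mi) disables pruning
  expect_equal(aracne(mi, dpi_tolerance = 1), mi)

  # exhaustive all-triangles oracle on random 8-node matrices
  dpi_oracle <- function(m, tol = 0) {
    n <- nrow(m); keep <- matrix(TRUE, n, n)
    for (i in 1:n) for (j in 1:n) for (k in 1:n) {
      if (length(unique(c(i, j, k))) == 3 &&
          m[i, j] < min(m[i, k], m[j, k]) - tol) {
        keep[i, j] <- FALSE
      }
    }
    m * keep
  }
  for (s in 1:25) {
    m <- withr::with_seed(100 + s, {
      v <- matrix(stats::runif(64), 8, 8)
      m <- (v + t(v)) / 2; diag(m) <- 0; m
    })
    expect_equal(aracne(m), dpi_oracle(m))
    # pruning never creates a positive score where MI was 0
    expect_true(all(aracne(m)[m == 0] == 0))
  }
})

test_that("CLR: hand-computed 4-node scores, flat backgrounds", {
  mi <- matrix(c(0, .5, .2, .1,
                 .5, 0, .4, .3,
                 .2, .4, 0, .6,
                 .1, .3, .6, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  out <- clr(mi)
  # spreadsheet oracle from the stated formula
  z_expected <- matrix(0, 4, 4)
  for (i in 1:4) {
    bg <- mi[i, -i]
    z_expected[i, ] <- pmax(0, (mi[i, ] - mean(bg)) / stats::sd(bg))
  }
  expected <- sqrt(z_expected^2 + t(z_expected)^2)
  diag(expected) <- 0
  expect_equal(unname(unclass(out)), unname(expected))

  # symmetric, non-negative
  expect_true(all(out >= 0))
  expect_equal(out, t(out))

  # node with constant MI background contributes 0 everywhere
  mi2 <- mi; mi2[4, 1:3] <- 0.2; mi2[1:3, 4] <- 0.2
  expect_warning(out2 <- clr(mi2), "constant MI background")
  # d's own z is zero, so score(d, j) only carries the partner's z
  for (j in 1:3) {
    bg <- mi2[j, -j]
    expect_equal(out2[4, j], max(0, (mi2[j, 4] - mean(bg)) / stats::sd(bg)))
  }
})

test_that("LARS stability selection finds a planted regulator", {
  # one strong TF among 30 nulls over 50 lines
  n <- 50
  im <- withr::with_seed(20, {
    tfx <- matrix(stats::rnorm(31 * n), 31, n,
                  dimnames = list(sprintf("TF%03d", 1:31), sprintf("L%02d", 1:n)))
    y <- 2 * tfx["TF001", ] + stats::rnorm(n, 0, 0.5)
    prof <- matrix(y, 1, n, dimnames = list("module_01", colnames(tfx)))
    build_inference_matrix(prof, tfx, rownames(tfx))
  })
  freq <- lars_stability(im, "module_01", n_resamples = 100, seed = 21)
  expect_true(all(freq >= 0 & freq <= 1))
  expect_gte(freq[["TF001"]], 0.9)
  expect_identical(names(which.max(freq)), "TF001")

  # determinism
  expect_identical(freq, lars_stability(im, "module_01", n_resamples = 100,
                                        seed = 21))

  # zero-variance TF never enters
  im2 <- im
  im2["TF002", ] <- 3
  freq2 <- lars_stability(im2, "module_01", n_resamples = 50, seed = 22)
  expect_identical(freq2[["TF002"]], 0)

  # n_steps capped at the number of TFs
  small <- toy_infmat(1, 2, 12, seed = 23)
  expect_warning(lars_stability(small, "module_01", n_resamples = 10,
                                n_steps = 5, seed = 23), "capped")

  expect_error(lars_stability(im, "TF001"), "module row")
})

test_that("LARS entry order matches least-squares geometry on orthogonal designs", {
  # with orthonormal predictors LARS enters variables in order of |correlation|
  n <- 32
  X <- withr::with_seed(30, qr.Q(qr(matrix(stats::rnorm(n * 5), n, 5))))
  beta <- c(5, 3, 1.5, 0, 0)
  y <- drop(X %*% beta)
  ord <- modnet:::lars_enter_order(X, y - mean(y), 3)
  expect_identical(ord, c(1L, 2L, 3L))
})

test_that("shrinkage partial correlation: closed forms and oracle", {
  # two variables at lambda 0: |pcor| equals |cor|
  m2 <- withr::with_seed(40, matrix(stats::rnorm(2 * 30), 2, 30,
                                    dimnames = list(c("x", "y"), NULL)))
  pc <- shrinkage_pcor(m2, lambda = 0)
  expect_equal(abs(pc["x", "y"]), abs(stats::cor(m2["x", ], m2["y", ])))
  # under the shrunk matrix the off-diagonal scales by (1 - lambda)
  pc5 <- shrinkage_pcor(m2, lambda = 0.5)
  expect_equal(pc5["x", "y"], 0.5 * pc["x", "y"])

  # 3-variable oracle: classical partial correlation via residuals
  m3 <- withr::with_seed(41, {
    z <- stats::rnorm(50)
    rbind(a = z + stats::rnorm(50, 0, 0.7),
          b = -z + stats::rnorm(50, 0, 0.7),
          c = stats::rnorm(50))
  })
  pc3 <- shrinkage_pcor(m3, lambda = 0)
  resid_pcor <- function(i, j, k) {
    ri <- stats::resid(stats::lm(m3[i, ] ~ m3[k, ]))
    rj <- stats::resid(stats::lm(m3[j, ] ~ m3[k, ]))
    stats::cor(ri, rj)
  }
  expect_equal(pc3["a", "b"], resid_pcor("a", "b", "c"), tolerance = 1e-9)
  expect_equal(pc3["a", "c"], resid_pcor("a", "c", "b"), tolerance = 1e-9)

  # analytic lambda stays in [0, 1]
  for (s in 1:5) {
    m <- withr::with_seed(50 + s, matrix(stats::rnorm(20 * 8), 20, 8))
    rownames(m) <- sprintf("v%02d", 1:20)
    lam <- attr(shrinkage_pcor(m), "lambda")
    expect_gte(lam, 0); expect_lte(lam, 1)
  }

  expect_error(shrinkage_pcor(matrix(c(1, Inf, 2, 3), 2, 2)), "finite")
})

test_that("run_all_methods emits aligned TF x module score matrices", {
  im <- toy_infmat(4, 10, 20, seed = 60)
  scores <- run_all_methods(im, n_resamples = 20, seed = 60)
  expect_named(scores, c("aracne", "clr", "lars", "pcor"))
  for (s in scores) {
    expect_identical(dim(unclass(s)), c(10L, 4L))
    expect_identical(attr(s, "orientation"), "higher_stronger")
    expect_true(all(is.finite(s)))
  }
  expect_true(all(scores$aracne >= 0))
  expect_true(all(scores$clr >= 0))
  expect_true(all(scores$lars >= 0 & scores$lars <= 1))
  expect_true(all(abs(scores$pcor) <= 1))

  # disabling a method drops exactly its matrix
  sub <- run_all_methods(im, methods = c("clr", "pcor"), seed = 60)
  expect_named(sub, c("clr", "pcor"))
  expect_equal(unclass(sub$clr), unclass(scores$clr), ignore_attr = TRUE)

  # the optional fifth method
  five <- run_all_methods(im, methods = c("aracne", "clr", "lars", "pcor",
                                          "spearman"),
                          n_resamples = 20, seed = 60)
  expect_identical(length(five), 5L)
  expect_true(all(five$spearman >= 0 & five$spearman <= 1))

  expect_error(run_all_methods(im, methods = "genie3"), "unknown method")

  long <- tidy_scores(scores)
  expect_identical(nrow(long), 4L * 40L)
  expect_true(all(long$rank >= 1 & long$rank <= 40))
})

test_that("every method ranks true edges above null pairs on the wide fixture", {
  # rank dominance (AUROC > 0.5) per method, sign test over 20 seeds, and
  # the median comparison for the continuous-score methods
  mets <- lapply(1:20, wide_metrics)
  for (m in c("aracne", "clr", "lars", "pcor")) {
    wins <- sum(vapply(mets, function(x) x$per_method[[m]][["auroc"]] > 0.5,
                       logical(1)))
    # sign test: >= 15 of 20 one-sided successes gives p < 0.05
    expect_gte(wins, 15)
  }
  for (m in c("clr", "lars", "pcor")) {
    med_wins <- sum(vapply(mets, function(x) {
      x$per_method[[m]][["med_true"]] > x$per_method[[m]][["med_null"]]
    }, logical(1)))
    expect_gte(med_wins, 15)
  }
})
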