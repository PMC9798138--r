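test_that("correlation measures reproduce hand-computed coefficients", {
  x <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(8, 6, 4, 2),
             d = c(1, 3, 2, 4))
  p <- pearson_matrix(x)
  expect_equal(p["a", "b"], 1)
  expect_equal(p["a", "c"], -1)
  expect_equal(p["a", "d"], 0.8)

  s <- spearman_matrix(rbind(a = c(1, 2, 3, 4), cube = c(1, 8, 27, 64),
                             rev = c(4, 3, 2, 1), d = c(1, 3, 2, 4)))
  expect_equal(s["a", "cube"], 1)   # monotone transform
  expect_equal(s["a", "rev"], -1)
  expect_equal(s["a", "d"], 0.8)    # pearson on ranks

  k <- kendall_matrix(rbind(a = c(1, 2, 3), conc = c(10, 20, 30),
                            disc = c(3, 2, 1), mix = c(1, 3, 2)))
  expect_equal(k["a", "conc"], 1)
  expect_equal(k["a", "disc"], -1)
  expect_equal(k["a", "mix"], 1 / 3)  # 2 concordant, 1 discordant
})

test_that("zero-variance rows give NA scores and small inputs error", {
  x <- rbind(a = c(1, 2, 3), flat = c(5, 5, 5))
  p <- pearson_matrix(x)
  expect_true(is.na(p["a", "flat"]))
  expect_error(pearson_matrix(x[, 1:2, drop = FALSE]), "samples")
})

test_that("measures agree with brute-force formula evaluation on random matrices", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(60), 6, 10, dimnames = list(paste0("v", 1:6), NULL))
    if (seed == 3) x[2, ] <- round(x[2, ])  # inject ties
    p <- pearson_matrix(x)
    s <- spearman_matrix(x)
    k <- kendall_matrix(x)
    m <- mutual_information_matrix(x, levels = 3)
    f <- funchisq_matrix(x, levels = 3)
    d <- t(apply(x, 1, discretize_1d_kmeans, k = 3))
    for (i in 1:5) for (j in (i + 1):6) {
      expect_equal(p[i, j], oracle_pearson(x[i, ], x[j, ]), tolerance = 1e-10)
      expect_equal(s[i, j], oracle_spearman(x[i, ], x[j, ]), tolerance = 1e-10)
      expect_equal(k[i, j], oracle_kendall(x[i, ], x[j, ]), tolerance = 1e-10)
      expect_equal(m[i, j], oracle_mi(d[i, ], d[j, ]), tolerance = 1e-10)
      tab <- table(d[j, ], d[i, ])   # effect on rows for direction i -> j
      df <- (nrow(tab) - 1) * (ncol(tab) - 1)
      expect_equal(f[i, j], (oracle_funchisq(tab) - df) / sqrt(2 * df),
                   tolerance = 1e-10)
    }
  }
})

test_that("1-D k-means finds the globally optimal partition", {
  expect_equal(discretize_1d_kmeans(c(1, 1, 1, 10, 10, 10), 2),
               c(1L, 1L, 1L, 2L, 2L, 2L))
  # the outlier must be isolated, not split at the mean
  expect_equal(discretize_1d_kmeans(c(0, 1, 2, 100), 2), c(1L, 1L, 1L, 2L))
  expect_equal(discretize_1d_kmeans(rep(3.7, 5), 1), rep(1L, 5))
  expect_warning(out <- discretize_1d_kmeans(c(1, 1, 2, 2), 3), "reduced")
  expect_equal(length(unique(out)), 2)
  for (seed in 1:8) {
    set.seed(seed)
    v <- rnorm(12)
    for (k in 2:4) {
      labs <- discretize_1d_kmeans(v, k)
      expect_equal(within_ss(v, labs), oracle_kmeans_ss(v, k),
                   tolerance = 1e-10)
      # labels ordered by cluster mean
      means <- vapply(split(v, labs), mean, numeric(1))
      expect_true(all(diff(means[order(as.integer(names(means)))]) > 0))
    }
  }
})

test_that("mutual information hits its closed-form anchors", {
  x <- rbind(a = c(0, 0, 0, 10, 10, 10), b = c(0, 0, 0, 10, 10, 10))
  m <- mutual_information_matrix(x, levels = 2)
  expect_equal(m["a", "b"], log(2), tolerance = 1e-12)
  # exact product joint: independence => MI 0
  a <- rep(c(0, 10), each = 4)
  b <- rep(c(0, 10), times = 4)
  m0 <- mutual_information_matrix(rbind(a = a, b = b), levels = 2)
  expect_equal(m0["a", "b"], 0, tolerance = 1e-12)
  set.seed(1)
  xr <- matrix(rnorm(40), 4, 10)
  rownames(xr) <- paste0("v", 1:4)
  mr <- mutual_information_matrix(xr)
  expect_true(all(mr >= -1e-12))
  expect_equal(unclass(mr), t(unclass(mr)), ignore_attr = TRUE)
})

test_that("functional chi-squared matches hand-evaluated tables and is directional", {
  expect_equal(fun_chisq_stat(matrix(c(3, 0, 0, 3), 2))$stat, 6)
  expect_equal(fun_chisq_stat(matrix(c(2, 2, 2, 2), 2))$stat, 0)
  # y = f(x) deterministically (3 x-levels collapse onto 2 y-levels);
  # the functional direction must outscore the reverse
  a <- rep(1:3, each = 4)
  b <- c(rep(1, 4), rep(2, 4), rep(1, 4)) + 0.0
  fm <- funchisq_matrix(rbind(a = a * 1.0, b = b), levels = 3)
  expect_gt(fm["a", "b"], fm["b", "a"])
  # spec'd 2x2 asymmetry: direction toward the deterministic row wins
  x <- c(1, 1, 1, 1, 2, 2, 2, 2)
  y <- c(1, 1, 2, 2, 1, 1, 1, 1)
  fm2 <- funchisq_matrix(rbind(x = x, y = y), levels = 2)
  expect_equal(fm2["x", "y"], (8 / 3 - 1) / sqrt(2), tolerance = 1e-10)
  expect_equal(fm2["y", "x"], (2 - 1) / sqrt(2), tolerance = 1e-10)
  expect_gt(fm2["x", "y"], fm2["y", "x"])
})

test_that("shrinkage partial correlations behave like partial correlations", {
  # two variables: nothing to condition on, equals Pearson up to shrinkage
  set.seed(2)
  x2 <- matrix(rnorm(40), 2, 20, dimnames = list(c("a", "b"), NULL))
  g2 <- ggm_matrix(x2)
  lam <- attr(g2, "lambda")
  expect_equal(g2["a", "b"], (1 - lam) * cor(x2[1, ], x2[2, ]),
               tolerance = 1e-10)

  # population limit of the chain A -> B -> C: rho_AC|B = 0
  w1 <- 0.8
  w2 <- -1.3
  S <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  S["A", "A"] <- 1
  S["B", "B"] <- w1^2 + 1
  S["C", "C"] <- w2^2 * (w1^2 + 1) + 1
  S["A", "B"] <- S["B", "A"] <- w1
  S["B", "C"] <- S["C", "B"] <- w2 * (w1^2 + 1)
  S["A", "C"] <- S["C", "A"] <- w1 * w2
  R <- stats::cov2cor(S)
  pc <- phosbench:::partial_cor_from_cor(R)
  expect_equal(pc["A", "C"], 0, tolerance = 1e-12)
  expect_equal(sign(pc["A", "B"]), 1)
  expect_equal(sign(pc["B", "C"]), -1)

  # diagonal covariance: all off-diagonal partial correlations vanish
  pc0 <- phosbench:::partial_cor_from_cor(diag(4))
  expect_true(all(abs(pc0[upper.tri(pc0)]) < 1e-14))

  # direct inversion agrees with the regression-residual oracle
  set.seed(3)
  x <- matrix(rnorm(5 * 400), 5, 400, dimnames = list(paste0("v", 1:5), NULL))
  x[2, ] <- x[1, ] * 0.5 + x[2, ]
  x[3, ] <- x[2, ] * -0.7 + x[3, ]
  pc <- phosbench:::partial_cor_from_cor(cor(t(x)))
  for (pair in list(c(1, 2), c(1, 3), c(2, 5))) {
    expect_equal(pc[pair[1], pair[2]],
                 oracle_partial_cor(x, pair[1], pair[2]), tolerance = 1e-6)
  }
  # with n >> p the data-driven shrinkage intensity is small
  expect_lt(attr(ggm_matrix(x), "lambda"), 0.1)
})

test_that("score matrices respect variable relabeling and bounds", {
  set.seed(4)
  x <- matrix(rnorm(50), 5, 10, dimnames = list(paste0("v", 1:5), NULL))
  perm <- c(3, 1, 5, 2, 4)
  for (m in phos_measures()) {
    a <- score_associations(x, m)
    ap <- score_associations(x[perm, ], m)
    expect_equal(unclass(ap), unclass(a)[perm, perm], tolerance = 1e-10,
                 ignore_attr = TRUE)
    if (m %in% c("pearson", "spearman", "kendall", "ggm")) {
      expect_true(all(abs(a) <= 1 + 1e-12, na.rm = TRUE))
    }
  }
})

test_that("every measure fills a directed matrix from lagged pairs", {
  set.seed(5)
  x <- matrix(rnorm(60), 6, 10,
              dimnames = list(paste0("v", 1:6), paste0("t", 1:10)))
  lp <- make_lagged_pairs(x)
  for (m in phos_measures()) {
    a <- score_associations(x, m, lagged = lp)
    expect_true(attr(a, "directed"))
    expect_equal(dim(a), c(6L, 6L))
    expect_equal(rownames(a), paste0("v", 1:6))
  }
  # lagged pearson is literally cor(lead_i, trail_j)
  a <- pearson_matrix(x, lagged = lp)
  expect_equal(a["v1", "v2"], cor(x["v1", 1:9], x["v2", 2:10]),
               tolerance = 1e-12)
})
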