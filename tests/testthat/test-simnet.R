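test_that("the bundled Raf pathway has the expected topology", {
  net <- load_raf_network()
  expect_equal(length(net$nodes), 11)
  expect_equal(nrow(net$edges), 19)
  expect_true(all(c(net$edges$parent, net$edges$child) %in% net$nodes))
  expect_equal(anyDuplicated(net$edges[, c("parent", "child")]), 0L)
})

test_that("weight sampling respects the magnitude interval and the seed", {
  net <- load_raf_network()
  w1 <- sample_weights(net, seed = 42)
  expect_true(all(abs(w1$edges$weight) >= 0.5 & abs(w1$edges$weight) <= 2))
  expect_true(all(abs(w1$self_weights) >= 0.5 & abs(w1$self_weights) <= 2))
  w2 <- sample_weights(net, seed = 42)
  expect_identical(w1$edges$weight, w2$edges$weight)
  expect_error(sample_weights(directed_network("A", tibble::tibble(
    parent = character(0), child = character(0)))), "no edges")
  # sign symmetry: positive fraction within 4-sigma binomial bounds
  set.seed(7)
  draws <- replicate(100, sample_weights(net)$edges$weight)
  n <- length(draws)
  expect_gt(mean(draws > 0), 0.5 - 2 / sqrt(n))
  expect_lt(mean(draws > 0), 0.5 + 2 / sqrt(n))
})

test_that("lagged simulation follows the stabilized linear recursion", {
  chain <- directed_network(c("A", "B"),
                            tibble::tibble(parent = "A", child = "B",
                                           weight = 1.5))
  chain$self_weights <- c(A = 0.9, B = 0.4)
  ds <- simulate_dataset(chain, k = 6, noise_sd = 0, mode = "lagged",
                         init = c(1, 0))
  W <- phosbench:::stabilize_weights(phosbench:::weight_matrix(chain), 0.95)
  x <- c(1, 0)
  for (t in 2:6) {
    x <- as.numeric(W %*% x)
    expect_equal(unname(ds$values[, t]), x, tolerance = 1e-12)
  }
})

test_that("null networks produce i.i.d. Gaussian noise", {
  net <- directed_network(c("A", "B"), tibble::tibble(
    parent = "A", child = "B", weight = 0))
  net$self_weights <- c(A = 0, B = 0)
  ds <- simulate_dataset(net, k = 4000, noise_sd = 1, mode = "lagged",
                         seed = 8)
  z <- rowMeans(ds$values) / (1 / sqrt(4000))
  expect_true(all(abs(z) < 4))        # z-test at 4 sigma
  expect_lt(abs(sd(ds$values["B", ]) - 1), 0.05)
})

test_that("simulation is reproducible and validates its inputs", {
  net <- sample_weights(load_raf_network(), seed = 1)
  d1 <- simulate_dataset(net, k = 20, seed = 5)
  d2 <- simulate_dataset(net, k = 20, seed = 5)
  expect_identical(d1$values, d2$values)
  expect_error(simulate_dataset(net, k = 1), "timepoints")
  cyc <- directed_network(c("A", "B"), tibble::tibble(
    parent = c("A", "B"), child = c("B", "A"), weight = c(1, 1)))
  expect_error(simulate_dataset(cyc, k = 5, mode = "instantaneous"),
               "cyclic")
})

test_that("lagged dynamics stay stationary over long runs", {
  net <- sample_weights(load_raf_network(), seed = 9)
  ds <- simulate_dataset(net, k = 1000, mode = "lagged", seed = 10)
  v_early <- apply(ds$values[, 101:300], 1, var)
  v_late <- apply(ds$values[, 801:1000], 1, var)
  expect_true(all(is.finite(ds$values)))
  expect_true(all(v_late / v_early < 10))
})

test_that("intermittent subsampling keeps the right timepoints", {
  net <- sample_weights(load_raf_network(), seed = 2)
  ds <- simulate_dataset(net, k = 100, seed = 3)
  expect_identical(subsample_timepoints(ds, 1)$values, ds$values)
  expect_equal(ncol(subsample_timepoints(ds, 4)$values), 25)
  ds5 <- simulate_dataset(net, k = 5, seed = 3)
  expect_equal(subsample_timepoints(ds5, 2)$sample_info$timepoint, c(1, 3, 5))
  expect_error(subsample_timepoints(ds5, 5), "interval")
})

test_that("lagged pairs align leading and trailing samples", {
  net <- sample_weights(load_raf_network(), seed = 2)
  ds <- simulate_dataset(net, k = 5, seed = 3)
  lp <- make_lagged_pairs(ds)
  expect_equal(ncol(lp$leading), 4)
  expect_identical(lp$leading, ds$values[, 1:4])
  expect_identical(lp$trailing, ds$values[, 2:5])
  ds2 <- simulate_dataset(net, k = 2, seed = 3)
  expect_equal(ncol(make_lagged_pairs(ds2)$leading), 1)
  x <- ds$values
  x[1, ] <- 7
  expect_equal(make_lagged_pairs(x)$zero_variance, rownames(x)[1])
  expect_error(make_lagged_pairs(x[, 1, drop = FALSE]), "2 samples")
})

test_that("perfect scores yield AUROC 1 and sweeps are seeded", {
  net <- sample_weights(load_raf_network(), seed = 4)
  labs <- phosbench:::truth_labels(net)
  oracle <- assoc_matrix(ifelse(is.na(unclass(labs)), 0, unclass(labs)),
                         measure = "oracle")
  expect_equal(phosbench:::auroc_matrix(oracle, labs), 1)
  s1 <- run_sweep(net, "length", values = c(4, 8), n_datasets = 3,
                  measures = c("pearson", "ggm"), seed = 6)
  s2 <- run_sweep(net, "length", values = c(4, 8), n_datasets = 3,
                  measures = c("pearson", "ggm"), seed = 6)
  expect_identical(s1, s2)
  expect_error(run_sweep(net, "length", values = 4, measures = "magic"),
               "arg")
})

test_that("shuffled truth sits at the chance floor", {
  net <- load_raf_network()
  set.seed(11)
  aucs <- replicate(100, {
    wnet <- sample_weights(net)
    ds <- simulate_dataset(wnet, k = 20)
    a <- pearson_matrix(ds$values)
    labs <- phosbench:::truth_labels(wnet)
    l <- unclass(labs)
    ut <- which(upper.tri(l))
    l[ut] <- sample(l[ut])       # shuffle edge labels over the pair space
    l[lower.tri(l)] <- t(l)[lower.tri(l)]
    phosbench:::auroc_matrix(a, label_matrix(l, mode = "SS"))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})
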