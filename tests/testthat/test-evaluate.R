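make_eval_case <- function(score, label, directed = FALSE) {
  # wrap plain vectors into matched assoc/label matrices over one row set
  n <- length(score)
  sites <- paste0("s", seq_len(n + 1))
  A <- matrix(0, n + 1, n + 1, dimnames = list(sites, sites))
  L <- matrix(NA_real_, n + 1, n + 1, dimnames = list(sites, sites))
  idx <- cbind(1, 2:(n + 1))
  A[idx] <- score
  A[idx[, c(2, 1)]] <- score
  L[idx] <- label
  L[idx[, c(2, 1)]] <- label
  list(assoc = assoc_matrix(A, "pearson", directed = FALSE),
       labels = label_matrix(L, mode = "SS"))
}

test_that("the TP gate admits datasets with at least five positives", {
  L <- matrix(c(rep(1, 5), rep(0, 5)), 2, 5)
  dimnames(L) <- list(c("a", "b"), paste0("s", 1:5))
  expect_true(tp_gate(label_matrix(L, directed = TRUE)))
  L[1, 1] <- 0
  expect_false(tp_gate(label_matrix(L, directed = TRUE)))
  expect_false(tp_gate(label_matrix(L * 0, directed = TRUE)))
  expect_true(tp_gate(label_matrix(L, directed = TRUE), min_tp = 4))
})

test_that("metrics hit their closed-form anchors", {
  # perfect separation at prevalence 0.1
  cs <- make_eval_case(score = c(rep(2, 2), rep(0.5, 18)),
                       label = c(1, 1, rep(0, 18)))
  m <- compute_metrics(cs$assoc, cs$labels)
  expect_equal(m$auroc, 1)
  expect_equal(m$auprc, 1)
  expect_equal(m$baseline, 0.1)
  expect_equal(m$log10_auprc_ratio, 1)
  # constant scores: chance by midranks, AUPRC at baseline
  cs2 <- make_eval_case(score = rep(1, 20), label = c(rep(1, 4), rep(0, 16)))
  m2 <- compute_metrics(cs2$assoc, cs2$labels)
  expect_equal(m2$auroc, 0.5)
  expect_equal(m2$log10_auprc_ratio, 0)
  # 10 pairs, both TPs in the top 2: hypergeometric 1/C(10,2)
  cs3 <- make_eval_case(score = c(9, 8, 7:0) / 10,
                        label = c(1, 1, rep(0, 8)))
  m3 <- compute_metrics(cs3$assoc, cs3$labels)
  expect_equal(m3$top20_fisher_p, 1 / 45, tolerance = 1e-12)
  expect_error(compute_metrics(cs3$assoc,
                               label_matrix(matrix(rep(NA, 121), 11, 11,
                                                   dimnames = dimnames(cs3$labels)),
                                            mode = "SS")),
               "positive and negative")
})

test_that("AUROC equals exhaustive pair counting with ties", {
  set.seed(1)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    score <- sample(seq(0, 1, by = 0.1), n, TRUE)     # forces ties
    label <- sample(c(0, 1), n, TRUE, prob = c(0.7, 0.3))
    if (length(unique(label)) < 2) next
    expect_equal(phosbench:::auroc_vec(score, label),
                 oracle_auroc(score, label), tolerance = 1e-12)
  }
})

test_that("the top-20% Fisher test equals the hypergeometric tail", {
  set.seed(2)
  for (i in 1:10) {
    n <- sample(20:50, 1)
    score <- rnorm(n)
    label <- sample(c(0, 1), n, TRUE)
    if (sum(label) == 0 || sum(label) == n) next
    cs <- make_eval_case(abs(score), label)
    m <- compute_metrics(cs$assoc, cs$labels)
    k <- ceiling(0.2 * n)
    top <- order(-abs(score), seq_len(n))[1:k]
    a <- sum(label[top])
    expect_equal(m$top20_fisher_p,
                 oracle_fisher_tail(a, k - a, sum(label) - a,
                                    sum(label == 0) - (k - a)),
                 tolerance = 1e-9)
  }
})

test_that("permutation p-values follow the exceedance formula and seed", {
  cs <- make_eval_case(score = c(5, 4, 3, 2, 1, 0.5, 0.4, 0.3, 0.2, 0.1),
                       label = c(1, 1, 1, rep(0, 7)))
  pr <- permutation_pvalue(cs$assoc, cs$labels, n_perm = 2000, seed = 3)
  expect_equal(pr$p_value, sum(pr$null_aucs > pr$observed) / 2000)
  # observed is the maximum achievable AUROC with distinct scores: no
  # permutation can strictly exceed it
  expect_equal(pr$observed, 1)
  expect_equal(pr$p_value, 0)
  pr2 <- permutation_pvalue(cs$assoc, cs$labels, n_perm = 2000, seed = 3)
  expect_identical(pr2$null_aucs, pr$null_aucs)
  expect_error(permutation_pvalue(cs$assoc, cs$labels, n_perm = 0), "n_perm")
})

test_that("label shuffles and permutation nulls are calibrated", {
  set.seed(4)
  score <- rnorm(40)
  label <- c(rep(1, 10), rep(0, 30))
  cs <- make_eval_case(abs(score), label)
  # mean AUROC over 1,000 label shuffles sits at chance
  pr <- permutation_pvalue(cs$assoc, cs$labels, n_perm = 1000, seed = 5)
  expect_lt(abs(mean(pr$null_aucs) - 0.5), 0.02)
  # permutation p of score-shuffled matrices is approximately uniform
  set.seed(6)
  ps <- replicate(500, {
    cs_null <- make_eval_case(sample(abs(score)), label)
    permutation_pvalue(cs_null$assoc, cs_null$labels, n_perm = 200)$p_value
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("kinase ranking identifies the true kinase and rejects rank-based measures", {
  kin <- paste0("k", 1:10)
  subs <- paste0("s", 1:6)
  set.seed(7)
  A <- matrix(runif(16 * 16, 0, 0.5), 16, 16,
              dimnames = list(c(kin, subs), c(kin, subs)))
  L <- matrix(NA_real_, 10, 6, dimnames = list(kin, subs))
  L[] <- 0
  true_k <- sample(kin, 6, TRUE)
  for (j in seq_along(subs)) {
    L[true_k[j], j] <- 1
    A[true_k[j], subs[j]] <- 0.99          # true kinase scores highest
  }
  a <- assoc_matrix(A, "pearson", directed = FALSE)
  labs <- label_matrix(L, mode = "KS_direct", directed = TRUE)
  out <- kinase_rank_test(a, labs, n_random = 50, seed = 8)
  expect_true(all(out$ranks$rank == 1))
  expect_lt(out$wilcoxon_p, 0.01)
  expect_lt(abs(mean(out$random_ranks) - 0.5), 0.05)
  expect_error(kinase_rank_test(assoc_matrix(A, "kendall"), labs),
               "continuous")
  expect_error(kinase_rank_test(assoc_matrix(A, "mi"), labs), "continuous")
})
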