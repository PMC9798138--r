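# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from its definition rather than reusing package
# internals.

oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum((x - mean(x)) * (y - mean(y))) / n
  den <- sqrt(sum((x - mean(x))^2) / n) * sqrt(sum((y - mean(y))^2) / n)
  num / den
}

oracle_spearman <- function(x, y) oracle_pearson(rank(x), rank(y))

# tau-b: concordant minus discordant over the geometric mean of
# tie-corrected pair counts, by full pair enumeration
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sx <- sign(x[j] - x[i])
    sy <- sign(y[j] - y[i])
    if (sx == 0 && sy == 0) next
    if (sx == 0) tx <- tx + 1
    else if (sy == 0) ty <- ty + 1
    else if (sx == sy) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

oracle_mi <- function(a, b) {
  n <- length(a)
  total <- 0
  for (i in unique(a)) for (j in unique(b)) {
    pij <- sum(a == i & b == j) / n
    if (pij > 0) {
      total <- total + pij * log(pij / (sum(a == i) / n * sum(b == j) / n))
    }
  }
  total
}

oracle_funchisq <- function(tab) {
  r <- nrow(tab)
  s <- ncol(tab)
  n <- sum(tab)
  t1 <- 0
  for (i in 1:r) {
    if (sum(tab[i, ]) == 0) next
    e <- sum(tab[i, ]) / s
    for (j in 1:s) t1 <- t1 + (tab[i, j] - e)^2 / e
  }
  t2 <- sum((colSums(tab) - n / s)^2 / (n / s))
  t1 - t2
}

# Partial correlation via regression residuals: cor of the residuals of
# x_i and x_k each regressed on all remaining variables.
oracle_partial_cor <- function(x, i, k) {
  others <- setdiff(seq_len(nrow(x)), c(i, k))
  d <- as.data.frame(t(x))
  ri <- stats::resid(stats::lm(d[[i]] ~ ., data = d[others]))
  rk <- stats::resid(stats::lm(d[[k]] ~ ., data = d[others]))
  stats::cor(ri, rk)
}

# AUROC by exhaustive TP x TN pair comparison, ties counted 1/2.
oracle_auroc <- function(score, label) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# One-sided (enrichment) Fisher p as the hypergeometric upper tail.
oracle_fisher_tail <- function(a, b, c_, d) {
  m <- a + c_       # positives
  n <- b + d        # negatives
  k <- a + b        # top-set size
  hi <- min(m, k)
  sum(vapply(a:hi, function(x) {
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }, numeric(1)))
}

# Exact 1-D k-means by enumerating all contiguous partitions of the
# sorted values.
oracle_kmeans_ss <- function(v, k) {
  s <- sort(v)
  n <- length(s)
  cuts <- utils::combn(n - 1, k - 1, simplify = FALSE)
  best <- Inf
  for (ct in cuts) {
    bounds <- c(0, ct, n)
    ssq <- 0
    for (g in seq_len(k)) {
      seg <- s[(bounds[g] + 1):bounds[g + 1]]
      ssq <- ssq + sum((seg - mean(seg))^2)
    }
    best <- min(best, ssq)
  }
  best
}

within_ss <- function(v, labels) {
  sum(vapply(split(v, labels), function(g) sum((g - mean(g))^2), numeric(1)))
}

# Smith-Waterman local alignment with affine gaps, plain dynamic
# programming over three matrices.
oracle_sw <- function(a, b, sub, gap_open = 10, gap_extend = 4) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a)
  m <- length(b)
  M <- Ix <- Iy <- matrix(0, n + 1, m + 1)
  Ix[] <- Iy[] <- -Inf
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                    Ix[i - 1, j] - gap_extend)
    Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                    Iy[i, j - 1] - gap_extend)
    M[i, j] <- max(0, max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                          Iy[i - 1, j - 1]) + sub[a[i - 1], b[j - 1]])
    best <- max(best, M[i, j])
  }
  best
}

random_aa_window <- function(n = 15) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"), n, TRUE),
        collapse = "")
}
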