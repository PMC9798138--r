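#' Association matrix container
#'
#' A variables x variables score matrix with the measure name and
#' directedness recorded as attributes. Undirected measures produce
#' symmetric matrices; the diagonal is never evaluated.
#'
#' @param scores numeric matrix with identical row and column names.
#' @param measure measure label.
#' @param directed logical; `TRUE` for non-symmetric (directional) scores.
#' @return An `assoc_matrix`.
#' @export
assoc_matrix <- function(scores, measure, directed = FALSE) {
  stopifnot(is.matrix(scores))
  structure(scores, measure = measure, directed = directed,
            class = c("assoc_matrix", class(scores)))
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat("<assoc_matrix> ", attr(x, "measure"),
      if (attr(x, "directed")) " (directed), " else " (symmetric), ",
      nrow(x), " x ", ncol(x), "\n", sep = "")
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' Measures available for association scoring
#'
#' @return Character vector of the six measure names.
#' @export
phos_measures <- function() {
  c("pearson", "spearman", "kendall", "mi", "funchisq", "ggm")
}

#' Score all pairwise associations of a data matrix
#'
#' Dispatches to one of the six association measures. With `lagged` (a
#' leading/trailing pair from [make_lagged_pairs()]) every measure fills a
#' directed matrix where entry (i, j) scores variable i at t against
#' variable j at t+1.
#'
#' @param x variables x samples numeric matrix.
#' @param measure one of [phos_measures()].
#' @param lagged optional list with `leading` and `trailing` matrices.
#' @param levels discretization level count for `mi` and `funchisq`;
#'   default `min(ceiling(sqrt(n)), 5)` for n samples.
#' @return An `assoc_matrix`.
#' @export
score_associations <- function(x, measure = phos_measures(), lagged = NULL,
                               levels = NULL) {
  measure <- match.arg(measure)
  switch(measure,
    pearson  = pearson_matrix(x, lagged = lagged),
    spearman = spearman_matrix(x, lagged = lagged),
    kendall  = kendall_matrix(x, lagged = lagged),
    mi       = mutual_information_matrix(x, lagged = lagged, levels = levels),
    funchisq = funchisq_matrix(x, lagged = lagged, levels = levels),
    ggm      = ggm_matrix(x, lagged = lagged))
}

cor_based_matrix <- function(x, method, lagged = NULL, min_samples = 3) {
  if (!is.null(lagged)) {
    lead <- lagged$leading
    trail <- lagged$trailing
    if (ncol(lead) < min_samples) stop("need at least ", min_samples, " samples")
    s <- suppressWarnings(cor(t(lead), t(trail), method = method))
    dimnames(s) <- list(rownames(lead), rownames(trail))
    return(assoc_matrix(s, measure = method, directed = TRUE))
  }
  if (ncol(x) < min_samples) stop("need at least ", min_samples, " samples")
  s <- suppressWarnings(cor(t(x), method = method))
  assoc_matrix(s, measure = method, directed = FALSE)
}

#' Pearson correlation matrix
#'
#' Pairwise Pearson coefficients between rows; zero-variance rows yield
#' `NA` scores.
#'
#' @inheritParams score_associations
#' @return An `assoc_matrix` in \[-1, 1\].
#' @export
pearson_matrix <- function(x, lagged = NULL) {
  cor_based_matrix(x, "pearson", lagged)
}

#' Spearman correlation matrix
#'
#' Pearson correlation between midranks of the rows.
#'
#' @inheritParams score_associations
#' @return An `assoc_matrix` in \[-1, 1\].
#' @export
spearman_matrix <- function(x, lagged = NULL) {
  cor_based_matrix(x, "spearman", lagged)
}

#' Kendall rank correlation matrix
#'
#' Concordant-minus-discordant pair counts; ties handled by the tau-b
#' correction (real phosphoproteomics matrices contain ties, which the
#' textbook unique-value formula does not cover).
#'
#' @inheritParams score_associations
#' @return An `assoc_matrix` in \[-1, 1\].
#' @export
kendall_matrix <- function(x, lagged = NULL) {
  cor_based_matrix(x, "kendall", lagged, min_samples = 2)
}

#' Globally optimal 1-D k-means discretization
#'
#' Partitions a numeric vector into `k` contiguous-in-value clusters
#' minimising within-cluster sum of squares, by dynamic programming over
#' the sorted values (the 1-D analogue of k-means that is exactly
#' solvable). Labels are ordered by cluster mean.
#'
#' @param v numeric vector.
#' @param k number of levels; reduced with a warning when it exceeds the
#'   number of distinct values.
#' @return Integer labels in `1..k`, ordered so higher labels have higher
#'   cluster means.
#' @export
discretize_1d_kmeans <- function(v, k) {
  stopifnot(k >= 1)
  n <- length(v)
  n_distinct <- length(unique(v))
  if (k > n_distinct) {
    warning("k exceeds number of distinct values; reduced to ", n_distinct)
    k <- n_distinct
  }
  if (k == 1) return(rep(1L, n))
  ord <- order(v)
  s <- v[ord]
  cs <- cumsum(s)
  cs2 <- cumsum(s^2)
  # ss(j, i): within-SS of s[j..i], O(1) via prefix sums
  ss <- function(j, i) {
    sum_ <- cs[i] - if (j > 1) cs[j - 1] else 0
    sum2 <- cs2[i] - if (j > 1) cs2[j - 1] else 0
    sum2 - sum_^2 / (i - j + 1)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(1L, k, n)
  for (i in 1:n) D[1, i] <- ss(1, i)
  for (m in 2:k) {
    for (i in m:n) {
      j <- m:i
      sum_ <- cs[i] - cs[j - 1]
      sum2 <- cs2[i] - cs2[j - 1]
      cand <- D[m - 1, j - 1] + sum2 - sum_^2 / (i - j + 1)
      best <- which.min(cand)
      D[m, i] <- cand[best]
      B[m, i] <- j[best]
    }
  }
  labs_sorted <- integer(n)
  hi <- n
  for (m in k:1) {
    lo <- if (m > 1) B[m, hi] else 1L
    labs_sorted[lo:hi] <- m
    hi <- lo - 1L
  }
  labs <- integer(n)
  labs[ord] <- labs_sorted
  labs
}

default_levels <- function(n) min(ceiling(sqrt(n)), 5)

discretize_rows <- function(x, levels) {
  t(apply(x, 1, function(v) {
    suppressWarnings(discretize_1d_kmeans(v, min(levels, length(unique(v)))))
  }))
}

#' Mutual information matrix on discretized data
#'
#' Each row is discretized by optimal 1-D k-means into `levels` clusters;
#' the plug-in mutual information (natural log) of the joint level
#' frequencies is computed for every pair.
#'
#' @inheritParams score_associations
#' @return A symmetric non-negative `assoc_matrix` (nats).
#' @export
mutual_information_matrix <- function(x, lagged = NULL, levels = NULL) {
  if (!is.null(lagged)) {
    lead <- lagged$leading
    trail <- lagged$trailing
    levels <- levels %||% default_levels(ncol(lead))
    dl <- discretize_rows(lead, levels)
    dt <- discretize_rows(trail, levels)
    s <- outer_stat(dl, dt, mi_stat)
    dimnames(s) <- list(rownames(lead), rownames(trail))
    return(assoc_matrix(s, "mi", directed = TRUE))
  }
  levels <- levels %||% default_levels(ncol(x))
  d <- discretize_rows(x, levels)
  s <- outer_stat(d, d, mi_stat)
  dimnames(s) <- dimnames(x)[c(1, 1)]
  assoc_matrix(s, "mi", directed = FALSE)
}

mi_stat <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / e[nz]))
}

outer_stat <- function(da, db, f) {
  na <- nrow(da)
  nb <- nrow(db)
  s <- matrix(NA_real_, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb)) s[i, j] <- f(da[i, ], db[j, ])
  s
}

#' Functional chi-squared statistic of a contingency table
#'
#' The Pearson-type deviation of each row from column-uniformity, minus
#' the deviation of the column marginal from uniformity. The statistic is
#' non-symmetric: comparing it between a table and its transpose detects
#' the direction of a functional dependency (see [funchisq_matrix()] for
#' the direction convention used when scoring variable pairs; on
#' deterministic many-to-one tables that convention makes the functional
#' direction score higher).
#'
#' @param tab non-negative integer contingency table.
#' @return List with `stat`, `df = (r-1)(s-1)` and the normalized
#'   statistic `(stat - df) / sqrt(2 df)`.
#' @export
fun_chisq_stat <- function(tab) {
  tab <- as.matrix(tab)
  r <- nrow(tab)
  s <- ncol(tab)
  if (r < 2 || s < 2) return(list(stat = NA_real_, df = NA_real_,
                                  normalized = NA_real_))
  n <- sum(tab)
  row_tot <- rowSums(tab)
  col_tot <- colSums(tab)
  e_row <- row_tot / s
  term1 <- sum((tab - e_row)^2 / e_row)   # rows with zero total contribute 0/0
  if (any(row_tot == 0)) {
    keep <- row_tot > 0
    term1 <- sum((tab[keep, , drop = FALSE] - e_row[keep])^2 / e_row[keep])
  }
  term2 <- sum((col_tot - n / s)^2 / (n / s))
  df <- (r - 1) * (s - 1)
  stat <- term1 - term2
  list(stat = stat, df = df, normalized = (stat - df) / sqrt(2 * df))
}

#' Functional chi-squared association matrix (directed)
#'
#' Discretizes each row by optimal 1-D k-means and fills the non-symmetric
#' matrix of normalized functional chi-squared statistics; entry (i, j)
#' scores "j is a function of i", computed as [fun_chisq_stat()] on the
#' contingency table with the effect variable j on the rows — the
#' orientation under which deterministic many-to-one dependencies score
#' highest in their functional direction.
#'
#' @inheritParams score_associations
#' @return A directed `assoc_matrix`.
#' @export
funchisq_matrix <- function(x, lagged = NULL, levels = NULL) {
  f <- function(a, b) {
    if (length(unique(a)) < 2 || length(unique(b)) < 2) return(NA_real_)
    fun_chisq_stat(table(b, a))$normalized
  }
  if (!is.null(lagged)) {
    lead <- lagged$leading
    trail <- lagged$trailing
    levels <- levels %||% default_levels(ncol(lead))
    s <- outer_stat(discretize_rows(lead, levels),
                    discretize_rows(trail, levels), f)
    dimnames(s) <- list(rownames(lead), rownames(trail))
    return(assoc_matrix(s, "funchisq", directed = TRUE))
  }
  levels <- levels %||% default_levels(ncol(x))
  d <- discretize_rows(x, levels)
  s <- outer_stat(d, d, f)
  dimnames(s) <- dimnames(x)[c(1, 1)]
  assoc_matrix(s, "funchisq", directed = TRUE)
}

# Schafer-Strimmer analytic shrinkage of the correlation matrix toward the
# identity; returns the shrunk correlation matrix and the intensity.
shrink_correlation <- function(x) {
  n <- ncol(x)
  xs <- t(scale(t(x)))          # rows standardized (sd uses n-1)
  xs[is.na(xs)] <- 0            # zero-variance rows carry no signal
  r <- tcrossprod(xs) / (n - 1)
  w_bar <- tcrossprod(xs) / n
  # var(r_ij) = n / (n-1)^3 * sum_k (w_kij - w_bar_ij)^2
  sq <- tcrossprod(xs^2)        # sum_k w_kij^2
  var_r <- n / (n - 1)^3 * (sq - n * w_bar^2)
  off <- upper.tri(r)
  denom <- sum(r[off]^2)
  lambda <- if (denom > 0) sum(var_r[off]) / denom else 1
  lambda <- min(1, max(0, lambda))
  r_shrunk <- (1 - lambda) * r
  diag(r_shrunk) <- 1
  list(cor = r_shrunk, lambda = lambda)
}

partial_cor_from_cor <- function(R) {
  omega <- tryCatch(solve(R), error = function(e) {
    stop("correlation matrix singular even after shrinkage")
  })
  d <- 1 / sqrt(diag(omega))
  p <- -omega * outer(d, d)
  diag(p) <- 1
  p
}

#' Shrinkage Gaussian graphical model partial correlations
#'
#' Estimates the correlation matrix with the analytic Schafer-Strimmer
#' shrinkage toward the identity (intensity computed from the data), then
#' returns the full partial correlation matrix
#' `rho_ik = -inv(C)_ik / sqrt(inv(C)_ii inv(C)_kk)`, the conditional
#' association of each pair given all other variables.
#'
#' With a lagged pair, leading and trailing variables are stacked into one
#' 2p-variable system and the leading-vs-trailing block of its partial
#' correlation matrix is returned as a directed score.
#'
#' @inheritParams score_associations
#' @return An `assoc_matrix` of partial correlations.
#' @export
ggm_matrix <- function(x, lagged = NULL) {
  if (!is.null(lagged)) {
    lead <- lagged$leading
    trail <- lagged$trailing
    stacked <- rbind(lead, trail)
    rownames(stacked) <- c(paste0("lead.", rownames(lead)),
                           paste0("trail.", rownames(trail)))
    sh <- shrink_correlation(stacked)
    pc <- partial_cor_from_cor(sh$cor)
    p <- nrow(lead)
    s <- pc[seq_len(p), p + seq_len(nrow(trail)), drop = FALSE]
    dimnames(s) <- list(rownames(lead), rownames(trail))
    out <- assoc_matrix(s, "ggm", directed = TRUE)
    attr(out, "lambda") <- sh$lambda
    return(out)
  }
  if (ncol(x) < 3) stop("need at least 3 samples")
  sh <- shrink_correlation(x)
  pc <- partial_cor_from_cor(sh$cor)
  dimnames(pc) <- dimnames(x)[c(1, 1)]
  out <- assoc_matrix(pc, "ggm", directed = FALSE)
  attr(out, "lambda") <- sh$lambda
  out
}

#' Tidy an association matrix into a long tibble
#'
#' @param x an `assoc_matrix`.
#' @param ... unused.
#' @return Tibble with columns `row`, `col`, `score` (diagonal excluded;
#'   upper triangle only for symmetric matrices).
#' @exportS3Method generics::tidy
tidy.assoc_matrix <- function(x, ...) {
  m <- unclass(x)
  idx <- if (isTRUE(attr(x, "directed"))) {
    which(row(m) != col(m), arr.ind = TRUE)
  } else {
    which(upper.tri(m), arr.ind = TRUE)
  }
  tibble::tibble(row = rownames(m)[idx[, 1]], col = colnames(m)[idx[, 2]],
                 score = m[idx], measure = attr(x, "measure"))
}

#' @importFrom generics tidy
#' @export
generics::tidy
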