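#' Gold-standard label matrix container
#'
#' Candidate-pair labels in `{1, 0, NA}`: 1 = known interaction, 0 =
#' assumed negative (residue class compatible but unannotated), NA = out
#' of the evaluable space. `NA` entries never enter evaluation.
#'
#' @param labels numeric/integer matrix with dimnames naming phosphosites.
#' @param mode one of `"KS_direct"`, `"KS_lagged"`, `"SS"`.
#' @param residue_class `"ST"`, `"Y"` or `NA`.
#' @param directed logical; whether (i, j) and (j, i) are distinct
#'   candidates.
#' @return A `label_matrix`.
#' @export
label_matrix <- function(labels, mode = "KS_direct", residue_class = NA,
                         directed = NA) {
  stopifnot(is.matrix(labels))
  if (!all(labels %in% c(0, 1, NA))) stop("labels must be 1, 0 or NA")
  if (is.na(directed)) directed <- mode != "SS"
  structure(labels, mode = mode, residue_class = residue_class,
            directed = directed, class = c("label_matrix", class(labels)))
}

#' @export
print.label_matrix <- function(x, ...) {
  cat("<label_matrix> mode=", attr(x, "mode"), ", ", nrow(x), " x ", ncol(x),
      ": ", sum(x == 1, na.rm = TRUE), " positives, ",
      sum(x == 0, na.rm = TRUE), " negatives, ",
      sum(is.na(x)), " NA\n", sep = "")
  invisible(x)
}

#' True-positive gate for dataset inclusion
#'
#' Datasets enter evaluation only when their label matrix holds at least
#' `min_tp` known positives.
#'
#' @param labels a `label_matrix`.
#' @param min_tp minimum number of 1-labels (default 5).
#' @return `TRUE` or `FALSE`.
#' @export
tp_gate <- function(labels, min_tp = 5) {
  sum(labels == 1, na.rm = TRUE) >= min_tp
}

# Align scores with labels into an edge list. Undirected label matrices are
# read from the upper triangle; a directed score matrix paired with
# undirected labels contributes the orientation with the larger |score|.
edge_list <- function(assoc, labels) {
  rs <- rownames(labels)
  cs <- colnames(labels)
  if (!all(rs %in% rownames(assoc)) || !all(cs %in% colnames(assoc))) {
    stop("label sites missing from the association matrix")
  }
  s <- unclass(assoc)[rs, cs, drop = FALSE]
  L <- unclass(labels)
  directed_labels <- isTRUE(attr(labels, "directed"))
  directed_scores <- isTRUE(attr(assoc, "directed"))
  if (directed_labels) {
    idx <- which(!is.na(L) & outer(rs, cs, "!="), arr.ind = TRUE)
    score <- s[idx]
  } else {
    if (nrow(L) != ncol(L) || !identical(rs, cs)) {
      stop("undirected labels require a square matrix over one site set")
    }
    idx <- which(upper.tri(L) & !is.na(L), arr.ind = TRUE)
    score <- s[idx]
    if (directed_scores) {
      rev_score <- s[idx[, c(2, 1), drop = FALSE]]
      take_rev <- !is.na(rev_score) &
        (is.na(score) | abs(rev_score) > abs(score))
      score[take_rev] <- rev_score[take_rev]
    }
  }
  tibble::tibble(row = rs[idx[, 1]], col = cs[idx[, 2]],
                 score = score, label = L[idx])
}

# Rank-sum AUROC with midranks; `score` already on the ranking scale.
auroc_vec <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label == 1)
  n0 <- sum(label == 0)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Average-precision AUPRC; tied scores are processed as blocks, each
# positive in a block credited with the precision at the block end.
auprc_vec <- function(score, label) {
  ord <- order(-score)
  lab <- label[ord]
  sc <- score[ord]
  grp_end <- c(which(diff(sc) != 0), length(sc))
  tp_cum <- cumsum(lab == 1)
  n_pos <- sum(label == 1)
  prec_at_end <- tp_cum[grp_end] / grp_end
  tp_in_grp <- diff(c(0, tp_cum[grp_end]))
  sum(tp_in_grp * prec_at_end) / n_pos
}

#' Evaluate an association matrix against gold labels
#'
#' Computes the three benchmark metrics over all non-NA labeled pairs:
#' AUROC (rank-sum identity with tie midranks), the area under the
#' precision-recall curve together with its ratio to the positive
#' prevalence baseline, and enrichment of true positives in the top 20%
#' of predictions (one-sided Fisher exact test). Ranking uses `|score|`
#' by default: strongly negative associations are still informative
#' associations.
#'
#' @param assoc an `assoc_matrix`.
#' @param labels a `label_matrix` whose sites appear in `assoc`.
#' @param top_frac fraction of predictions forming the "top" set
#'   (default 0.2).
#' @param rank_abs rank by absolute score (default `TRUE`).
#' @return A one-row tibble: `measure`, `auroc`, `auprc`, `baseline`,
#'   `log10_auprc_ratio`, `top20_odds_ratio`, `top20_fisher_p`, `n_tp`,
#'   `n_tn`.
#' @export
compute_metrics <- function(assoc, labels, top_frac = 0.2, rank_abs = TRUE) {
  el <- edge_list(assoc, labels)
  el <- el[!is.na(el$score), , drop = FALSE]
  if (nrow(el) == 0 || length(unique(el$label)) < 2) {
    stop("evaluation needs both positive and negative labeled pairs")
  }
  sc <- if (rank_abs) abs(el$score) else el$score
  lab <- el$label
  n <- length(lab)
  n_tp <- sum(lab == 1)
  n_tn <- sum(lab == 0)
  auroc <- auroc_vec(sc, lab)
  auprc <- auprc_vec(sc, lab)
  baseline <- n_tp / n
  # deterministic top-20% split: stable order on (-score, index)
  k <- ceiling(top_frac * n)
  top <- order(-sc, seq_len(n))[seq_len(k)]
  a <- sum(lab[top] == 1)
  b <- k - a
  c_ <- n_tp - a
  d <- n_tn - b
  tab <- matrix(c(a, b, c_, d), 2, 2)
  fisher_p <- fisher.test(tab, alternative = "greater")$p.value
  or <- if (any(tab == 0)) {
    (a + 0.5) * (d + 0.5) / ((b + 0.5) * (c_ + 0.5))
  } else {
    a * d / (b * c_)
  }
  tibble::tibble(measure = attr(assoc, "measure") %||% NA_character_,
                 auroc = auroc, auprc = auprc, baseline = baseline,
                 log10_auprc_ratio = log10(auprc / baseline),
                 top20_odds_ratio = or, top20_fisher_p = fisher_p,
                 n_tp = n_tp, n_tn = n_tn)
}

#' Permutation null for the AUROC of an association matrix
#'
#' Shuffles the score column of the labeled edge list `n_perm` times
#' (sampling without replacement), recomputes the AUROC each time, and
#' returns `p = #(null AUROC > observed) / n_perm`.
#'
#' @inheritParams compute_metrics
#' @param n_perm number of permutations (default 10000).
#' @param seed optional integer seed.
#' @return A `perm_result` list: `observed`, `null_aucs`, `p_value`,
#'   `n_perm`.
#' @export
permutation_pvalue <- function(assoc, labels, n_perm = 10000, seed = NULL,
                               rank_abs = TRUE) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  el <- edge_list(assoc, labels)
  el <- el[!is.na(el$score), , drop = FALSE]
  sc <- if (rank_abs) abs(el$score) else el$score
  lab <- el$label
  observed <- auroc_vec(sc, lab)
  r <- rank(sc)
  n1 <- sum(lab == 1)
  n0 <- sum(lab == 0)
  const <- n1 * (n1 + 1) / 2
  null_aucs <- vapply(seq_len(n_perm), function(b) {
    (sum(r[sample.int(length(r), n1)]) - const) / (n1 * n0)
  }, numeric(1))
  structure(list(observed = observed, null_aucs = null_aucs,
                 p_value = sum(null_aucs > observed) / n_perm,
                 n_perm = n_perm),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat("<perm_result> observed AUROC ", round(x$observed, 4), ", p = ",
      x$p_value, " (", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.perm_result <- function(x, ...) {
  tibble::tibble(observed = x$observed, p_value = x$p_value,
                 n_perm = x$n_perm,
                 null_mean = mean(x$null_aucs), null_sd = sd(x$null_aucs))
}

#' Rank the true kinase among candidates for each substrate
#'
#' For every substrate phosphosite with at least one annotated kinase, the
#' rank of the true kinase's score among all candidate kinase rows is
#' compared against the ranks obtained after randomising scores within the
#' substrate's candidate column; a rank-sum test contrasts the two rank
#' distributions. Only continuous-scale measures (Pearson, GGM) are
#' eligible: rank-based and discretized measures produce heavily tied
#' scores whose ranks are not meaningful here.
#'
#' @param assoc an `assoc_matrix` from `pearson_matrix()` or
#'   [ggm_matrix()].
#' @param labels a KS-mode `label_matrix` (kinase sites x substrate
#'   sites).
#' @param n_random randomisations per substrate (default 100).
#' @param seed optional integer seed.
#' @return List with `ranks` (tibble: substrate, rank, n_candidates,
#'   normalized_rank), `random_ranks` (numeric), `wilcoxon_p`.
#' @export
kinase_rank_test <- function(assoc, labels, n_random = 100, seed = NULL) {
  measure <- attr(assoc, "measure")
  if (!measure %in% c("pearson", "ggm")) {
    stop("kinase ranking is restricted to continuous-scale measures ",
         "(pearson, ggm); got '", measure, "'")
  }
  if (!is.null(seed)) set.seed(seed)
  s <- abs(unclass(assoc)[rownames(labels), colnames(labels), drop = FALSE])
  L <- unclass(labels)
  obs <- list()
  rand <- numeric(0)
  for (j in seq_len(ncol(L))) {
    true_k <- which(L[, j] == 1)
    cand <- which(!is.na(L[, j]) & !is.na(s[, j]))
    true_k <- intersect(true_k, cand)
    if (length(true_k) == 0 || length(cand) < 2) next
    r <- rank(-s[cand, j], ties.method = "average")
    best <- min(r[match(true_k, cand)])
    obs[[length(obs) + 1]] <- tibble::tibble(
      substrate = colnames(L)[j], rank = best,
      n_candidates = length(cand),
      normalized_rank = (best - 1) / (length(cand) - 1))
    null_j <- vapply(seq_len(n_random), function(b) {
      rp <- sample(r)
      (min(rp[match(true_k, cand)]) - 1) / (length(cand) - 1)
    }, numeric(1))
    rand <- c(rand, null_j)
  }
  if (length(obs) == 0) stop("no substrate with a known kinase to rank")
  ranks <- dplyr::bind_rows(obs)
  p <- suppressWarnings(
    wilcox.test(ranks$normalized_rank, rand, alternative = "less")$p.value)
  list(ranks = ranks, random_ranks = rand, wilcoxon_p = p)
}
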