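phos_env <- new.env(parent = emptyenv())

# BLOSUM62 with the padding character X scored 0 against everything, so
# window positions beyond a protein terminus neither reward nor penalise
# an alignment.
blosum62_pad <- function() {
  if (is.null(phos_env$blosum62_pad)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    m["X", ] <- 0
    m[, "X"] <- 0
    phos_env$blosum62_pad <- m
  }
  phos_env$blosum62_pad
}

# Elementwise Smith-Waterman scores for aligned sequence vectors.
sw_score <- function(a, b, gap_open = 10, gap_extend = 4) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(a), Biostrings::AAStringSet(b), type = "local",
    substitutionMatrix = blosum62_pad(),
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
}

# Self-alignment scores with caching over unique sequences.
sw_self <- function(seqs, gap_open = 10, gap_extend = 4) {
  u <- unique(seqs)
  s <- sw_score(u, u, gap_open, gap_extend)
  s[match(seqs, u)]
}

as_windows <- function(windows) {
  if (is.data.frame(windows)) {
    w <- stats::setNames(windows$window, windows$site)
  } else {
    w <- windows
  }
  if (is.null(names(w))) stop("windows must be named by site identifier")
  w
}

#' Extract the 15-mer peptide window around a phosphosite
#'
#' Residues at positions `pos - 7 .. pos + 7`; positions beyond the
#' protein termini are padded with `"X"` (scored 0 in alignments). The
#' residue at the centre must match the site's annotated residue.
#'
#' @param protein_sequence amino-acid string for the protein.
#' @param site list or one-row data frame with `accession`, `residue`,
#'   `position`.
#' @return A one-row tibble: `site` (identifier), `window` (15-mer).
#' @export
extract_window <- function(protein_sequence, site) {
  pos <- site$position
  res <- toupper(site$residue)
  n <- nchar(protein_sequence)
  if (pos < 1 || pos > n) stop("site position outside the protein sequence")
  actual <- substr(protein_sequence, pos, pos)
  if (toupper(actual) != res) {
    stop("sequence has '", actual, "' at position ", pos,
         " but the site claims '", res, "'")
  }
  lo <- pos - 7
  hi <- pos + 7
  core <- substr(protein_sequence, max(1, lo), min(n, hi))
  window <- paste0(strrep("X", max(0, 1 - lo)), toupper(core),
                   strrep("X", max(0, hi - n)))
  tibble::tibble(site = site_id(site$accession, res, pos), window = window)
}

#' Normalized local-alignment similarity between peptide windows
#'
#' Smith-Waterman local alignment with BLOSUM62 (gap open 10, gap extend
#' 4), normalized by the geometric mean of the two self-alignment scores:
#' `score(a, b) / sqrt(score(a, a) * score(b, b))`, giving a symmetric
#' similarity in \[0, 1\] that is 1 for identical peptides.
#'
#' @param a,b character vectors of peptide sequences (recycled
#'   elementwise).
#' @param gap_open,gap_extend affine gap penalties.
#' @return Numeric vector of similarities in \[0, 1\].
#' @export
peptide_similarity <- function(a, b, gap_open = 10, gap_extend = 4) {
  if (any(!nzchar(a)) || any(!nzchar(b))) stop("empty sequence")
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  cross <- sw_score(a, b, gap_open, gap_extend)
  self_a <- sw_self(a, gap_open, gap_extend)
  self_b <- sw_self(b, gap_open, gap_extend)
  denom <- sqrt(pmax(self_a, 0) * pmax(self_b, 0))
  ifelse(denom > 0, pmin(cross / denom, 1), 0)
}

# Full pairwise similarity matrix over a named window vector; all upper
# triangle pairs in a single vectorized alignment call.
similarity_matrix <- function(windows, gap_open = 10, gap_extend = 4) {
  w <- as_windows(windows)
  n <- length(w)
  S <- matrix(1, n, n, dimnames = list(names(w), names(w)))
  if (n < 2) return(S)
  idx <- which(upper.tri(S), arr.ind = TRUE)
  self <- sw_self(w, gap_open, gap_extend)
  sc <- sw_score(w[idx[, 1]], w[idx[, 2]], gap_open, gap_extend)
  denom <- sqrt(pmax(self[idx[, 1]], 0) * pmax(self[idx[, 2]], 0))
  sim <- ifelse(denom > 0, pmin(sc / denom, 1), 0)
  S[idx] <- sim
  S[idx[, c(2, 1), drop = FALSE]] <- sim
  S
}

# Elementwise similarity for two aligned site-id vectors, via unique
# window pairs.
pair_similarity <- function(sites_a, sites_b, windows) {
  w <- as_windows(windows)
  key <- paste(pmin(sites_a, sites_b), pmax(sites_a, sites_b))
  uk <- !duplicated(key)
  sims <- peptide_similarity(w[sites_a[uk]], w[sites_b[uk]])
  stats::setNames(sims, key[uk])[key]
}

unrank_pairs <- function(l, n) {
  cum <- cumsum((n - 1):1)
  i <- findInterval(l, cum, left.open = TRUE) + 1L
  j <- i + (l - c(0, cum)[i])
  cbind(i, j)
}

#' Derive the dataset-specific similarity threshold
#'
#' Removes the dataset's own phosphosites from the interactome pool, draws
#' up to `n_sample` true-positive pairs (substrate sites sharing a
#' kinase) and as many true-negative pairs (site pairs sharing no
#' kinase), computes both similarity distributions, and returns the TP
#' median as the filter threshold. When the pool holds fewer pairs than
#' `n_sample`, all pairs are used without resampling.
#'
#' @param records kinase-substrate records (see [read_interactome()]).
#' @param windows named character vector (or `site`/`window` tibble) of
#'   15-mer windows for the interactome substrate sites.
#' @param dataset_sites measured sites to exclude from the pool: a tibble
#'   with `accession`/`residue`/`position`, or a character vector of site
#'   identifiers.
#' @param n_sample pair sample size per class (default 100000).
#' @param residue_class restrict the pool to this residue class
#'   (default `"ST"`; the distribution shift supporting the filter is
#'   absent for Y sites).
#' @param seed optional integer seed.
#' @return A `similarity_threshold`: `threshold` (TP median),
#'   `tn_median`, `n_tp_sampled`, `n_tn_sampled`, `seed`.
#' @export
compute_threshold <- function(records, windows, dataset_sites,
                              n_sample = 100000, residue_class = "ST",
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- as_windows(windows)
  excl <- if (is.character(dataset_sites)) {
    dataset_sites
  } else {
    normalize_sites(dataset_sites)$site
  }
  rec <- records[!records$site %in% excl & records$site %in% names(w), ,
                 drop = FALSE]
  rec <- rec[substr(w[rec$site], 8, 8) %in%
               strsplit(residue_class, "")[[1]], , drop = FALSE]
  pool <- unique(rec$site)
  kin_of <- split(rec$kinase, rec$site)
  by_kin <- lapply(split(rec$site, rec$kinase), unique)
  tp_counts <- vapply(by_kin, function(s) choose(length(s), 2), numeric(1))
  if (sum(tp_counts) < 2) stop("fewer than 2 eligible TP pairs in the pool")

  # --- TP pairs: global index over per-kinase pair blocks
  total_tp <- sum(tp_counts)
  take <- min(total_tp, n_sample)
  idx <- if (total_tp <= n_sample) seq_len(total_tp) else
    sample.int(total_tp, n_sample)
  cum <- cumsum(tp_counts)
  kin_idx <- findInterval(idx, cum, left.open = TRUE) + 1L
  local <- idx - c(0, cum)[kin_idx]
  tp_a <- character(take)
  tp_b <- character(take)
  for (ki in unique(kin_idx)) {
    sel <- kin_idx == ki
    sites <- by_kin[[ki]]
    ij <- unrank_pairs(local[sel], length(sites))
    tp_a[sel] <- sites[ij[, 1]]
    tp_b[sel] <- sites[ij[, 2]]
  }
  shares_kinase <- function(a, b) {
    mapply(function(x, y) length(intersect(kin_of[[x]], kin_of[[y]])) > 0,
           a, b, USE.NAMES = FALSE)
  }
  # drop TP duplicates arising from pairs shared by several kinases
  dup <- duplicated(paste(pmin(tp_a, tp_b), pmax(tp_a, tp_b)))
  tp_a <- tp_a[!dup]
  tp_b <- tp_b[!dup]

  # --- TN pairs: random site pairs sharing no kinase
  np <- length(pool)
  total_pairs <- choose(np, 2)
  if (total_pairs <= max(n_sample, 2e5)) {
    ij <- unrank_pairs(seq_len(total_pairs), np)
    a <- pool[ij[, 1]]
    b <- pool[ij[, 2]]
    tn_keep <- !shares_kinase(a, b)
    tn_a <- a[tn_keep]
    tn_b <- b[tn_keep]
    if (length(tn_a) > n_sample) {
      pick <- sample.int(length(tn_a), n_sample)
      tn_a <- tn_a[pick]
      tn_b <- tn_b[pick]
    }
  } else {
    tn_a <- character(0)
    tn_b <- character(0)
    while (length(tn_a) < n_sample) {
      need <- n_sample - length(tn_a)
      l <- sample.int(total_pairs, min(total_pairs, need * 2))
      ij <- unrank_pairs(l, np)
      a <- pool[ij[, 1]]
      b <- pool[ij[, 2]]
      ok <- !shares_kinase(a, b)
      tn_a <- c(tn_a, a[ok])
      tn_b <- c(tn_b, b[ok])
      dup <- duplicated(paste(tn_a, tn_b))
      tn_a <- tn_a[!dup]
      tn_b <- tn_b[!dup]
    }
    tn_a <- tn_a[seq_len(n_sample)]
    tn_b <- tn_b[seq_len(n_sample)]
  }
  if (length(tn_a) < 1) stop("no eligible TN pairs in the pool")

  tp_sims <- pair_similarity(tp_a, tp_b, w)
  tn_sims <- pair_similarity(tn_a, tn_b, w)
  structure(list(threshold = median(tp_sims), tn_median = median(tn_sims),
                 tp_sims = tp_sims, tn_sims = tn_sims,
                 n_tp_sampled = length(tp_sims),
                 n_tn_sampled = length(tn_sims), seed = seed),
            class = "similarity_threshold")
}

#' @export
print.similarity_threshold <- function(x, ...) {
  cat("<similarity_threshold> TP median ", round(x$threshold, 4),
      " (TN median ", round(x$tn_median, 4), "; ",
      x$n_tp_sampled, " TP / ", x$n_tn_sampled, " TN pairs)\n", sep = "")
  invisible(x)
}

#' Apply the sequence-similarity filter to an association matrix
#'
#' Pairs whose window similarity falls below the threshold get their
#' association score set to 0 and are thereby evaluated as predicted
#' negatives; other pairs are untouched. Pairs lacking a window on either
#' side are set to NA with a warning. Idempotent.
#'
#' @param assoc an `assoc_matrix` over phosphosites.
#' @param windows named character vector (or tibble) of 15-mer windows.
#' @param thr a `similarity_threshold` (or a bare numeric threshold).
#' @return The filtered `assoc_matrix`.
#' @export
apply_similarity_filter <- function(assoc, windows, thr) {
  cutoff <- if (inherits(thr, "similarity_threshold")) thr$threshold else thr
  w <- as_windows(windows)
  sites <- unique(c(rownames(assoc), colnames(assoc)))
  missing <- setdiff(sites, names(w))
  have <- setdiff(sites, missing)
  if (length(missing) > 0) {
    warning(length(missing), " site(s) lack a peptide window; pairs set NA")
    assoc[rownames(assoc) %in% missing, ] <- NA
    assoc[, colnames(assoc) %in% missing] <- NA
  }
  S <- similarity_matrix(w[have])
  rs <- intersect(rownames(assoc), have)
  cs <- intersect(colnames(assoc), have)
  block <- unclass(assoc)[rs, cs, drop = FALSE]
  below <- S[rs, cs, drop = FALSE] < cutoff
  block[below] <- 0
  assoc[rs, cs] <- block
  attr(assoc, "similarity_filtered") <- TRUE
  assoc
}

#' Sequence similarity as a standalone predictor
#'
#' The filtered network without any association measure: pairs scoring 1
#' when their window similarity reaches the threshold and 0 otherwise.
#'
#' @param windows named character vector (or tibble) of 15-mer windows.
#' @param thr a `similarity_threshold` (or bare numeric threshold).
#' @param sites site identifiers to include (default: all windows).
#' @return A symmetric binary `assoc_matrix` (measure `"seqsim"`).
#' @export
filter_only_predictor <- function(windows, thr, sites = NULL) {
  cutoff <- if (inherits(thr, "similarity_threshold")) thr$threshold else thr
  w <- as_windows(windows)
  sites <- sites %||% names(w)
  missing <- setdiff(sites, names(w))
  if (length(missing) > 0) stop("windows missing for: ",
                                paste(head(missing, 5), collapse = ", "))
  S <- similarity_matrix(w[sites])
  out <- (S >= cutoff) * 1
  assoc_matrix(out, measure = "seqsim", directed = FALSE)
}
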