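#' Directed network container
#'
#' A light container for a weighted directed network: an ordered node list,
#' a tibble of directed edges (`parent`, `child`, `weight`) and a named
#' vector of autoregressive self-weights. Edge weights and self-weights may
#' be `NA` until [sample_weights()] has been called.
#'
#' @param nodes character vector of unique node identifiers.
#' @param edges data frame with columns `parent` and `child` (and optionally
#'   `weight`); every endpoint must appear in `nodes` and no edge may be
#'   duplicated.
#' @param self_weights optional named numeric vector of per-node
#'   self-weights.
#'
#' @return An object of class `directed_network`.
#' @export
directed_network <- function(nodes, edges, self_weights = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes) > 0) stop("duplicate node identifiers")
  edges <- tibble::as_tibble(edges)
  if (!all(c("parent", "child") %in% names(edges))) {
    stop("edges must have columns 'parent' and 'child'")
  }
  if (!"weight" %in% names(edges)) edges$weight <- NA_real_
  edges <- edges[, c("parent", "child", "weight")]
  if (anyDuplicated(edges[, c("parent", "child")]) > 0) {
    stop("duplicate edges")
  }
  bad <- setdiff(unique(c(edges$parent, edges$child)), nodes)
  if (length(bad) > 0) {
    stop("edge endpoints not declared as nodes: ", paste(bad, collapse = ", "))
  }
  if (is.null(self_weights)) {
    self_weights <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  }
  structure(list(nodes = nodes, edges = edges,
                 self_weights = self_weights[nodes]),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat("<directed_network> ", length(x$nodes), " nodes, ",
      nrow(x$edges), " directed edges\n", sep = "")
  cat("  nodes: ", paste(x$nodes, collapse = ", "), "\n", sep = "")
  if (all(is.na(x$edges$weight))) cat("  weights: unset\n")
  invisible(x)
}

#' Load the bundled Raf signalling pathway
#'
#' Returns the consensus Raf/Mek/Erk signalling pathway (11 nodes, 19
#' directed edges) used as the ground-truth network for the simulation
#' study. Weights are unset; call [sample_weights()] before simulating.
#'
#' @return A `directed_network` with 11 nodes and 19 edges.
#' @export
load_raf_network <- function() {
  path <- system.file("extdata", "raf_edges.tsv", package = "phosbench")
  if (!nzchar(path) || !file.exists(path)) {
    stop("bundled Raf edge list is missing from the installation")
  }
  edges <- readr::read_tsv(path, col_types = readr::cols(
    parent = readr::col_character(), child = readr::col_character()))
  if (nrow(edges) == 0 || !all(c("parent", "child") %in% names(edges))) {
    stop("bundled Raf edge list is corrupt")
  }
  nodes <- unique(c(edges$parent, edges$child))
  directed_network(nodes, edges)
}

#' Sample interaction weights for a network
#'
#' Draws a signed weight for every edge (and every node's self-weight) with
#' magnitude uniform on `weight_range` and an independent random sign, the
#' scheme used throughout the simulation study.
#'
#' @param net a `directed_network` with at least one edge.
#' @param weight_range numeric length-2 interval for |weight|
#'   (default `c(0.5, 2)`).
#' @param seed optional integer seed for reproducibility.
#' @param self_weights logical; also draw autoregressive self-weights
#'   (default `TRUE`).
#' @return The network with `weight` and `self_weights` populated.
#' @export
sample_weights <- function(net, weight_range = c(0.5, 2), seed = NULL,
                           self_weights = TRUE) {
  stopifnot(inherits(net, "directed_network"))
  if (nrow(net$edges) == 0) stop("network has no edges to weight")
  if (weight_range[1] <= 0 || weight_range[2] < weight_range[1]) {
    stop("weight_range must be a positive increasing interval")
  }
  if (!is.null(seed)) set.seed(seed)
  draw <- function(n) {
    runif(n, weight_range[1], weight_range[2]) * sample(c(-1, 1), n, TRUE)
  }
  net$edges$weight <- draw(nrow(net$edges))
  if (self_weights) {
    net$self_weights <- stats::setNames(draw(length(net$nodes)), net$nodes)
  } else {
    net$self_weights <- stats::setNames(rep(0, length(net$nodes)), net$nodes)
  }
  net
}

# Propagation matrix W with W[child, parent]; diagonal holds self-weights.
weight_matrix <- function(net) {
  p <- length(net$nodes)
  W <- matrix(0, p, p, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges) > 0 && !all(is.na(net$edges$weight))) {
    W[cbind(net$edges$child, net$edges$parent)] <- net$edges$weight
  }
  sw <- net$self_weights
  sw[is.na(sw)] <- 0
  diag(W) <- sw
  W
}

# Rescale W so its spectral radius is `radius`, guaranteeing a stationary
# VAR(1); a zero matrix is returned unchanged.
stabilize_weights <- function(W, radius = 0.95) {
  rho <- max(Mod(eigen(W, only.values = TRUE)$values))
  if (rho > 0) W * (radius / rho) else W
}

topological_order <- function(net) {
  remaining <- net$nodes
  edges <- net$edges
  order <- character(0)
  while (length(remaining) > 0) {
    has_parent <- unique(edges$child[edges$parent %in% remaining])
    roots <- setdiff(remaining, has_parent)
    if (length(roots) == 0) stop("network is cyclic")
    order <- c(order, roots)
    remaining <- setdiff(remaining, roots)
    edges <- edges[edges$parent %in% remaining & edges$child %in% remaining, ,
                   drop = FALSE]
  }
  order
}

#' Simulate a time-series dataset from a weighted network
#'
#' Generates `k` timepoints from the linear-Gaussian model on the network,
#' `X_i ~ N(sum_parents w_ik X_k, noise_sd^2)`. In `instantaneous` mode
#' (the default) nodes are sampled in topological order within each
#' timepoint, so each timepoint is an independent draw from the
#' structural model — the white-noise Gaussian-process reading under
#' which time-lagged associations carry no signal, matching the observed
#' behaviour of this simulation design. In `lagged` mode the same
#' equations are read as a first-order vector autoregression,
#' `X_i(t) = w_ii X_i(t-1) + sum_parents w_ik X_k(t-1) + e_i(t)`, with
#' the full weight matrix rescaled to spectral radius 0.95 so the
#' process is stationary.
#'
#' @param net a weighted `directed_network` (see [sample_weights()]).
#' @param k number of timepoints (>= 2).
#' @param noise_sd Gaussian noise standard deviation (default 1).
#' @param mode `"instantaneous"` (independent structural draws per
#'   timepoint; requires an acyclic network) or `"lagged"` (VAR(1)).
#' @param seed optional integer seed.
#' @param init optional numeric vector of initial node values for `t = 1`
#'   in lagged mode; defaults to independent `N(0, noise_sd)` draws.
#' @param spectral_radius stationarity target for the rescaled weight
#'   matrix in lagged mode.
#'
#' @return A `phospho_dataset`: list with `values` (nodes x samples
#'   matrix), `sample_info` tibble and the generating network as `truth`.
#' @export
simulate_dataset <- function(net, k, noise_sd = 1,
                             mode = c("instantaneous", "lagged"),
                             seed = NULL, init = NULL,
                             spectral_radius = 0.95) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "directed_network"))
  if (k < 2) stop("need at least 2 timepoints")
  if (any(is.na(net$edges$weight))) stop("weights unset; call sample_weights()")
  if (!is.null(seed)) set.seed(seed)
  p <- length(net$nodes)
  X <- matrix(NA_real_, p, k, dimnames = list(net$nodes, paste0("t", seq_len(k))))
  if (mode == "lagged") {
    W <- stabilize_weights(weight_matrix(net), spectral_radius)
    X[, 1] <- if (is.null(init)) rnorm(p, 0, noise_sd) else init
    for (t in 2:k) X[, t] <- W %*% X[, t - 1] + rnorm(p, 0, noise_sd)
  } else {
    ord <- topological_order(net)
    W <- weight_matrix(net)
    diag(W) <- 0
    for (t in seq_len(k)) {
      x <- stats::setNames(numeric(p), net$nodes)
      for (nd in ord) x[nd] <- sum(W[nd, ] * x) + rnorm(1, 0, noise_sd)
      X[, t] <- x[net$nodes]
    }
  }
  phospho_dataset(X,
                  sample_info = tibble::tibble(sample = colnames(X),
                                               timepoint = seq_len(k)),
                  truth = net, type = "timeseries")
}

#' Phosphoproteomics dataset container
#'
#' @param values variables x samples numeric matrix with dimnames.
#' @param sample_info tibble with one row per sample column.
#' @param truth optional generating `directed_network` or interactome.
#' @param type `"timeseries"` or `"perturbation"`.
#' @return An object of class `phospho_dataset`.
#' @export
phospho_dataset <- function(values, sample_info = NULL, truth = NULL,
                            type = "timeseries") {
  stopifnot(is.matrix(values))
  if (is.null(rownames(values))) stop("values must have rownames")
  if (any(rowSums(!is.na(values)) == 0)) stop("entirely-missing rows present")
  if (is.null(sample_info)) {
    sample_info <- tibble::tibble(sample = colnames(values))
  }
  if (nrow(sample_info) != ncol(values)) {
    stop("sample_info must have one row per sample")
  }
  structure(list(values = values, sample_info = sample_info,
                 truth = truth, type = type),
            class = "phospho_dataset")
}

#' @export
print.phospho_dataset <- function(x, ...) {
  cat("<phospho_dataset> ", nrow(x$values), " variables x ",
      ncol(x$values), " samples (", x$type, ")\n", sep = "")
  invisible(x)
}

#' Keep every `interval`-th timepoint of a time-series dataset
#'
#' Emulates intermittent sampling: timepoints 1, 1+interval, 1+2*interval,
#' ... are retained and sample labels updated.
#'
#' @param ds a `phospho_dataset` of type `"timeseries"`.
#' @param interval positive integer sampling interval (must be smaller than
#'   the series length).
#' @return The subsampled `phospho_dataset`.
#' @export
subsample_timepoints <- function(ds, interval) {
  stopifnot(inherits(ds, "phospho_dataset"))
  interval <- as.integer(interval)
  n <- ncol(ds$values)
  if (interval < 1) stop("interval must be >= 1")
  if (interval >= n) stop("interval must be smaller than the series length")
  keep <- seq(1, n, by = interval)
  ds$values <- ds$values[, keep, drop = FALSE]
  ds$sample_info <- ds$sample_info[keep, , drop = FALSE]
  ds
}

#' Build time-lagged sample pairs
#'
#' Splits an n-sample series into aligned leading (t = 1..n-1) and trailing
#' (t = 2..n) matrices. Associating row i of the leading matrix with row j
#' of the trailing matrix is interpreted as a directed i -> j candidate.
#'
#' @param ds a `phospho_dataset` with at least 2 samples.
#' @return A list with elements `leading` and `trailing` (both variables x
#'   (n-1) matrices) and `zero_variance`, the variable names constant in
#'   either half.
#' @export
make_lagged_pairs <- function(ds) {
  x <- if (inherits(ds, "phospho_dataset")) ds$values else ds
  n <- ncol(x)
  if (n < 2) stop("need at least 2 samples to lag")
  leading <- x[, 1:(n - 1), drop = FALSE]
  trailing <- x[, 2:n, drop = FALSE]
  zv <- rownames(x)[apply(leading, 1, sd) == 0 | apply(trailing, 1, sd) == 0]
  list(leading = leading, trailing = trailing, zero_variance = zv)
}

#' Ground-truth label matrix of a directed network
#'
#' Converts a network's edge set into a `label_matrix` over its nodes: 1
#' for an edge, 0 for a non-edge, NA diagonal. Undirected labels (the
#' default) mark a pair positive when an edge exists in either direction;
#' directed labels keep the orientation for time-lagged evaluation.
#'
#' @param net a `directed_network`.
#' @param directed build directed labels (default `FALSE`).
#' @return A `label_matrix`.
#' @export
truth_labels <- function(net, directed = FALSE) {
  p <- length(net$nodes)
  L <- matrix(0, p, p, dimnames = list(net$nodes, net$nodes))
  L[cbind(net$edges$parent, net$edges$child)] <- 1
  if (!directed) L <- pmax(L, t(L))
  diag(L) <- NA
  label_matrix(L, mode = if (directed) "KS_lagged" else "SS",
               directed = directed)
}

#' Sweep simulation conditions and score network recovery
#'
#' For each grid value (series length, or sampling interval on a length-100
#' series) simulates `n_datasets` replicate datasets with freshly sampled
#' weights, scores every variable pair with each requested measure, and
#' evaluates recovery of the true edges by AUROC.
#'
#' @param net a `directed_network` topology (weights are resampled per
#'   replicate).
#' @param mode `"length"` or `"interval"`.
#' @param values grid values: series lengths, or sampling intervals applied
#'   to a series of length `base_length`.
#' @param n_datasets replicate datasets per grid value (default 200).
#' @param measures character vector of measure names (see
#'   [score_associations()]).
#' @param lagged logical; score time-lagged pairs and evaluate against the
#'   directed edge set instead of 1:1 associations.
#' @param dynamics sampling scheme passed to [simulate_dataset()].
#' @param noise_sd,weight_range simulation parameters.
#' @param base_length series length used for interval sweeps (default 100).
#' @param seed integer seed controlling the whole sweep.
#'
#' @details Replicates use common random numbers across grid values: one
#'   seed per replicate drives the weight draw and the noise stream, so a
#'   length-50 dataset is the first 50 timepoints of its length-100
#'   sibling, and interval sweeps subsample one length-`base_length`
#'   dataset per replicate at every interval. Grid values are therefore
#'   compared on paired data, as in the original intermittent-sampling
#'   design.
#' @return A tibble with columns `mode`, `value`, `replicate`, `measure`,
#'   `auroc`, of class `sweep_result`.
#' @export
run_sweep <- function(net, mode = c("length", "interval"), values,
                      n_datasets = 200, measures = phos_measures(),
                      lagged = FALSE,
                      dynamics = c("instantaneous", "lagged"),
                      noise_sd = 1, weight_range = c(0.5, 2),
                      base_length = 100, seed = 1) {
  mode <- match.arg(mode)
  dynamics <- match.arg(dynamics)
  measures <- match.arg(measures, phos_measures(), several.ok = TRUE)
  set.seed(seed)
  rep_seed <- sample.int(.Machine$integer.max %/% 2L, n_datasets)
  res <- purrr::map(seq_len(n_datasets), function(r) {
    wnet <- sample_weights(net, weight_range = weight_range,
                           seed = rep_seed[r])
    base_ds <- if (mode == "interval") {
      simulate_dataset(wnet, k = base_length, noise_sd = noise_sd,
                       mode = dynamics, seed = rep_seed[r] + 1L)
    } else {
      NULL
    }
    purrr::map_dfr(values, function(v) {
      ds <- if (mode == "length") {
        simulate_dataset(wnet, k = v, noise_sd = noise_sd, mode = dynamics,
                         seed = rep_seed[r] + 1L)
      } else if (v > 1) {
        subsample_timepoints(base_ds, v)
      } else {
        base_ds
      }
      labels <- truth_labels(wnet, directed = lagged)
      lag_pair <- if (lagged) make_lagged_pairs(ds) else NULL
      purrr::map_dfr(measures, function(m) {
        a <- score_associations(ds$values, measure = m, lagged = lag_pair)
        tibble::tibble(value = v, replicate = r, measure = m,
                       auroc = auroc_matrix(a, labels))
      })
    })
  })
  out <- dplyr::mutate(dplyr::bind_rows(res), mode = mode, .before = 1)
  class(out) <- c("sweep_result", class(out))
  out
}

# AUROC of an association matrix against a label matrix, NA-safe; returns
# NA when a class is empty.
auroc_matrix <- function(assoc, labels) {
  el <- edge_list(assoc, labels)
  el <- el[!is.na(el$score), , drop = FALSE]
  if (length(unique(el$label)) < 2) return(NA_real_)
  auroc_vec(abs(el$score), el$label)
}
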