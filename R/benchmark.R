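#' Run the full association-measure benchmark
#'
#' Orchestrates datasets x measures x association modes (direct 1:1 and
#' time-lagged) x similarity filters x gold-standard variants, evaluating
#' every combination with [compute_metrics()] and recording datasets that
#' fail the true-positive gate in a skip log. Time-lagged associations
#' are only formed for time-series datasets; the sequence-similarity
#' filter and the filter-only predictor apply to the substrate-substrate
#' network (S/T sites), where the similarity shift that justifies them
#' exists.
#'
#' @param config a list with elements:
#'   * `datasets`: named list; each element a `phospho_dataset` (rows
#'     named by site identifiers);
#'   * `sites`: tibble of measured site metadata (`accession`, `residue`,
#'     `position`) covering every dataset row;
#'   * `interactome`: record tibble (see [read_interactome()]);
#'   * `kinase_classes`: tibble (`kinase`, `class`);
#'   * `windows`: named window vector (needed for similarity filters);
#'   * `measures` (default all six), `modes` (`"direct"`, `"lagged"`),
#'     `networks` (`"KS"`, `"SS"`), `filters` (`"none"`,
#'     `"similarity"`, `"filter_only"`), `gold` (`"database"`,
#'     `"database_ml"`), `ml_tables`, `min_tp` (default 5),
#'     `threshold_n_sample` (default 100000),
#'     `threshold_exclude_dataset` (default `TRUE`: the dataset's own
#'     phosphosites are removed from the interactome pool before the
#'     similarity threshold is sampled; set `FALSE` when the reference
#'     interactome covers only the measured sites), `n_perm` (default 0 =
#'     no permutation test), `seed`.
#' @return A tibble with one row per evaluated combination (EvalResult
#'   columns plus `dataset`, `mode`, `network`, `filter`, `gold`), with
#'   the skip log in `attr(, "skipped")` and the run manifest (seeds,
#'   thresholds, versions) in `attr(, "manifest")`.
#' @export
run_benchmark <- function(config) {
  cfg <- config
  measures <- cfg$measures %||% phos_measures()
  modes <- cfg$modes %||% c("direct", "lagged")
  networks <- cfg$networks %||% c("KS", "SS")
  filters <- cfg$filters %||% c("none", "similarity", "filter_only")
  gold <- cfg$gold %||% "database"
  min_tp <- cfg$min_tp %||% 5
  n_perm <- cfg$n_perm %||% 0
  seed <- cfg$seed %||% 1
  bad <- setdiff(measures, phos_measures())
  if (length(bad) > 0) stop("unknown measure(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(modes, c("direct", "lagged"))
  if (length(bad) > 0) stop("unknown mode(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(filters, c("none", "similarity", "filter_only"))
  if (length(bad) > 0) stop("unknown filter(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(gold, c("database", "database_ml"))
  if (length(bad) > 0) stop("unknown gold variant(s): ",
                            paste(bad, collapse = ", "))
  if (is.null(cfg$datasets) || is.null(names(cfg$datasets))) {
    stop("config$datasets must be a named list")
  }

  records_by_gold <- list(database = cfg$interactome)
  if ("database_ml" %in% gold) {
    records_by_gold$database_ml <-
      augment_with_ml(cfg$interactome, cfg$ml_tables %||% stop(
        "gold 'database_ml' requires config$ml_tables"))
  }

  set.seed(seed)
  results <- list()
  skipped <- list()
  thresholds <- list()

  for (ds_name in names(cfg$datasets)) {
    ds <- cfg$datasets[[ds_name]]
    x <- ds$values
    ds_sites <- cfg$sites[cfg$sites$site %in% rownames(x), , drop = FALSE]
    ds_modes <- if (ds$type == "timeseries") modes else "direct"
    need_thr <- any(filters != "none") && "SS" %in% networks
    thr <- NULL
    if (need_thr) {
      excl <- if (isFALSE(cfg$threshold_exclude_dataset)) {
        character(0)
      } else {
        ds_sites$site
      }
      thr <- compute_threshold(cfg$interactome, cfg$windows, excl,
                               n_sample = cfg$threshold_n_sample %||% 100000,
                               seed = seed)
      thresholds[[ds_name]] <- thr$threshold
    }
    lag_pair <- if ("lagged" %in% ds_modes) make_lagged_pairs(ds) else NULL

    for (g in gold) {
      recs <- records_by_gold[[g]]
      labels_by <- list()
      if ("KS" %in% networks) {
        labels_by$KS <- tryCatch(
          build_ks_labels(recs, ds_sites, cfg$kinase_classes),
          error = function(e) NULL)
      }
      if ("SS" %in% networks) {
        labels_by$SS <- tryCatch(build_ss_labels(recs, ds_sites),
                                 error = function(e) NULL)
      }
      for (net in networks) {
        labels <- labels_by[[net]]
        if (is.null(labels) || !tp_gate(labels, min_tp)) {
          n_tp <- if (is.null(labels)) 0 else sum(labels == 1, na.rm = TRUE)
          skipped[[length(skipped) + 1]] <- tibble::tibble(
            dataset = ds_name, network = net, gold = g, n_tp = n_tp,
            reason = paste0("fewer than ", min_tp, " true positives"))
          next
        }
        net_filters <- if (net == "SS") filters else "none"
        for (mode in ds_modes) {
          lp <- if (mode == "lagged") lag_pair else NULL
          for (m in measures) {
            a0 <- score_associations(x, measure = m, lagged = lp)
            for (filt in setdiff(net_filters, "filter_only")) {
              a <- a0
              if (filt == "similarity") {
                a <- apply_similarity_filter(a, cfg$windows, thr)
              }
              results[[length(results) + 1]] <- dplyr::bind_cols(
                tibble::tibble(dataset = ds_name, network = net, mode = mode,
                               filter = filt, gold = g),
                eval_one(a, labels, n_perm))
            }
          }
          if ("filter_only" %in% net_filters && mode == "direct") {
            a <- filter_only_predictor(cfg$windows, thr,
                                       sites = rownames(labels))
            results[[length(results) + 1]] <- dplyr::bind_cols(
              tibble::tibble(dataset = ds_name, network = net, mode = mode,
                             filter = "filter_only", gold = g),
              eval_one(a, labels, n_perm))
          }
        }
      }
    }
  }

  out <- dplyr::bind_rows(results)
  attr(out, "skipped") <- dplyr::bind_rows(skipped)
  attr(out, "manifest") <- list(
    seed = seed, measures = measures, modes = modes, networks = networks,
    filters = filters, gold = gold, min_tp = min_tp, n_perm = n_perm,
    thresholds = thresholds,
    package_version = as.character(utils::packageVersion("phosbench")),
    r_version = R.version.string)
  class(out) <- c("benchmark_result", class(out))
  out
}

eval_one <- function(assoc, labels, n_perm) {
  met <- compute_metrics(assoc, labels)
  if (n_perm > 0) {
    met$permutation_p <- permutation_pvalue(assoc, labels,
                                            n_perm = n_perm)$p_value
  }
  met
}

#' Write benchmark outputs to a directory
#'
#' Emits `results.tsv`, `skipped.tsv` and `manifest.json` (seeds,
#' thresholds, versions) for a [run_benchmark()] result.
#'
#' @param results a `benchmark_result`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(tibble::as_tibble(results), file.path(dir, "results.tsv"))
  skipped <- attr(results, "skipped")
  if (!is.null(skipped) && nrow(skipped) > 0) {
    readr::write_tsv(skipped, file.path(dir, "skipped.tsv"))
  }
  jsonlite::write_json(attr(results, "manifest"),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
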