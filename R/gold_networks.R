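#' Read a phosphosite-resolved kinase-substrate interactome table
#'
#' Reads the common export dialect of phosphosite interaction databases: a
#' TSV with columns `kinase` (accession), `substrate` (accession),
#' `residue` (S/T/Y) and `position` (1-based). Rows with malformed
#' residues or positions are rejected individually (the rejected count is
#' attached as the `n_rejected` attribute and reported via a message);
#' duplicates are collapsed. Isoform suffixes (`-1`, `-2`, ...) are
#' stripped from accessions so sites are keyed by the canonical protein.
#'
#' @param path TSV file path.
#' @return Tibble of kinase-substrate records: `kinase`, `substrate`,
#'   `residue`, `position`, `source = "database"`, `probability = NA`,
#'   plus the derived `site` identifier of the substrate phosphosite.
#' @export
read_interactome <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    kinase = readr::col_character(), substrate = readr::col_character(),
    residue = readr::col_character(), position = readr::col_double()))
  as_ks_records(raw)
}

# Validate/normalize a raw interactome table into the record dialect.
as_ks_records <- function(raw, source = "database", probability = NULL) {
  raw$residue <- toupper(raw$residue)
  ok <- raw$residue %in% c("S", "T", "Y") &
    !is.na(raw$position) & raw$position >= 1 &
    raw$position == round(raw$position) &
    !is.na(raw$kinase) & !is.na(raw$substrate)
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    message(n_rejected, " malformed interactome row(s) rejected")
  }
  rec <- tibble::as_tibble(raw[ok, , drop = FALSE])
  rec$kinase <- strip_isoform(rec$kinase)
  rec$substrate <- strip_isoform(rec$substrate)
  rec$position <- as.integer(rec$position)
  rec$source <- if ("source" %in% names(raw)) rec$source else source
  rec$probability <- if (!is.null(probability)) {
    probability[ok]
  } else if ("probability" %in% names(rec)) {
    rec$probability
  } else {
    NA_real_
  }
  rec$site <- site_id(rec$substrate, rec$residue, rec$position)
  rec <- dplyr::distinct(rec, .data$kinase, .data$site, .keep_all = TRUE)
  attr(rec, "n_rejected") <- n_rejected
  rec
}

#' Augment database records with machine-learning predictions
#'
#' Predicted kinase-substrate interactions with probability strictly above
#' `cutoff` are unioned with the database records; where a prediction
#' duplicates a database record, the database record wins.
#'
#' @param records database records (see [read_interactome()]).
#' @param ml_tables a data frame (or list of data frames) with columns
#'   `kinase`, `substrate`, `residue`, `position`, `probability` in
#'   \[0, 1\].
#' @param cutoff probability cutoff, strict inequality (default 0.5).
#' @return Combined record tibble with `source` marking provenance.
#' @export
augment_with_ml <- function(records, ml_tables, cutoff = 0.5) {
  if (is.data.frame(ml_tables)) ml_tables <- list(ml_tables)
  ml <- dplyr::bind_rows(ml_tables)
  if (!"probability" %in% names(ml)) stop("ml tables need a probability column")
  bad_p <- is.na(ml$probability) | ml$probability < 0 | ml$probability > 1
  if (any(bad_p)) {
    message(sum(bad_p), " prediction row(s) with invalid probability rejected")
    ml <- ml[!bad_p, , drop = FALSE]
  }
  ml <- ml[ml$probability > cutoff, , drop = FALSE]
  ml_rec <- as_ks_records(ml[setdiff(names(ml), "source")],
                          source = "ml_prediction",
                          probability = NULL)
  ml_rec$source <- "ml_prediction"
  out <- dplyr::bind_rows(records, ml_rec)
  out <- dplyr::arrange(out, factor(.data$source,
                                    levels = c("database", "ml_prediction")))
  dplyr::distinct(out, .data$kinase, .data$site, .keep_all = TRUE)
}

#' Build the kinase-substrate gold label matrix
#'
#' Rows are the measured phosphosites lying on annotated kinases; columns
#' are all measured phosphosites. A row-column entry is 1 when a record
#' links the row's kinase protein to the column site, 0 when the column
#' site's residue matches the kinase's specificity class (S/T kinases vs
#' S/T sites, Y kinases vs Y sites) but no record exists, and NA
#' otherwise: class-mismatched pairs, self pairs, and rows for kinases
#' lacking a class annotation (flagged with a warning) stay outside the
#' evaluable space. Non-kinase proteins contribute no rows at all, so
#' non-kinase pairs are never evaluated.
#'
#' @param records kinase-substrate records.
#' @param dataset_sites tibble of measured sites: `accession`, `residue`,
#'   `position`.
#' @param kinase_classes tibble mapping `kinase` accession to `class`
#'   (`"ST"` or `"Y"`); dual-specificity kinases appear once per class.
#' @param mode stored on the result (`"KS_direct"` or `"KS_lagged"`).
#' @return A directed `label_matrix` (kinase sites x all sites).
#' @export
build_ks_labels <- function(records, dataset_sites, kinase_classes,
                            mode = "KS_direct") {
  ds <- normalize_sites(dataset_sites)
  kin_acc <- unique(c(records$kinase, kinase_classes$kinase))
  rows <- ds[ds$accession %in% kin_acc, , drop = FALSE]
  if (nrow(rows) == 0) stop("no measured phosphosite lies on a kinase")
  class_of <- split(kinase_classes$class, kinase_classes$kinase)
  pos_key <- paste(records$kinase, records$site)
  L <- matrix(NA_real_, nrow(rows), nrow(ds),
              dimnames = list(rows$site, ds$site))
  col_class <- residue_class(ds$residue)
  unclassed <- character(0)
  for (i in seq_len(nrow(rows))) {
    kin <- rows$accession[i]
    kcls <- class_of[[kin]]
    if (is.null(kcls)) {
      unclassed <- c(unclassed, kin)
      next
    }
    match_cls <- col_class %in% kcls
    lab <- rep(NA_real_, nrow(ds))
    lab[match_cls] <- as.numeric(paste(kin, ds$site[match_cls]) %in% pos_key)
    lab[ds$site == rows$site[i]] <- NA  # self pair
    L[i, ] <- lab
  }
  if (length(unique(unclassed)) > 0) {
    warning("kinase(s) without class annotation set to NA rows: ",
            paste(unique(unclassed), collapse = ", "))
  }
  label_matrix(L, mode = mode, residue_class = NA, directed = TRUE)
}

normalize_sites <- function(dataset_sites) {
  ds <- tibble::as_tibble(dataset_sites)
  stopifnot(all(c("accession", "residue", "position") %in% names(ds)))
  ds$accession <- strip_isoform(ds$accession)
  ds$residue <- toupper(ds$residue)
  ds$site <- site_id(ds$accession, ds$residue, ds$position)
  dplyr::distinct(ds, .data$site, .keep_all = TRUE)
}

#' Build the substrate-substrate gold label matrix
#'
#' Symmetric labels over measured substrate phosphosites of one residue
#' class (S/T by default): a pair is 1 when any kinase is recorded to
#' regulate both sites and 0 otherwise; the diagonal is NA.
#'
#' @inheritParams build_ks_labels
#' @param residue_class `"ST"` (default) or `"Y"`.
#' @return A symmetric `label_matrix` of mode `"SS"`.
#' @export
build_ss_labels <- function(records, dataset_sites, residue_class = "ST") {
  ds <- normalize_sites(dataset_sites)
  ds <- ds[residue_class(ds$residue) %in% residue_class, , drop = FALSE]
  if (nrow(ds) < 2) stop("fewer than 2 sites in the requested residue class")
  n <- nrow(ds)
  L <- matrix(0, n, n, dimnames = list(ds$site, ds$site))
  rec <- records[records$site %in% ds$site, , drop = FALSE]
  for (sites in split(rec$site, rec$kinase)) {
    sites <- unique(sites)
    if (length(sites) >= 2) {
      L[sites, sites] <- 1
    }
  }
  diag(L) <- NA
  label_matrix(L, mode = "SS", residue_class = residue_class,
               directed = FALSE)
}
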