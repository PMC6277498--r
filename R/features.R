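# The 22-feature mutational-load panel. Nine "type" features summarize
# Variant_Type and repeat overlap (the MSIseq panel); thirteen
# "classification" features count Variant_Classification categories, i.e.
# the translational/regulatory effect of each mutation. All count features
# are normalized by the captured exome length in Mb; the three RATIO_*
# features are dimensionless.

.type_feature_names <- c("SNP", "INDEL", "TOTAL", "SNP_R", "INDEL_R",
                         "TOTAL_R", "RATIO_SNP", "RATIO_INDEL", "RATIO_TOTAL")

.default_classification_features <- c(
  "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
  "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation", "Silent",
  "Splice_Site", "Translation_Start_Site", "3'UTR", "5'UTR", "5'Flank"
)

#' Define the mutational-load feature panel
#'
#' The default panel has 22 features: the nine Variant_Type-based features
#' `SNP`, `INDEL`, `TOTAL`, `SNP_R`, `INDEL_R`, `TOTAL_R`, `RATIO_SNP`,
#' `RATIO_INDEL`, `RATIO_TOTAL` (`*_R` restricts to mutations inside
#' simple-sequence repeats; `RATIO_*` are in-repeat over overall counts,
#' defined as 0 when the denominator is 0) plus thirteen per-Mb counts of
#' Variant_Classification categories. The classification list is
#' configurable; trained models record the panel version they assume so a
#' mismatch is detected at load time.
#'
#' @param classification character vector of Variant_Classification
#'   categories to count (default: the 13-category panel above).
#' @param version short version tag recorded in feature tables and models.
#' @return a `feature_spec` object.
#' @export
feature_spec <- function(classification = .default_classification_features,
                         version = "1") {
  classification <- as.character(classification)
  nm <- c(.type_feature_names, classification)
  if (anyDuplicated(nm)) stop_config("feature names must be distinct")
  structure(list(type = .type_feature_names,
                 classification = classification,
                 version = version),
            class = "feature_spec")
}

#' Feature names of a panel, in column order
#' @param spec a `feature_spec`.
#' @return character vector (type features first, then classification).
#' @export
feature_names <- function(spec = feature_spec()) c(spec$type, spec$classification)

new_feature_matrix <- function(df, capture_mb, spec_version,
                               msi_status = NULL) {
  structure(df,
            capture_mb = capture_mb,
            spec_version = spec_version,
            msi_status = msi_status,
            class = c("feature_matrix", "data.frame"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  lab <- attr(x, "msi_status")
  cat(sprintf("Feature matrix: %d tumor(s) x %d feature(s)%s\n",
              nrow(x), ncol(x),
              if (!is.null(lab)) sprintf(", labelled (%d MSI-H / %d MSS)",
                                         sum(lab == "MSI-H"), sum(lab == "MSS"))
              else ""))
  if (nrow(x) > 0L) print(utils::head(as.data.frame(x)[, seq_len(min(6L, ncol(x))), drop = FALSE], 5L))
  invisible(x)
}

#' MSI status labels attached to a feature matrix
#' @param x a `feature_matrix`.
#' @return named character vector (`MSS`/`MSI-H`) keyed by tumor id, or
#'   `NULL` if the matrix is unlabelled.
#' @export
msi_status <- function(x) attr(x, "msi_status")

# Normalize clinical MSI categories to the binary task: MSI-L tumors carry
# an MSI burden indistinguishable from MSS, so MSS and MSI-L collapse to
# the negative class.
normalize_msi_labels <- function(x) {
  x <- trimws(as.character(x))
  x[x == "MSI-L"] <- "MSS"
  bad <- !(x %in% c("MSS", "MSI-H"))
  if (any(bad)) {
    stop_data(sprintf("unrecognized MSI status value(s): %s",
                      paste(unique(x[bad]), collapse = ", ")))
  }
  x
}

#' Extract the per-Mb mutational-load feature matrix
#'
#' Computes, for every distinct tumor in a repeat-tagged cohort, each
#' feature of the panel as (number of qualifying mutation records) divided
#' by the tumor's captured exome length in Mb. `SNP` counts
#' `Variant_Type == "SNP"`, `INDEL` counts `INS` or `DEL`, `TOTAL` counts
#' every record (so DNP/TNP/ONP contribute to `TOTAL` only); the `*_R`
#' variants restrict to `In_repeats == 1`; `RATIO_*` are count ratios
#' (in-repeat over overall, 0 when the overall count is 0); each
#' classification feature counts records with that
#' `Variant_Classification`.
#'
#' @param cohort a tagged `maf_cohort` (see [tag_in_repeats()]).
#' @param capture_mb captured exome length in Mb: a single number applied
#'   to every tumor, or a named vector keyed by tumor barcode.
#' @param spec a `feature_spec` (default: the 22-feature panel).
#' @return a `feature_matrix`: data frame with one row per tumor (row
#'   names are tumor barcodes) and one column per feature, plus
#'   `capture_mb` and `spec_version` attributes.
#' @export
extract_features <- function(cohort, capture_mb, spec = feature_spec()) {
  if (!is_tagged(cohort)) {
    stop_state("cohort has untagged records: run tag_in_repeats() first")
  }
  ids <- tumor_ids(cohort)
  if (is.null(names(capture_mb))) {
    if (length(capture_mb) != 1L) {
      stop_config("capture_mb must be a single value or a named vector keyed by tumor barcode")
    }
    capture <- stats::setNames(rep(as.numeric(capture_mb), length(ids)), ids)
  } else {
    missing <- setdiff(ids, names(capture_mb))
    if (length(missing) > 0L) {
      stop_config(sprintf("no capture size (Mb) for tumor(s): %s",
                          paste(missing, collapse = ", ")))
    }
    capture <- as.numeric(capture_mb[ids])
    names(capture) <- ids
  }
  if (any(!is.finite(capture)) || any(capture <= 0)) {
    stop_config("capture sizes must be positive and finite")
  }

  f <- factor(cohort[["Tumor_Sample_Barcode"]], levels = ids)
  vt <- cohort[["Variant_Type"]]
  vc <- cohort[["Variant_Classification"]]
  inr <- cohort[["In_repeats"]] == 1L

  count_by_tumor <- function(keep) {
    as.numeric(tabulate(f[keep], nbins = length(ids)))
  }
  is_snp <- vt == "SNP"
  is_indel <- vt %in% c("INS", "DEL")
  n_snp <- count_by_tumor(is_snp)
  n_indel <- count_by_tumor(is_indel)
  n_total <- count_by_tumor(rep(TRUE, nrow(cohort)))
  n_snp_r <- count_by_tumor(is_snp & inr)
  n_indel_r <- count_by_tumor(is_indel & inr)
  n_total_r <- count_by_tumor(inr)
  ratio <- function(num, den) ifelse(den > 0, num / den, 0)

  out <- data.frame(
    SNP = n_snp / capture,
    INDEL = n_indel / capture,
    TOTAL = n_total / capture,
    SNP_R = n_snp_r / capture,
    INDEL_R = n_indel_r / capture,
    TOTAL_R = n_total_r / capture,
    RATIO_SNP = ratio(n_snp_r, n_snp),
    RATIO_INDEL = ratio(n_indel_r, n_indel),
    RATIO_TOTAL = ratio(n_total_r, n_total),
    row.names = ids,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  for (cls in spec$classification) {
    out[[cls]] <- count_by_tumor(vc == cls) / capture
  }
  new_feature_matrix(out, capture_mb = capture, spec_version = spec$version)
}

#' Select a subset of feature columns
#'
#' Used e.g. to restrict the 22-feature panel to the nine Variant_Type
#' features when fitting the reduced-panel classifier variant.
#'
#' @param x a `feature_matrix`.
#' @param names feature names to keep, in the requested order.
#' @return a `feature_matrix` with those columns; rows, labels and capture
#'   metadata preserved.
#' @export
select_feature_subset <- function(x, names) {
  missing <- setdiff(names, colnames(x))
  if (length(missing) > 0L) {
    stop_key(sprintf("unknown feature name(s): %s",
                     paste(missing, collapse = ", ")))
  }
  out <- as.data.frame(x)[, names, drop = FALSE]
  new_feature_matrix(out,
                     capture_mb = attr(x, "capture_mb"),
                     spec_version = attr(x, "spec_version"),
                     msi_status = attr(x, "msi_status"))
}

#' Mutation profile of mismatch-repair genes
#'
#' Tallies, per tumor, mutations (of any classification) in the core
#' mismatch-repair genes. Loss of these genes causes microsatellite
#' instability, so the profile is the standard follow-up when predicted
#' and assay-determined MSI status disagree.
#'
#' @param cohort a `maf_cohort` whose records carry `Hugo_Symbol`.
#' @param genes gene symbols to profile (default the five MMR genes
#'   `MLH1`, `MSH2`, `MSH3`, `MSH6`, `PMS2`).
#' @return list with two data frames keyed by tumor barcode: `counts`
#'   (mutation counts per gene) and `presence` (0/1 per gene).
#' @export
mmr_gene_profile <- function(cohort,
                             genes = c("MLH1", "MSH2", "MSH3", "MSH6", "PMS2")) {
  if (!"Hugo_Symbol" %in% names(cohort)) {
    stop_schema("cohort has no Hugo_Symbol column; gene profiling needs gene symbols")
  }
  ids <- tumor_ids(cohort)
  f <- factor(cohort[["Tumor_Sample_Barcode"]], levels = ids)
  counts <- matrix(0L, nrow = length(ids), ncol = length(genes),
                   dimnames = list(ids, genes))
  for (j in seq_along(genes)) {
    counts[, j] <- tabulate(f[cohort[["Hugo_Symbol"]] == genes[j]],
                            nbins = length(ids))
  }
  counts <- as.data.frame(counts, check.names = FALSE)
  presence <- as.data.frame((counts > 0) * 1L, check.names = FALSE)
  list(counts = counts, presence = presence)
}

#' Write a feature matrix as CSV
#'
#' Layout: `Tumor_ID`, one column per feature, and (when the matrix is
#' labelled) a final `MSI_status` column.
#'
#' @param x a `feature_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(x, path) {
  out <- data.frame(Tumor_ID = rownames(x), as.data.frame(x),
                    check.names = FALSE, stringsAsFactors = FALSE)
  lab <- attr(x, "msi_status")
  if (!is.null(lab)) out[["MSI_status"]] <- unname(lab[rownames(x)])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' Reads tables in the layout written by [write_feature_csv()], or any
#' compatible CSV via the `id_col`/`label_col` mapping. MSI status strings
#' are normalized to the binary task (`MSI-L` becomes `MSS`). If `spec` is
#' supplied, the file must contain every feature of the panel.
#'
#' @param path CSV path.
#' @param spec optional `feature_spec`; when given, the panel's columns
#'   are required (schema error otherwise) and selected in panel order.
#' @param id_col name of the tumor-identifier column.
#' @param label_col name of the MSI status column (ignored if absent).
#' @return a `feature_matrix`, labelled when the file has labels.
#' @export
read_feature_csv <- function(path, spec = NULL, id_col = "Tumor_ID",
                             label_col = "MSI_status") {
  if (!file.exists(path)) stop_data(sprintf("feature CSV not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!id_col %in% names(df)) {
    stop_schema(sprintf("feature CSV is missing identifier column '%s'", id_col))
  }
  ids <- as.character(df[[id_col]])
  lab <- NULL
  if (label_col %in% names(df)) {
    lab <- stats::setNames(normalize_msi_labels(df[[label_col]]), ids)
  }
  feats <- setdiff(names(df), c(id_col, label_col))
  if (!is.null(spec)) {
    want <- feature_names(spec)
    missing <- setdiff(want, feats)
    if (length(missing) > 0L) {
      stop_schema(sprintf("feature CSV is missing feature column(s): %s",
                          paste(missing, collapse = ", ")))
    }
    feats <- want
  }
  out <- df[, feats, drop = FALSE]
  for (cl in feats) out[[cl]] <- as.numeric(out[[cl]])
  rownames(out) <- ids
  new_feature_matrix(out,
                     capture_mb = NULL,
                     spec_version = if (!is.null(spec)) spec$version else NULL,
                     msi_status = lab)
}

#' Attach MSI status labels to a feature matrix
#' @param x a `feature_matrix`.
#' @param labels character vector of statuses (`MSS`, `MSI-L`, `MSI-H`),
#'   either named by tumor barcode or in row order; `MSI-L` is merged into
#'   `MSS`.
#' @return the labelled `feature_matrix`.
#' @export
set_msi_status <- function(x, labels) {
  if (is.null(names(labels))) {
    if (length(labels) != nrow(x)) stop_data("labels length must match rows")
    labels <- stats::setNames(as.character(labels), rownames(x))
  } else {
    missing <- setdiff(rownames(x), names(labels))
    if (length(missing) > 0L) {
      stop_key(sprintf("no MSI status for tumor(s): %s",
                       paste(utils::head(missing, 5L), collapse = ", ")))
    }
    labels <- labels[rownames(x)]
  }
  attr(x, "msi_status") <- stats::setNames(normalize_msi_labels(labels),
                                           rownames(x))
  x
}
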