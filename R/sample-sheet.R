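#' Validate a sample sheet
#'
#' Checks the per-sample metadata table against the pipeline's contract:
#' unique `sample_id`; `group` in \{case, control\}; `gc_subgroup` in
#' \{hypersensitive, typical, unknown\} with the informative labels allowed
#' only for cases; positive `age` and `bmi`; a `batch` label; non-negative
#' `cell_*` proportion columns summing to at most 1 per sample; the eight
#' RAND-36 scores (when present) in \[0, 100\]; `onset` in
#' \{sudden, gradual, not_applicable\}. Missing optional columns
#' (`gc_subgroup`, `onset`) are filled with their neutral level. Unknown
#' columns are preserved untouched.
#'
#' @param df A data frame of per-sample metadata.
#' @return A validated tibble.
#' @export
validate_sample_sheet <- function(df) {
  stop_if_missing_cols(df, c("sample_id", "group", "age", "bmi", "batch"),
                       "sample sheet")
  df <- as_tibble(df)
  if (anyDuplicated(df$sample_id)) {
    abort("duplicate sample_id in sample sheet", class = "gcm_validation_error")
  }
  bad_group <- setdiff(unique(df$group), c("case", "control"))
  if (length(bad_group) > 0) {
    abort(sprintf(
      "invalid group value(s) %s; allowed: case, control",
      paste(sQuote(bad_group), collapse = ", ")),
      class = "gcm_schema_error")
  }
  if (!"gc_subgroup" %in% names(df) || all(is.na(df$gc_subgroup))) {
    df$gc_subgroup <- "unknown"
  }
  df$gc_subgroup[is.na(df$gc_subgroup)] <- "unknown"
  bad_sub <- setdiff(unique(df$gc_subgroup),
                     c("hypersensitive", "typical", "unknown"))
  if (length(bad_sub) > 0) {
    abort(sprintf(
      "invalid gc_subgroup value(s) %s; allowed: hypersensitive, typical, unknown",
      paste(sQuote(bad_sub), collapse = ", ")),
      class = "gcm_schema_error")
  }
  if (any(df$group == "control" & df$gc_subgroup != "unknown")) {
    abort("gc_subgroup labels are only valid for cases; controls are their own stratum",
          class = "gcm_validation_error")
  }
  if (!"onset" %in% names(df) || all(is.na(df$onset))) {
    df$onset <- "not_applicable"
  }
  df$onset[is.na(df$onset)] <- "not_applicable"
  bad_onset <- setdiff(unique(df$onset), c("sudden", "gradual", "not_applicable"))
  if (length(bad_onset) > 0) {
    abort(sprintf("invalid onset value(s) %s; allowed: sudden, gradual, not_applicable",
                  paste(sQuote(bad_onset), collapse = ", ")),
          class = "gcm_schema_error")
  }
  if (any(!is.na(df$age) & df$age <= 0) || any(!is.na(df$bmi) & df$bmi <= 0)) {
    abort("age and bmi must be positive", class = "gcm_validation_error")
  }
  cells <- cell_proportion_cols(df)
  if (length(cells) > 0) {
    cm <- as.matrix(df[cells])
    if (any(cm < 0, na.rm = TRUE)) {
      abort("cell proportions must be non-negative",
            class = "gcm_validation_error")
    }
    if (any(rowSums(cm, na.rm = TRUE) > 1 + 1e-8)) {
      abort("cell proportions must sum to at most 1 per sample",
            class = "gcm_validation_error")
    }
  }
  r36 <- intersect(rand36_cols(), names(df))
  for (col in r36) {
    v <- df[[col]]
    if (any(!is.na(v) & (v < 0 | v > 100))) {
      abort(sprintf("%s outside [0, 100]", col), class = "gcm_validation_error")
    }
  }
  df
}

#' Read a sample sheet from TSV
#'
#' @param path Path to a tab-separated sample sheet with a header row.
#' @return A validated tibble (see [validate_sample_sheet()]).
#' @export
read_sample_sheet <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_sample_sheet(df)
}

#' Validate a probe annotation table
#'
#' Checks `probe_id` uniqueness, membership of `genic_region` and
#' `island_relation` in their closed vocabularies (see
#' [annotation_vocab()]), and a logical `snp_flag`. `gene_symbols` holds
#' zero or more symbols per probe, semicolon-separated; empty string or
#' `NA` means no annotated gene.
#'
#' @param df A data frame of per-probe annotation.
#' @return A validated tibble.
#' @export
validate_probe_annotation <- function(df) {
  stop_if_missing_cols(df, c("probe_id", "gene_symbols", "genic_region",
                             "island_relation", "snp_flag"),
                       "probe annotation")
  df <- as_tibble(df)
  if (anyDuplicated(df$probe_id)) {
    abort("duplicate probe_id in annotation", class = "gcm_validation_error")
  }
  vocab <- annotation_vocab()
  bad_gr <- setdiff(unique(df$genic_region), vocab$genic_region)
  if (length(bad_gr) > 0) {
    abort(sprintf("invalid genic_region value(s): %s",
                  paste(sQuote(bad_gr), collapse = ", ")),
          class = "gcm_schema_error")
  }
  bad_ir <- setdiff(unique(df$island_relation), vocab$island_relation)
  if (length(bad_ir) > 0) {
    abort(sprintf("invalid island_relation value(s): %s",
                  paste(sQuote(bad_ir), collapse = ", ")),
          class = "gcm_schema_error")
  }
  if (!is.logical(df$snp_flag)) {
    val <- df$snp_flag
    if (all(val %in% c(0, 1, "0", "1", "TRUE", "FALSE", "true", "false"))) {
      df$snp_flag <- as.logical(as.numeric(val %in% c(1, "1", "TRUE", "true")))
    } else {
      abort("snp_flag must be logical", class = "gcm_schema_error")
    }
  }
  df$gene_symbols[is.na(df$gene_symbols)] <- ""
  df
}

#' Read a probe annotation table from TSV
#'
#' @param path Path to a tab-separated annotation table with a header row.
#' @return A validated tibble (see [validate_probe_annotation()]).
#' @export
read_probe_annotation <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_probe_annotation(df)
}
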