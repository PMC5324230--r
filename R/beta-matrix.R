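#' Construct a beta-value matrix container
#'
#' A `beta_matrix` holds the central probe-by-sample array of methylation
#' beta-values (the ratio of methylated probe fluorescence intensity over
#' total intensity, in \[0, 1\]), optionally paired with a same-shaped
#' matrix of per-probe per-sample detection p-values. Probes are rows,
#' samples are columns; both axes must carry unique names. `NA` beta-values
#' are tolerated in the container (probes carrying any `NA` are dropped at
#' preprocessing by [filter_probes()]), all non-missing values must lie in
#' \[0, 1\].
#'
#' @param values Numeric matrix of beta-values with unique rownames
#'   (probe ids) and colnames (sample ids).
#' @param detection Optional numeric matrix of detection p-values with
#'   identical dimensions and dimnames.
#' @return An object of class `gcm_beta` with elements `values` and
#'   `detection` (possibly `NULL`).
#' @examples
#' m <- matrix(runif(6), 3, 2,
#'             dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' b <- beta_matrix(m)
#' dim(b)
#' @export
beta_matrix <- function(values, detection = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix", class = "gcm_validation_error")
  }
  pid <- rownames(values)
  sid <- colnames(values)
  if (is.null(pid) && nrow(values) == 0) pid <- character(0)
  if (is.null(sid) && ncol(values) == 0) sid <- character(0)
  if (is.null(pid) || is.null(sid)) {
    abort("`values` must have rownames (probes) and colnames (samples)",
          class = "gcm_validation_error")
  }
  if (anyDuplicated(pid)) {
    abort("duplicate probe ids in beta matrix", class = "gcm_validation_error")
  }
  if (anyDuplicated(sid)) {
    abort("duplicate sample ids in beta matrix", class = "gcm_validation_error")
  }
  bad <- which(!is.na(values) & (values < 0 | values > 1 | !is.finite(values)))
  if (length(bad) > 0) {
    i <- arrayInd(bad[1], dim(values))
    abort(sprintf(
      "beta-value out of [0, 1] at probe '%s', sample '%s' (value %s)",
      pid[i[1]], sid[i[2]], format(values[bad[1]])),
      class = "gcm_validation_error")
  }
  if (!is.null(detection)) {
    if (!is.matrix(detection) || !identical(dim(detection), dim(values))) {
      abort("detection matrix must have the same shape as the beta matrix",
            class = "gcm_alignment_error")
    }
    dpid <- rownames(detection) %||% if (nrow(detection) == 0) character(0)
    dsid <- colnames(detection) %||% if (ncol(detection) == 0) character(0)
    if (!identical(dpid, pid) || !identical(dsid, sid)) {
      abort("detection matrix axis labels do not match the beta matrix",
            class = "gcm_alignment_error")
    }
    badd <- which(!is.na(detection) &
                    (detection < 0 | detection > 1 | !is.finite(detection)))
    if (length(badd) > 0) {
      i <- arrayInd(badd[1], dim(detection))
      abort(sprintf(
        "detection p-value out of [0, 1] at probe '%s', sample '%s'",
        pid[i[1]], sid[i[2]]),
        class = "gcm_validation_error")
    }
  }
  structure(list(values = values, detection = detection), class = "gcm_beta")
}

#' @export
dim.gcm_beta <- function(x) dim(x$values)

#' @export
dimnames.gcm_beta <- function(x) dimnames(x$values)

#' Probe and sample identifiers of a beta matrix
#' @param x A `gcm_beta` object.
#' @return Character vector of identifiers.
#' @export
probe_ids <- function(x) rownames(x$values)

#' @rdname probe_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' @export
print.gcm_beta <- function(x, ...) {
  cat(sprintf("<beta matrix: %d probes x %d samples%s>\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$detection)) "" else ", with detection p-values"))
  invisible(x)
}

#' Subset a beta matrix by probes and/or samples
#' @param x A `gcm_beta` object.
#' @param i,j Probe / sample indices or names.
#' @param ... Ignored.
#' @return A `gcm_beta` restricted to the selected axes.
#' @export
`[.gcm_beta` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  beta_matrix(x$values[i, j, drop = FALSE],
              if (is.null(x$detection)) NULL else
                x$detection[i, j, drop = FALSE])
}

#' @export
as_tibble.gcm_beta <- function(x, ...) {
  as_tibble(x$values, rownames = "probe_id")
}

read_numeric_tsv_matrix <- function(path, what = "beta") {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = col_character()),
                        progress = FALSE)
  if (ncol(df) < 2) {
    abort(sprintf("'%s' must have a probe-id column plus sample columns", path),
          class = "gcm_parse_error")
  }
  ids <- df[[1]]
  sample_names <- names(df)[-1]
  vals <- matrix(NA_real_, nrow(df), length(sample_names),
                 dimnames = list(ids, sample_names))
  for (k in seq_along(sample_names)) {
    col <- df[[k + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & col != "NA")
    if (length(bad) > 0) {
      abort(sprintf(
        "non-numeric %s cell '%s' at probe '%s', sample '%s' in '%s'",
        what, col[bad[1]], ids[bad[1]], sample_names[k], path),
        class = "gcm_parse_error")
    }
    vals[, k] <- num
  }
  vals
}

#' Read a beta-value matrix from TSV
#'
#' Expects a tab-separated file with a header row: the first column holds
#' probe ids, remaining columns one sample each. Missing values are encoded
#' `NA`. An optional detection-p-value file in the same layout is aligned by
#' its probe and sample labels.
#'
#' @param path Path to the beta-value TSV.
#' @param detection_path Optional path to the detection-p-value TSV.
#' @return A validated [beta_matrix()].
#' @export
read_beta_matrix <- function(path, detection_path = NULL) {
  vals <- read_numeric_tsv_matrix(path, "beta")
  detection <- NULL
  if (!is.null(detection_path)) {
    detection <- read_numeric_tsv_matrix(detection_path, "detection p-value")
    if (!setequal(rownames(detection), rownames(vals)) ||
        !setequal(colnames(detection), colnames(vals))) {
      abort("detection table labels do not match the beta table",
            class = "gcm_alignment_error")
    }
    detection <- detection[rownames(vals), colnames(vals), drop = FALSE]
  }
  beta_matrix(vals, detection)
}

#' Write a beta-value matrix to TSV
#'
#' @param x A `gcm_beta` object.
#' @param path Output path for the beta values.
#' @param detection_path Optional output path for the detection matrix.
#' @return `x`, invisibly.
#' @export
write_beta_matrix <- function(x, path, detection_path = NULL) {
  stopifnot(inherits(x, "gcm_beta"))
  readr::write_tsv(as_tibble(x$values, rownames = "probe_id"), path)
  if (!is.null(detection_path)) {
    if (is.null(x$detection)) {
      abort("no detection matrix to write", class = "gcm_validation_error")
    }
    readr::write_tsv(as_tibble(x$detection, rownames = "probe_id"),
                     detection_path)
  }
  invisible(x)
}
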