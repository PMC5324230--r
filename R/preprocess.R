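#' Probe-exclusion cascade
#'
#' Applies the quality-filtering rules to a beta matrix, sequentially, so
#' each removed probe is counted under the first rule that catches it:
#'
#' 1. *detection*: the probe's fluorescence signal is statistically
#'    indistinguishable from background — detection p-value above
#'    `detection_alpha` — in more than `max_fail_fraction` of samples
#'    (default: any sample);
#' 2. *SNP*: the probe is flagged as overlapping a SNP at the interrogated
#'    CpG or its single-base extension;
#' 3. *invariant*: cross-sample mean beta at or above `invariant_high`
#'    or at or below `invariant_low` (bounds inclusive);
#' 4. *missing*: any `NA` beta-value remains.
#'
#' @param beta A [beta_matrix()]; must carry a detection matrix unless
#'   `use_detection = FALSE`.
#' @param annot Probe annotation (needed for the SNP rule; pass `NULL` to
#'   skip it).
#' @param detection_alpha Detection p-value above which a probe is
#'   considered failed in a sample. Default 0.01.
#' @param invariant_low,invariant_high Invariant-methylation bounds on the
#'   cross-sample mean beta. Defaults 0.05 and 0.95.
#' @param max_fail_fraction Maximum tolerated fraction of samples failing
#'   detection before the probe is removed. Default 0 (remove on any
#'   failing sample).
#' @param use_detection Apply the detection rule? Default `TRUE`.
#' @return A list with `beta` (the retained [beta_matrix()]) and `report`,
#'   a `gcm_filter_report` accounting for every input probe.
#' @export
filter_probes <- function(beta, annot = NULL,
                          detection_alpha = 0.01,
                          invariant_low = 0.05,
                          invariant_high = 0.95,
                          max_fail_fraction = 0,
                          use_detection = TRUE) {
  stopifnot(inherits(beta, "gcm_beta"))
  if (use_detection && is.null(beta$detection)) {
    abort("detection rule enabled but the beta matrix has no detection p-values",
          class = "gcm_config_error")
  }
  probes <- probe_ids(beta)
  remaining <- rep(TRUE, length(probes))
  removed <- list()

  if (use_detection) {
    fail_frac <- rowMeans(beta$detection > detection_alpha, na.rm = TRUE)
    hit <- remaining & fail_frac > max_fail_fraction
    removed$detection <- probes[hit]
    remaining <- remaining & !hit
  } else {
    removed$detection <- character(0)
  }

  if (!is.null(annot)) {
    snp_probes <- annot$probe_id[annot$snp_flag]
    hit <- remaining & probes %in% snp_probes
    removed$snp <- probes[hit]
    remaining <- remaining & !hit
  } else {
    removed$snp <- character(0)
  }

  mean_beta <- rowMeans(beta$values, na.rm = TRUE)
  hit <- remaining &
    (mean_beta >= invariant_high | mean_beta <= invariant_low)
  removed$invariant <- probes[hit]
  remaining <- remaining & !hit

  hit <- remaining & apply(is.na(beta$values), 1, any)
  removed$missing <- probes[hit]
  remaining <- remaining & !hit

  report <- structure(list(
    n_input_probes = length(probes),
    n_removed_detection = length(removed$detection),
    n_removed_snp = length(removed$snp),
    n_removed_invariant = length(removed$invariant),
    n_removed_missing = length(removed$missing),
    n_retained = sum(remaining),
    removed = removed
  ), class = "gcm_filter_report")

  list(beta = beta[remaining, ], report = report)
}

#' @export
print.gcm_filter_report <- function(x, ...) {
  cat(sprintf(
    paste0("<filter report: %d probes in; removed %d detection, %d SNP, ",
           "%d invariant, %d missing; %d retained>\n"),
    x$n_input_probes, x$n_removed_detection, x$n_removed_snp,
    x$n_removed_invariant, x$n_removed_missing, x$n_retained))
  invisible(x)
}

#' @export
tidy.gcm_filter_report <- function(x, ...) {
  tibble(
    rule = c("input", "detection", "snp", "invariant", "missing", "retained"),
    n = c(x$n_input_probes, x$n_removed_detection, x$n_removed_snp,
          x$n_removed_invariant, x$n_removed_missing, x$n_retained)
  )
}

#' Batch and covariate adjustment of beta-values
#'
#' Removes array-batch effects from the beta matrix by parametric
#' empirical-Bayes location/scale adjustment (the ComBat model, via the
#' sva package), protecting the biological signal by including group,
#' age, BMI and the cell-composition estimates in the model matrix.
#' Adjustment operates directly on the beta scale; adjusted values are
#' clipped into \[eps, 1 - eps\].
#'
#' A single-batch input is returned unchanged (no batch effect to
#' remove). A batch containing a single sample is an error, as its
#' location/scale cannot be estimated.
#'
#' @param beta A [beta_matrix()] (no missing values; filter first).
#' @param samples Sample sheet aligned to the matrix columns; needs
#'   `sample_id`, `batch` and the covariate columns.
#' @param covariates Covariate columns to protect. Default group, age,
#'   BMI plus every `cell_*` column present.
#' @param eps Clipping bound. Default `1e-6`.
#' @return The adjusted [beta_matrix()] (detection matrix carried over).
#' @export
adjust_batch_covariates <- function(beta, samples,
                                    covariates = NULL, eps = 1e-6) {
  stopifnot(inherits(beta, "gcm_beta"))
  stop_if_missing_cols(samples, c("sample_id", "batch"), "sample sheet")
  if (!setequal(samples$sample_id, sample_ids(beta))) {
    abort("sample sheet and beta matrix contain different samples",
          class = "gcm_alignment_error")
  }
  samples <- samples[match(sample_ids(beta), samples$sample_id), ]
  if (anyNA(beta$values)) {
    abort("beta matrix contains NA; run filter_probes() first",
          class = "gcm_validation_error")
  }
  batch <- as.character(samples$batch)
  tab <- table(batch)
  if (length(tab) == 1) {
    out <- beta
    out$values <- clip01(out$values, eps)
    return(out)
  }
  if (any(tab < 2)) {
    abort(sprintf("batch '%s' has a single sample; cannot estimate its effect",
                  names(tab)[tab < 2][1]),
          class = "gcm_validation_error")
  }
  if (is.null(covariates)) {
    covariates <- intersect(c("group", "age", "bmi"), names(samples))
    cells <- cell_proportion_cols(samples)
    # proportions summing to a constant are collinear with the intercept;
    # include K - 1 of the K composition columns
    if (length(cells) > 1) cells <- cells[-length(cells)]
    covariates <- c(covariates, cells)
  }
  stop_if_missing_cols(samples, covariates, "sample sheet")
  if (anyNA(samples[covariates])) {
    abort("covariate columns must be complete", class = "gcm_validation_error")
  }
  mod <- model.matrix(
    as.formula(paste("~", paste(covariates, collapse = " + "))),
    data = samples)
  if (qr(mod)$rank < ncol(mod)) {
    abort("collinear covariates in the adjustment model",
          class = "gcm_validation_error")
  }
  adjusted <- suppressMessages(
    sva::ComBat(dat = beta$values, batch = batch, mod = mod,
                par.prior = TRUE, prior.plots = FALSE))
  out <- beta
  out$values <- clip01(adjusted, eps)
  out
}
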