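#' Principal component analysis of RAND-36 scores
#'
#' PCA of the eight RAND-36 category scores, each category centred and
#' unit-scaled over all samples (correlation-matrix PCA; the categories
#' share a 0-100 scale but differ in variance). The first component's
#' sign is oriented so that a higher PC1 score means better self-reported
#' health (positive loading on General Health), making the sign
#' deterministic.
#'
#' @param samples Sample sheet with the eight complete `rand36_*` columns
#'   (see [rand36_cols()]).
#' @param scale. Scale categories to unit variance? Default `TRUE`.
#' @return A `gcm_pca` object: `loadings` (8 x 8 matrix), `scores`
#'   (tibble with `sample_id`, `PC1` ... and, when present, `group`),
#'   `variance_explained` (fractions summing to 1). [tidy()] returns the
#'   long loading table; [glance()] the variance fractions.
#' @export
rand36_pca <- function(samples, scale. = TRUE) {
  cols <- rand36_cols()
  stop_if_missing_cols(samples, c("sample_id", cols), "sample sheet")
  m <- as.matrix(samples[cols])
  if (anyNA(m)) {
    abort("RAND-36 scores must be complete for every sample",
          class = "gcm_validation_error")
  }
  vars <- apply(m, 2, var)
  if (any(vars == 0)) {
    abort(sprintf("zero-variance RAND-36 category: %s",
                  cols[which(vars == 0)[1]]),
          class = "gcm_validation_error")
  }
  fit <- prcomp(m, center = TRUE, scale. = scale.)
  # orient PC1: better health = higher score
  gh <- "rand36_general_health"
  if (fit$rotation[gh, 1] < 0) {
    fit$rotation[, 1] <- -fit$rotation[, 1]
    fit$x[, 1] <- -fit$x[, 1]
  }
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- as_tibble(fit$x)
  scores <- bind_cols(tibble(sample_id = samples$sample_id), scores)
  if ("group" %in% names(samples)) scores$group <- samples$group
  structure(list(loadings = fit$rotation, scores = scores,
                 variance_explained = ve, scaled = scale.),
            class = "gcm_pca")
}

#' @export
print.gcm_pca <- function(x, ...) {
  cat(sprintf("<RAND-36 PCA: PC1 %.1f%%, PC2 %.1f%% of variance, %d samples>\n",
              100 * x$variance_explained[1], 100 * x$variance_explained[2],
              nrow(x$scores)))
  invisible(x)
}

#' @export
tidy.gcm_pca <- function(x, ...) {
  as_tibble(x$loadings, rownames = "category") |>
    pivot_longer(-"category", names_to = "component", values_to = "loading")
}

#' @export
glance.gcm_pca <- function(x, ...) {
  tibble(component = paste0("PC", seq_along(x$variance_explained)),
         variance_explained = x$variance_explained,
         cumulative = cumsum(x$variance_explained))
}

#' Aggregate differentially methylated probes into gene regions
#'
#' Groups probes by (gene symbol, genic region) pairs from the annotation
#' (a probe annotated to several genes contributes to each), keeps the
#' member probes whose absolute mean beta-difference is at least
#' `diff_min`, and emits a region when at least `min_sites` such members
#' remain. Region methylation per sample is the unweighted mean of the
#' member-probe beta-values; the region beta-difference is the g1 - g2
#' difference of the per-group means of that summary.
#'
#' @param dms DM records over the retained probe universe (needs
#'   `probe_id`, `beta_diff`).
#' @param annot Probe annotation.
#' @param beta The [beta_matrix()] the records were computed from.
#' @param samples Sample sheet with `sample_id` and `group`.
#' @param diff_min Per-site effect-size requirement. Default 0.05.
#' @param min_sites Minimum qualifying sites per region. Default 2.
#' @return A `gcm_regions` object: `$regions` (tibble with `region_id`,
#'   `gene`, `genic_region`, `n_sites`, member `probe_ids` list-column,
#'   `mean_case`, `mean_control`, `beta_diff`) and `$methylation`
#'   (region x sample matrix of per-sample region methylation).
#' @export
define_regions <- function(dms, annot, beta, samples,
                           diff_min = 0.05, min_sites = 2) {
  stopifnot(inherits(beta, "gcm_beta"))
  stop_if_missing_cols(dms, c("probe_id", "beta_diff"), "DM records")
  qualifying <- dms |>
    filter(abs(.data$beta_diff) >= diff_min) |>
    inner_join(annot, by = "probe_id") |>
    filter(.data$gene_symbols != "") |>
    mutate(gene = strsplit(.data$gene_symbols, ";", fixed = TRUE)) |>
    unnest("gene")
  groups <- qualifying |>
    group_by(.data$gene, .data$genic_region) |>
    summarise(probe_ids = list(unique(.data$probe_id)), .groups = "drop") |>
    mutate(n_sites = lengths(.data$probe_ids)) |>
    filter(.data$n_sites >= min_sites) |>
    mutate(region_id = paste(.data$gene, .data$genic_region, sep = ":")) |>
    arrange(.data$region_id)

  grp <- setNames(samples$group, samples$sample_id)[sample_ids(beta)]
  if (nrow(groups) == 0) {
    meth <- matrix(numeric(0), 0, ncol(beta$values),
                   dimnames = list(NULL, sample_ids(beta)))
    regions <- tibble(region_id = character(), gene = character(),
                      genic_region = character(), n_sites = integer(),
                      probe_ids = list(), mean_case = numeric(),
                      mean_control = numeric(), beta_diff = numeric())
    return(structure(list(regions = regions, methylation = meth),
                     class = "gcm_regions"))
  }
  meth <- t(vapply(groups$probe_ids, function(pids) {
    colMeans(beta$values[pids, , drop = FALSE])
  }, numeric(ncol(beta$values))))
  rownames(meth) <- groups$region_id
  mean_case <- rowMeans(meth[, grp == "case", drop = FALSE])
  mean_control <- rowMeans(meth[, grp == "control", drop = FALSE])
  regions <- groups |>
    select("region_id", "gene", "genic_region", "n_sites", "probe_ids") |>
    mutate(mean_case = mean_case, mean_control = mean_control,
           beta_diff = mean_case - mean_control)
  structure(list(regions = regions, methylation = meth),
            class = "gcm_regions")
}

#' @export
print.gcm_regions <- function(x, ...) {
  cat(sprintf("<%d differentially methylated region(s) over %d sample(s)>\n",
              nrow(x$regions), ncol(x$methylation)))
  invisible(x)
}

#' @export
tidy.gcm_regions <- function(x, ...) x$regions |> select(-"probe_ids")

#' Regress region methylation on overall quality of life
#'
#' Ordinary least squares of each region's per-sample methylation on the
#' PC1 quality-of-life score across all samples (cases and controls
#' pooled). Reports the squared correlation and BH-FDR across all
#' regions, sorted by decreasing R-squared. R-squared is invariant under
#' affine rescaling of the score.
#'
#' @param regions A `gcm_regions` object from [define_regions()].
#' @param scores Either a `gcm_pca` object (its PC1 is used) or a tibble
#'   with `sample_id` and `pc1`.
#' @param adjust_group Optionally include a case/control indicator as a
#'   covariate (needs a `group` column in the scores); the reported
#'   R-squared is then the partial fit's squared correlation between
#'   observed and fitted values. Default `FALSE`.
#' @return Tibble with `region_id`, `gene`, `genic_region`, `n_sites`,
#'   `beta_diff`, `slope`, `r_squared`, `p`, `q_fdr`, sorted by
#'   `r_squared` descending.
#' @export
region_qol_regression <- function(regions, scores, adjust_group = FALSE) {
  stopifnot(inherits(regions, "gcm_regions"))
  if (inherits(scores, "gcm_pca")) {
    scores <- scores$scores |>
      select("sample_id", pc1 = "PC1",
             any_of("group"))
  }
  stop_if_missing_cols(scores, c("sample_id", "pc1"), "scores")
  meth <- regions$methylation
  common <- intersect(colnames(meth), scores$sample_id)
  if (length(common) < 3) {
    abort("need at least 3 samples with both methylation and scores",
          class = "gcm_validation_error")
  }
  meth <- meth[, common, drop = FALSE]
  sc <- scores[match(common, scores$sample_id), ]
  if (nrow(regions$regions) == 0) {
    return(tibble(region_id = character(), gene = character(),
                  genic_region = character(), n_sites = integer(),
                  beta_diff = numeric(), slope = numeric(),
                  r_squared = numeric(), p = numeric(), q_fdr = numeric()))
  }
  fits <- map(seq_len(nrow(meth)), function(i) {
    y <- meth[i, ]
    if (adjust_group && "group" %in% names(sc)) {
      fit <- lm(y ~ sc$pc1 + sc$group)
    } else {
      fit <- lm(y ~ sc$pc1)
    }
    s <- suppressWarnings(summary(fit))  # quiet on exact fits
    tibble(slope = coef(fit)[["sc$pc1"]],
           r_squared = cor(y, fitted(fit))^2,
           p = s$coefficients["sc$pc1", 4])
  }) |> list_rbind()
  out <- regions$regions |>
    select("region_id", "gene", "genic_region", "n_sites", "beta_diff") |>
    bind_cols(fits) |>
    mutate(q_fdr = bh_fdr(.data$p)) |>
    arrange(desc(.data$r_squared))
  out
}
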