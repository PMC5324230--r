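#' Two-sided Wilcoxon rank-sum p-value
#'
#' Rank-sum test between two samples with the policy used across the
#' pipeline: exact enumeration when the combined size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie-corrected
#' variance and continuity correction.
#'
#' @param x,y Numeric samples (both non-empty).
#' @return The two-sided p-value.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))  # 0.1 (exact)
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    abort("both samples must be non-empty", class = "gcm_validation_error")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12) && !ties
  suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment over the supplied p-value
#' vector.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1] with no NA",
          class = "gcm_validation_error")
  }
  p.adjust(p, method = "BH")
}

#' Per-probe two-group differential methylation
#'
#' For every probe, computes the group mean beta-values, their signed
#' difference (`beta_diff = mean(g1) - mean(g2)`; hypermethylation is
#' positive), the two-sided Wilcoxon rank-sum p-value, and the BH q-value
#' over all tested probes, then applies the three-part significance
#' criteria via [call_dms()].
#'
#' @param beta A [beta_matrix()] (filtered and adjusted).
#' @param samples Sample sheet covering the matrix columns.
#' @param group_col Column of `samples` holding the two-group labels.
#' @param levels Length-2 character: the g1 and g2 labels, in that order.
#' @param diff_min,p_max,q_max,require_q Significance criteria passed to
#'   [call_dms()].
#' @return A tibble of DM records: `probe_id`, `mean_beta_g1`,
#'   `mean_beta_g2`, `beta_diff`, `p_wilcoxon`, `q_bh`, `direction`,
#'   `significant`, with the comparison stored in attributes.
#' @export
diff_methylation <- function(beta, samples, group_col = "group",
                             levels = c("case", "control"),
                             diff_min = 0.05, p_max = 0.05, q_max = 0.05,
                             require_q = TRUE) {
  stopifnot(inherits(beta, "gcm_beta"), length(levels) == 2)
  stop_if_missing_cols(samples, c("sample_id", group_col), "sample sheet")
  labels <- setNames(samples[[group_col]], samples$sample_id)[sample_ids(beta)]
  g1 <- which(labels == levels[1])
  g2 <- which(labels == levels[2])
  if (length(g1) == 0 || length(g2) == 0) {
    abort(sprintf("empty group in comparison %s vs %s",
                  levels[1], levels[2]),
          class = "gcm_validation_error")
  }
  v <- beta$values
  m1 <- rowMeans(v[, g1, drop = FALSE])
  m2 <- rowMeans(v[, g2, drop = FALSE])
  pvals <- vapply(seq_len(nrow(v)), function(i) {
    wilcoxon_rank_sum(v[i, g1], v[i, g2])
  }, numeric(1))
  records <- tibble(
    probe_id = probe_ids(beta),
    mean_beta_g1 = unname(m1),
    mean_beta_g2 = unname(m2),
    beta_diff = unname(m1 - m2),
    p_wilcoxon = pvals,
    q_bh = bh_fdr(pvals)
  )
  records <- call_dms(records, diff_min = diff_min, p_max = p_max,
                      q_max = q_max, require_q = require_q)
  attr(records, "comparison") <- levels
  records
}

#' Apply the differential-methylation significance criteria
#'
#' A probe is called significant when all enabled gates pass:
#' `|beta_diff| >= diff_min` (effect size, both directions), nominal
#' Wilcoxon `p <= p_max`, and (when `require_q`) BH `q <= q_max`. Setting
#' `require_q = FALSE` reproduces the two-part criteria used for the
#' smaller assay-subgroup comparisons. Direction is `hyper` when
#' `beta_diff > 0`, else `hypo`.
#'
#' @param records Tibble with `beta_diff`, `p_wilcoxon` and (when
#'   `require_q`) `q_bh`.
#' @param diff_min Minimum absolute mean beta-difference. Default 0.05.
#' @param p_max Nominal p threshold. Default 0.05.
#' @param q_max FDR threshold. Default 0.05.
#' @param require_q Apply the FDR gate? Default `TRUE`.
#' @return `records` with `direction` and `significant` columns set.
#' @export
call_dms <- function(records, diff_min = 0.05, p_max = 0.05, q_max = 0.05,
                     require_q = TRUE) {
  stop_if_missing_cols(records, c("beta_diff", "p_wilcoxon"), "DM records")
  if (require_q) stop_if_missing_cols(records, "q_bh", "DM records")
  sig <- abs(records$beta_diff) >= diff_min & records$p_wilcoxon <= p_max
  if (require_q) sig <- sig & records$q_bh <= q_max
  records |>
    mutate(direction = ifelse(.data$beta_diff > 0, "hyper", "hypo"),
           significant = sig)
}

#' Genomic-context enrichment of methylation direction
#'
#' Cross-tabulates significant probes by direction of change
#' (hyper/hypo) against a genomic-context axis (CpG-island relation or
#' genic region), tests global homogeneity with a Pearson chi-squared
#' test (no continuity correction), and contrasts each category against a
#' reference category with pairwise 2x2 chi-squared tests, BH-adjusted
#' across the pairwise family. On the island axis the S_Shelf-vs-S_Shore
#' contrast is additionally included in the family.
#'
#' @param records DM records with `significant` and `direction` set.
#' @param annot Probe annotation covering the record probes.
#' @param axis `"island_relation"` (default) or `"genic_region"`.
#' @param reference Reference category for pairwise contrasts.
#'   Default `"Island"` (use e.g. `"Body"` for the genic axis).
#' @param correct Continuity-correct the 2x2 tables? Default `FALSE`
#'   (plain Pearson).
#' @return A `gcm_enrichment` list: `counts` (category x direction),
#'   `global` (statistic, df, p) and `pairwise` (per-contrast statistic,
#'   p, q). Empty categories are dropped with a warning.
#' @export
context_enrichment <- function(records, annot,
                               axis = c("island_relation", "genic_region"),
                               reference = "Island", correct = FALSE) {
  axis <- match.arg(axis)
  sig <- records |>
    filter(.data$significant) |>
    inner_join(annot, by = "probe_id")
  if (nrow(sig) == 0) {
    abort("no significant probes to test for enrichment",
          class = "gcm_validation_error")
  }
  counts <- sig |>
    count(category = .data[[axis]], .data$direction) |>
    pivot_wider(names_from = "direction", values_from = "n", values_fill = 0L)
  for (col in c("hyper", "hypo")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  empty <- setdiff(annotation_vocab()[[axis]], counts$category)
  if (length(empty) > 0) {
    warn(sprintf("category(ies) with no significant probes excluded: %s",
                 paste(empty, collapse = ", ")))
  }
  if (!reference %in% counts$category) {
    abort(sprintf("reference category '%s' has no significant probes",
                  reference),
          class = "gcm_validation_error")
  }
  tab <- as.matrix(counts[, c("hyper", "hypo")])
  rownames(tab) <- counts$category
  global_test <- suppressWarnings(chisq.test(tab, correct = FALSE))
  contrasts <- lapply(setdiff(counts$category, reference), function(cat) {
    c(a = cat, b = reference)
  })
  if (axis == "island_relation" &&
      all(c("S_Shelf", "S_Shore") %in% counts$category)) {
    contrasts <- c(contrasts, list(c(a = "S_Shelf", b = "S_Shore")))
  }
  pairwise <- map(contrasts, function(ct) {
    t2 <- tab[c(ct["a"], ct["b"]), , drop = FALSE]
    ht <- suppressWarnings(chisq.test(t2, correct = correct))
    tibble(category = ct[["a"]], reference = ct[["b"]],
           statistic = unname(ht$statistic), p = ht$p.value)
  }) |> list_rbind()
  pairwise$q <- bh_fdr(pairwise$p)
  structure(list(
    axis = axis,
    counts = counts,
    global = tibble(statistic = unname(global_test$statistic),
                    df = unname(global_test$parameter),
                    p = global_test$p.value),
    pairwise = pairwise
  ), class = "gcm_enrichment")
}

#' @export
print.gcm_enrichment <- function(x, ...) {
  cat(sprintf("<context enrichment on %s: global X^2 = %.2f (p = %.3g), %d pairwise contrasts>\n",
              x$axis, x$global$statistic, x$global$p, nrow(x$pairwise)))
  invisible(x)
}

#' @export
tidy.gcm_enrichment <- function(x, ...) x$pairwise

#' @export
glance.gcm_enrichment <- function(x, ...) x$global
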