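#' Assemble a run report
#'
#' Aggregates the stage outputs into the summary surface of a full run:
#' probe and call counts, direction fractions among significant sites
#' (hyper% + hypo% = 100, `NA` when nothing is significant), top-k
#' hyper- and hypomethylated site tables by absolute beta-difference
#' (ties broken by probe id), Venn region counts, and top regions by
#' R-squared. Every number is recomputed from the supplied tables, so the
#' report carries no independent state.
#'
#' @param dms DM records (from [diff_methylation()]).
#' @param perm Optional permutation results (from [permute_null()]).
#' @param venn Optional `gcm_venn` object.
#' @param regions Optional region regression table (from
#'   [region_qol_regression()]).
#' @param top_k Rows per direction in the top tables. Default 5.
#' @param thresholds Named list of thresholds/seeds to record verbatim.
#' @return A `gcm_report` list with a plain-text `print()` method and
#'   [tidy()] returning the headline counts.
#' @export
run_report <- function(dms, perm = NULL, venn = NULL, regions = NULL,
                       top_k = 5, thresholds = list()) {
  stop_if_missing_cols(dms, c("probe_id", "beta_diff", "significant"),
                       "DM records")
  sig <- dms |> filter(.data$significant)
  n_sig <- nrow(sig)
  hyper_pct <- if (n_sig > 0) 100 * mean(sig$direction == "hyper") else NA_real_
  hypo_pct <- if (n_sig > 0) 100 - hyper_pct else NA_real_
  top_tbl <- function(d) {
    sig |>
      filter(.data$direction == d) |>
      arrange(desc(abs(.data$beta_diff)), .data$probe_id) |>
      head(top_k)
  }
  structure(list(
    n_probes = nrow(dms),
    n_significant = n_sig,
    hyper_pct = hyper_pct,
    hypo_pct = hypo_pct,
    top_hyper = top_tbl("hyper"),
    top_hypo = top_tbl("hypo"),
    n_perm_significant = if (!is.null(perm)) sum(perm$significant_perm)
    else NA_integer_,
    venn = if (!is.null(venn)) venn$regions else NULL,
    n_gc_loci = if (!is.null(venn))
      length(venn$derived$gc_sensitivity_loci) else NA_integer_,
    top_regions = if (!is.null(regions)) head(regions, top_k) else NULL,
    thresholds = thresholds
  ), class = "gcm_report")
}

#' @export
tidy.gcm_report <- function(x, ...) {
  tibble(
    quantity = c("n_probes", "n_significant", "hyper_pct", "hypo_pct",
                 "n_perm_significant", "n_gc_loci"),
    value = c(x$n_probes, x$n_significant, x$hyper_pct, x$hypo_pct,
              x$n_perm_significant, x$n_gc_loci)
  )
}

#' @export
print.gcm_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.gcm_report <- function(x, ...) {
  out <- c(
    "== differential methylation run report ==",
    sprintf("probes tested:        %d", x$n_probes),
    sprintf("significant sites:    %d", x$n_significant),
    if (is.na(x$hyper_pct))
      "direction fractions:  NA (no significant sites)"
    else
      sprintf("direction fractions:  %.1f%% hyper / %.1f%% hypo",
              x$hyper_pct, x$hypo_pct)
  )
  if (nrow(x$top_hyper) > 0) {
    out <- c(out, "top hypermethylated sites:",
             sprintf("  %s  diff %+0.3f", x$top_hyper$probe_id,
                     x$top_hyper$beta_diff))
  }
  if (nrow(x$top_hypo) > 0) {
    out <- c(out, "top hypomethylated sites:",
             sprintf("  %s  diff %+0.3f", x$top_hypo$probe_id,
                     x$top_hypo$beta_diff))
  }
  if (!is.null(x$venn)) {
    out <- c(out, "three-comparison overlap:",
             sprintf("  %-9s %d", x$venn$region, x$venn$count),
             sprintf("GC-sensitivity loci:  %d", x$n_gc_loci))
  }
  if (!is.null(x$top_regions) && nrow(x$top_regions) > 0) {
    out <- c(out, "top quality-of-life regions (R^2):",
             sprintf("  %s  R^2 %.3f", x$top_regions$region_id,
                     x$top_regions$r_squared))
  }
  if (length(x$thresholds) > 0) {
    out <- c(out, "settings:",
             sprintf("  %s = %s", names(x$thresholds),
                     vapply(x$thresholds, function(v)
                       paste(format(v), collapse = ","), character(1))))
  }
  out
}
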