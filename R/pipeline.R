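#' Default pipeline configuration
#'
#' Returns the full configuration list with every threshold at its
#' default: detection alpha 0.01, invariant bounds 0.05/0.95, the
#' three-part significance criteria at 0.05, 10,000 permutations, mixture
#' subgrouping, region rule of at least 2 sites at 0.05. Any entry can be
#' overridden via the `config` argument of [run_pipeline()] or a YAML
#' file with the same keys.
#'
#' @return Named list of configuration defaults.
#' @export
default_config <- function() {
  list(
    inputs = list(beta = NULL, detection = NULL, annotation = NULL,
                  samples = NULL, assay = NULL),
    simulate = TRUE,
    design = list(),
    detection_alpha = 0.01,
    invariant_low = 0.05,
    invariant_high = 0.95,
    diff_min = 0.05,
    p_max = 0.05,
    q_max = 0.05,
    n_perm = 10000,
    perm_alpha = 0.05,
    subgroup_method = "mixture_em",
    subgroup_threshold = NULL,
    region_min_sites = 2,
    top_k = 5,
    seed = 1L,
    out_dir = NULL
  )
}

log_stage <- function(log_level, ...) {
  if (identical(log_level, "quiet")) return(invisible())
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...))
}

#' Run the full analysis pipeline
#'
#' Chains every stage in order — input acquisition (read the configured
#' TSVs, or generate a synthetic study), probe filtering, batch/covariate
#' adjustment, case-vs-control differential methylation with context
#' enrichment, assay aggregation and subgroup assignment, the three
#' subgroup comparisons with permutation nulls and concordance, the
#' three-way overlap, RAND-36 PCA with region definition and
#' quality-of-life regression, and the final report. With an `out_dir`
#' set, per-stage TSV outputs, `report.txt` and a `run_log.txt` recording
#' package version, seed and thresholds are written; outputs are a pure
#' function of (inputs, config, seed), so two runs with identical
#' configuration produce byte-identical files.
#'
#' @param config A named list overriding entries of [default_config()],
#'   or a path to a YAML file of such entries.
#' @param log_level `"info"` (timestamps to standard error) or
#'   `"quiet"`.
#' @return A named list of all stage results (invisible when writing to
#'   `out_dir`).
#' @export
run_pipeline <- function(config = list(), log_level = "info") {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort(sprintf("config file '%s' does not exist", config),
            class = "gcm_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_config(), config)

  # validate inputs before any computation
  if (!isTRUE(cfg$simulate)) {
    needed <- c("beta", "annotation", "samples", "assay")
    for (nm in needed) {
      path <- cfg$inputs[[nm]]
      if (is.null(path) || !file.exists(path)) {
        abort(sprintf("input '%s' missing or does not exist (%s)",
                      nm, path %||% "unset"),
              class = "gcm_config_error")
      }
    }
  }

  if (isTRUE(cfg$simulate)) {
    log_stage(log_level, "simulate: generating synthetic study (seed %d)",
              cfg$seed)
    design <- do.call(sim_design, c(cfg$design, list(seed = cfg$seed)))
    sim <- simulate_study(design)
    beta <- sim$beta; annotation <- sim$annotation
    samples <- sim$samples; assay <- sim$assay
  } else {
    log_stage(log_level, "read: loading input tables")
    beta <- read_beta_matrix(cfg$inputs$beta, cfg$inputs$detection)
    annotation <- read_probe_annotation(cfg$inputs$annotation)
    samples <- read_sample_sheet(cfg$inputs$samples)
    assay <- readr::read_tsv(cfg$inputs$assay, show_col_types = FALSE,
                             progress = FALSE)
    sim <- NULL
  }

  log_stage(log_level, "preprocess: filtering %d probes", nrow(beta$values))
  filt <- filter_probes(beta, annotation,
                        detection_alpha = cfg$detection_alpha,
                        invariant_low = cfg$invariant_low,
                        invariant_high = cfg$invariant_high,
                        use_detection = !is.null(beta$detection))
  log_stage(log_level, "preprocess: %d probes retained; adjusting batches",
            filt$report$n_retained)
  adjusted <- adjust_batch_covariates(filt$beta, samples)

  log_stage(log_level, "diffmeth: case vs control on %d probes",
            nrow(adjusted$values))
  dms <- diff_methylation(adjusted, samples,
                          diff_min = cfg$diff_min, p_max = cfg$p_max,
                          q_max = cfg$q_max, require_q = TRUE)
  enrichment <- if (sum(dms$significant) > 0) {
    tryCatch(context_enrichment(dms, annotation), error = function(e) NULL)
  } else NULL

  log_stage(log_level, "gc-assay: inhibition and subgrouping")
  inhibition <- assay_inhibition(assay)
  case_ids <- samples$sample_id[samples$group == "case"]
  subgroups <- assign_subgroups(
    inhibition |> filter(.data$sample_id %in% case_ids),
    method = cfg$subgroup_method, threshold = cfg$subgroup_threshold,
    seed = cfg$seed)
  tests <- group_tests(inhibition, samples, subgroups)

  # assay-sample stratification for the three comparisons
  assay_ids <- inhibition$sample_id
  strata <- tibble(sample_id = assay_ids) |>
    left_join(samples |> select("sample_id", "group"), by = "sample_id") |>
    left_join(subgroups$assignments |> select("sample_id", "gc_subgroup"),
              by = "sample_id") |>
    mutate(stratum = ifelse(.data$group == "control", "control",
                            .data$gc_subgroup))
  sub_sheet <- strata |> select("sample_id", group = "stratum")
  beta_assay <- adjusted[, intersect(sample_ids(adjusted), assay_ids)]

  comparisons <- list(
    HvT = c("hypersensitive", "typical"),
    HvC = c("hypersensitive", "control"),
    TvC = c("typical", "control")
  )
  dm_sub <- list(); perm_sub <- list(); conc <- list()
  for (nm in names(comparisons)) {
    lv <- comparisons[[nm]]
    keep <- sub_sheet$sample_id[sub_sheet$group %in% lv]
    b <- beta_assay[, intersect(sample_ids(beta_assay), keep)]
    sheet <- sub_sheet |> filter(.data$sample_id %in% sample_ids(b))
    log_stage(log_level, "permute: %s (%d vs %d samples, %d shuffles)",
              nm, sum(sheet$group == lv[1]), sum(sheet$group == lv[2]),
              cfg$n_perm)
    d <- diff_methylation(b, sheet, group_col = "group", levels = lv,
                          diff_min = cfg$diff_min, p_max = cfg$p_max,
                          require_q = FALSE)
    pr <- permute_null(b, setNames(sheet$group, sheet$sample_id),
                       levels = lv, n_perm = cfg$n_perm,
                       seed = cfg$seed + match(nm, names(comparisons)),
                       alpha = cfg$perm_alpha)
    dm_sub[[nm]] <- d |> left_join(pr |> select("probe_id", "perm_p"),
                                   by = "probe_id")
    perm_sub[[nm]] <- pr
    conc[[nm]] <- concordance(d, pr, alpha = cfg$perm_alpha,
                              diff_min = cfg$diff_min)
  }
  venn <- three_way_overlap(dm_sub$HvT, dm_sub$HvC, dm_sub$TvC,
                            alpha = cfg$perm_alpha, diff_min = cfg$diff_min)
  gc_loci <- if (length(venn$derived$gc_sensitivity_loci) > 0) {
    gc_site_magnitude(beta_assay,
                      strata |> select("sample_id", "stratum"),
                      venn$derived$gc_sensitivity_loci)
  } else NULL

  log_stage(log_level, "qol: PCA and region regression")
  pca <- rand36_pca(samples)
  regions <- define_regions(dms, annotation, adjusted, samples,
                            diff_min = cfg$diff_min,
                            min_sites = cfg$region_min_sites)
  region_fit <- region_qol_regression(regions, pca)

  thresholds <- cfg[c("detection_alpha", "invariant_low", "invariant_high",
                      "diff_min", "p_max", "q_max", "n_perm", "perm_alpha",
                      "region_min_sites", "seed")]
  report <- run_report(dms, perm = perm_sub$HvT, venn = venn,
                       regions = region_fit, top_k = cfg$top_k,
                       thresholds = thresholds)

  results <- list(
    config = cfg, simulation = sim, filter_report = filt$report,
    beta = adjusted, dms = dms, enrichment = enrichment,
    inhibition = inhibition, subgroups = subgroups, tests = tests,
    dm_subgroup = dm_sub, perm = perm_sub, concordance = conc,
    venn = venn, gc_loci = gc_loci, pca = pca, regions = regions,
    region_fit = region_fit, report = report
  )

  if (!is.null(cfg$out_dir)) {
    write_pipeline_outputs(results, cfg$out_dir)
    log_stage(log_level, "done: outputs in %s", cfg$out_dir)
    return(invisible(results))
  }
  results
}

write_pipeline_outputs <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) readr::write_tsv(df, file.path(out_dir, name))
  w(tidy(results$filter_report), "filter_report.tsv")
  w(results$dms, "dms.tsv")
  if (!is.null(results$enrichment)) {
    w(tidy(results$enrichment), "context_enrichment.tsv")
  }
  w(results$inhibition, "inhibition.tsv")
  w(results$subgroups$assignments, "subgroups.tsv")
  w(tidy(results$tests), "tests.tsv")
  for (nm in names(results$perm)) {
    w(results$perm[[nm]], sprintf("perm_%s.tsv", nm))
    w(results$dm_subgroup[[nm]], sprintf("dms_%s.tsv", nm))
  }
  w(bind_rows(results$concordance, .id = "comparison"), "concordance.tsv")
  w(tidy(results$venn), "venn.tsv")
  if (!is.null(results$gc_loci)) w(results$gc_loci, "gc_loci.tsv")
  w(results$pca$scores, "pca_scores.tsv")
  w(glance(results$pca), "pca_summary.tsv")
  w(tidy(results$regions), "regions.tsv")
  w(results$region_fit, "region_qol.tsv")
  w(tidy(results$report), "report.tsv")
  writeLines(format(results$report), file.path(out_dir, "report.txt"))
  cfg <- results$config
  writeLines(c(
    sprintf("package gcmethyl %s", as.character(packageVersion("gcmethyl"))),
    sprintf("R %s", as.character(getRversion())),
    sprintf("seed %d", cfg$seed),
    sprintf("n_perm %d", cfg$n_perm),
    sprintf("thresholds: diff_min %s, p_max %s, q_max %s, detection_alpha %s, invariant %s/%s",
            cfg$diff_min, cfg$p_max, cfg$q_max, cfg$detection_alpha,
            cfg$invariant_low, cfg$invariant_high)
  ), file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
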