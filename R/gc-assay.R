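#' Percent inhibition of stimulated proliferation
#'
#' `(stimulated - suppressed) / stimulated * 100`, the glucocorticoid
#' sensitivity statistic of the dexamethasone suppression assay. Inputs
#' are condition means over replicate wells. May be negative when the
#' suppressed condition exceeds the stimulated one. Scale-invariant:
#' multiplying both optical densities by a positive constant leaves it
#' unchanged.
#'
#' @param stimulated,suppressed Optical densities (stimulated must be
#'   strictly positive). Vectorised.
#' @return Inhibition percentage(s).
#' @examples
#' inhibition_percent(2.0, 0.5)  # 75
#' @export
inhibition_percent <- function(stimulated, suppressed) {
  if (any(stimulated <= 0)) {
    abort("stimulated optical density must be positive",
          class = "gcm_validation_error")
  }
  (stimulated - suppressed) / stimulated * 100
}

#' Aggregate an assay plate into per-subject inhibition
#'
#' Averages the triplicate wells of each culture condition per subject
#' (arithmetic mean), computes the coefficient of variation of each
#' triplicate (warning above `cv_warn`), and derives the inhibition
#' percentage from the stimulated and suppressed condition means.
#'
#' @param plate Long tibble with `sample_id`, `condition`
#'   (control/stimulated/suppressed), `replicate`, `od`.
#' @param cv_warn Coefficient-of-variation warning threshold per
#'   triplicate. Default 0.2.
#' @return A tibble with `sample_id`, `mean_control_od`,
#'   `mean_stimulated_od`, `mean_suppressed_od`, `max_cv`,
#'   `inhibition_pct`.
#' @export
assay_inhibition <- function(plate, cv_warn = 0.2) {
  stop_if_missing_cols(plate, c("sample_id", "condition", "od"), "assay plate")
  agg <- plate |>
    group_by(.data$sample_id, .data$condition) |>
    summarise(mean_od = mean(.data$od),
              cv = sd(.data$od) / mean(.data$od), .groups = "drop")
  high_cv <- agg |> filter(!is.na(.data$cv), .data$cv > cv_warn)
  if (nrow(high_cv) > 0) {
    warn(sprintf("%d triplicate(s) exceed CV %.2f (worst: %s / %s, CV %.2f)",
                 nrow(high_cv), cv_warn,
                 high_cv$sample_id[which.max(high_cv$cv)],
                 high_cv$condition[which.max(high_cv$cv)],
                 max(high_cv$cv)))
  }
  wide <- agg |>
    group_by(.data$sample_id) |>
    summarise(
      mean_control_od = .data$mean_od[.data$condition == "control"],
      mean_stimulated_od = .data$mean_od[.data$condition == "stimulated"],
      mean_suppressed_od = .data$mean_od[.data$condition == "suppressed"],
      max_cv = max(.data$cv, na.rm = TRUE), .groups = "drop")
  wide |>
    mutate(inhibition_pct = inhibition_percent(.data$mean_stimulated_od,
                                               .data$mean_suppressed_od))
}

# log-likelihood of a univariate 2-component Gaussian mixture
mix_loglik <- function(x, w, mu, sigma) {
  sum(log(w[1] * dnorm(x, mu[1], sigma[1]) +
            w[2] * dnorm(x, mu[2], sigma[2])))
}

fit_mixture_em <- function(x, n_restarts = 10, tol = 1e-8, max_iter = 1000) {
  n <- length(x)
  best <- NULL
  sd_floor <- max(sd(x), 1e-6) * 1e-3
  for (r in seq_len(n_restarts)) {
    mu <- sort(sample(x, 2)) + rnorm(2, 0, sd(x) * 0.05)
    sigma <- rep(max(sd(x), sd_floor), 2)
    w <- c(0.5, 0.5)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      d1 <- w[1] * dnorm(x, mu[1], sigma[1])
      d2 <- w[2] * dnorm(x, mu[2], sigma[2])
      tot <- d1 + d2
      tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
      g <- d1 / tot
      w <- c(mean(g), 1 - mean(g))
      if (any(w * n < 1e-8)) break
      mu <- c(sum(g * x) / sum(g), sum((1 - g) * x) / sum(1 - g))
      sigma <- c(sqrt(sum(g * (x - mu[1])^2) / sum(g)),
                 sqrt(sum((1 - g) * (x - mu[2])^2) / sum(1 - g)))
      sigma <- pmax(sigma, sd_floor)
      ll <- mix_loglik(x, w, mu, sigma)
      if (is.finite(ll) && abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    ll <- mix_loglik(x, w, mu, sigma)
    if (is.null(best) || (is.finite(ll) && ll > best$loglik)) {
      best <- list(w = w, mu = mu, sigma = sigma, loglik = ll)
    }
  }
  best
}

#' Stratify cases by glucocorticoid sensitivity
#'
#' Formalises the bimodal split of case inhibition percentages into
#' GC-Hypersensitive and GC-Typical subgroups. The default fits a
#' two-component univariate Gaussian mixture by EM (10 random restarts,
#' log-likelihood tolerance 1e-8) and assigns each case to its
#' maximum-posterior component, the component with the higher mean
#' inhibition being hypersensitive; posterior ties break toward typical.
#' When the fitted mixture is degenerate (either component carries weight
#' below 2/n) the function falls back, with a warning, to a fixed
#' threshold at the midpoint between the two most separated k-means
#' cluster centres. `method = "fixed_threshold"` assigns hypersensitive
#' to inhibition strictly above a user-given cutoff.
#'
#' @param results Tibble with `sample_id` and `inhibition_pct` for the
#'   case samples (at least 4).
#' @param method `"mixture_em"` (default) or `"fixed_threshold"`.
#' @param threshold Inhibition cutoff for the fixed-threshold mode.
#' @param n_restarts,tol EM control parameters.
#' @param seed Random seed for the EM restarts.
#' @return A `gcm_subgroups` object: component parameters, per-case
#'   assignments (`$assignments`), the threshold when relevant, and the
#'   fit log-likelihood. [tidy()] returns the component table; the
#'   assignment tibble has columns `sample_id`, `gc_subgroup`,
#'   `posterior_hypersensitive`.
#' @export
assign_subgroups <- function(results,
                             method = c("mixture_em", "fixed_threshold"),
                             threshold = NULL, n_restarts = 10, tol = 1e-8,
                             seed = NULL) {
  method <- match.arg(method)
  stop_if_missing_cols(results, c("sample_id", "inhibition_pct"),
                       "assay results")
  x <- results$inhibition_pct
  n <- length(x)
  if (method == "mixture_em" && n < 4) {
    abort("mixture subgrouping needs at least 4 case results",
          class = "gcm_validation_error")
  }
  fallback <- FALSE
  components <- NULL
  loglik <- NA_real_
  posterior_hyper <- rep(NA_real_, n)

  if (method == "mixture_em") {
    if (!is.null(seed)) set.seed(seed)
    if (diff(range(x)) < .Machine$double.eps^0.5) {
      warn("all inhibition values identical; assigning every case to typical")
      assignments <- tibble(sample_id = results$sample_id,
                            gc_subgroup = "typical",
                            posterior_hypersensitive = 0)
      out <- structure(list(method = "fixed_threshold", components = NULL,
                            assignments = assignments, threshold = Inf,
                            loglik = NA_real_, n = n, fallback = TRUE),
                       class = "gcm_subgroups")
      return(out)
    }
    fit <- fit_mixture_em(x, n_restarts = n_restarts, tol = tol)
    ord <- order(fit$mu)  # component 2 = higher mean = hypersensitive
    w <- fit$w[ord]; mu <- fit$mu[ord]; sigma <- fit$sigma[ord]
    if (min(w) < 2 / n) {
      km <- kmeans(x, centers = 2, nstart = 5)
      threshold <- mean(range(km$centers))
      warn(sprintf(
        "degenerate mixture (weight %.3f < 2/n); falling back to threshold %.1f",
        min(w), threshold))
      fallback <- TRUE
      method <- "fixed_threshold"
    } else {
      d_t <- w[1] * dnorm(x, mu[1], sigma[1])
      d_h <- w[2] * dnorm(x, mu[2], sigma[2])
      posterior_hyper <- d_h / (d_t + d_h)
      subgroup <- ifelse(posterior_hyper > 0.5, "hypersensitive", "typical")
      components <- tibble(
        component = c("typical", "hypersensitive"),
        mean = mu, sd = sigma, weight = w)
      loglik <- fit$loglik
    }
  }
  if (method == "fixed_threshold") {
    if (is.null(threshold)) {
      abort("fixed_threshold mode needs a threshold",
            class = "gcm_validation_error")
    }
    subgroup <- ifelse(x > threshold, "hypersensitive", "typical")
    posterior_hyper <- as.numeric(x > threshold)
  }
  assignments <- tibble(sample_id = results$sample_id,
                        gc_subgroup = subgroup,
                        posterior_hypersensitive = posterior_hyper)
  structure(list(method = method, components = components,
                 assignments = assignments, threshold = threshold,
                 loglik = loglik, n = n, fallback = fallback),
            class = "gcm_subgroups")
}

#' @export
print.gcm_subgroups <- function(x, ...) {
  n_h <- sum(x$assignments$gc_subgroup == "hypersensitive")
  cat(sprintf("<GC subgroups (%s%s): %d hypersensitive / %d typical of %d cases>\n",
              x$method, if (x$fallback) ", fallback" else "",
              n_h, x$n - n_h, x$n))
  invisible(x)
}

#' @export
tidy.gcm_subgroups <- function(x, ...) {
  x$components %||%
    tibble(component = character(), mean = numeric(), sd = numeric(),
           weight = numeric())
}

#' @export
glance.gcm_subgroups <- function(x, ...) {
  tibble(method = x$method, loglik = x$loglik, n = x$n,
         n_hypersensitive = sum(x$assignments$gc_subgroup == "hypersensitive"),
         fallback = x$fallback)
}

#' @export
augment.gcm_subgroups <- function(x, ...) x$assignments

# Welch t-test row, tolerating constant or tiny groups
welch_row <- function(comparison, x1, x2) {
  if (length(x1) < 2 || length(x2) < 2) {
    return(tibble(comparison = comparison, n1 = length(x1), n2 = length(x2),
                  mean1 = mean(x1), mean2 = mean(x2),
                  statistic = NA_real_, p = NA_real_,
                  note = "group too small"))
  }
  if (sd(x1) == 0 && sd(x2) == 0) {
    return(tibble(comparison = comparison, n1 = length(x1), n2 = length(x2),
                  mean1 = mean(x1), mean2 = mean(x2),
                  statistic = if (mean(x1) == mean(x2)) 0 else NA_real_,
                  p = if (mean(x1) == mean(x2)) 1 else NA_real_,
                  note = "constant inhibition within groups"))
  }
  ht <- t.test(x1, x2)
  tibble(comparison = comparison, n1 = length(x1), n2 = length(x2),
         mean1 = mean(x1), mean2 = mean(x2),
         statistic = unname(ht$statistic), p = ht$p.value, note = NA_character_)
}

#' Group comparisons and covariate associations of GC sensitivity
#'
#' Two-tailed Welch t-tests of inhibition percentage for case vs control,
#' hypersensitive vs control, typical vs control and hypersensitive vs
#' typical; logistic regression of subgroup membership on onset type
#' (cases only); and Pearson correlations of inhibition percentage with
#' each RAND-36 category and with the overall quality-of-life score (PC1
#' of the RAND-36 PCA, computed over the assayed samples).
#'
#' @param results Per-subject inhibition tibble (from
#'   [assay_inhibition()]).
#' @param samples Sample sheet covering the assayed subjects.
#' @param subgroups A `gcm_subgroups` assignment for the case subjects.
#' @return A `gcm_gc_tests` list with tibbles `t_tests`, `onset_logit`
#'   and `correlations`. [tidy()] returns the t-test table.
#' @export
group_tests <- function(results, samples, subgroups) {
  stopifnot(inherits(subgroups, "gcm_subgroups"))
  df <- results |>
    inner_join(samples, by = "sample_id") |>
    left_join(subgroups$assignments |> select("sample_id", "gc_subgroup"),
              by = "sample_id", suffix = c(".sheet", "")) |>
    mutate(stratum = ifelse(.data$group == "control", "control",
                            .data$gc_subgroup))
  x_case <- df$inhibition_pct[df$group == "case"]
  x_ctrl <- df$inhibition_pct[df$group == "control"]
  x_hyp <- df$inhibition_pct[df$stratum == "hypersensitive"]
  x_typ <- df$inhibition_pct[df$stratum == "typical"]
  t_tests <- bind_rows(
    welch_row("case_vs_control", x_case, x_ctrl),
    welch_row("hypersensitive_vs_control", x_hyp, x_ctrl),
    welch_row("typical_vs_control", x_typ, x_ctrl),
    welch_row("hypersensitive_vs_typical", x_hyp, x_typ)
  )

  cases <- df |> filter(.data$group == "case", .data$onset != "not_applicable")
  onset_logit <- if (nrow(cases) >= 4 &&
                     n_distinct(cases$onset) == 2 &&
                     n_distinct(cases$gc_subgroup) == 2) {
    fit <- glm(I(gc_subgroup == "hypersensitive") ~ onset,
               data = cases, family = binomial())
    s <- summary(fit)$coefficients
    tibble(term = rownames(s), estimate = s[, 1], p = s[, 4])
  } else {
    tibble(term = character(), estimate = numeric(), p = numeric())
  }

  r36 <- intersect(rand36_cols(), names(df))
  correlations <- map(r36, function(col) {
    ct <- cor.test(df$inhibition_pct, df[[col]])
    tibble(variable = col, r = unname(ct$estimate), p = ct$p.value)
  }) |> list_rbind()
  if (length(r36) == length(rand36_cols()) &&
      all(complete.cases(df[r36])) && nrow(df) >= 3) {
    pca <- rand36_pca(df)
    pc1 <- pca$scores$PC1[match(df$sample_id, pca$scores$sample_id)]
    ct <- cor.test(df$inhibition_pct, pc1)
    correlations <- bind_rows(correlations,
                              tibble(variable = "rand36_pc1",
                                     r = unname(ct$estimate), p = ct$p.value))
  }
  structure(list(t_tests = t_tests, onset_logit = onset_logit,
                 correlations = correlations),
            class = "gcm_gc_tests")
}

#' @export
tidy.gcm_gc_tests <- function(x, ...) x$t_tests

#' @export
print.gcm_gc_tests <- function(x, ...) {
  cat("<GC sensitivity tests>\n")
  print(x$t_tests)
  invisible(x)
}

#' Three-comparison overlap of differentially methylated sites
#'
#' Given DM records (with permutation p-values joined in a `perm_p`
#' column) for the hypersensitive-vs-typical (HvT),
#' hypersensitive-vs-control (HvC) and typical-vs-control (TvC)
#' comparisons over the same probe universe, forms each comparison's
#' significant set — `|beta_diff| >= diff_min`, nominal `p <= alpha` and
#' permutation `p <= alpha` — and partitions their union into the seven
#' disjoint Venn regions. Derived sets:
#'
#' * `gc_sensitivity_loci` = (HvT intersect HvC) minus TvC — loci whose
#'   methylation tracks glucocorticoid hypersensitivity;
#' * `triple_overlap` = significant in all three comparisons;
#' * `mecfs_associated` = (HvC intersect TvC) minus HvT — case-wide loci;
#' * `typical_unique` = TvC minus the other two.
#'
#' The inclusive sensitivity set (HvT intersect HvC, triple overlap kept)
#' is also emitted as `gc_sensitivity_loci_inclusive`.
#'
#' @param dms_hvt,dms_hvc,dms_tvc Tibbles with `probe_id`, `beta_diff`,
#'   `p_wilcoxon`, `perm_p`.
#' @param alpha Nominal and permutation p threshold. Default 0.05.
#' @param diff_min Effect-size gate. Default 0.05.
#' @return A `gcm_venn` object: `$sets` (the three significant sets),
#'   `$regions` (seven disjoint counts), `$derived` (named probe-id
#'   vectors). [tidy()] returns the region-count tibble.
#' @export
three_way_overlap <- function(dms_hvt, dms_hvc, dms_tvc,
                              alpha = 0.05, diff_min = 0.05) {
  tabs <- list(HvT = dms_hvt, HvC = dms_hvc, TvC = dms_tvc)
  universe <- tabs[[1]]$probe_id
  for (nm in names(tabs)) {
    stop_if_missing_cols(tabs[[nm]],
                         c("probe_id", "beta_diff", "p_wilcoxon", "perm_p"),
                         paste("DM records", nm))
    if (!setequal(tabs[[nm]]$probe_id, universe)) {
      abort("the three comparisons cover different probe universes",
            class = "gcm_alignment_error")
    }
  }
  sets <- map(tabs, function(d) {
    d$probe_id[abs(d$beta_diff) >= diff_min &
                 d$p_wilcoxon <= alpha & d$perm_p <= alpha]
  })
  a <- sets$HvT; b <- sets$HvC; c_ <- sets$TvC
  triple <- intersect(intersect(a, b), c_)
  regions <- tibble(
    region = c("HvT_only", "HvC_only", "TvC_only",
               "HvT_HvC", "HvT_TvC", "HvC_TvC", "all_three"),
    count = c(
      length(setdiff(a, union(b, c_))),
      length(setdiff(b, union(a, c_))),
      length(setdiff(c_, union(a, b))),
      length(setdiff(intersect(a, b), c_)),
      length(setdiff(intersect(a, c_), b)),
      length(setdiff(intersect(b, c_), a)),
      length(triple)
    )
  )
  derived <- list(
    gc_sensitivity_loci = setdiff(intersect(a, b), c_),
    gc_sensitivity_loci_inclusive = intersect(a, b),
    triple_overlap = triple,
    mecfs_associated = setdiff(intersect(b, c_), a),
    typical_unique = setdiff(c_, union(a, b))
  )
  structure(list(sets = sets, regions = regions, derived = derived,
                 alpha = alpha, diff_min = diff_min),
            class = "gcm_venn")
}

#' @export
print.gcm_venn <- function(x, ...) {
  cat(sprintf(
    "<three-way DM overlap: |HvT| = %d, |HvC| = %d, |TvC| = %d; %d GC-sensitivity loci>\n",
    length(x$sets$HvT), length(x$sets$HvC), length(x$sets$TvC),
    length(x$derived$gc_sensitivity_loci)))
  invisible(x)
}

#' @export
tidy.gcm_venn <- function(x, ...) x$regions

#' Methylation magnitude of the hypersensitive stratum vs pooled reference
#'
#' Percentage-point difference between the hypersensitive stratum mean
#' beta and the unweighted average of the typical-case and control
#' stratum means: `(hyper - (typical + control) / 2) * 100`.
#'
#' @param hyper,typical,control Stratum mean beta-values. Vectorised.
#' @return Percentage-point difference(s).
#' @examples
#' magnitude_vs_pooled_reference(0.440, 0.318, 0.276)  # 14.3
#' @export
magnitude_vs_pooled_reference <- function(hyper, typical, control) {
  (hyper - (typical + control) / 2) * 100
}

#' Per-probe stratum means and pooled-reference magnitude
#'
#' Computes the hypersensitive, typical and control stratum mean
#' beta-values for the requested probes and the percentage-point
#' magnitude of the hypersensitive stratum against the pooled reference
#' (see [magnitude_vs_pooled_reference()]).
#'
#' @param beta A [beta_matrix()].
#' @param strata Tibble with `sample_id` and `stratum` in
#'   \{hypersensitive, typical, control\}; all three strata non-empty.
#' @param probes Probe ids (default: all probes in `beta`).
#' @return Tibble with per-probe stratum means and `magnitude_pct`,
#'   sorted by decreasing absolute magnitude.
#' @export
gc_site_magnitude <- function(beta, strata, probes = probe_ids(beta)) {
  stopifnot(inherits(beta, "gcm_beta"))
  stop_if_missing_cols(strata, c("sample_id", "stratum"), "strata")
  missing_probes <- setdiff(probes, probe_ids(beta))
  if (length(missing_probes) > 0) {
    abort(sprintf("probe(s) not in beta matrix: %s",
                  paste(head(missing_probes, 3), collapse = ", ")),
          class = "gcm_validation_error")
  }
  strata <- strata |> filter(.data$sample_id %in% sample_ids(beta))
  groups <- split(strata$sample_id, strata$stratum)
  need <- c("hypersensitive", "typical", "control")
  if (!all(need %in% names(groups)) ||
      any(lengths(groups[need]) == 0)) {
    abort("all three strata (hypersensitive, typical, control) must be non-empty",
          class = "gcm_validation_error")
  }
  v <- beta$values[probes, , drop = FALSE]
  means <- vapply(need, function(s) {
    rowMeans(v[, groups[[s]], drop = FALSE])
  }, numeric(length(probes)))
  if (length(probes) == 1) means <- matrix(means, 1,
                                           dimnames = list(probes, need))
  tibble(
    probe_id = probes,
    mean_hypersensitive = means[, "hypersensitive"],
    mean_typical = means[, "typical"],
    mean_control = means[, "control"],
    magnitude_pct = magnitude_vs_pooled_reference(
      means[, "hypersensitive"], means[, "typical"], means[, "control"])
  ) |>
    arrange(desc(abs(.data$magnitude_pct)))
}
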