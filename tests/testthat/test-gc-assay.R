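test_that("inhibition percentage arithmetic and scale invariance", {
  expect_equal(inhibition_percent(2.0, 0.5), 75)
  expect_equal(inhibition_percent(1.5, 1.5), 0)
  expect_equal(inhibition_percent(1.2, 0), 100)
  expect_equal(inhibition_percent(1, 1.5), -50)  # may be negative
  expect_equal(inhibition_percent(3 * 2.0, 3 * 0.5), 75)  # scale-invariant
  expect_error(inhibition_percent(0, 0.5), class = "gcm_validation_error")
})

test_that("plate aggregation averages triplicates and flags high CV", {
  plate <- tidyr::expand_grid(
    sample_id = c("P1", "P2"),
    condition = c("control", "stimulated", "suppressed"),
    replicate = 1:3)
  plate$od <- c(0.30, 0.31, 0.29, 2.0, 2.0, 2.0, 0.5, 0.5, 0.5,
                0.30, 0.30, 0.30, 1.0, 1.0, 1.0, 0.2, 0.9, 0.4)
  expect_warning(out <- assay_inhibition(plate), "CV")
  expect_equal(out$inhibition_pct[out$sample_id == "P1"], 75)
  expect_equal(out$mean_suppressed_od[out$sample_id == "P2"], 0.5)
})

test_that("mixture EM recovers planted bimodal subgroups", {
  set.seed(19)
  truth <- rep(c("hypersensitive", "typical"), c(14, 19))
  x <- c(rnorm(14, 85, 3), rnorm(19, 45, 5))
  res <- tibble::tibble(sample_id = sprintf("C%02d", 1:33), inhibition_pct = x)
  fit <- assign_subgroups(res, seed = 4)
  expect_gte(mean(fit$assignments$gc_subgroup == truth), 0.95)
  comp <- tidy(fit)
  expect_gt(comp$mean[comp$component == "hypersensitive"],
            comp$mean[comp$component == "typical"])
  expect_lt(abs(comp$mean[comp$component == "hypersensitive"] - 85), 4)
})

test_that("EM agrees with an independent mixture implementation", {
  set.seed(23)
  x <- c(rnorm(15, 80, 5), rnorm(20, 47, 6))
  res <- tibble::tibble(sample_id = sprintf("C%02d", 1:35), inhibition_pct = x)
  ours <- assign_subgroups(res, seed = 5)
  withr::local_package("mclust")
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  hyper_comp <- which.max(mc$parameters$mean)
  theirs <- ifelse(mc$classification == hyper_comp, "hypersensitive", "typical")
  expect_gte(mean(ours$assignments$gc_subgroup == theirs), 0.95)
})

test_that("degenerate inputs fall back to a threshold assignment", {
  res <- tibble::tibble(sample_id = sprintf("C%02d", 1:6),
                        inhibition_pct = rep(50, 6))
  expect_warning(fit <- assign_subgroups(res, seed = 1), "identical")
  expect_true(all(fit$assignments$gc_subgroup == "typical"))
  expect_true(fit$fallback)
  expect_error(assign_subgroups(res[1:3, ]), class = "gcm_validation_error")
})

test_that("fixed-threshold mode splits at the supplied cutoff", {
  res <- tibble::tibble(sample_id = c("C1", "C2"),
                        inhibition_pct = c(50, 70))
  fit <- assign_subgroups(res, method = "fixed_threshold", threshold = 65)
  expect_equal(fit$assignments$gc_subgroup, c("typical", "hypersensitive"))
  expect_error(assign_subgroups(res, method = "fixed_threshold"),
               class = "gcm_validation_error")
})

test_that("group tests report Welch comparisons and associations", {
  sim <- small_sim(seed = 25, n_probes = 50)
  inh <- assay_inhibition(sim$assay)
  cases <- sim$samples$sample_id[sim$samples$group == "case"]
  fit <- assign_subgroups(inh |> dplyr::filter(sample_id %in% cases), seed = 2)
  tests <- group_tests(inh, sim$samples, fit)
  tt <- tidy(tests)
  expect_setequal(tt$comparison,
                  c("case_vs_control", "hypersensitive_vs_control",
                    "typical_vs_control", "hypersensitive_vs_typical"))
  # hypersensitive cases clearly exceed controls under the default design
  expect_lte(tt$p[tt$comparison == "hypersensitive_vs_control"], 0.05)
  expect_gt(tt$mean1[tt$comparison == "hypersensitive_vs_control"],
            tt$mean2[tt$comparison == "hypersensitive_vs_control"])
  expect_true(all(c("r", "p") %in% names(tests$correlations)))
  expect_true("rand36_pc1" %in% tests$correlations$variable)
})

test_that("identical groups give t = 0, p = 1 and constant groups a note", {
  res <- tibble::tibble(sample_id = sprintf("X%02d", 1:8),
                        inhibition_pct = rep(42, 8))
  samples <- tibble::tibble(
    sample_id = res$sample_id,
    group = rep(c("case", "control"), each = 4),
    gc_subgroup = rep(c("typical", "unknown"), each = 4),
    age = 50, bmi = 23, batch = "B1", onset = "not_applicable")
  fit <- assign_subgroups(res[1:4, ], method = "fixed_threshold",
                          threshold = 100)
  tt <- tidy(group_tests(res, samples, fit))
  row <- tt[tt$comparison == "case_vs_control", ]
  expect_equal(row$statistic, 0)
  expect_equal(row$p, 1)
  expect_match(row$note, "constant")
})

test_that("a planted case shift is detected with high power at study size", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    x_case <- rnorm(33, 60, 15)
    x_ctrl <- rnorm(24, 45, 15)
    t.test(x_case, x_ctrl)$p.value <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("three-way overlap performs the documented set algebra", {
  universe <- c("a", "b", "c", "d", "e")
  mk <- function(sig) tibble::tibble(
    probe_id = universe,
    beta_diff = ifelse(universe %in% sig, 0.1, 0.01),
    p_wilcoxon = ifelse(universe %in% sig, 0.01, 0.9),
    perm_p = ifelse(universe %in% sig, 0.01, 0.9))
  vn <- three_way_overlap(mk(c("a", "b", "c")), mk(c("b", "c", "d")),
                          mk("c"))
  expect_equal(vn$derived$gc_sensitivity_loci, "b")
  expect_equal(vn$derived$triple_overlap, "c")
  expect_length(vn$derived$mecfs_associated, 0)
  expect_length(vn$derived$typical_unique, 0)
  expect_setequal(vn$derived$gc_sensitivity_loci_inclusive, c("b", "c"))
  # the seven disjoint regions partition the union
  expect_equal(sum(vn$regions$count), length(unique(c("a","b","c","d"))))

  empty <- three_way_overlap(mk(character()), mk(character()), mk(character()))
  expect_true(all(empty$regions$count == 0))
  expect_error(three_way_overlap(mk("a"), mk("a")[1:3, ], mk("a")),
               class = "gcm_alignment_error")
})

test_that("hypersensitive magnitude against the pooled reference strata", {
  expect_equal(magnitude_vs_pooled_reference(0.440, 0.318, 0.276), 14.3)
  expect_equal(magnitude_vs_pooled_reference(0.762, 0.636, 0.614), 13.7)
  expect_equal(magnitude_vs_pooled_reference(0.5, 0.5, 0.5), 0)

  v <- rbind(cgX = c(0.44, 0.44, 0.32, 0.32, 0.27, 0.28))
  colnames(v) <- sprintf("s%d", 1:6)
  strata <- tibble::tibble(
    sample_id = colnames(v),
    stratum = rep(c("hypersensitive", "typical", "control"), each = 2))
  out <- gc_site_magnitude(beta_matrix(v), strata)
  expect_equal(out$magnitude_pct,
               magnitude_vs_pooled_reference(0.44, 0.32, 0.275))
  expect_error(gc_site_magnitude(beta_matrix(v), strata[1:4, ]),
               class = "gcm_validation_error")
  expect_error(gc_site_magnitude(beta_matrix(v), strata, "cgZ"),
               class = "gcm_validation_error")
})
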