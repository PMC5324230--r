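test_that("null design plants nothing and the group difference is noise", {
  sim <- small_sim(seed = 3, n_probes = 600, dm_fraction = 0, gc_loci = 0)
  expect_equal(nrow(sim$truth$dm), 0)
  grp <- sim$samples$group
  d <- rowMeans(sim$beta$values[, grp == "case"]) -
    rowMeans(sim$beta$values[, grp == "control"])
  expect_lt(median(abs(d)), 0.02)
})

test_that("planted case-vs-control effects are recovered empirically", {
  sim <- small_sim(seed = 5, n_probes = 1000, dm_fraction = 0.1,
                   delta_grid = 0.15, hyper_fraction = 1, gc_loci = 0)
  tr <- sim$truth$dm
  expect_equal(nrow(tr), 100)
  grp <- sim$samples$group
  d <- rowMeans(sim$beta$values[tr$probe_id, grp == "case"]) -
    rowMeans(sim$beta$values[tr$probe_id, grp == "control"])
  expect_lt(abs(mean(d) - 0.15), 0.03)
})

test_that("hypermethylated fraction of planted effects follows the design", {
  sim <- small_sim(seed = 9, n_probes = 4000, dm_fraction = 0.25)
  frac <- mean(sim$truth$dm$delta > 0)
  expect_lt(abs(frac - 0.716), 0.035)
  # recovered exactly from the truth table
  expect_identical(sim$truth$dm$direction,
                   ifelse(sim$truth$dm$delta > 0, "hyper", "hypo"))
})

test_that("emitted tables satisfy the data-model invariants", {
  sim <- small_sim(seed = 11, n_probes = 300)
  expect_s3_class(sim$beta, "gcm_beta")   # constructor validated on build
  expect_silent(validate_sample_sheet(sim$samples))
  expect_silent(validate_probe_annotation(sim$annotation))
  expect_true(all(sim$beta$values > 0 & sim$beta$values < 1))
  # truth tables cover every planted class
  expect_true(all(sim$truth$gc$probe_id %in% sim$annotation$probe_id))
  expect_equal(sort(sim$truth$snp),
               sort(sim$annotation$probe_id[sim$annotation$snp_flag]))
})

test_that("fixing the seed fixes every emitted value", {
  a <- small_sim(seed = 21, n_probes = 200)
  b <- small_sim(seed = 21, n_probes = 200)
  expect_identical(a$beta$values, b$beta$values)
  expect_identical(a$beta$detection, b$beta$detection)
  expect_identical(a$samples, b$samples)
  expect_identical(a$assay, b$assay)
  c <- small_sim(seed = 22, n_probes = 200)
  expect_false(identical(a$beta$values, c$beta$values))
})

test_that("assay plate reproduces the designed control inhibition mode", {
  d <- sim_design(n_probes = 50, seed = 13,
                  inhibition_params = list(control = c(mean = 40, sd = 5),
                                           typical = c(mean = 48, sd = 7),
                                           hypersensitive = c(mean = 82, sd = 5)))
  sim <- simulate_study(d)
  inh <- assay_inhibition(sim$assay)
  ctrl <- inh$inhibition_pct[inh$sample_id %in%
                               sim$samples$sample_id[sim$samples$group == "control"]]
  expect_length(ctrl, 24)
  expect_lt(abs(mean(ctrl) - 40), 3)
})

test_that("case inhibition is bimodal by default, unimodal when designed so", {
  sim_bi <- small_sim(seed = 17, n_probes = 50)
  sim_uni <- small_sim(seed = 17, n_probes = 50, fraction_hypersensitive = 0)
  case_ids <- function(s) s$samples$sample_id[s$samples$group == "case"]
  x_bi <- assay_inhibition(sim_bi$assay)
  x_bi <- x_bi$inhibition_pct[x_bi$sample_id %in% case_ids(sim_bi)]
  x_uni <- assay_inhibition(sim_uni$assay)
  x_uni <- x_uni$inhibition_pct[x_uni$sample_id %in% case_ids(sim_uni)]
  withr::local_package("mclust")
  bic_pref <- function(x) {
    b <- mclustBIC(x, G = 1:2, modelNames = "V", verbose = FALSE)
    which.max(apply(b, 1, max, na.rm = TRUE))
  }
  expect_equal(unname(bic_pref(x_bi)), 2)
  expect_equal(unname(bic_pref(x_uni)), 1)
})

test_that("suppressed OD equal to stimulated gives zero inhibition", {
  plate <- tidyr::expand_grid(sample_id = "P1",
                              condition = c("control", "stimulated", "suppressed"),
                              replicate = 1:3)
  plate$od <- ifelse(plate$condition == "control", 0.3, 1.5)
  out <- assay_inhibition(plate)
  expect_equal(out$inhibition_pct, 0)
})

test_that("RAND-36 generator matches its reference parameters", {
  d <- sim_design(n_probes = 50, seed = 1)
  base <- tibble::tibble(sample_id = sprintf("S%03d", 1:74),
                         group = rep(c("case", "control"), c(49, 25)))
  # zero-variance design reproduces the means exactly
  ref0 <- rand36_reference()
  ref0$case_se <- 0; ref0$control_se <- 0
  d0 <- sim_design(n_probes = 50, rand36 = ref0)
  out0 <- simulate_rand36(d0, base, seed = 2)
  expect_equal(unique(out0$rand36_physical_functioning[out0$group == "case"]),
               40.6)
  expect_equal(unique(out0$rand36_energy[out0$group == "control"]), 71.7)
  # stochastic defaults recover the case mean across replicates
  means <- vapply(1:30, function(s) {
    out <- simulate_rand36(d, base, seed = s)
    mean(out$rand36_physical_functioning[out$group == "case"])
  }, numeric(1))
  expect_lt(abs(mean(means) - 40.6), 2.5)
})

test_that("design validation rejects impossible requests", {
  expect_error(sim_design(dm_fraction = 1.2), class = "gcm_validation_error")
  expect_error(sim_design(n_probes = 100, dm_fraction = 0.95, gc_loci = 50),
               "planted", class = "gcm_validation_error")
  expect_error(sim_design(delta_grid = c(0.1, 1.5)),
               class = "gcm_validation_error")
  expect_error(sim_design(n_assay_cases = 60), class = "gcm_validation_error")
})
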