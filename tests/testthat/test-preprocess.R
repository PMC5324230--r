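make_filter_fixture <- function() {
  # 5 probes: detection failure, SNP, invariant-high, boundary 0.95, clean
  v <- rbind(
    cgDET = c(0.5, 0.5, 0.5, 0.5),
    cgSNP = c(0.5, 0.5, 0.5, 0.5),
    cgINV = c(0.96, 0.96, 0.96, 0.96),
    cgBND = c(0.95, 0.95, 0.95, 0.95),
    cgOK  = c(0.4, 0.5, 0.6, 0.5)
  )
  colnames(v) <- paste0("s", 1:4)
  d <- matrix(0.001, 5, 4, dimnames = dimnames(v))
  d["cgDET", 2] <- 0.2
  ann <- tiny_annotation(rownames(v),
                         snp = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  list(beta = beta_matrix(v, d), annot = ann)
}

test_that("filtering applies the exclusion cascade with inclusive bounds", {
  fx <- make_filter_fixture()
  out <- filter_probes(fx$beta, fx$annot)
  r <- out$report
  expect_equal(r$removed$detection, "cgDET")
  expect_equal(r$removed$snp, "cgSNP")
  expect_setequal(r$removed$invariant, c("cgINV", "cgBND"))  # 0.95 inclusive
  expect_equal(probe_ids(out$beta), "cgOK")
  expect_equal(r$n_input_probes,
               r$n_retained + r$n_removed_detection + r$n_removed_snp +
                 r$n_removed_invariant + r$n_removed_missing)
})

test_that("each probe is counted once, under the first rule that removes it", {
  fx <- make_filter_fixture()
  # make the SNP probe also fail detection: it must fall under detection
  fx$beta$detection["cgSNP", 1] <- 0.5
  out <- filter_probes(fx$beta, fx$annot)
  expect_setequal(out$report$removed$detection, c("cgDET", "cgSNP"))
  expect_equal(out$report$n_removed_snp, 0)
})

test_that("probes with missing betas are removed and counted", {
  fx <- make_filter_fixture()
  v <- fx$beta$values
  v["cgOK", 2] <- NA
  b <- beta_matrix(v, fx$beta$detection)
  out <- filter_probes(b, fx$annot)
  expect_equal(out$report$removed$missing, "cgOK")
  expect_equal(out$report$n_retained, 0)
})

test_that("filtering is idempotent", {
  sim <- small_sim(seed = 2, n_probes = 400)
  once <- filter_probes(sim$beta, sim$annotation)
  twice <- filter_probes(once$beta, sim$annotation)
  expect_equal(twice$report$n_retained, once$report$n_retained)
  expect_equal(twice$report$n_removed_detection +
                 twice$report$n_removed_snp +
                 twice$report$n_removed_invariant +
                 twice$report$n_removed_missing, 0)
})

test_that("the detection rule requires a detection matrix", {
  b <- tiny_beta(3, 4)
  expect_error(filter_probes(b, NULL), class = "gcm_config_error")
  expect_s3_class(filter_probes(b, NULL, use_detection = FALSE)$beta,
                  "gcm_beta")
})

test_that("single-batch adjustment is the identity up to clipping", {
  sim <- small_sim(seed = 4, n_probes = 200, n_batches = 1)
  filt <- filter_probes(sim$beta, sim$annotation)
  adj <- adjust_batch_covariates(filt$beta, sim$samples)
  expect_lt(max(abs(adj$values - filt$beta$values)), 1e-6)
})

test_that("planted batch offsets are removed, planted group effects kept", {
  sim <- small_sim(seed = 6, n_probes = 800, dm_fraction = 0.05,
                   delta_grid = 0.15, batch_shift = 0.5)
  filt <- filter_probes(sim$beta, sim$annotation)
  v <- filt$beta$values
  batch <- sim$samples$batch[match(colnames(v), sim$samples$sample_id)]
  gap <- function(m) mean(abs(rowMeans(m[, batch == "B1", drop = FALSE]) -
                                rowMeans(m[, batch == "B2", drop = FALSE])))
  adj <- adjust_batch_covariates(filt$beta, sim$samples)
  expect_lt(gap(adj$values), 0.1 * gap(v))          # >= 90% reduction
  expect_identical(dimnames(adj$values), dimnames(v))
  expect_true(all(adj$values >= 0 & adj$values <= 1))

  grp <- sim$samples$group[match(colnames(v), sim$samples$sample_id)]
  planted <- intersect(sim$truth$dm$probe_id, rownames(v))
  diff_after <- rowMeans(adj$values[planted, grp == "case"]) -
    rowMeans(adj$values[planted, grp == "control"])
  truth <- sim$truth$dm$delta[match(planted, sim$truth$dm$probe_id)]
  expect_lt(mean(abs(diff_after - truth)), 0.02)
})

test_that("degenerate adjustment inputs raise informative errors", {
  sim <- small_sim(seed = 8, n_probes = 100)
  filt <- filter_probes(sim$beta, sim$annotation)
  s <- sim$samples
  s$batch <- c("Bsolo", rep("B1", nrow(s) - 1))
  expect_error(adjust_batch_covariates(filt$beta, s), "Bsolo",
               class = "gcm_validation_error")
  s2 <- sim$samples
  s2$bmi <- s2$age  # perfectly collinear
  expect_error(adjust_batch_covariates(filt$beta, s2,
                                       covariates = c("age", "bmi")),
               "collinear", class = "gcm_validation_error")
  na_beta <- filt$beta
  na_beta$values[1, 1] <- NA
  expect_error(adjust_batch_covariates(na_beta, sim$samples),
               class = "gcm_validation_error")
})
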