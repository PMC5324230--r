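test_that("PCA satisfies its algebraic invariants", {
  sim <- small_sim(seed = 27, n_probes = 50)
  pca <- rand36_pca(sim$samples)
  expect_equal(sum(pca$variance_explained), 1)
  expect_true(all(diff(pca$variance_explained) <= 1e-12))
  expect_equal(crossprod(pca$loadings), diag(8), tolerance = 1e-8,
               ignore_attr = TRUE)
  # orientation: controls (better health) score higher on PC1
  sc <- pca$scores
  expect_gt(mean(sc$PC1[sc$group == "control"]),
            mean(sc$PC1[sc$group == "case"]))
  expect_gt(pca$loadings["rand36_general_health", 1], 0)
})

test_that("PC1 separates the clinical groups under the default design", {
  sim <- small_sim(seed = 29, n_probes = 50)
  pca <- rand36_pca(sim$samples)
  sc <- pca$scores
  cut <- (mean(sc$PC1[sc$group == "case"]) +
            mean(sc$PC1[sc$group == "control"])) / 2
  misclass <- mean(c(sc$PC1[sc$group == "case"] > cut,
                     sc$PC1[sc$group == "control"] < cut))
  expect_lte(misclass, 0.05)
})

test_that("degenerate score geometry is handled as specified", {
  base <- tiny_samples(4, 4)
  for (k in rand36_cols()) base[[k]] <- 50
  expect_error(rand36_pca(base), "zero-variance",
               class = "gcm_validation_error")
  # scores on a single line through category space: PC1 carries everything
  t <- seq(10, 90, length.out = 8)
  for (i in seq_along(rand36_cols())) {
    base[[rand36_cols()[i]]] <- t * (0.5 + i / 10)
  }
  pca <- rand36_pca(base)
  expect_equal(pca$variance_explained[1], 1, tolerance = 1e-10)
})

test_that("identical group means give no systematic PC1 separation", {
  ref <- rand36_reference()
  ref$control_mean <- ref$case_mean
  d <- sim_design(n_probes = 50, rand36 = ref)
  base <- tibble::tibble(sample_id = sprintf("S%03d", 1:74),
                         group = rep(c("case", "control"), c(49, 25)))
  seps <- vapply(1:20, function(s) {
    out <- simulate_rand36(d, base, seed = s)
    pca <- rand36_pca(out)
    t.test(PC1 ~ group, data = pca$scores)$p.value
  }, numeric(1))
  expect_gt(mean(seps <= 0.05), 0)   # a few false positives are expected...
  expect_lt(mean(seps <= 0.05), 0.3) # ...but no systematic separation
})

region_fixture <- function(diffs, genes = "GENE1", region = "TSS200") {
  p <- length(diffs)
  probes <- sprintf("cg%03d", seq_len(p))
  v <- matrix(runif(p * 6, 0.3, 0.7), p, 6,
              dimnames = list(probes, sprintf("s%02d", 1:6)))
  samples <- tibble::tibble(sample_id = colnames(v),
                            group = rep(c("case", "control"), each = 3))
  dms <- tibble::tibble(probe_id = probes, beta_diff = diffs)
  ann <- tiny_annotation(probes, gene = genes, region = region)
  list(dms = dms, ann = ann, beta = beta_matrix(v), samples = samples)
}

test_that("regions require two qualifying sites in the same gene region", {
  set.seed(33)
  fx <- region_fixture(c(0.06, 0.07))
  rs <- define_regions(fx$dms, fx$ann, fx$beta, fx$samples)
  expect_equal(nrow(rs$regions), 1)
  expect_equal(rs$regions$n_sites, 2)

  fx2 <- region_fixture(c(0.06, 0.03))
  rs2 <- define_regions(fx2$dms, fx2$ann, fx2$beta, fx2$samples)
  expect_equal(nrow(rs2$regions), 0)

  fx3 <- region_fixture(c(-0.06, -0.07))  # magnitude rule is sign-symmetric
  rs3 <- define_regions(fx3$dms, fx3$ann, fx3$beta, fx3$samples)
  expect_equal(nrow(rs3$regions), 1)
})

test_that("region methylation is the mean of member probes, per sample", {
  set.seed(35)
  fx <- region_fixture(c(0.08, 0.09, 0.1))
  rs <- define_regions(fx$dms, fx$ann, fx$beta, fx$samples)
  expect_equal(rs$methylation[1, ], colMeans(fx$beta$values),
               tolerance = 1e-12)
  expect_equal(rs$regions$beta_diff,
               rs$regions$mean_case - rs$regions$mean_control)
})

test_that("multi-gene probes contribute to each annotated gene once", {
  set.seed(37)
  fx <- region_fixture(c(0.06, 0.07, 0.08),
                       genes = c("GENE1;GENE2", "GENE1", "GENE2"))
  rs <- define_regions(fx$dms, fx$ann, fx$beta, fx$samples)
  expect_setequal(rs$regions$gene, c("GENE1", "GENE2"))
  # no probe appears twice within one region
  expect_true(all(vapply(rs$regions$probe_ids,
                         function(p) !anyDuplicated(p), logical(1))))
})

test_that("a perfectly linear region has R-squared one", {
  set.seed(39)
  fx <- region_fixture(c(0.06, 0.07))
  pc1 <- tibble::tibble(sample_id = sprintf("s%02d", 1:6),
                        pc1 = c(-2, -1, 0, 1, 2, 3))
  rs <- define_regions(fx$dms, fx$ann, fx$beta, fx$samples)
  # force methylation to be exactly linear in the score
  rs$methylation[1, ] <- 0.3 + 0.02 * pc1$pc1
  fit <- region_qol_regression(rs, pc1)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # affine rescaling of the score leaves R-squared unchanged
  fit2 <- region_qol_regression(
    rs, pc1 |> dplyr::mutate(pc1 = 10 * pc1 + 3))
  expect_equal(fit2$r_squared, fit$r_squared, tolerance = 1e-10)
  expect_error(region_qol_regression(rs, pc1[1:2, ]),
               class = "gcm_validation_error")
})

test_that("null regions are rarely called and planted R-squared is recovered", {
  set.seed(41)
  n <- 74; m <- 150
  pc1 <- tibble::tibble(sample_id = sprintf("S%03d", 1:n),
                        pc1 = rnorm(n))
  mk_regions <- function(meth) {
    regions <- tibble::tibble(
      region_id = rownames(meth), gene = rownames(meth),
      genic_region = "TSS200", n_sites = 2L,
      probe_ids = replicate(nrow(meth), c("x", "y"), simplify = FALSE),
      mean_case = rowMeans(meth), mean_control = rowMeans(meth),
      beta_diff = 0.06)
    structure(list(regions = regions, methylation = meth),
              class = "gcm_regions")
  }
  # planted null: methylation independent of the score
  null_meth <- matrix(runif(m * n, 0.3, 0.5), m, n,
                      dimnames = list(sprintf("R%03d", 1:m), pc1$sample_id))
  null_fit <- region_qol_regression(mk_regions(null_meth), pc1)
  expect_lte(mean(null_fit$q_fdr <= 0.05), 0.05)
  # planted signal at R-squared 0.22
  r2 <- 0.22
  z <- scale(pc1$pc1)[, 1]
  sig_meth <- t(vapply(seq_len(m), function(i) {
    y <- sqrt(r2) * z + sqrt(1 - r2) * rnorm(n)
    0.4 + 0.05 * y
  }, numeric(n)))
  dimnames(sig_meth) <- dimnames(null_meth)
  sig_fit <- region_qol_regression(mk_regions(sig_meth), pc1)
  expect_lt(abs(mean(sig_fit$r_squared) - r2), 0.08)
  expect_true(all(diff(sig_fit$r_squared) <= 1e-12))  # sorted descending
})
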