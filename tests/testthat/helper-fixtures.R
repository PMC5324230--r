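# fixture builders and independent oracles used across the suite

tiny_beta <- function(p = 4, n = 6, seed = 1, detection = FALSE) {
  set.seed(seed)
  v <- matrix(runif(p * n, 0.1, 0.9), p, n,
              dimnames = list(sprintf("cg%03d", seq_len(p)),
                              sprintf("s%02d", seq_len(n))))
  d <- if (detection) matrix(runif(p * n, 0, 0.005), p, n,
                             dimnames = dimnames(v)) else NULL
  beta_matrix(v, d)
}

tiny_samples <- function(n_case = 3, n_control = 3) {
  n <- n_case + n_control
  tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n)),
    group = rep(c("case", "control"), c(n_case, n_control)),
    age = 45 + seq_len(n), bmi = 23 + seq_len(n) / 10,
    batch = rep_len(c("B1", "B2"), n)
  )
}

tiny_annotation <- function(probes, snp = rep(FALSE, length(probes)),
                            gene = "GENE1", region = "TSS200",
                            island = "Island") {
  tibble::tibble(
    probe_id = probes,
    gene_symbols = rep_len(gene, length(probes)),
    genic_region = rep_len(region, length(probes)),
    island_relation = rep_len(island, length(probes)),
    snp_flag = snp
  )
}

# Exhaustive two-sided rank-sum p-value: enumerate every assignment of the
# pooled observations into groups of the observed sizes, tabulate the
# Mann-Whitney U statistic, and report 2 * min(P(U <= u), P(U >= u)),
# capped at 1 (the exact-test convention).
oracle_wilcoxon_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_stat <- function(ix) {
    a <- pooled[ix]; b <- pooled[-ix]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_stat(seq_len(n1))
  us <- apply(utils::combn(length(pooled), n1), 2, u_stat)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Exhaustive permutation p per probe: all distinct assignments of n1
# columns to group 1, two-sided on the absolute mean difference.
oracle_perm_p <- function(values, n1) {
  n <- ncol(values)
  parts <- utils::combn(n, n1)
  diffs <- apply(parts, 2, function(ix) {
    rowMeans(values[, ix, drop = FALSE]) -
      rowMeans(values[, -ix, drop = FALSE])
  })
  if (is.null(dim(diffs))) diffs <- matrix(diffs, nrow = 1)
  obs <- diffs[, 1]  # first partition is the observed labelling
  vapply(seq_len(nrow(values)), function(i) {
    mean(abs(diffs[i, ]) >= abs(obs[i]) - 1e-12)
  }, numeric(1))
}

# small fully-specified simulation used by several files
small_sim <- function(seed = 7, n_probes = 800, ...) {
  simulate_study(sim_design(n_probes = n_probes, seed = seed, ...))
}
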