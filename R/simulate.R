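#' Reference RAND-36 group parameters
#'
#' Published cohort means and standard errors of the eight RAND-36
#' categories for ME/CFS cases (n = 49) and healthy controls (n = 25),
#' used as the simulator's default quality-of-life parameters.
#'
#' @return A tibble with columns `category`, `case_mean`, `case_se`,
#'   `control_mean`, `control_se`.
#' @export
rand36_reference <- function() {
  tibble(
    category = rand36_cols(),
    case_mean    = c(40.6,  7.7, 55.9, 25.2, 16.9, 33.0, 71.4, 73.2),
    case_se      = c( 3.9,  3.1,  3.6,  2.3,  2.3,  3.7,  5.9,  2.4),
    control_mean = c(95.3, 96.9, 90.0, 81.8, 71.7, 91.9, 84.5, 80.6),
    control_se   = c( 1.4,  2.2,  1.8,  2.4,  2.5,  2.4,  5.4,  2.6)
  )
}

#' Specify a synthetic methylation study design
#'
#' Captures every parameter of the synthetic-data generator. Defaults
#' mirror the study dimensions the pipeline targets: 49 female cases and
#' 25 controls on a 450K-like array; a dexamethasone-assay subset of 33
#' cases and 24 controls; a case subgroup split of 14 glucocorticoid-
#' hypersensitive vs 19 typical; 71.6% of planted case-vs-control effects
#' hypermethylated; RAND-36 score parameters from [rand36_reference()]
#' (standard errors converted to standard deviations by the group square
#' root of n).
#'
#' Beta-values are generated additively on the logit scale (baseline +
#' planted group effect + batch offset + noise) and mapped back through
#' the inverse logit, which keeps them inside (0, 1) without clipping.
#' Planted effect sizes are expressed as target beta-scale differences;
#' the generator converts them to the equivalent logit offset at each
#' probe's baseline.
#'
#' @param n_probes Number of array probes.
#' @param n_cases,n_controls Cohort sizes.
#' @param n_assay_cases,n_assay_controls Sizes of the suppression-assay
#'   subset (taken from the head of each group).
#' @param fraction_hypersensitive Fraction of assay cases in the
#'   glucocorticoid-hypersensitive subgroup.
#' @param n_batches Number of array batches (samples assigned cyclically).
#' @param batch_shift Additive logit-scale offset of each batch relative
#'   to batch 1; recycled to `n_batches - 1` values.
#' @param dm_fraction Fraction of probes carrying a planted case-vs-control
#'   effect.
#' @param delta_grid Magnitudes (beta scale) that planted case effects are
#'   drawn from, uniformly.
#' @param hyper_fraction Probability that a planted case effect is
#'   hypermethylated (positive).
#' @param gc_loci Number of probes with a planted hypersensitive-specific
#'   effect.
#' @param gc_delta Beta-scale magnitude of the hypersensitive-specific
#'   effect.
#' @param gc_hyper_fraction Probability a hypersensitive-specific effect
#'   is positive.
#' @param invariant_fraction Fraction of probes drawn near 0 or 1
#'   (invariably methylated / unmethylated).
#' @param snp_fraction Fraction of probes flagged as SNP-overlapping.
#' @param detection_fail_fraction Fraction of probes given a failing
#'   detection p-value (> 0.01) in at least one sample.
#' @param noise_sd Logit-scale within-group standard deviation
#'   (0.08 corresponds to a beta-scale SD of about 0.02 at beta = 0.5,
#'   typical of 450K within-group dispersion).
#' @param rand36 Data frame of per-category group parameters in the layout
#'   of [rand36_reference()].
#' @param inhibition_params Named list of `c(mean, sd)` inhibition-%
#'   parameters for the `control`, `typical` and `hypersensitive` modes.
#' @param od_unstimulated,od_stimulated Mean optical densities of the
#'   unstimulated and PHA-stimulated culture conditions.
#' @param od_subject_sd Between-subject SD of the stimulated OD.
#' @param od_well_sd Within-triplicate well noise SD.
#' @param seed Default random seed carried by the design.
#' @return A `gcm_design` list.
#' @export
sim_design <- function(n_probes = 5000,
                       n_cases = 49,
                       n_controls = 25,
                       n_assay_cases = 33,
                       n_assay_controls = 24,
                       fraction_hypersensitive = 14 / 33,
                       n_batches = 2,
                       batch_shift = 0.5,
                       dm_fraction = 0.05,
                       delta_grid = seq(0.05, 0.17, by = 0.02),
                       hyper_fraction = 0.716,
                       gc_loci = 13,
                       gc_delta = 0.12,
                       gc_hyper_fraction = 0.7,
                       invariant_fraction = 0.10,
                       snp_fraction = 0.02,
                       detection_fail_fraction = 0.005,
                       noise_sd = 0.08,
                       rand36 = rand36_reference(),
                       inhibition_params = list(
                         control = c(mean = 45, sd = 7),
                         typical = c(mean = 48, sd = 7),
                         hypersensitive = c(mean = 82, sd = 5)
                       ),
                       od_unstimulated = 0.35,
                       od_stimulated = 1.6,
                       od_subject_sd = 0.15,
                       od_well_sd = 0.03,
                       seed = 1L) {
  design <- as.list(environment())
  fracs <- c(fraction_hypersensitive, dm_fraction, hyper_fraction,
             gc_hyper_fraction, invariant_fraction, snp_fraction,
             detection_fail_fraction)
  if (any(fracs < 0 | fracs > 1)) {
    abort("all design fractions must lie in [0, 1]",
          class = "gcm_validation_error")
  }
  counts <- c(n_probes, n_cases, n_controls, n_assay_cases, n_assay_controls,
              n_batches)
  if (any(counts < 1)) {
    abort("design counts must be positive", class = "gcm_validation_error")
  }
  if (n_assay_cases > n_cases || n_assay_controls > n_controls) {
    abort("assay subset cannot exceed the cohort", class = "gcm_validation_error")
  }
  if (any(abs(delta_grid) >= 1) || abs(gc_delta) >= 1) {
    abort("planted beta-differences must lie in (-1, 1)",
          class = "gcm_validation_error")
  }
  n_planted <- round(dm_fraction * n_probes) + gc_loci
  if (n_planted > n_probes * (1 - invariant_fraction - snp_fraction)) {
    abort("design requests more planted loci than available probes",
          class = "gcm_validation_error")
  }
  structure(design, class = "gcm_design")
}

#' @export
print.gcm_design <- function(x, ...) {
  cat(sprintf(
    "<simulation design: %d probes, %d cases / %d controls, assay %d/%d, seed %d>\n",
    x$n_probes, x$n_cases, x$n_controls, x$n_assay_cases, x$n_assay_controls,
    x$seed))
  invisible(x)
}

# convert a target beta-scale difference into the logit offset that
# produces it exactly at the probe's baseline beta
beta_delta_to_logit <- function(base_beta, delta) {
  logit(base_beta + delta) - logit(base_beta)
}

#' Simulate RAND-36 quality-of-life scores
#'
#' Draws the eight category scores per sample from group-specific normal
#' distributions (means and standard errors from the design; SE converted
#' to SD by the square root of the design's group size), truncated to
#' \[0, 100\].
#'
#' @param design A [sim_design()].
#' @param samples Sample sheet with `sample_id` and `group`.
#' @param seed Random seed (defaults to the design seed).
#' @param rho Share of within-group variance carried by a shared
#'   per-subject health factor (induces the within-person correlation of
#'   survey categories). Default 0.3; 0 gives independent categories.
#' @return `samples` with the eight `rand36_*` columns added or replaced.
#' @export
simulate_rand36 <- function(design, samples, seed = design$seed,
                            rho = 0.3) {
  set.seed(seed)
  ref <- design$rand36
  n_by_group <- c(case = design$n_cases, control = design$n_controls)
  # shared per-subject health factor induces the within-person correlation
  # survey categories show; rho is the share of within-group variance it
  # carries (0 = independent categories)
  h <- rnorm(nrow(samples))
  for (k in seq_len(nrow(ref))) {
    col <- ref$category[k]
    mu <- ifelse(samples$group == "case", ref$case_mean[k], ref$control_mean[k])
    sdv <- ifelse(samples$group == "case",
                  ref$case_se[k] * sqrt(n_by_group["case"]),
                  ref$control_se[k] * sqrt(n_by_group["control"]))
    z <- sqrt(rho) * h + sqrt(1 - rho) * rnorm(nrow(samples))
    samples[[col]] <- pmin(pmax(mu + sdv * z, 0), 100)
  }
  samples
}

#' Simulate a complete methylation study
#'
#' Generates every input the pipeline consumes, with planted ground truth:
#' a 450K-like beta matrix with case-vs-control effects, hypersensitive-
#' subgroup effects, batch offsets and logit-scale noise; detection
#' p-values (mostly well below 0.01, with a configurable failing
#' fraction); a probe annotation table over the closed vocabularies; a
#' sample sheet with covariates, batch, RAND-36 scores and onset; and
#' truth tables listing the planted differentially methylated probes with
#' their signed beta-scale deltas, the planted glucocorticoid-sensitivity
#' loci, SNP-flagged probes, invariant probes and the true subgroup of
#' every assay case.
#'
#' @param design A [sim_design()].
#' @param seed Random seed (defaults to the design seed). Fixing the seed
#'   fixes every emitted value.
#' @return A `gcm_simulation` list with elements `beta` (a
#'   [beta_matrix()] with detection p-values), `annotation`, `samples`,
#'   `assay` (triplicate optical densities, see [simulate_assay_plate()]),
#'   `truth` and `design`.
#' @export
simulate_study <- function(design = sim_design(), seed = design$seed) {
  stopifnot(inherits(design, "gcm_design"))
  set.seed(seed)
  n <- design$n_cases + design$n_controls
  sample_id <- sprintf("S%03d", seq_len(n))
  group <- rep(c("case", "control"), c(design$n_cases, design$n_controls))

  ## --- sample sheet -------------------------------------------------
  age <- ifelse(group == "case",
                rnorm(n, 49.4, 1.9 * sqrt(design$n_cases)),
                rnorm(n, 51.1, 2.7 * sqrt(design$n_controls)))
  age <- pmax(age, 20)
  bmi <- ifelse(group == "case",
                rnorm(n, 23.3, 0.5 * sqrt(design$n_cases)),
                rnorm(n, 23.4, 0.6 * sqrt(design$n_controls)))
  bmi <- pmin(pmax(bmi, 17), 29.9)
  batch <- paste0("B", rep_len(seq_len(design$n_batches), n)[sample.int(n)])
  # PBMC composition around typical fractions, renormalised to sum 0.98
  cell_means <- c(cell_cd4t = 0.30, cell_cd8t = 0.20, cell_b = 0.12,
                  cell_nk = 0.12, cell_mono = 0.24)
  cells <- sapply(cell_means, function(m) pmax(rnorm(n, m, 0.03), 0.01))
  cells <- cells / rowSums(cells) * 0.98
  onset <- ifelse(group == "case",
                  sample(c("sudden", "gradual"), n, replace = TRUE,
                         prob = c(33, 16) / 49),
                  "not_applicable")
  in_assay <- c(seq_len(design$n_assay_cases),
                design$n_cases + seq_len(design$n_assay_controls))
  assay_flag <- seq_len(n) %in% in_assay
  n_hyper <- round(design$fraction_hypersensitive * design$n_assay_cases)
  hyper_idx <- sample(seq_len(design$n_assay_cases), n_hyper)
  gc_subgroup_true <- rep("unknown", n)
  gc_subgroup_true[seq_len(design$n_assay_cases)] <- "typical"
  gc_subgroup_true[hyper_idx] <- "hypersensitive"

  samples <- tibble(
    sample_id = sample_id, group = group,
    gc_subgroup = gc_subgroup_true,
    age = age, bmi = bmi, batch = batch,
    onset = onset, in_assay = assay_flag
  )
  samples <- bind_cols(samples, as_tibble(cells))
  samples <- simulate_rand36(design, samples, seed = seed + 1L)

  ## --- probe annotation ---------------------------------------------
  p <- design$n_probes
  probe_id <- sprintf("cg%08d", seq_len(p))
  vocab <- annotation_vocab()
  island_relation <- sample(vocab$island_relation, p, replace = TRUE,
                            prob = c(0.31, 0.13, 0.10, 0.05, 0.04, 0.37))
  genic_region <- sample(vocab$genic_region, p, replace = TRUE,
                         prob = c(0.14, 0.10, 0.09, 0.06, 0.35, 0.04, 0.22))
  n_genes <- max(2L, ceiling(p / 3))
  gene_pool <- sprintf("GENE%05d", seq_len(n_genes))
  gene1 <- sample(gene_pool, p, replace = TRUE)
  two_genes <- runif(p) < 0.05
  gene2 <- sample(gene_pool, p, replace = TRUE)
  gene_symbols <- ifelse(genic_region == "intergenic", "",
                         ifelse(two_genes & gene2 != gene1,
                                paste(gene1, gene2, sep = ";"), gene1))
  snp_flag <- runif(p) < design$snp_fraction
  annotation <- tibble(probe_id, gene_symbols, genic_region,
                       island_relation, snp_flag)

  ## --- baselines and planted effects --------------------------------
  invariant <- runif(p) < design$invariant_fraction
  base_beta <- runif(p, 0.10, 0.90)
  base_beta[invariant] <- ifelse(runif(sum(invariant)) < 0.5,
                                 runif(sum(invariant), 0.005, 0.035),
                                 runif(sum(invariant), 0.965, 0.995))
  eligible <- which(!invariant & !snp_flag)
  n_dm <- round(design$dm_fraction * p)
  planted <- sample(eligible, n_dm + design$gc_loci)
  dm_idx <- planted[seq_len(n_dm)]
  gc_idx <- planted[n_dm + seq_len(design$gc_loci)]

  dm_delta <- sample(design$delta_grid, n_dm, replace = TRUE) *
    ifelse(runif(n_dm) < design$hyper_fraction, 1, -1)
  gc_delta <- rep(design$gc_delta, design$gc_loci) *
    ifelse(runif(design$gc_loci) < design$gc_hyper_fraction, 1, -1)
  # keep baseline + delta comfortably inside (0, 1)
  base_beta[dm_idx] <- runif(n_dm, 0.20, 0.80) - pmax(dm_delta, 0) / 2 -
    pmin(dm_delta, 0) / 2
  base_beta[gc_idx] <- runif(design$gc_loci, 0.25, 0.75) - gc_delta / 2

  mu <- matrix(logit(base_beta), p, n)
  # planted case-vs-control effect: applied to all cases
  case_cols <- which(group == "case")
  mu[dm_idx, case_cols] <- mu[dm_idx, case_cols] +
    beta_delta_to_logit(base_beta[dm_idx], dm_delta)
  # hypersensitive-specific effect: applied to hypersensitive cases only
  hyper_cols <- which(gc_subgroup_true == "hypersensitive")
  mu[gc_idx, hyper_cols] <- mu[gc_idx, hyper_cols] +
    beta_delta_to_logit(base_beta[gc_idx], gc_delta)
  # per-probe batch offsets around the design shift
  shifts <- c(0, rep_len(design$batch_shift, design$n_batches - 1))
  batch_index <- as.integer(sub("^B", "", batch))
  batch_offsets <- matrix(0, p, design$n_batches)
  for (b in seq_len(design$n_batches)[-1]) {
    batch_offsets[, b] <- rnorm(p, shifts[b], 0.1)
  }
  mu <- mu + batch_offsets[, batch_index]
  values <- inv_logit(mu + matrix(rnorm(p * n, 0, design$noise_sd), p, n))
  dimnames(values) <- list(probe_id, sample_id)

  ## --- detection p-values -------------------------------------------
  detection <- matrix(runif(p * n, 0, 0.005), p, n,
                      dimnames = list(probe_id, sample_id))
  n_fail <- round(design$detection_fail_fraction * p)
  if (n_fail > 0) {
    fail_idx <- sample(setdiff(seq_len(p), planted), n_fail)
    for (i in fail_idx) {
      detection[i, sample.int(n, 1)] <- runif(1, 0.02, 0.5)
    }
  } else {
    fail_idx <- integer(0)
  }

  truth <- list(
    dm = tibble(probe_id = probe_id[dm_idx], delta = dm_delta,
                direction = ifelse(dm_delta > 0, "hyper", "hypo")),
    gc = tibble(probe_id = probe_id[gc_idx], delta = gc_delta),
    invariant = probe_id[invariant],
    snp = probe_id[snp_flag],
    detection_fail = probe_id[fail_idx],
    subgroup = samples |>
      filter(.data$in_assay, .data$group == "case") |>
      select("sample_id", gc_subgroup_true = "gc_subgroup"),
    batch_shift = shifts
  )

  assay <- simulate_assay_plate(design, samples, seed = seed + 2L)

  structure(list(
    beta = beta_matrix(values, detection),
    annotation = annotation,
    samples = samples,
    assay = assay,
    truth = truth,
    design = design,
    seed = seed
  ), class = "gcm_simulation")
}

#' Simulate a dexamethasone suppression assay plate
#'
#' For every assay sample, draws a subject-level true inhibition
#' percentage from its stratum's mode (controls unimodal; cases a mixture
#' of the typical and hypersensitive modes, hence bimodal when both are
#' represented), then emits triplicate optical densities for the three
#' culture conditions (unstimulated control, PHA-stimulated, PHA +
#' dexamethasone suppressed) whose condition means imply that inhibition
#' percentage.
#'
#' @param design A [sim_design()].
#' @param samples Sample sheet produced by [simulate_study()] (needs
#'   `in_assay`, `group`, `gc_subgroup`).
#' @param seed Random seed.
#' @return A tibble with columns `sample_id`, `condition`
#'   (control/stimulated/suppressed), `replicate` (1:3) and `od`, plus a
#'   `truth` attribute with each subject's drawn inhibition percentage.
#' @export
simulate_assay_plate <- function(design, samples, seed = design$seed) {
  set.seed(seed)
  sub <- samples[samples$in_assay, ]
  stratum <- ifelse(sub$group == "control", "control", sub$gc_subgroup)
  pars <- design$inhibition_params
  inhib <- vapply(stratum, function(s) {
    rnorm(1, pars[[s]]["mean"], pars[[s]]["sd"])
  }, numeric(1))
  inhib <- pmin(inhib, 97)
  stim <- pmax(rnorm(nrow(sub), design$od_stimulated, design$od_subject_sd),
               0.5)
  unstim <- pmax(rnorm(nrow(sub), design$od_unstimulated, 0.05), 0.05)
  supp <- stim * (1 - inhib / 100)
  base_tbl <- tibble(
    sample_id = rep(sub$sample_id, 3),
    condition = rep(c("control", "stimulated", "suppressed"),
                    each = nrow(sub)),
    base = c(unstim, stim, supp)
  )
  wells <- base_tbl |>
    tidyr::expand_grid(replicate = 1:3) |>
    arrange(.data$sample_id, .data$condition, .data$replicate) |>
    mutate(od = pmax(.data$base +
                       rnorm(n(), 0, 0.005 + design$od_well_sd * .data$base / 1.6),
                     0.001)) |>
    select("sample_id", "condition", "replicate", "od")
  attr(wells, "truth") <- tibble(sample_id = sub$sample_id,
                                 stratum = stratum,
                                 inhibition_true = inhib)
  wells
}

#' Write all simulated tables to a directory
#'
#' Emits `beta.tsv`, `detection.tsv`, `annotation.tsv`, `samples.tsv`,
#' `assay.tsv` and the planted-truth tables under `truth/`.
#'
#' @param sim A `gcm_simulation` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "gcm_simulation"))
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  write_beta_matrix(sim$beta, file.path(dir, "beta.tsv"),
                    file.path(dir, "detection.tsv"))
  readr::write_tsv(sim$annotation, file.path(dir, "annotation.tsv"))
  readr::write_tsv(sim$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(sim$assay, file.path(dir, "assay.tsv"))
  readr::write_tsv(sim$truth$dm, file.path(dir, "truth", "dm.tsv"))
  readr::write_tsv(sim$truth$gc, file.path(dir, "truth", "gc.tsv"))
  readr::write_tsv(sim$truth$subgroup, file.path(dir, "truth", "subgroup.tsv"))
  readr::write_tsv(tibble(probe_id = sim$truth$invariant),
                   file.path(dir, "truth", "invariant.tsv"))
  invisible(dir)
}
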