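#' Label-permutation null distribution of the mean beta-difference
#'
#' Implements the constructed per-locus null: the two-group assignment is
#' shuffled, the mean beta-difference is recomputed for every probe, and
#' the shuffle is repeated `n_perm` times (one shared sequence of
#' permutations across all probes, preserving inter-probe correlation
#' under the null). The approximate p-value per probe is the proportion
#' of null mean beta-differences equal or more extreme than the observed
#' value, two-sided on the absolute difference.
#'
#' In exhaustive mode every distinct assignment of `n1` samples to group 1
#' is enumerated instead (feasible when `choose(n, n1) <= 1e5`); this is
#' the exact reference the sampled mode converges to.
#'
#' @param beta A [beta_matrix()].
#' @param labels Character vector of group labels aligned to the matrix
#'   columns (or named by sample id), with exactly two distinct values.
#' @param levels Length-2 character giving the g1/g2 orientation; default
#'   the sorted unique labels.
#' @param n_perm Number of label shuffles. Default 10000.
#' @param seed Random seed for the shuffle stream.
#' @param exhaustive Enumerate all distinct label partitions instead of
#'   sampling.
#' @param add_one Use the (n_extreme + 1) / (n_perm + 1) estimator, which
#'   is strictly positive; the default is the literal proportion, which
#'   can return 0.
#' @param alpha Significance threshold for `significant_perm`.
#'   Default 0.05.
#' @return A tibble with `probe_id`, `observed_diff`, `n_perm`,
#'   `n_extreme`, `perm_p`, `significant_perm`.
#' @export
permute_null <- function(beta, labels, levels = NULL, n_perm = 10000,
                         seed = NULL, exhaustive = FALSE, add_one = FALSE,
                         alpha = 0.05) {
  stopifnot(inherits(beta, "gcm_beta"))
  if (!is.null(names(labels))) {
    labels <- labels[sample_ids(beta)]
  }
  if (length(labels) != ncol(beta$values) || anyNA(labels)) {
    abort("labels must cover every sample in the beta matrix",
          class = "gcm_validation_error")
  }
  levels <- levels %||% sort(unique(labels))
  if (length(levels) != 2 || !setequal(unique(labels), levels)) {
    abort("labels must take exactly two values", class = "gcm_validation_error")
  }
  if (n_perm < 1) abort("n_perm must be at least 1",
                        class = "gcm_validation_error")
  n <- length(labels)
  n1 <- sum(labels == levels[1])
  n2 <- n - n1
  if (n1 == 0 || n2 == 0) {
    abort("both groups must be non-empty", class = "gcm_validation_error")
  }
  v <- beta$values
  contrast <- function(idx1) {
    w <- rep(-1 / n2, n)
    w[idx1] <- 1 / n1
    w
  }
  observed <- as.vector(v %*% contrast(which(labels == levels[1])))

  if (exhaustive) {
    if (choose(n, n1) > 1e5) {
      abort(sprintf("exhaustive mode infeasible: choose(%d, %d) > 1e5", n, n1),
            class = "gcm_validation_error")
    }
    parts <- utils::combn(n, n1)
    W <- apply(parts, 2, contrast)
    null_diff <- v %*% W
    n_extreme <- rowSums(abs(null_diff) >= abs(observed) - 1e-12)
    n_used <- ncol(parts)
  } else {
    if (!is.null(seed)) set.seed(seed)
    n_extreme <- numeric(nrow(v))
    chunk <- 2000L
    done <- 0L
    while (done < n_perm) {
      k <- min(chunk, n_perm - done)
      W <- vapply(seq_len(k), function(j) contrast(sample.int(n, n1)),
                  numeric(n))
      null_diff <- v %*% W
      n_extreme <- n_extreme +
        rowSums(abs(null_diff) >= abs(observed) - 1e-12)
      done <- done + k
    }
    n_used <- n_perm
  }
  perm_p <- if (add_one) (n_extreme + 1) / (n_used + 1) else
    n_extreme / n_used
  tibble(
    probe_id = probe_ids(beta),
    observed_diff = unname(observed),
    n_perm = n_used,
    n_extreme = as.integer(unname(n_extreme)),
    perm_p = unname(perm_p),
    significant_perm = unname(perm_p <= alpha)
  )
}

#' Concordance between nominal and permutation calls
#'
#' Among probes passing the nominal criteria (`|beta_diff| >= diff_min`
#' and Wilcoxon `p <= alpha`), the fraction whose permutation p-value is
#' also at most `alpha`.
#'
#' @param nominal DM records (from [diff_methylation()]).
#' @param perm Permutation results (from [permute_null()]) over the same
#'   probe universe.
#' @param alpha Significance threshold. Default 0.05.
#' @param diff_min Effect-size gate. Default 0.05.
#' @return One-row tibble: `n_nominal`, `n_concordant`, `concordance`
#'   (fraction in \[0, 1\], `NA` when no probe is nominally significant).
#' @export
concordance <- function(nominal, perm, alpha = 0.05, diff_min = 0.05) {
  if (!setequal(nominal$probe_id, perm$probe_id)) {
    abort("nominal and permutation results cover different probes",
          class = "gcm_alignment_error")
  }
  joined <- inner_join(
    nominal |> select("probe_id", "beta_diff", "p_wilcoxon"),
    perm |> select("probe_id", "perm_p"),
    by = "probe_id")
  nom <- joined |>
    filter(abs(.data$beta_diff) >= diff_min, .data$p_wilcoxon <= alpha)
  if (nrow(nom) == 0) {
    return(tibble(n_nominal = 0L, n_concordant = NA_integer_,
                  concordance = NA_real_))
  }
  n_conc <- sum(nom$perm_p <= alpha)
  tibble(n_nominal = nrow(nom), n_concordant = n_conc,
         concordance = n_conc / nrow(nom))
}
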