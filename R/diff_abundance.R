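# Two-group per-taxon testing: exact Wilcoxon rank-sum with midrank ties,
# BH-FDR correction, tabular reporting, and signed-profile extraction.

#' Two-sided Wilcoxon rank-sum test with exact tie handling
#'
#' Computes the two-sided p-value for the unpaired two-group rank-sum test.
#' When the number of group assignments `choose(n1 + n2, n1)` is at most
#' `exact_limit`, the full permutation distribution of the rank sum of `x`
#' (midranks for ties) is enumerated and the two-sided p-value is
#' `min(1, 2 * min(lower tail, upper tail))`. Larger problems use the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param x,y Numeric value vectors for the two groups (both non-empty).
#' @param exact_limit Enumeration cutoff on `choose(n1 + n2, n1)`.
#' @param method Two-sided rule for the exact branch: `"doubling"` (default,
#'   tail doubling capped at 1) or `"abs_dev"` (probability of a rank sum at
#'   least as far from its mean as observed).
#' @return The two-sided p-value.
#' @export
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4))  # 1/3
rank_sum_test <- function(x, y, exact_limit = 2e5,
                          method = c("doubling", "abs_dev")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop_("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) stop_("missing values are not supported")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (choose(n, n1) <= exact_limit) {
    cmb <- combn(n, n1)
    ws <- colSums(matrix(r[cmb], nrow = n1))
    p <- if (method == "doubling") {
      2 * min(mean(ws <= w), mean(ws >= w))
    } else {
      mu <- n1 * (n + 1) / 2
      mean(abs(ws - mu) >= abs(w - mu))
    }
    min(1, p)
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    d <- w - mu
    z <- (d - sign(d) * 0.5) / sqrt(sigma2)
    min(1, 2 * pnorm(-abs(z)))
  }
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Maps p-values to q-values with `q_(i) = min_{j >= i} p_(j) * m / j`,
#' capped at 1 and returned in input order. The family size `m` defaults to
#' the number of p-values supplied but may be set larger when only part of a
#' family is passed in.
#'
#' @param p P-values, all in (0, 1].
#' @param m Family size, at least `length(p)`.
#' @return q-values in input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
bh_adjust <- function(p, m = length(p)) {
  p <- as.numeric(p)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1))
    stop_("p-values must lie in (0, 1]")
  if (m < length(p))
    stop_("family size m must be at least the number of p-values")
  p.adjust(p, method = "BH", n = m)
}

#' Per-taxon two-group differential abundance
#'
#' Collapses a relative-abundance table to `rank`, drops taxa detected in
#' fewer than `prevalence_min` of all samples, tests each remaining taxon
#' with [rank_sum_test()] (case vs control), and adjusts p-values with
#' [bh_adjust()] within the rank. Means are group means of the relative
#' abundance; `direction` is the sign of `mean_case - mean_control`.
#'
#' @param table A `taxa_table` or relative-abundance table (counts are
#'   converted internally).
#' @param design A [group_design()] labelling every sample.
#' @param rank Rank to collapse to, one of [taxa_ranks()].
#' @param prevalence_min Minimum fraction of samples in which a taxon must
#'   be non-zero to be tested (default 0.1).
#' @param m Optional BH family size override passed to [bh_adjust()].
#' @return A `diff_abundance` data frame with columns `taxon`, `rank`,
#'   `mean_case`, `mean_control`, `p_value`, `q_value`, `direction`, ordered
#'   by increasing p-value.
#' @export
differential_abundance <- function(table, design, rank,
                                   prevalence_min = 0.1, m = NULL) {
  stopifnot(inherits(table, "taxa_table"))
  rel <- if (is_relative(table)) table else to_relative(table)
  rel <- collapse_rank(rel, rank)
  grp <- design_groups(design, sample_ids(rel))
  if (sum(grp == "case") < 2 || sum(grp == "control") < 2)
    stop_("each group needs at least 2 samples")
  keep <- colMeans(rel$values > 0) >= prevalence_min
  vals <- rel$values[, keep, drop = FALSE]
  if (ncol(vals) == 0L)
    return(structure(data.frame(taxon = character(0), rank = character(0),
                                mean_case = numeric(0),
                                mean_control = numeric(0),
                                p_value = numeric(0), q_value = numeric(0),
                                direction = integer(0)),
                     class = c("diff_abundance", "data.frame")))
  case <- vals[grp == "case", , drop = FALSE]
  ctrl <- vals[grp == "control", , drop = FALSE]
  pvals <- vapply(seq_len(ncol(vals)),
                  function(j) rank_sum_test(case[, j], ctrl[, j]), 0)
  qvals <- bh_adjust(pvals, m = if (is.null(m)) length(pvals) else m)
  mc <- colMeans(case); mk <- colMeans(ctrl)
  out <- data.frame(taxon = colnames(vals), rank = rank,
                    mean_case = unname(mc), mean_control = unname(mk),
                    p_value = pvals, q_value = qvals,
                    direction = as.integer(sign(mc - mk)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p_value, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("diff_abundance", "data.frame"))
}

#' Write differential-abundance results to TSV
#'
#' One row per taxon with the group means, p-value, q-value and direction.
#'
#' @param results A `diff_abundance` data frame.
#' @param path Output path.
#' @export
write_diff_results <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract a disease's signed microbe profile from test results
#'
#' Keeps taxa with `q_value < alpha` and a non-zero direction; the profile
#' sign is the direction of change. Microbe labels are normalized with
#' [normalize_microbe()] so profiles extracted from taxa tables and profiles
#' parsed from association TSVs share one key convention.
#'
#' @param results A `diff_abundance` data frame (one rank).
#' @param alpha Significance threshold on the q-value (default 0.05).
#' @param disease Disease name for the profile (default `"ASD"`).
#' @return A [signed_profile()]; may be empty.
#' @export
extract_signed_profile <- function(results, alpha = 0.05, disease = "ASD") {
  sel <- results$q_value < alpha & results$direction != 0L
  keep <- results[sel, , drop = FALSE]
  signs <- setNames(as.integer(keep$direction),
                    normalize_microbe(keep$taxon))
  if (anyDuplicated(names(signs)))
    signs <- signs[!duplicated(names(signs))]
  signed_profile(disease, signs,
                 rank = if (nrow(results)) results$rank[1] else NA_character_)
}
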