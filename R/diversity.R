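# Alpha diversity (Shannon), Bray-Curtis beta diversity, classical
# principal-coordinates analysis, and a PERMANOVA-style permutation test.

#' Shannon diversity of an abundance vector
#'
#' `H = -sum(p_i * log_base(p_i))` over non-zero entries after renormalizing
#' to proportions. Base defaults to 2 (the common amplicon-pipeline
#' convention); use `base = exp(1)` for nats.
#'
#' @param abundances Non-negative vector with positive sum (counts or
#'   proportions).
#' @param base Logarithm base.
#' @return Shannon diversity.
#' @export
#' @examples
#' shannon(rep(1, 4))             # 2 bits
#' shannon(c(0.5, 0.25, 0.25))    # 1.5 bits
shannon <- function(abundances, base = 2) {
  x <- as.numeric(abundances)
  if (anyNA(x) || any(x < 0)) stop_("abundances must be non-negative")
  if (sum(x) <= 0) stop_("abundance vector must have positive sum")
  unname(vegan::diversity(x, index = "shannon", base = base))
}

#' Per-sample Shannon diversity of a table
#'
#' @param table A count or relative-abundance table.
#' @param base Logarithm base.
#' @return Named numeric vector, one value per sample.
#' @export
shannon_per_sample <- function(table, base = 2) {
  stopifnot(inherits(table, "taxa_table"))
  apply(table$values, 1, shannon, base = base)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(a, b) = sum |a_i - b_i| / sum (a_i + b_i)` for every sample pair.
#'
#' @param table A relative-abundance table (or counts, used as-is) with at
#'   least two samples.
#' @return Symmetric numeric matrix with zero diagonal, labelled by sample.
#' @export
bray_curtis_matrix <- function(table) {
  stopifnot(inherits(table, "taxa_table"))
  if (nrow(table$values) < 2) stop_("need at least 2 samples")
  as.matrix(vegan::vegdist(table$values, method = "bray"))
}

#' Principal-coordinates analysis (classical scaling)
#'
#' Double-centres `-d^2 / 2`, eigendecomposes, and scales eigenvectors by
#' the square root of their (positive) eigenvalues. Negative eigenvalues are
#' reported but their axes are dropped, with no Lingoes/Cailliez correction.
#' If fewer than `k` positive eigenvalues exist the result is truncated with
#' a warning; a fully degenerate (all-zero) matrix yields all-zero
#' coordinates.
#'
#' @param dm Square symmetric dissimilarity matrix (or `dist`).
#' @param k Number of axes requested (at least 1).
#' @return A `pcoa_ordination` list: `points` (samples x axes), all
#'   `eigenvalues` in decreasing order, `prop_explained` per returned axis
#'   (relative to the sum of positive eigenvalues), and `n_positive`.
#' @export
pcoa <- function(dm, k = 2) {
  d <- as.matrix(dm)
  if (k < 1) stop_("k must be at least 1")
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop_("dm must be a square symmetric matrix")
  n <- nrow(d)
  a <- -0.5 * d^2
  b <- a - outer(rowMeans(a), rep(1, n)) - outer(rep(1, n), colMeans(a)) +
    mean(a)
  e <- eigen(b, symmetric = TRUE)
  tol <- max(abs(e$values), 0) * 1e-8 + 1e-12
  npos <- sum(e$values > tol)
  if (npos == 0L) {
    warn_("no positive eigenvalues; returning all-zero coordinates")
    pts <- matrix(0, n, k, dimnames = list(rownames(d),
                                           paste0("Axis", seq_len(k))))
    return(structure(list(points = pts, eigenvalues = e$values,
                          prop_explained = rep(0, k), n_positive = 0L),
                     class = "pcoa_ordination"))
  }
  keff <- min(k, npos)
  if (keff < k)
    warn_("only %d positive eigenvalue(s); returning %d axis/axes",
          npos, keff)
  pts <- e$vectors[, seq_len(keff), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(keff)]), keff)
  dimnames(pts) <- list(rownames(d), paste0("Axis", seq_len(keff)))
  structure(list(points = pts, eigenvalues = e$values,
                 prop_explained = e$values[seq_len(keff)] /
                   sum(e$values[e$values > tol]),
                 n_positive = as.integer(npos)),
            class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d axes returned (%d positive eigenvalues)\n",
              nrow(x$points), ncol(x$points), x$n_positive))
  invisible(x)
}

ss_within <- function(d2, idx_list) {
  sum(vapply(idx_list,
             function(ix) sum(d2[ix, ix]) / (2 * length(ix)), 0))
}

#' Permutation test for group separation in a distance matrix
#'
#' PERMANOVA-style pseudo-F (among-group vs within-group sums of squared
#' dissimilarities) with a label-permutation null at fixed group sizes.
#' The p-value uses add-one smoothing,
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`, so the smallest
#' attainable value is `1 / (n_perm + 1)`.
#'
#' @param dm Square dissimilarity matrix (or `dist`) with sample labels.
#' @param design A [group_design()]; both groups need at least 2 samples.
#' @param n_perm Number of permutations (at least 99).
#' @param seed Seed for the permutation stream (restored afterwards).
#' @return List with `statistic` (pseudo-F), `p_value` and `n_perm`.
#' @export
permutation_group_test <- function(dm, design, n_perm = 999, seed = 1) {
  d <- as.matrix(dm)
  if (n_perm < 99) stop_("n_perm must be at least 99")
  samples <- rownames(d)
  if (is.null(samples)) stop_("distance matrix must carry sample labels")
  grp <- design_groups(design, samples)
  sizes <- table(grp)
  if (any(sizes < 2)) stop_("each group needs at least 2 samples")
  n <- nrow(d)
  a <- nlevels(grp)
  d2 <- d^2
  sst <- sum(d2) / (2 * n)
  idx <- split(seq_len(n), grp)
  ssw <- ss_within(d2, idx)
  fstat <- ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  sz <- lengths(idx)
  gid <- rep(seq_along(sz), sz)
  count <- with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      ssw_p <- ss_within(d2, split(perm, gid))
      f_p <- ((sst - ssw_p) / (a - 1)) / (ssw_p / (n - a))
      if (f_p >= fstat - 1e-12) hits <- hits + 1L
    }
    hits
  })
  list(statistic = fstat, p_value = (1 + count) / (1 + n_perm),
       n_perm = as.integer(n_perm))
}

#' Write a labelled square distance matrix to TSV
#'
#' @param dm Square matrix with sample labels.
#' @param path Output path.
#' @export
write_distance_matrix <- function(dm, path) {
  d <- as.matrix(dm)
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write PCoA coordinates to TSV
#'
#' Sample coordinates per axis; the eigenvalues are stored in a leading
#' comment line.
#'
#' @param ord A `pcoa_ordination`.
#' @param path Output path.
#' @export
write_ordination <- function(ord, path) {
  stopifnot(inherits(ord, "pcoa_ordination"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# eigenvalues: %s",
                     paste(sprintf("%.10g", ord$eigenvalues),
                           collapse = ", ")), con)
  df <- data.frame(sample_id = rownames(ord$points), ord$points,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
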