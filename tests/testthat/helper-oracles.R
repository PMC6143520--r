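# Independent oracles and small fixture builders used across tests.

# Brute-force two-sided rank-sum p-value: enumerate every assignment of
# group labels, score each by the midrank sum of the first group, and double
# the smaller tail. Independent of the package's vectorised implementation.
oracle_rank_sum_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(n, n1)
  ws <- apply(sets, 2, function(ix) sum(r[ix]))
  lower <- sum(ws <= w_obs) / ncol(sets)
  upper <- sum(ws >= w_obs) / ncol(sets)
  min(1, 2 * min(lower, upper))
}

# Literal step-up definition of Benjamini-Hochberg adjusted p-values.
oracle_bh <- function(p, m = length(p)) {
  o <- order(p)
  q <- p[o] * m / seq_along(p)
  q <- rev(cummin(rev(q)))
  pmin(1, q)[order(o)]
}

# Classical BH step-up rejection set at level alpha: reject the smallest
# k p-values where k = max { i : p_(i) <= i * alpha / m }.
oracle_bh_rejections <- function(p, alpha, m = length(p)) {
  o <- order(p)
  ok <- p[o] <= seq_along(p) * alpha / m
  k <- if (any(ok)) max(which(ok)) else 0L
  rejected <- logical(length(p))
  if (k > 0) rejected[o[seq_len(k)]] <- TRUE
  rejected
}

# Minimal lineage matrix: all slots empty unless given as name=value pairs
# of rank -> character vector (recycled over taxa).
mk_lineage <- function(taxa, ...) {
  lin <- matrix("", length(taxa), 7,
                dimnames = list(taxa, taxa_ranks()))
  extra <- list(...)
  for (rk in names(extra)) lin[, rk] <- extra[[rk]]
  lin
}

# Count table from a matrix (samples x taxa) plus optional lineage pairs.
mk_table <- function(counts, ...) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("s%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("t%02d", seq_len(ncol(counts)))
  taxa_table(counts, mk_lineage(colnames(counts), ...))
}

# A small two-group design over the rownames of a table/matrix.
mk_design <- function(ids, n_case) {
  group_design(ids, rep(c("case", "control"),
                        c(n_case, length(ids) - n_case)))
}
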