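# Taxon count tables: containers, QIIME-legacy TSV I/O, relative abundance,
# rank collapsing and the Bacteroidetes/Firmicutes ratio.

new_abund_table <- function(values, lineage, relative, rank = NULL) {
  structure(list(values = values, lineage = lineage),
            relative = relative, rank = rank,
            class = if (relative) c("rel_abundance", "taxa_table") else "taxa_table")
}

validate_lineage <- function(lineage, taxa) {
  lineage <- as.matrix(lineage)
  if (!is.character(lineage)) storage.mode(lineage) <- "character"
  if (ncol(lineage) != length(.gg_ranks) ||
      !identical(colnames(lineage), .gg_ranks))
    stop_("lineage must have exactly the columns %s",
          paste(.gg_ranks, collapse = ", "))
  if (nrow(lineage) != length(taxa))
    stop_("lineage has %d rows but the table has %d taxa",
          nrow(lineage), length(taxa))
  lineage[is.na(lineage)] <- ""
  rownames(lineage) <- taxa
  lineage
}

#' Construct a taxon count table
#'
#' Samples are rows, taxa are columns. Counts must be non-negative integers;
#' the lineage gives each taxon's Greengenes-style rank labels (any slot may
#' be empty).
#'
#' @param counts Numeric matrix (samples x taxa) of non-negative integer
#'   counts, with unique sample row names and taxon column names.
#' @param lineage Matrix or data frame with one row per taxon and the seven
#'   columns returned by [taxa_ranks()].
#' @return An object of class `taxa_table` with elements `values` and
#'   `lineage`.
#' @seealso [to_relative()], [collapse_rank()], [read_taxa_table()]
#' @export
#' @examples
#' cnt <- matrix(c(2L, 2L, 4L, 1L, 0L, 3L), nrow = 2, byrow = TRUE,
#'               dimnames = list(c("s1", "s2"), c("t1", "t2", "t3")))
#' lin <- matrix("", 3, 7, dimnames = list(c("t1", "t2", "t3"), taxa_ranks()))
#' lin[, "kingdom"] <- "Bacteria"
#' taxa_table(cnt, lin)
taxa_table <- function(counts, lineage) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_("counts must carry sample row names and taxon column names")
  if (anyDuplicated(rownames(counts)))
    stop_("sample ids must be unique")
  if (anyDuplicated(colnames(counts)))
    stop_("taxon ids must be unique")
  if (!is.numeric(counts) || anyNA(counts))
    stop_("counts must be numeric with no missing values")
  bad <- which(counts < 0 | !is_whole(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_("count for sample '%s', taxon '%s' is not a non-negative integer",
          rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]])
  lineage <- validate_lineage(lineage, colnames(counts))
  if (max(counts) <= .Machine$integer.max)
    storage.mode(counts) <- "integer"
  new_abund_table(counts, lineage, relative = FALSE)
}

rel_abundance_table <- function(values, lineage, rank = NULL) {
  values <- as.matrix(values)
  if (anyNA(values) || any(values < 0) || any(values > 1 + 1e-9))
    stop_("relative abundances must lie in [0, 1]")
  rs <- rowSums(values)
  if (any(abs(rs - 1) > 1e-9))
    stop_("relative-abundance rows must sum to 1 (sample '%s' sums to %g)",
          rownames(values)[which.max(abs(rs - 1))], rs[which.max(abs(rs - 1))])
  lineage <- validate_lineage(lineage, colnames(values))
  new_abund_table(values, lineage, relative = TRUE, rank = rank)
}

is_relative <- function(x) inherits(x, "rel_abundance")

#' @export
print.taxa_table <- function(x, ...) {
  kind <- if (is_relative(x)) "relative-abundance" else "count"
  cat(sprintf("%s table: %d samples x %d taxa\n",
              kind, nrow(x$values), ncol(x$values)))
  if (!is.null(attr(x, "rank")))
    cat(sprintf("collapsed at rank: %s\n", attr(x, "rank")))
  invisible(x)
}

#' Sample and taxon identifiers of a table
#'
#' @param x A `taxa_table` or relative-abundance table.
#' @return Character vector of ids.
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname sample_ids
#' @export
taxon_ids <- function(x) colnames(x$values)

#' Convert counts to relative abundances
#'
#' Divides each sample row by its total. Idempotent on tables that are
#' already relative.
#'
#' @param x A `taxa_table` (or relative-abundance table).
#' @return A relative-abundance table with the same axes and lineage.
#' @export
#' @examples
#' cnt <- matrix(c(2L, 2L, 4L), 1, dimnames = list("s1", c("a", "b", "c")))
#' lin <- matrix("", 3, 7, dimnames = list(c("a", "b", "c"), taxa_ranks()))
#' to_relative(taxa_table(cnt, lin))$values
to_relative <- function(x) {
  stopifnot(inherits(x, "taxa_table"))
  rs <- rowSums(x$values)
  if (any(rs == 0))
    stop_("sample '%s' has zero total abundance",
          rownames(x$values)[which(rs == 0)[1]])
  rel_abundance_table(x$values / rs, x$lineage, rank = attr(x, "rank"))
}

# Collapse labels at `rank`: taxa named at that rank keep their label; taxa
# with an empty slot are pooled under "<deepest named ancestor>_unclass".
collapse_labels <- function(lineage, rank) {
  ri <- match(rank, .gg_ranks)
  if (is.na(ri)) stop_("unknown rank '%s'", rank)
  lab <- lineage[, ri]
  empty <- !nzchar(lab)
  if (any(empty)) {
    anc <- apply(lineage[empty, seq_len(ri - 1), drop = FALSE], 1, function(v) {
      named <- which(nzchar(v))
      if (length(named)) v[max(named)] else "Root"
    })
    lab[empty] <- ifelse(grepl("_unclass$", anc), anc, paste0(anc, "_unclass"))
  }
  lab
}

#' Collapse a table to a taxonomic rank
#'
#' Taxa sharing the same label at `rank` are summed. Taxa with an empty label
#' at that rank are pooled under `"<deepest named ancestor>_unclass"` (e.g.
#' a genus-less member of family Clostridiaceae becomes
#' `Clostridiaceae_unclass`, and a taxon unclassified below kingdom becomes
#' `Bacteria_unclass`), reproducing the conventional QIIME-style labels.
#'
#' @param x A count or relative-abundance table.
#' @param rank One of [taxa_ranks()].
#' @return A table of the same kind whose taxa are the labels at `rank`.
#'   Per-sample totals are conserved exactly.
#' @export
collapse_rank <- function(x, rank) {
  stopifnot(inherits(x, "taxa_table"))
  if (!rank %in% .gg_ranks) stop_("unknown rank '%s'", rank)
  ri <- match(rank, .gg_ranks)
  lab <- collapse_labels(x$lineage, rank)
  groups <- factor(lab, levels = unique(lab))
  agg <- t(rowsum(t(x$values), group = groups, reorder = FALSE))
  colnames(agg) <- levels(groups)
  first <- match(levels(groups), lab)
  lin <- x$lineage[first, , drop = FALSE]
  lin[, ri] <- ifelse(nzchar(x$lineage[first, ri]),
                      x$lineage[first, ri], "")
  if (ri < length(.gg_ranks))
    lin[, (ri + 1):length(.gg_ranks)] <- ""
  rownames(lin) <- levels(groups)
  if (is_relative(x)) {
    rel_abundance_table(agg, lin, rank = rank)
  } else {
    out <- taxa_table(agg, lin)
    attr(out, "rank") <- rank
    out
  }
}

#' Per-sample Bacteroidetes/Firmicutes ratio
#'
#' Computes, for every sample, the ratio of the Bacteroidetes to the
#' Firmicutes relative abundance. Samples whose Firmicutes proportion falls
#' below `eps` are flagged as excluded (ratio `NA`): a pseudocount would
#' silently distort the ranks used by downstream rank-sum tests.
#'
#' @param phylum_table Relative-abundance table collapsed at the phylum rank,
#'   containing taxa labelled `"Bacteroidetes"` and `"Firmicutes"`.
#' @param eps Exclusion floor for the Firmicutes proportion (default 1e-6).
#' @return Data frame with columns `sample_id`, `bacteroidetes`,
#'   `firmicutes`, `ratio` and logical `excluded`.
#' @export
bf_ratio <- function(phylum_table, eps = 1e-6) {
  stopifnot(is_relative(phylum_table))
  need <- c("Bacteroidetes", "Firmicutes")
  miss <- setdiff(need, taxon_ids(phylum_table))
  if (length(miss))
    stop_("phylum table lacks label(s): %s", paste(miss, collapse = ", "))
  b <- phylum_table$values[, "Bacteroidetes"]
  f <- phylum_table$values[, "Firmicutes"]
  excluded <- f < eps
  data.frame(sample_id = sample_ids(phylum_table),
             bacteroidetes = unname(b), firmicutes = unname(f),
             ratio = ifelse(excluded, NA_real_, b / f),
             excluded = unname(excluded),
             stringsAsFactors = FALSE, row.names = NULL)
}

format_lineage <- function(lineage) {
  apply(lineage, 1, function(v) paste0(.gg_prefixes, v, collapse = "; "))
}

parse_lineage_string <- function(s, taxon) {
  out <- rep("", length(.gg_ranks))
  if (is.na(s) || !nzchar(trimws(s))) return(out)
  parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  if (length(parts) > length(.gg_ranks))
    stop_("taxon '%s': lineage has more than %d fields", taxon,
          length(.gg_ranks))
  for (j in seq_along(parts)) {
    if (substr(parts[j], 1, 3) != .gg_prefixes[j])
      stop_("taxon '%s': lineage field %d ('%s') must start with '%s'",
            taxon, j, parts[j], .gg_prefixes[j])
    out[j] <- substring(parts[j], 4)
  }
  out
}

#' Read a taxon count table from TSV
#'
#' Reads the legacy QIIME export dialect: header cell `#OTU ID`, one row per
#' taxon, one column per sample, and a final `taxonomy` column holding a
#' `"; "`-separated Greengenes-prefixed lineage
#' (`k__Bacteria; p__Firmicutes; ...`). A transposed dialect with samples as
#' rows (header cell `#Sample ID`, no taxonomy column) is available via
#' `samples_as_rows = TRUE`, optionally with a two-column companion taxonomy
#' file (`taxon_id`, `taxonomy`).
#'
#' @param path Path to the TSV file.
#' @param samples_as_rows Read the transposed dialect.
#' @param taxonomy Optional companion taxonomy TSV (transposed dialect only).
#' @return A `taxa_table`.
#' @export
read_taxa_table <- function(path, samples_as_rows = FALSE, taxonomy = NULL) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   comment.char = "", colClasses = "character")
  if (!samples_as_rows) {
    if (names(df)[1] != "#OTU ID" || names(df)[ncol(df)] != "taxonomy")
      stop_("expected header starting '#OTU ID' and ending 'taxonomy'")
    taxa <- df[[1]]
    samples <- names(df)[2:(ncol(df) - 1)]
    raw <- as.matrix(df[, 2:(ncol(df) - 1), drop = FALSE])
    counts <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
    bad <- which(is.na(counts) | counts < 0 | !is_whole(counts),
                 arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop_("invalid count '%s' for taxon '%s', sample '%s'",
            raw[bad[1, 1], bad[1, 2]], taxa[bad[1, 1]], samples[bad[1, 2]])
    lin <- t(vapply(seq_along(taxa),
                    function(i) parse_lineage_string(df$taxonomy[i], taxa[i]),
                    character(length(.gg_ranks))))
    colnames(lin) <- .gg_ranks
    counts <- t(counts)
    dimnames(counts) <- list(samples, taxa)
    taxa_table(counts, lin)
  } else {
    if (names(df)[1] != "#Sample ID")
      stop_("expected header starting '#Sample ID'")
    samples <- df[[1]]
    taxa <- names(df)[-1]
    raw <- as.matrix(df[, -1, drop = FALSE])
    counts <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
    bad <- which(is.na(counts) | counts < 0 | !is_whole(counts),
                 arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop_("invalid count '%s' for sample '%s', taxon '%s'",
            raw[bad[1, 1], bad[1, 2]], samples[bad[1, 1]], taxa[bad[1, 2]])
    dimnames(counts) <- list(samples, taxa)
    lin <- matrix("", length(taxa), length(.gg_ranks),
                  dimnames = list(taxa, .gg_ranks))
    if (!is.null(taxonomy)) {
      tx <- read.delim(taxonomy, check.names = FALSE,
                       stringsAsFactors = FALSE, comment.char = "")
      hit <- match(taxa, tx$taxon_id)
      for (i in which(!is.na(hit)))
        lin[i, ] <- parse_lineage_string(tx$taxonomy[hit[i]], taxa[i])
    }
    taxa_table(counts, lin)
  }
}

#' Write a taxon table to TSV
#'
#' Inverse of [read_taxa_table()]; writing then reading reproduces the table
#' exactly, lineage included.
#'
#' @param x A count or relative-abundance table.
#' @param path Output path.
#' @param samples_as_rows Write the transposed dialect (lineage omitted).
#' @return `path`, invisibly.
#' @export
write_taxa_table <- function(x, path, samples_as_rows = FALSE) {
  stopifnot(inherits(x, "taxa_table"))
  fmt <- function(v) {
    if (is_relative(x)) sprintf("%.17g", v) else format(v, scientific = FALSE,
                                                        trim = TRUE)
  }
  if (!samples_as_rows) {
    mat <- apply(t(x$values), c(1, 2), fmt)
    df <- data.frame(taxon = taxon_ids(x), mat,
                     taxonomy = format_lineage(x$lineage),
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(df) <- c("#OTU ID", sample_ids(x), "taxonomy")
  } else {
    mat <- apply(x$values, c(1, 2), fmt)
    df <- data.frame(sample = sample_ids(x), mat,
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(df) <- c("#Sample ID", taxon_ids(x))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a two-group sample design
#'
#' @param sample_id Character vector of sample ids.
#' @param group Character vector of labels, each `"case"` or `"control"`.
#' @return A `group_design` data frame.
#' @export
group_design <- function(sample_id, group) {
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  if (length(sample_id) != length(group))
    stop_("sample_id and group lengths differ")
  if (anyDuplicated(sample_id)) stop_("sample ids must be unique")
  if (!all(group %in% c("case", "control")))
    stop_("group labels must be 'case' or 'control'")
  structure(data.frame(sample_id = sample_id, group = group,
                       stringsAsFactors = FALSE),
            class = c("group_design", "data.frame"))
}

# Aligned group factor for the given sample ids; errors on unlabeled samples.
design_groups <- function(design, samples) {
  stopifnot(inherits(design, "group_design"))
  hit <- match(samples, design$sample_id)
  if (anyNA(hit))
    stop_("sample '%s' has no group label", samples[which(is.na(hit))[1]])
  factor(design$group[hit], levels = c("case", "control"))
}

#' Read / write a sample design TSV
#'
#' Two columns, `sample_id` and `group` (`case`/`control`); round-trips
#' exactly.
#'
#' @param path File path.
#' @return `read_group_design` returns a `group_design`.
#' @export
read_group_design <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop_("design file must have columns sample_id and group")
  group_design(df$sample_id, df$group)
}

#' @rdname read_group_design
#' @param design A `group_design`.
#' @export
write_group_design <- function(design, path) {
  stopifnot(inherits(design, "group_design"))
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
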