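# SCFA-related functional grouping of genera and per-sample group
# proportions.

fg_groups <- c("butyrate", "lactate", "mucin", "other_scfa")

#' Default SCFA functional-group map
#'
#' Genus-level producers of butyrate (Fusobacterium, Eubacterium,
#' Anaerostipes, Subdoligranulum, Faecalibacterium, Roseburia) and lactate
#' (Lactobacillus, Bifidobacterium, Streptococcus, Lactococcus), and the
#' mucin degraders Prevotella and Akkermansia. The `other_scfa` group
#' (propionate/succinate/acetate producers) ships empty: its membership is
#' not well standardized at genus level, so users extend it explicitly
#' rather than inheriting invented biology.
#'
#' @return A `functional_group_map` data frame with columns `genus` and
#'   `group`.
#' @export
#' @examples
#' default_group_map()
default_group_map <- function() {
  butyrate <- c("Fusobacterium", "Eubacterium", "Anaerostipes",
                "Subdoligranulum", "Faecalibacterium", "Roseburia")
  lactate <- c("Lactobacillus", "Bifidobacterium", "Streptococcus",
               "Lactococcus")
  mucin <- c("Prevotella", "Akkermansia")
  functional_group_map(data.frame(
    genus = c(butyrate, lactate, mucin),
    group = rep(c("butyrate", "lactate", "mucin"),
                c(length(butyrate), length(lactate), length(mucin))),
    stringsAsFactors = FALSE))
}

#' Construct or validate a functional-group map
#'
#' @param map Data frame with columns `genus` and `group`; groups must be
#'   among butyrate, lactate, mucin, other_scfa, and each genus may belong
#'   to one group only.
#' @return A `functional_group_map`.
#' @export
functional_group_map <- function(map) {
  if (!all(c("genus", "group") %in% names(map)))
    stop_("map must have columns genus and group")
  if (!all(map$group %in% fg_groups))
    stop_("groups must be among: %s", paste(fg_groups, collapse = ", "))
  if (anyDuplicated(map$genus))
    stop_("each genus may belong to only one group")
  structure(as.data.frame(map, stringsAsFactors = FALSE),
            class = c("functional_group_map", "data.frame"))
}

#' Per-sample functional-group proportions
#'
#' For each sample, the summed relative abundance of the member genera of
#' each group. Genera absent from the map contribute to no group, so group
#' sums never exceed the per-sample total of 1.
#'
#' @param genus_table Relative-abundance table collapsed at the genus rank
#'   (i.e. produced by `collapse_rank(x, "genus")`).
#' @param map A `functional_group_map` (default [default_group_map()]).
#' @return Numeric matrix samples x groups (butyrate, lactate, mucin,
#'   other_scfa).
#' @export
group_proportions <- function(genus_table, map = default_group_map()) {
  stopifnot(is_relative(genus_table))
  if (!identical(attr(genus_table, "rank"), "genus"))
    stop_("table must be collapsed at the genus rank; use collapse_rank(x, \"genus\")")
  map <- functional_group_map(map)
  out <- matrix(0, nrow(genus_table$values), length(fg_groups),
                dimnames = list(sample_ids(genus_table), fg_groups))
  for (g in fg_groups) {
    members <- intersect(map$genus[map$group == g], taxon_ids(genus_table))
    if (length(members))
      out[, g] <- rowSums(genus_table$values[, members, drop = FALSE])
  }
  out
}

#' Compare functional-group proportions between case and control
#'
#' One [rank_sum_test()] per group on the per-sample group proportions.
#'
#' @param props Matrix from [group_proportions()].
#' @param design A [group_design()].
#' @return Data frame with columns `group`, `mean_case`, `mean_control`,
#'   `p_value`.
#' @export
compare_group_proportions <- function(props, design) {
  grp <- design_groups(design, rownames(props))
  case <- props[grp == "case", , drop = FALSE]
  ctrl <- props[grp == "control", , drop = FALSE]
  data.frame(group = colnames(props),
             mean_case = unname(colMeans(case)),
             mean_control = unname(colMeans(ctrl)),
             p_value = vapply(seq_len(ncol(props)), function(j)
               rank_sum_test(case[, j], ctrl[, j]), 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read / write a functional-group map TSV
#'
#' Two columns: `genus`, `group`.
#'
#' @param path File path.
#' @return `read_group_map` returns a `functional_group_map`.
#' @export
read_group_map <- function(path) {
  functional_group_map(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_group_map
#' @param map A `functional_group_map`.
#' @export
write_group_map <- function(map, path) {
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
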