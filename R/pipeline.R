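# End-to-end orchestration: simulate -> differential abundance -> diversity
# -> functional groups -> signed profile -> disease network, with a
# reproducible run manifest.

#' Assemble and validate a pipeline configuration
#'
#' @param out_dir Output directory for all stage files (created if absent).
#' @param seed Base seed; stage sub-seeds are derived deterministically.
#' @param scenario A [community_scenario()] (default
#'   [default_asd_scenario()]).
#' @param assoc_scenario An [association_scenario()] providing the
#'   comparison diseases for the network stage (the default simulates 12
#'   diseases over 60 microbes at density 0.15).
#' @param ranks Ranks at which differential abundance is reported.
#' @param profile_rank Rank whose significant taxa form the case-group
#'   signed profile.
#' @param alpha Significance threshold (q-value for taxa, p-value for
#'   network edges), in (0, 1).
#' @param prevalence_min Prevalence filter for [differential_abundance()].
#' @param n_perm Permutations for the beta-diversity test and the network
#'   edge test (at least 99).
#' @param disease Name under which the case-group profile enters the
#'   network (pinned as a node).
#' @param stages Subset of `simulate`, `diffabund`, `diversity`,
#'   `funcgroups`, `profile`, `hmdn` to run (dependencies are implicit:
#'   every stage reads only files written by earlier ones in this order).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            scenario = default_asd_scenario(seed = seed),
                            assoc_scenario = association_scenario(
                              n_diseases = 12, n_microbes = 60,
                              density = 0.15, seed = derive_seed(seed, 9001)),
                            ranks = c("phylum", "genus"),
                            profile_rank = "genus", alpha = 0.05,
                            prevalence_min = 0.1, n_perm = 999,
                            disease = "ASD",
                            stages = c("simulate", "diffabund", "diversity",
                                       "funcgroups", "profile", "hmdn")) {
  if (missing(out_dir) || !nzchar(out_dir)) stop_("out_dir is required")
  if (alpha <= 0 || alpha >= 1) stop_("alpha must lie in (0, 1)")
  if (prevalence_min < 0 || prevalence_min >= 1)
    stop_("prevalence_min must lie in [0, 1)")
  if (n_perm < 99) stop_("n_perm must be at least 99")
  known <- c("simulate", "diffabund", "diversity", "funcgroups", "profile",
             "hmdn")
  if (!all(stages %in% known))
    stop_("unknown stage(s): %s",
          paste(setdiff(stages, known), collapse = ", "))
  if (!all(ranks %in% .gg_ranks) || !profile_rank %in% .gg_ranks)
    stop_("ranks must be among: %s", paste(.gg_ranks, collapse = ", "))
  stopifnot(inherits(scenario, "community_scenario"),
            inherits(assoc_scenario, "association_scenario"))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 scenario = scenario, assoc_scenario = assoc_scenario,
                 ranks = ranks, profile_rank = profile_rank, alpha = alpha,
                 prevalence_min = prevalence_min,
                 n_perm = as.integer(n_perm), disease = disease,
                 stages = stages),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop_("stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in order, writing every output as TSV under
#' `config$out_dir`, and finishes with `manifest.json` recording the package
#' version, seeds, parameters and an MD5 hash per output file. Identical
#' configurations yield byte-identical outputs and manifests. A stage
#' failure aborts the run naming the stage; files already written are kept.
#'
#' @param config A [pipeline_config()] (or a list of its arguments).
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$out_dir, f)
  files <- character(0)
  emit <- function(f) files <<- c(files, f)
  st <- config$stages

  if ("simulate" %in% st) run_stage("simulate", {
    sim <- simulate_counts(config$scenario)
    write_taxa_table(sim$table, path("counts.tsv")); emit("counts.tsv")
    write_group_design(sim$design, path("design.tsv")); emit("design.tsv")
    write.table(sim$truth, path("truth.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE); emit("truth.tsv")
  })

  rel <- run_stage("load_inputs", {
    table <- read_taxa_table(path("counts.tsv"))
    to_relative(table)
  })
  design <- run_stage("load_inputs", read_group_design(path("design.tsv")))

  if ("diffabund" %in% st) run_stage("diffabund", {
    for (r in config$ranks) {
      res <- differential_abundance(rel, design, r,
                                    prevalence_min = config$prevalence_min)
      f <- sprintf("diffabund_%s.tsv", r)
      write_diff_results(res, path(f)); emit(f)
    }
  })

  if ("diversity" %in% st) run_stage("diversity", {
    sh <- shannon_per_sample(rel)
    write.table(data.frame(sample_id = names(sh), shannon = sprintf("%.10g", sh)),
                path("shannon.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE); emit("shannon.tsv")
    bc <- bray_curtis_matrix(rel)
    write_distance_matrix(bc, path("bray_curtis.tsv")); emit("bray_curtis.tsv")
    ord <- pcoa(bc, k = 2)
    write_ordination(ord, path("pcoa.tsv")); emit("pcoa.tsv")
    pt <- permutation_group_test(bc, design, n_perm = config$n_perm,
                                 seed = derive_seed(config$seed, 101))
    write.table(data.frame(statistic = sprintf("%.10g", pt$statistic),
                           p_value = sprintf("%.10g", pt$p_value),
                           n_perm = pt$n_perm),
                path("permutation_test.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE); emit("permutation_test.tsv")
    pf <- bf_ratio(collapse_rank(rel, "phylum"))
    write.table(pf, path("bf_ratio.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE); emit("bf_ratio.tsv")
  })

  if ("funcgroups" %in% st) run_stage("funcgroups", {
    gp <- group_proportions(collapse_rank(rel, "genus"))
    long <- data.frame(sample_id = rep(rownames(gp), ncol(gp)),
                       group = rep(colnames(gp), each = nrow(gp)),
                       proportion = sprintf("%.10g", as.vector(gp)))
    write.table(long, path("group_proportions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE); emit("group_proportions.tsv")
    write.table(compare_group_proportions(gp, design),
                path("group_tests.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE); emit("group_tests.tsv")
  })

  if ("profile" %in% st) run_stage("profile", {
    res <- differential_abundance(rel, design, config$profile_rank,
                                  prevalence_min = config$prevalence_min)
    prof <- extract_signed_profile(res, alpha = config$alpha,
                                   disease = config$disease)
    write_profiles(prof, path("case_profile.tsv")); emit("case_profile.tsv")
  })

  if ("hmdn" %in% st) run_stage("hmdn", {
    assoc <- simulate_associations(config$assoc_scenario)
    write_associations(assoc$records, path("associations.tsv"))
    emit("associations.tsv")
    profiles <- build_profiles(read_associations(path("associations.tsv")))
    case_prof <- read_profiles(path("case_profile.tsv"))
    profiles <- c(profiles, case_prof)
    net <- build_network(profiles, alpha = config$alpha,
                         n_perm = config$n_perm,
                         seed = derive_seed(config$seed, 202),
                         pinned = config$disease)
    write_network(net, path("network_edges.tsv"), format = "tsv")
    emit("network_edges.tsv")
    write_network(net, path("network.graphml"), format = "graphml")
    emit("network.graphml")
    nb <- disease_neighbors(net, config$disease)
    write.table(nb, path("neighbors.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE); emit("neighbors.tsv")
  })

  manifest <- list(
    package = "gutnet",
    version = as.character(packageVersion("gutnet")),
    seed = config$seed,
    parameters = list(alpha = config$alpha,
                      prevalence_min = config$prevalence_min,
                      n_perm = config$n_perm, ranks = config$ranks,
                      profile_rank = config$profile_rank,
                      disease = config$disease,
                      scenario_seed = config$scenario$seed,
                      assoc_seed = config$assoc_scenario$seed),
    stages = config$stages,
    files = as.list(setNames(unname(md5sum(file.path(config$out_dir, files))),
                             files)))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
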