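# Synthetic community and association generators with planted ground truth.
# These define the study conditions every downstream stage is validated on.

#' Define a two-group community scenario
#'
#' A scenario fixes everything the Dirichlet-multinomial simulator needs:
#' group sizes, the taxon set with lineages, the control-group baseline
#' composition, multiplicative fold changes applied in the case group,
#' the Dirichlet concentration (overdispersion), and the lognormal law for
#' per-sample library sizes.
#'
#' @param n_case,n_control Group sizes (each at least 1).
#' @param taxa Data frame with columns `taxon_id` plus the seven
#'   [taxa_ranks()] columns.
#' @param baseline_props Numeric vector of control-group proportions, one per
#'   taxon, summing to 1 within 1e-12.
#' @param fold_changes Named numeric vector of positive multipliers applied
#'   to baseline proportions in the case group (names are taxon ids); taxa
#'   not named keep fold 1.
#' @param dispersion Dirichlet concentration (total); larger means less
#'   between-sample overdispersion.
#' @param library_size_mean,library_size_shape Arithmetic mean and lognormal
#'   shape (sdlog) of per-sample total counts; draws are rounded with a floor
#'   of 1000 reads so no sample is empty.
#' @param seed Integer seed driving all randomness of the scenario.
#' @return A `community_scenario` object.
#' @seealso [default_asd_scenario()], [simulate_counts()],
#'   [expected_proportions()]
#' @export
community_scenario <- function(n_case, n_control, taxa, baseline_props,
                               fold_changes = numeric(0), dispersion = 200,
                               library_size_mean = 30000,
                               library_size_shape = 0.5, seed = 1) {
  if (n_case < 1 || n_control < 1)
    stop_("n_case and n_control must each be at least 1")
  need <- c("taxon_id", .gg_ranks)
  if (!is.data.frame(taxa) || !all(need %in% names(taxa)))
    stop_("taxa must be a data frame with columns: %s",
          paste(need, collapse = ", "))
  if (anyDuplicated(taxa$taxon_id)) stop_("taxon ids must be unique")
  k <- nrow(taxa)
  baseline_props <- as.numeric(baseline_props)
  if (length(baseline_props) != k)
    stop_("baseline_props must have one entry per taxon")
  if (any(baseline_props < 0))
    stop_("baseline proportions must be non-negative")
  if (abs(sum(baseline_props) - 1) > 1e-12)
    stop_("baseline_props must sum to 1 (got %.15f)", sum(baseline_props))
  if (length(fold_changes)) {
    if (is.null(names(fold_changes)) ||
        !all(names(fold_changes) %in% taxa$taxon_id))
      stop_("fold_changes must be named by taxon id")
    if (any(fold_changes <= 0)) stop_("fold changes must be positive")
  }
  if (dispersion <= 0) stop_("dispersion must be positive")
  if (library_size_mean <= 0 || library_size_shape < 0)
    stop_("library size law must have positive mean and non-negative shape")
  structure(list(n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 taxa = taxa, baseline_props = baseline_props,
                 fold_changes = fold_changes, dispersion = dispersion,
                 library_size_mean = library_size_mean,
                 library_size_shape = library_size_shape,
                 seed = as.integer(seed)),
            class = "community_scenario")
}

#' @export
print.community_scenario <- function(x, ...) {
  cat(sprintf("community scenario: %d case + %d control samples, %d taxa, %d planted effect(s), seed %d\n",
              x$n_case, x$n_control, nrow(x$taxa),
              length(x$fold_changes), x$seed))
  invisible(x)
}

#' Expected group composition of a scenario
#'
#' Closed form of the planted-effect construction: case proportions are
#' `f_i * p_i / sum_j f_j * p_j`, control proportions are the baseline.
#'
#' @param scenario A `community_scenario`.
#' @return Matrix with rows `control` and `case`, one column per taxon.
#' @export
expected_proportions <- function(scenario) {
  stopifnot(inherits(scenario, "community_scenario"))
  p <- scenario$baseline_props
  f <- rep(1, length(p))
  names(f) <- scenario$taxa$taxon_id
  f[names(scenario$fold_changes)] <- scenario$fold_changes
  q <- f * p
  rbind(control = setNames(p, scenario$taxa$taxon_id),
        case = q / sum(q))
}

scenario_lineage <- function(scenario) {
  lin <- as.matrix(scenario$taxa[, .gg_ranks])
  storage.mode(lin) <- "character"
  lin[is.na(lin)] <- ""
  rownames(lin) <- scenario$taxa$taxon_id
  lin
}

#' Simulate a taxon count table with planted effects
#'
#' Each sample draws its composition from a Dirichlet distribution centred
#' on its group's expected proportions with total concentration
#' `dispersion`, then draws counts multinomially at a lognormal library size
#' (rounded, floored at 1000). Case-group proportions are the renormalized
#' fold-changed baseline (see [expected_proportions()]). Every sample uses a
#' deterministic sub-seed derived from the scenario seed, so identical
#' scenarios give identical tables.
#'
#' @param scenario A `community_scenario`.
#' @return List with `table` (a `taxa_table`), `design` (a `group_design`)
#'   and `truth`, a data frame listing each planted taxon once with its
#'   `fold`, `direction` (+1/-1) and its label after genus-level collapsing.
#' @export
simulate_counts <- function(scenario) {
  stopifnot(inherits(scenario, "community_scenario"))
  ep <- expected_proportions(scenario)
  k <- ncol(ep)
  ids <- c(sprintf("case_%02d", seq_len(scenario$n_case)),
           sprintf("control_%02d", seq_len(scenario$n_control)))
  grp <- rep(c("case", "control"), c(scenario$n_case, scenario$n_control))
  meanlog <- log(scenario$library_size_mean) -
    scenario$library_size_shape^2 / 2
  counts <- matrix(0L, length(ids), k, dimnames = list(ids, colnames(ep)))
  for (i in seq_along(ids)) {
    counts[i, ] <- with_seed(derive_seed(scenario$seed, i), {
      size <- max(1000, round(rlnorm(1, meanlog, scenario$library_size_shape)))
      alpha <- scenario$dispersion * ep[grp[i], ]
      g <- rgamma(k, shape = alpha)
      as.integer(rmultinom(1, size, g / sum(g)))
    })
  }
  lin <- scenario_lineage(scenario)
  planted <- scenario$fold_changes[scenario$fold_changes != 1]
  idx <- match(names(planted), scenario$taxa$taxon_id)
  truth <- data.frame(taxon_id = names(planted),
                      genus_label = if (length(idx))
                        collapse_labels(lin, "genus")[idx] else character(0),
                      fold = unname(planted),
                      direction = ifelse(planted > 1, 1L, -1L),
                      stringsAsFactors = FALSE, row.names = NULL)
  list(table = taxa_table(counts, lin),
       design = group_design(ids, grp),
       truth = truth)
}

gg_row <- function(taxon_id, phylum, family = "", genus = "",
                   kingdom = "Bacteria") {
  data.frame(taxon_id = taxon_id, kingdom = kingdom, phylum = phylum,
             class = "", order = "", family = family, genus = genus,
             species = "", stringsAsFactors = FALSE)
}

#' Default ASD-vs-TD community scenario
#'
#' An unbalanced 35-case vs 6-control gut-community scenario. Control
#' baselines put the Bacteroidetes phylum near 0.31 and let Firmicutes absorb
#' most of the remainder; the case group plants 4-fold increases on the major
#' Bacteroidetes genera (so the case group is Bacteroidetes-enriched and,
#' after renormalization, Firmicutes-depleted) and 4-fold decreases
#' (fold 0.25) on eight genera commonly depleted in ASD gut communities
#' (Streptococcus, Veillonella, Escherichia, the unclassified Clostridiaceae
#' bucket, Actinomyces, Parvimonas, Bulleidia, Peptoniphilus) plus the
#' kingdom-only `Bacteria_unclass` bucket.
#'
#' @param include_abstract_trio Also plant 4-fold case-group increases on
#'   Sutterella, Odoribacter and Butyricimonas (reported elsewhere as ASD
#'   increases but without a significance level; off by default).
#' @param seed Scenario seed.
#' @return A `community_scenario`.
#' @export
default_asd_scenario <- function(include_abstract_trio = FALSE, seed = 1) {
  taxa <- rbind(
    gg_row("otu_bacteroides",     "Bacteroidetes",  "Bacteroidaceae",     "Bacteroides"),
    gg_row("otu_prevotella",      "Bacteroidetes",  "Prevotellaceae",     "Prevotella"),
    gg_row("otu_parabacteroides", "Bacteroidetes",  "Porphyromonadaceae", "Parabacteroides"),
    gg_row("otu_odoribacter",     "Bacteroidetes",  "Odoribacteraceae",   "Odoribacter"),
    gg_row("otu_butyricimonas",   "Bacteroidetes",  "Odoribacteraceae",   "Butyricimonas"),
    gg_row("otu_faecalibacterium","Firmicutes",     "Ruminococcaceae",    "Faecalibacterium"),
    gg_row("otu_oscillospira",    "Firmicutes",     "Ruminococcaceae",    "Oscillospira"),
    gg_row("otu_subdoligranulum", "Firmicutes",     "Ruminococcaceae",    "Subdoligranulum"),
    gg_row("otu_roseburia",       "Firmicutes",     "Lachnospiraceae",    "Roseburia"),
    gg_row("otu_anaerostipes",    "Firmicutes",     "Lachnospiraceae",    "Anaerostipes"),
    gg_row("otu_lachnospiraceae", "Firmicutes",     "Lachnospiraceae",    ""),
    gg_row("otu_streptococcus",   "Firmicutes",     "Streptococcaceae",   "Streptococcus"),
    gg_row("otu_lactococcus",     "Firmicutes",     "Streptococcaceae",   "Lactococcus"),
    gg_row("otu_veillonella",     "Firmicutes",     "Veillonellaceae",    "Veillonella"),
    gg_row("otu_clostridiaceae",  "Firmicutes",     "Clostridiaceae",     ""),
    gg_row("otu_parvimonas",      "Firmicutes",     "Tissierellaceae",    "Parvimonas"),
    gg_row("otu_bulleidia",       "Firmicutes",     "Erysipelotrichaceae","Bulleidia"),
    gg_row("otu_peptoniphilus",   "Firmicutes",     "Tissierellaceae",    "Peptoniphilus"),
    gg_row("otu_lactobacillus",   "Firmicutes",     "Lactobacillaceae",   "Lactobacillus"),
    gg_row("otu_eubacterium",     "Firmicutes",     "Eubacteriaceae",     "Eubacterium"),
    gg_row("otu_escherichia",     "Proteobacteria", "Enterobacteriaceae", "Escherichia"),
    gg_row("otu_sutterella",      "Proteobacteria", "Alcaligenaceae",     "Sutterella"),
    gg_row("otu_bifidobacterium", "Actinobacteria", "Bifidobacteriaceae", "Bifidobacterium"),
    gg_row("otu_actinomyces",     "Actinobacteria", "Actinomycetaceae",   "Actinomyces"),
    gg_row("otu_akkermansia",     "Verrucomicrobia","Verrucomicrobiaceae","Akkermansia"),
    gg_row("otu_fusobacterium",   "Fusobacteria",   "Fusobacteriaceae",   "Fusobacterium"),
    gg_row("otu_bacteria_unclass","",               "",                   "")
  )
  baseline <- c(
    otu_bacteroides = 0.200, otu_prevotella = 0.060,
    otu_parabacteroides = 0.030, otu_odoribacter = 0.012,
    otu_butyricimonas = 0.008,
    otu_faecalibacterium = 0.110, otu_oscillospira = 0.040,
    otu_subdoligranulum = 0.012, otu_roseburia = 0.035,
    otu_anaerostipes = 0.010, otu_lachnospiraceae = 0.080,
    otu_streptococcus = 0.025, otu_lactococcus = 0.004,
    otu_veillonella = 0.027, otu_clostridiaceae = 0.050,
    otu_parvimonas = 0.008, otu_bulleidia = 0.006,
    otu_peptoniphilus = 0.005, otu_lactobacillus = 0.010,
    otu_eubacterium = 0.020,
    otu_escherichia = 0.024, otu_sutterella = 0.014,
    otu_bifidobacterium = 0.030, otu_actinomyces = 0.010,
    otu_akkermansia = 0.015, otu_fusobacterium = 0.010,
    otu_bacteria_unclass = 0.145)
  stopifnot(identical(names(baseline), taxa$taxon_id))
  folds <- c(otu_bacteroides = 4, otu_prevotella = 4, otu_parabacteroides = 4,
             otu_streptococcus = 0.25, otu_veillonella = 0.25,
             otu_escherichia = 0.25, otu_clostridiaceae = 0.25,
             otu_actinomyces = 0.25, otu_parvimonas = 0.25,
             otu_bulleidia = 0.25, otu_peptoniphilus = 0.25,
             otu_bacteria_unclass = 0.25)
  if (include_abstract_trio)
    folds <- c(folds, otu_sutterella = 4, otu_odoribacter = 4,
               otu_butyricimonas = 4)
  community_scenario(n_case = 35, n_control = 6, taxa = taxa,
                     baseline_props = baseline, fold_changes = folds,
                     seed = seed)
}

#' Define a microbe-disease association scenario
#'
#' Background associations are sampled independently per (disease, microbe)
#' pair at rate `density` with a random direction. Planted disease pairs
#' additionally share exactly `n_shared` microbes whose signs agree on a
#' `consistency` fraction of them.
#'
#' @param n_diseases,n_microbes Universe sizes.
#' @param density Probability of a background association.
#' @param planted_pairs List of lists with elements `a`, `b` (disease names
#'   of the form `"disease_01"`), `n_shared` and `consistency` in `[0, 1]`.
#' @param seed Integer seed.
#' @return An `association_scenario`.
#' @export
association_scenario <- function(n_diseases, n_microbes, density,
                                 planted_pairs = list(), seed = 1) {
  if (density < 0 || density > 1) stop_("density must lie in [0, 1]")
  if (n_diseases < 1 || n_microbes < 1)
    stop_("universe sizes must be positive")
  diseases <- sprintf("disease_%02d", seq_len(n_diseases))
  for (pp in planted_pairs) {
    if (!all(c("a", "b", "n_shared", "consistency") %in% names(pp)))
      stop_("each planted pair needs fields a, b, n_shared, consistency")
    if (!all(c(pp$a, pp$b) %in% diseases))
      stop_("planted pair names unknown disease '%s'",
            setdiff(c(pp$a, pp$b), diseases)[1])
    if (pp$a == pp$b) stop_("planted pair must name two distinct diseases")
    if (pp$n_shared > n_microbes)
      stop_("n_shared (%d) exceeds n_microbes (%d)", pp$n_shared, n_microbes)
    if (pp$consistency < 0 || pp$consistency > 1)
      stop_("consistency must lie in [0, 1]")
  }
  structure(list(n_diseases = as.integer(n_diseases),
                 n_microbes = as.integer(n_microbes),
                 density = density, planted_pairs = planted_pairs,
                 seed = as.integer(seed)),
            class = "association_scenario")
}

#' Simulate signed microbe-disease association records
#'
#' @param scenario An `association_scenario`.
#' @return List with `records` (data frame: `disease`, `microbe`,
#'   `direction` in increase/decrease, `evidence`) and `truth`, one row per
#'   planted pair with its expected edge sign (+1 if consistency > 0.5, -1
#'   if < 0.5, 0 at exactly 0.5).
#' @export
simulate_associations <- function(scenario) {
  stopifnot(inherits(scenario, "association_scenario"))
  nd <- scenario$n_diseases; nm <- scenario$n_microbes
  diseases <- sprintf("disease_%02d", seq_len(nd))
  microbes <- sprintf("microbe_%03d", seq_len(nm))
  signs <- with_seed(scenario$seed, {
    m <- matrix(0L, nd, nm, dimnames = list(diseases, microbes))
    present <- matrix(stats::runif(nd * nm) < scenario$density, nd, nm)
    m[present] <- sample(c(-1L, 1L), sum(present), replace = TRUE)
    for (pp in scenario$planted_pairs) {
      shared <- sample.int(nm, pp$n_shared)
      sa <- sample(c(-1L, 1L), pp$n_shared, replace = TRUE)
      sb <- sa
      n_flip <- pp$n_shared - round(pp$consistency * pp$n_shared)
      if (n_flip > 0) {
        flip <- sample.int(pp$n_shared, n_flip)
        sb[flip] <- -sa[flip]
      }
      m[pp$a, shared] <- sa
      m[pp$b, shared] <- sb
      # enforce "exactly n_shared": drop chance co-occurrences outside the
      # planted set from the second disease
      extra <- setdiff(which(m[pp$a, ] != 0L & m[pp$b, ] != 0L), shared)
      if (length(extra)) m[pp$b, extra] <- 0L
    }
    m
  })
  hit <- which(signs != 0L, arr.ind = TRUE)
  ord <- order(hit[, 1], hit[, 2])
  hit <- hit[ord, , drop = FALSE]
  records <- data.frame(
    disease = diseases[hit[, 1]],
    microbe = microbes[hit[, 2]],
    direction = as.character(ifelse(signs[hit] > 0, "increase",
                                    "decrease")),
    evidence = rep("synthetic", nrow(hit)),
    stringsAsFactors = FALSE, row.names = NULL)
  truth <- do.call(rbind, lapply(scenario$planted_pairs, function(pp)
    data.frame(disease_a = pp$a, disease_b = pp$b,
               n_shared = as.integer(pp$n_shared),
               consistency = pp$consistency,
               expected_sign = as.integer(sign(pp$consistency - 0.5)),
               stringsAsFactors = FALSE)))
  if (is.null(truth))
    truth <- data.frame(disease_a = character(0), disease_b = character(0),
                        n_shared = integer(0), consistency = numeric(0),
                        expected_sign = integer(0))
  list(records = records, truth = truth)
}

#' Write association records to TSV
#'
#' @param records Data frame as produced by [simulate_associations()].
#' @param path Output path.
#' @export
write_associations <- function(records, path) {
  need <- c("disease", "microbe", "direction")
  if (!all(need %in% names(records)))
    stop_("records must have columns %s", paste(need, collapse = ", "))
  if (is.null(records$evidence)) records$evidence <- ""
  write.table(records[, c("disease", "microbe", "direction", "evidence")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
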