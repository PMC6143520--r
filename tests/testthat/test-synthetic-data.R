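tiny_scenario <- function(folds = numeric(0), seed = 1, n_case = 4,
                          n_control = 4, dispersion = 200) {
  taxa <- data.frame(taxon_id = c("tA", "tB", "tC"),
                     kingdom = "Bacteria",
                     phylum = c("Bacteroidetes", "Firmicutes", "Firmicutes"),
                     class = "", order = "", family = "",
                     genus = c("Bacteroides", "Roseburia", "Veillonella"),
                     species = "", stringsAsFactors = FALSE)
  community_scenario(n_case, n_control, taxa,
                     baseline_props = c(0.1, 0.6, 0.3),
                     fold_changes = folds, dispersion = dispersion,
                     seed = seed)
}

test_that("planted fold changes renormalize in closed form", {
  sc <- tiny_scenario(folds = c(tA = 4))
  ep <- expected_proportions(sc)
  # f*p / (1 + (f-1)*p) with p = 0.1, f = 4
  expect_equal(unname(ep["case", "tA"]), 0.4 / 1.3, tolerance = 1e-12)
  expect_equal(unname(ep["control", ]), c(0.1, 0.6, 0.3))
  expect_equal(sum(ep["case", ]), 1, tolerance = 1e-12)
})

test_that("no planted effects means both groups share one composition and row sums are library sizes", {
  sc <- tiny_scenario()
  ep <- expected_proportions(sc)
  expect_equal(ep["case", ], ep["control", ])
  sim <- simulate_counts(sc)
  expect_equal(nrow(sim$table$values), sc$n_case + sc$n_control)
  expect_true(all(rowSums(sim$table$values) >= 1000))
  expect_equal(nrow(sim$truth), 0L)
})

test_that("simulation is deterministic: same seed, byte-identical output", {
  sc <- tiny_scenario(folds = c(tC = 0.25), seed = 99)
  a <- simulate_counts(sc)
  b <- simulate_counts(sc)
  expect_identical(a, b)
  fa <- withr::local_tempfile(); fb <- withr::local_tempfile()
  write_taxa_table(a$table, fa)
  write_taxa_table(b$table, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
})

test_that("sampled compositions approach the group vector at deep sequencing", {
  sc <- tiny_scenario(folds = c(tA = 4), n_case = 3, n_control = 3,
                      dispersion = 1e8)
  sc$library_size_mean <- 1e6
  sc$library_size_shape <- 0
  sim <- simulate_counts(sc)
  rel <- to_relative(sim$table)$values
  ep <- expected_proportions(sc)
  grp <- sim$design$group
  expect_true(max(abs(t(rel[grp == "case", ]) - ep["case", ])) < 0.01)
  expect_true(max(abs(t(rel[grp == "control", ]) - ep["control", ])) < 0.01)
})

test_that("scenario invariants are enforced", {
  expect_error(tiny_scenario(folds = c(tA = -2)), "positive")
  expect_error(tiny_scenario(folds = c(nope = 2)), "named by taxon id")
  sc <- tiny_scenario()
  expect_error(community_scenario(0, 4, sc$taxa, sc$baseline_props),
               "at least 1")
  expect_error(community_scenario(4, 4, sc$taxa, c(0.5, 0.4, 0.2)),
               "sum to 1")
  expect_error(community_scenario(4, 4, sc$taxa, c(-0.1, 0.8, 0.3)),
               "non-negative")
})

test_that("the default ASD scenario matches its stated design", {
  sc <- default_asd_scenario()
  expect_equal(sc$n_case, 35L)
  expect_equal(sc$n_control, 6L)
  dec <- names(sc$fold_changes)[sc$fold_changes < 1]
  expect_true(all(c("otu_streptococcus", "otu_veillonella",
                    "otu_escherichia", "otu_clostridiaceae",
                    "otu_actinomyces", "otu_parvimonas", "otu_bulleidia",
                    "otu_peptoniphilus") %in% dec))
  sim <- simulate_counts(sc)
  expect_equal(nrow(sim$truth), length(sc$fold_changes))
  expect_equal(anyDuplicated(sim$truth$taxon_id), 0L)
  # the eight decreased genera appear under their genus-level labels
  expect_true(all(c("Streptococcus", "Veillonella", "Escherichia",
                    "Clostridiaceae_unclass") %in% sim$truth$genus_label))
  trio <- default_asd_scenario(include_abstract_trio = TRUE)
  expect_true(all(c("otu_sutterella", "otu_odoribacter",
                    "otu_butyricimonas") %in% names(trio$fold_changes)))
})

test_that("the simulated case group is Bacteroidetes-enriched across seeds", {
  higher <- vapply(1:20, function(s) {
    sim <- simulate_counts(default_asd_scenario(seed = s))
    ph <- collapse_rank(to_relative(sim$table), "phylum")
    grp <- sim$design$group
    mean(ph$values[grp == "case", "Bacteroidetes"]) >
      mean(ph$values[grp == "control", "Bacteroidetes"])
  }, TRUE)
  expect_true(all(higher))
})

test_that("association simulation honours density and planting exactly", {
  empty <- simulate_associations(association_scenario(5, 20, 0, seed = 1))
  expect_equal(nrow(empty$records), 0L)

  sc <- association_scenario(10, 50, 0.1, seed = 42)
  n <- nrow(simulate_associations(sc)$records)
  expect_lt(abs(n - 50), 3 * sqrt(500 * 0.1 * 0.9) + 1e-9)

  pp <- list(list(a = "disease_01", b = "disease_02", n_shared = 5,
                  consistency = 1.0))
  sim <- simulate_associations(association_scenario(6, 40, 0.1,
                                                    planted_pairs = pp,
                                                    seed = 7))
  profs <- build_profiles(sim$records)
  a <- profs[["disease_01"]]$signs
  b <- profs[["disease_02"]]$signs
  shared <- intersect(names(a), names(b))
  expect_equal(length(shared), 5L)
  expect_true(all(a[shared] == b[shared]))
  expect_equal(nrow(sim$truth), 1L)
  expect_equal(sim$truth$expected_sign, 1L)

  expect_error(association_scenario(4, 4, 0.1, planted_pairs = list(
    list(a = "disease_01", b = "disease_02", n_shared = 9,
         consistency = 1))), "exceeds")
  expect_error(association_scenario(4, 10, 1.5), "density")
})
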