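mk_profile <- function(disease, ...) {
  signs <- c(...)
  signed_profile(disease, setNames(as.integer(signs), names(signs)))
}

test_that("microbe names normalize to one key convention", {
  expect_equal(normalize_microbe("g__Veillonella"), "veillonella")
  expect_equal(normalize_microbe(" Veillonella "), "veillonella")
  expect_equal(normalize_microbe("Clostridium difficile"), "clostridium")
  expect_equal(normalize_microbe("Clostridiaceae_unclass"),
               "clostridiaceae_unclass")
  expect_equal(normalize_microbe("g__Veillonella"),
               normalize_microbe("Veillonella"))
})

test_that("association TSVs are validated and direction tokens mapped", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("disease\tmicrobe\tdirection\tevidence",
               "ASD\tg__Veillonella\tdecrease\tpmid:1",
               "T1D\tVeillonella\tincrease\tpmid:2"), f)
  rec <- read_associations(f)
  expect_equal(rec$microbe, c("veillonella", "veillonella"))
  profs <- build_profiles(rec)
  expect_equal(profs[["ASD"]]$signs, c(veillonella = -1L))
  expect_equal(profs[["T1D"]]$signs, c(veillonella = 1L))

  writeLines(c("disease\tmicrobe\tdirection\tevidence",
               "ASD\tVeillonella\tdecrease\t",
               "ASD\tBacteroides\televated\t"), f)
  expect_error(read_associations(f), "line 3.*elevated")
})

test_that("profile construction votes by majority and drops exact ties", {
  rec <- data.frame(
    disease = "d", microbe = c("m1", "m1", "m1", "m2", "m2"),
    direction = c("increase", "increase", "decrease", "increase",
                  "decrease"),
    stringsAsFactors = FALSE)
  expect_warning(profs <- build_profiles(rec), "tied")
  expect_equal(profs[["d"]]$signs, c(m1 = 1L))
  one <- build_profiles(data.frame(disease = "d", microbe = "m",
                                   direction = "increase"))
  expect_equal(one[["d"]]$signs, c(m = 1L))
})

test_that("signed similarity hits its closed-form extremes", {
  a <- mk_profile("a", m1 = 1, m2 = -1)
  expect_equal(microbe_similarity(a, mk_profile("b", m1 = 1, m2 = -1)), 1)
  expect_equal(microbe_similarity(a, mk_profile("b", m1 = -1, m2 = 1)), -1)
  expect_equal(microbe_similarity(a, mk_profile("b", m3 = 1, m4 = 1)), 0)
  x <- mk_profile("x", m1 = 1, m2 = -1, m3 = 1)
  y <- mk_profile("y", m1 = 1, m2 = 1)
  expect_equal(microbe_similarity(x, y), 0)  # (1 - 1) / sqrt(6)
  # a Veillonella decrease in one disease and increase in the other
  # contributes -1 to the shared-sign sum
  asd <- mk_profile("ASD", veillonella = -1, bacteroides = 1)
  t1d <- mk_profile("T1D", veillonella = 1)
  expect_equal(microbe_similarity(asd, t1d), -1 / sqrt(2))
  expect_error(microbe_similarity(a, signed_profile("e", integer(0))),
               "non-empty")
})

test_that("similarity is symmetric, bounded, and order-invariant", {
  set.seed(31)
  for (i in 1:50) {
    u <- paste0("m", 1:12)
    a <- mk_profile("a", setNames(sample(c(-1, 1), 6, TRUE),
                                  sample(u, 6)))
    b <- mk_profile("b", setNames(sample(c(-1, 1), 8, TRUE),
                                  sample(u, 8)))
    s <- microbe_similarity(a, b)
    expect_lte(abs(s), 1)
    expect_equal(microbe_similarity(b, a), s)
    ashuf <- signed_profile("a", a$signs[sample(seq_along(a$signs))])
    expect_equal(microbe_similarity(ashuf, b), s)
  }
})

test_that("permutation p-values respect smoothing, symmetry and the universe", {
  a <- mk_profile("a", m1 = 1, m2 = 1, m3 = 1)
  b <- mk_profile("b", m1 = 1, m2 = 1, m3 = 1)
  u <- paste0("m", 1:40)
  p <- similarity_pvalue(a, b, u, n_perm = 199, seed = 8)
  expect_gte(p, 1 / 200)
  expect_equal(similarity_pvalue(b, a, u, n_perm = 199, seed = 8), p)
  expect_error(similarity_pvalue(a, b, c("m1", "m2"), n_perm = 199),
               "universe")
  # adding microbes absent from both profiles changes S not at all
  expect_equal(microbe_similarity(a, b), 1)
})

test_that("build_network keeps signed significant edges only", {
  a <- mk_profile("a", m1 = 1, m2 = 1, m3 = 1, m4 = 1, m5 = 1)
  b <- mk_profile("b", m1 = 1, m2 = 1, m3 = 1, m4 = 1, m5 = 1)
  c_ <- mk_profile("c", m1 = -1, m2 = -1, m3 = -1, m4 = -1, m5 = -1)
  d <- mk_profile("d", setNames(rep(c(1, -1), 5), paste0("m", 6:15)))
  profs <- list(a, b, c_, d)
  net <- build_network(profs, alpha = 0.05, n_perm = 199, seed = 2,
                       pinned = "d")
  key <- paste(net$edges$disease_a, net$edges$disease_b)
  expect_true("a b" %in% key)
  expect_equal(net$edges$sign[key == "a b"], "positive")
  expect_true(all(c("a c", "b c") %in% key))
  expect_equal(net$edges$sign[key == "a c"], "negative")
  expect_true("d" %in% net$nodes)
  expect_true(all(net$edges$p < 0.05))
  expect_true(all((net$edges$score > 0) == (net$edges$sign == "positive")))

  disjoint <- build_network(list(a, d), alpha = 0.05, n_perm = 199,
                            seed = 2)
  expect_equal(nrow(disjoint$edges), 0L)
})

test_that("planted association pairs are recovered with their sign", {
  hits <- 0L
  for (s in 1:5) {
    sc <- association_scenario(8, 60, 0.1, planted_pairs = list(
      list(a = "disease_01", b = "disease_02", n_shared = 5,
           consistency = 1.0),
      list(a = "disease_03", b = "disease_04", n_shared = 5,
           consistency = 0.0)), seed = s)
    profs <- build_profiles(simulate_associations(sc)$records)
    net <- build_network(profs, alpha = 0.05, n_perm = 999, seed = s)
    key <- paste(net$edges$disease_a, net$edges$disease_b)
    ok_pos <- "disease_01 disease_02" %in% key &&
      net$edges$sign[key == "disease_01 disease_02"] == "positive"
    ok_neg <- "disease_03 disease_04" %in% key &&
      net$edges$sign[key == "disease_03 disease_04"] == "negative"
    if (ok_pos && ok_neg) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("neighbors rank by absolute similarity with sign retained", {
  net <- structure(list(
    nodes = c("ASD", "periodontitis", "t1d", "lonely"),
    edges = data.frame(disease_a = c("ASD", "ASD"),
                       disease_b = c("periodontitis", "t1d"),
                       score = c(0.9, -0.4), shared = c(4L, 2L),
                       p = c(0.001, 0.02),
                       sign = c("positive", "negative"),
                       stringsAsFactors = FALSE)),
    class = "disease_network")
  nb <- disease_neighbors(net, "ASD")
  expect_equal(nb$neighbor, c("periodontitis", "t1d"))
  expect_equal(nb$score, c(0.9, -0.4))
  expect_equal(nrow(disease_neighbors(net, "lonely")), 0L)
  expect_error(disease_neighbors(net, "nope"), "unknown disease")
})

test_that("an ASD-like profile links positively to consistent and negatively to reversed diseases", {
  core <- c(bacteroidetes = 1, streptococcus = -1, veillonella = -1,
            escherichia = -1, parvimonas = -1, bulleidia = -1,
            prevotella = 1, parabacteroides = 1)
  asd <- mk_profile("ASD", core)
  periodontitis <- mk_profile("periodontitis",
                              c(core, porphyromonas = 1, treponema = 1))
  t1d <- mk_profile("t1d", c(-core, blautia = 1, dorea = -1))
  net <- build_network(list(asd, periodontitis, t1d), alpha = 0.05,
                       n_perm = 999, seed = 4, pinned = "ASD")
  nb <- disease_neighbors(net, "ASD")
  expect_gt(nb$score[nb$neighbor == "periodontitis"], 0)
  expect_lt(nb$score[nb$neighbor == "t1d"], 0)
})

test_that("networks round-trip through TSV and GraphML, empty and pinned included", {
  a <- mk_profile("a", m1 = 1, m2 = 1, m3 = 1, m4 = 1)
  b <- mk_profile("b", m1 = 1, m2 = 1, m3 = 1, m4 = 1)
  c_ <- mk_profile("c", m1 = -1, m2 = -1, m3 = -1, m4 = -1)
  net <- build_network(list(a, b, c_), alpha = 0.05, n_perm = 199,
                       seed = 6, pinned = "isolated")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, f, "tsv")
  expect_equal(read_network(f, "tsv"), net)
  g <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, g, "graphml")
  back <- read_network(g, "graphml")
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges[order(back$edges$disease_a), ],
               net$edges[order(net$edges$disease_a), ],
               ignore_attr = TRUE)

  empty <- structure(list(nodes = "x",
                          edges = net$edges[0, ]),
                     class = "disease_network")
  fe <- withr::local_tempfile(fileext = ".tsv")
  write_network(empty, fe, "tsv")
  expect_equal(read_network(fe, "tsv")$nodes, "x")
  expect_equal(nrow(read_network(fe, "tsv")$edges), 0L)
})

test_that("signed profiles round-trip through TSV", {
  p1 <- mk_profile("ASD", veillonella = -1, bacteroides = 1)
  p2 <- mk_profile("T1D", veillonella = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profiles(list(p1, p2), f)
  back <- read_profiles(f)
  expect_equal(sort(names(back)), c("ASD", "T1D"))
  expect_equal(back[["ASD"]]$signs[order(names(back[["ASD"]]$signs))],
               p1$signs[order(names(p1$signs))])
})
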