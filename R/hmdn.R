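# Signed microbe-based human disease network (HMDN): association parsing,
# per-disease signed profiles, signed-cosine similarity, permutation
# significance, network assembly and export.

#' Normalize a microbe name
#'
#' Trims whitespace, strips a Greengenes rank prefix (`g__` etc.), extracts
#' the genus token from a binomial (`"Clostridium difficile"` becomes
#' `clostridium`), and lowercases. Underscore-joined bucket labels such as
#' `Clostridiaceae_unclass` are kept whole.
#'
#' @param x Character vector of microbe names.
#' @return Normalized keys.
#' @export
#' @examples
#' normalize_microbe(c("g__Veillonella", " Veillonella "))
normalize_microbe <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("^[kpcofgs]__", "", x)
  x <- sub("\\s.*$", "", x)
  tolower(x)
}

#' Construct a signed microbe profile
#'
#' A disease's microbiome signature: for each microbe, +1 (increased in the
#' disease) or -1 (decreased). Zero signs are not stored.
#'
#' @param disease Disease name.
#' @param signs Named integer vector of +1/-1, named by normalized microbe
#'   keys (see [normalize_microbe()]).
#' @param rank Optional rank context (e.g. `"genus"`).
#' @return A `signed_profile`.
#' @export
signed_profile <- function(disease, signs, rank = NA_character_) {
  if (!nzchar(disease)) stop_("disease name must be non-empty")
  signs <- setNames(as.integer(signs), names(signs))
  if (length(signs)) {
    if (is.null(names(signs)) || any(!nzchar(names(signs))))
      stop_("signs must be named by microbe")
    if (anyDuplicated(names(signs))) stop_("duplicate microbe in profile")
    if (!all(signs %in% c(-1L, 1L)))
      stop_("signs must be +1 or -1 (no zeros stored)")
  }
  structure(list(disease = disease, signs = signs, rank = rank),
            class = "signed_profile")
}

#' @export
print.signed_profile <- function(x, ...) {
  cat(sprintf("signed profile '%s': %d microbe(s) (%d up, %d down)\n",
              x$disease, length(x$signs), sum(x$signs > 0),
              sum(x$signs < 0)))
  invisible(x)
}

#' Read microbe-disease association records from TSV
#'
#' Expects the columns `disease`, `microbe`, `direction` (tokens `increase`
#' or `decrease`) and optionally `evidence`. Microbe names are normalized
#' with [normalize_microbe()]; an unknown direction token raises an error
#' naming the offending line.
#'
#' @param path Path to the TSV file.
#' @return Data frame of validated records.
#' @export
read_associations <- function(path) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("disease", "microbe", "direction")
  if (!all(need %in% names(df)))
    stop_("association file must have columns %s",
          paste(need, collapse = ", "))
  if (is.null(df$evidence)) df$evidence <- ""
  bad <- which(!df$direction %in% c("increase", "decrease"))
  if (length(bad))
    stop_("line %d: unknown direction token '%s'",
          bad[1] + 1L, df$direction[bad[1]])
  empty <- which(!nzchar(trimws(df$disease)) | !nzchar(trimws(df$microbe)))
  if (length(empty))
    stop_("line %d: empty disease or microbe name", empty[1] + 1L)
  df$disease <- trimws(df$disease)
  df$microbe <- normalize_microbe(df$microbe)
  df[, c("disease", "microbe", "direction", "evidence")]
}

#' Build per-disease signed profiles from association records
#'
#' Per (disease, microbe) the sign is decided by majority vote over records;
#' exact ties drop the microbe from that disease's profile with a warning.
#'
#' @param records Data frame from [read_associations()] or
#'   [simulate_associations()] (microbe names are normalized here if needed).
#' @return Named list of [signed_profile()] objects, one per disease, in
#'   alphabetical disease order.
#' @export
build_profiles <- function(records) {
  need <- c("disease", "microbe", "direction")
  if (!all(need %in% names(records)))
    stop_("records must have columns %s", paste(need, collapse = ", "))
  sgn <- ifelse(records$direction == "increase", 1L, -1L)
  key_m <- normalize_microbe(records$microbe)
  diseases <- sort(unique(records$disease))
  out <- lapply(diseases, function(d) {
    sel <- records$disease == d
    votes <- tapply(sgn[sel], key_m[sel], sum)
    tied <- names(votes)[votes == 0]
    if (length(tied))
      warn_("disease '%s': dropping microbe(s) with tied directions: %s",
            d, paste(tied, collapse = ", "))
    votes <- votes[votes != 0]
    signed_profile(d, setNames(as.integer(sign(votes)), names(votes)))
  })
  setNames(out, diseases)
}

#' Signed microbe similarity between two diseases
#'
#' `S(a, b) = sum over shared microbes of sign_a * sign_b /
#' sqrt(|M_a| * |M_b|)`: a signed cosine over \{-1, 0, +1\} microbe vectors,
#' normalized by the geometric mean of the two support sizes. It is
#' symmetric, bounded in `[-1, 1]`, 0 for disjoint profiles, +1 for
#' identical and -1 for fully reversed profiles.
#'
#' @param a,b Non-empty [signed_profile()] objects.
#' @return Similarity score in `[-1, 1]`.
#' @export
microbe_similarity <- function(a, b) {
  stopifnot(inherits(a, "signed_profile"), inherits(b, "signed_profile"))
  if (length(a$signs) == 0L || length(b$signs) == 0L)
    stop_("profiles must be non-empty")
  shared <- intersect(names(a$signs), names(b$signs))
  if (length(shared) == 0L) return(0)
  sum(a$signs[shared] * b$signs[shared]) /
    sqrt(length(a$signs) * length(b$signs))
}

shared_count <- function(a, b) length(intersect(names(a$signs),
                                                names(b$signs)))

#' Permutation p-value for a disease-pair similarity
#'
#' The null redraws each profile's microbe support uniformly from the
#' `universe` at its observed support size, with an independently shuffled
#' sign assignment preserving each profile's sign counts. Two-sided p-value
#' with add-one smoothing:
#' `p = (1 + #\{|S_perm| >= |S_obs|\}) / (1 + n_perm)`. The pair is
#' canonically ordered by disease name first, so `p(a, b) = p(b, a)` for the
#' same seed.
#'
#' @param a,b Non-empty [signed_profile()] objects.
#' @param universe Character vector of microbe keys covering both supports.
#' @param n_perm Number of permutations (at least 99).
#' @param seed Seed for the permutation stream.
#' @return Permutation p-value.
#' @export
similarity_pvalue <- function(a, b, universe, n_perm = 999, seed = 1) {
  stopifnot(inherits(a, "signed_profile"), inherits(b, "signed_profile"))
  if (n_perm < 99) stop_("n_perm must be at least 99")
  if (a$disease > b$disease) { tmp <- a; a <- b; b <- tmp }
  universe <- unique(as.character(universe))
  if (!all(names(a$signs) %in% universe) ||
      !all(names(b$signs) %in% universe))
    stop_("universe must contain every microbe of both profiles")
  s_obs <- abs(microbe_similarity(a, b))
  la <- length(a$signs); lb <- length(b$signs)
  nu <- length(universe)
  sa <- unname(a$signs); sb <- unname(b$signs)
  norm <- sqrt(la * lb)
  count <- with_seed(seed, {
    hits <- 0L
    for (k in seq_len(n_perm)) {
      ia <- sample.int(nu, la)
      ib <- sample.int(nu, lb)
      pa <- sample(sa)
      pb <- sample(sb)
      m <- match(ia, ib)
      sel <- which(!is.na(m))
      s_perm <- if (length(sel))
        abs(sum(pa[sel] * pb[m[sel]])) / norm else 0
      if (s_perm >= s_obs - 1e-12) hits <- hits + 1L
    }
    hits
  })
  (1 + count) / (1 + n_perm)
}

#' Build the signed microbe-based disease network
#'
#' Scores every unordered disease pair with [microbe_similarity()]; pairs
#' sharing at least `min_shared` microbes with a non-zero score are tested
#' with [similarity_pvalue()] (one deterministic sub-seed per pair), and
#' edges with `p < alpha` are kept, labelled positive (score > 0) or
#' negative (score < 0). Nodes are all diseases with a retained edge plus
#' any `pinned` disease.
#'
#' @param profiles List of at least two [signed_profile()] objects.
#' @param alpha Edge significance threshold.
#' @param min_shared Minimum shared-microbe count for a pair to be tested.
#' @param n_perm Permutations per pair.
#' @param seed Base seed; each pair derives its own sub-seed.
#' @param pinned Disease names always kept as nodes (e.g. `"ASD"`).
#' @param adjust `"none"` (default) or `"BH"` to apply [bh_adjust()] across
#'   all tested pairs before thresholding.
#' @return A `disease_network`: list with `nodes` and an `edges` data frame
#'   (`disease_a`, `disease_b`, `score`, `shared`, `p`, `sign`).
#' @export
build_network <- function(profiles, alpha = 0.05, min_shared = 1,
                          n_perm = 999, seed = 1, pinned = character(0),
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (alpha <= 0 || alpha >= 1) stop_("alpha must lie in (0, 1)")
  if (length(profiles) < 2) stop_("need at least 2 profiles")
  names(profiles) <- vapply(profiles, function(p) p$disease, "")
  if (anyDuplicated(names(profiles))) stop_("duplicate disease names")
  profiles <- profiles[order(names(profiles))]
  universe <- unique(unlist(lapply(profiles, function(p) names(p$signs))))
  nd <- length(profiles)
  rows <- list()
  pair_idx <- 0L
  for (i in seq_len(nd - 1)) {
    for (j in (i + 1):nd) {
      pair_idx <- pair_idx + 1L
      a <- profiles[[i]]; b <- profiles[[j]]
      if (length(a$signs) == 0L || length(b$signs) == 0L) next
      sh <- shared_count(a, b)
      if (sh < min_shared) next
      sc <- microbe_similarity(a, b)
      if (sc == 0) next
      pv <- similarity_pvalue(a, b, universe, n_perm = n_perm,
                              seed = derive_seed(seed, pair_idx))
      rows[[length(rows) + 1L]] <-
        data.frame(disease_a = a$disease, disease_b = b$disease,
                   score = sc, shared = as.integer(sh), p = pv,
                   stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(disease_a = character(0), disease_b = character(0),
               score = numeric(0), shared = integer(0), p = numeric(0),
               stringsAsFactors = FALSE)
  crit <- if (adjust == "BH" && nrow(edges)) bh_adjust(edges$p) else edges$p
  edges <- edges[crit < alpha, , drop = FALSE]
  edges$sign <- if (nrow(edges))
    ifelse(edges$score > 0, "positive", "negative") else character(0)
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$disease_a, edges$disease_b, pinned)))
  structure(list(nodes = nodes, edges = edges), class = "disease_network")
}

#' @export
print.disease_network <- function(x, ...) {
  cat(sprintf("disease network: %d node(s), %d edge(s) (%d positive, %d negative)\n",
              length(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "positive"),
              sum(x$edges$sign == "negative")))
  invisible(x)
}

#' Ranked signed neighbors of a disease
#'
#' Neighbors of `disease` in the network, sorted by decreasing absolute
#' similarity with the sign retained — the machine-readable analogue of a
#' signed neighbor-strength bar chart.
#'
#' @param network A `disease_network`.
#' @param disease A node name.
#' @return Data frame with columns `neighbor`, `score`, `shared`, `p`.
#' @export
disease_neighbors <- function(network, disease) {
  stopifnot(inherits(network, "disease_network"))
  if (!disease %in% network$nodes) stop_("unknown disease '%s'", disease)
  e <- network$edges
  sel <- e$disease_a == disease | e$disease_b == disease
  e <- e[sel, , drop = FALSE]
  out <- data.frame(neighbor = ifelse(e$disease_a == disease,
                                      e$disease_b, e$disease_a),
                    score = e$score, shared = e$shared, p = e$p,
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$score), out$neighbor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a disease network
#'
#' Formats: `"tsv"` — an edge list with columns `disease_a`, `disease_b`,
#' `score`, `shared`, `p`, `sign`, preceded by a `# nodes:` comment line so
#' isolated pinned nodes survive the round trip; `"graphml"` — via igraph,
#' with the same edge attributes. Both round-trip losslessly.
#'
#' @param network A `disease_network`.
#' @param path File path.
#' @param format `"tsv"` or `"graphml"`.
#' @return `read_network` returns a `disease_network`.
#' @export
write_network <- function(network, path, format = c("tsv", "graphml")) {
  stopifnot(inherits(network, "disease_network"))
  format <- match.arg(format)
  e <- network$edges
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# nodes: %s", paste(network$nodes, collapse = ",")),
               con)
    e$score <- sprintf("%.17g", e$score)
    e$p <- sprintf("%.17g", e$p)
    write.table(e, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, length(network$nodes),
                              name = network$nodes)
    if (nrow(e)) {
      g <- igraph::add_edges(g, rbind(match(e$disease_a, network$nodes),
                                      match(e$disease_b, network$nodes)))
      igraph::E(g)$score <- e$score
      igraph::E(g)$shared <- e$shared
      igraph::E(g)$p <- e$p
      igraph::E(g)$sign <- e$sign
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    first <- readLines(path, n = 1)
    nodes <- character(0)
    if (startsWith(first, "# nodes:")) {
      spec <- trimws(sub("^# nodes:", "", first))
      if (nzchar(spec)) nodes <- strsplit(spec, ",", fixed = TRUE)[[1]]
    }
    e <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    if (nrow(e)) {
      e$shared <- as.integer(e$shared)
    } else {
      e <- data.frame(disease_a = character(0), disease_b = character(0),
                      score = numeric(0), shared = integer(0),
                      p = numeric(0), sign = character(0),
                      stringsAsFactors = FALSE)
    }
    nodes <- sort(unique(c(nodes, e$disease_a, e$disease_b)))
    structure(list(nodes = nodes, edges = e), class = "disease_network")
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- igraph::V(g)$name
    ee <- igraph::as_edgelist(g)
    if (nrow(ee)) {
      e <- data.frame(disease_a = ee[, 1], disease_b = ee[, 2],
                      score = igraph::E(g)$score,
                      shared = as.integer(igraph::E(g)$shared),
                      p = igraph::E(g)$p, sign = igraph::E(g)$sign,
                      stringsAsFactors = FALSE)
    } else {
      e <- data.frame(disease_a = character(0), disease_b = character(0),
                      score = numeric(0), shared = integer(0),
                      p = numeric(0), sign = character(0),
                      stringsAsFactors = FALSE)
    }
    structure(list(nodes = sort(nodes), edges = e),
              class = "disease_network")
  }
}

#' Write / read signed profiles as TSV
#'
#' Columns `disease`, `microbe`, `sign` (+1/-1); one file may hold several
#' diseases.
#'
#' @param profiles A [signed_profile()] or list of them.
#' @param path File path.
#' @return `read_profiles` returns a named list of profiles.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "signed_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p)
    if (length(p$signs))
      data.frame(disease = p$disease, microbe = names(p$signs),
                 sign = unname(p$signs), stringsAsFactors = FALSE)
    else NULL)
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(disease = character(0), microbe = character(0),
                     sign = integer(0))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("disease", "microbe", "sign") %in% names(df)))
    stop_("profile file must have columns disease, microbe, sign")
  diseases <- sort(unique(df$disease))
  setNames(lapply(diseases, function(d) {
    sel <- df$disease == d
    signed_profile(d, setNames(as.integer(df$sign[sel]),
                               normalize_microbe(df$microbe[sel])))
  }), diseases)
}
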