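pair_net <- function(edges, species = "N") {
  interaction_network(
    tibble::tibble(
      id_a = vapply(edges, `[[`, "", 1L), id_b = vapply(edges, `[[`, "", 2L),
      itype = "physical", source_db = "db",
      pubmed_ids = rep(list(character()), length(edges))
    ),
    species = species
  )
}

test_that("network overlap is the neighborhood Jaccard index with missing conventions", {
  ## N(a) = {x,y,z}, N(b) = {y,z,w} -> 2/4
  net <- pair_net(list(c("a", "x"), c("a", "y"), c("a", "z"),
                       c("b", "y"), c("b", "z"), c("b", "w")))
  expect_equal(network_overlap(net, "a", "b"), 0.5)
  ## identical neighborhoods -> 1
  net2 <- pair_net(list(c("a", "x"), c("a", "y"), c("b", "x"), c("b", "y")))
  expect_equal(network_overlap(net2, "a", "b"), 1)
  ## interacting pair: a and b are removed from each other's neighborhoods
  net3 <- pair_net(list(c("a", "b"), c("a", "x"), c("b", "x")))
  expect_equal(network_overlap(net3, "a", "b"), 1)
  ## isolated pair (0/0) and absent proteins are missing, not 0
  expect_true(is.na(network_overlap(pair_net(list(c("a", "b"))), "a", "b")))
  expect_true(is.na(network_overlap(net, "a", "ghost")))
})

test_that("scalar similarity features match their closed forms", {
  expect_equal(harmonic_sequence_similarity(0.8, 0.4), 2 * 0.8 * 0.4 / 1.2)
  expect_equal(harmonic_sequence_similarity(0.3, 0.3), 0.3)
  expect_equal(harmonic_sequence_similarity(0.5, 0), 0)
  expect_equal(harmonic_sequence_similarity(0, 0), 0)
  expect_true(is.na(harmonic_sequence_similarity(NA, 0.5)))

  ann <- annotation_store(
    tokens = list(p1 = c("kinas", "serin"), p2 = c("kinas", "threonin"),
                  p3 = c("kinas", "serin"), p4 = character()),
    domains = list(p1 = c("IPR001", "PF001"), p2 = "IPR001", p3 = "PF009"),
    pathways = list(p1 = c("pA"), p2 = c("pA", "pB"), p3 = "pC")
  )
  expect_equal(token_similarity(ann, "p1", "p2"), 1 / 3)
  expect_equal(token_similarity(ann, "p1", "p3"), 1)
  expect_true(is.na(token_similarity(ann, "p1", "p4")))
  expect_equal(domain_similarity(ann, "p1", "p2"), 0.5)
  expect_equal(domain_similarity(ann, "p1", "p3"), 0)
  expect_true(is.na(domain_similarity(ann, "p1", "p9")))
  expect_true(pathway_shared(ann, "p1", "p2"))
  expect_false(pathway_shared(ann, "p1", "p3"))
  expect_true(is.na(pathway_shared(ann, "p1", "p9")))

  expect_equal(ortholog_score(1, 1, 1, 1), 1)
  expect_equal(ortholog_score(1, 1, 0.5, 1), 0.75)
  expect_true(is.na(ortholog_score(1, 1, NA, 1)))
})

test_that("expression correlation handles perfect, inverse and degenerate cases", {
  ann <- annotation_store(expression = list(
    a = c(1, 2, 3, 4), b = c(3, 5, 7, 9), c = c(4, 3, 2, 1),
    flat = c(2, 2, 2, 2), short = c(1, 2)
  ))
  expect_equal(expression_correlation(ann, "a", "b"), 1)
  expect_equal(expression_correlation(ann, "a", "c"), -1)
  expect_true(is.na(expression_correlation(ann, "a", "flat")))
  expect_true(is.na(expression_correlation(ann, "a", "none")))
  ann2 <- annotation_store(expression = list(a = c(1, 2), b = c(3, 4)))
  expect_true(is.na(expression_correlation(ann2, "a", "b")))
})

test_that("phylogenetic distance sums branch lengths or counts edges", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_equal(phylo_distance(tr, "A", "B"), 2)
  expect_equal(phylo_distance(tr, "A", "C"), 4)
  expect_equal(phylo_distance(tr, "A", "A"), 0)
  un <- parse_newick("((A,B),(C,D));")
  expect_equal(phylo_distance(un, "A", "D"), 4) # edge count without lengths
  expect_error(phylo_distance(un, "A", "nope"), "leaf")
})

test_that("transitive orthology follows the closest-leaf chain", {
  tree <- parse_newick("((A,B),(C,D));")
  rec <- function(g1, s1, g2, s2) {
    tibble::tibble(gene_source = g1, sp_source = s1, gene_target = g2,
                   sp_target = s2, db = "oma", inpara_s = 1, inpara_t = 1,
                   boot_s = 1, boot_t = 1, seq_identity = 0.5)
  }
  ## species between A and D: B (from the (A,B) node) then C (from (C,D))
  expect_equal(intermediate_species(tree, "A", "D"), c("B", "C"))
  mapping <- ortholog_mapping(dplyr::bind_rows(
    rec("a", "A", "b", "B"), rec("b", "B", "c", "C"),
    rec("c", "C", "d", "D"), rec("a", "A", "d", "D")
  ))
  expect_true(transitive_ortholog(tree, mapping, "A", "D", "a", "d"))
  ## chain reaching a different gene d2 only: false
  mapping2 <- ortholog_mapping(dplyr::bind_rows(
    rec("a", "A", "b", "B"), rec("b", "B", "c", "C"),
    rec("c", "C", "d2", "D"), rec("a", "A", "d", "D")
  ))
  expect_false(transitive_ortholog(tree, mapping2, "A", "D", "a", "d"))
  ## a broken hop yields false (no skipping)
  mapping3 <- ortholog_mapping(dplyr::bind_rows(
    rec("a", "A", "b", "B"), rec("c", "C", "d", "D"), rec("a", "A", "d", "D")
  ))
  expect_false(transitive_ortholog(tree, mapping3, "A", "D", "a", "d"))
  ## sibling species: no intermediate, direct record decides
  expect_equal(intermediate_species(tree, "A", "B"), character())
  expect_true(transitive_ortholog(tree, mapping, "A", "B", "a", "b"))
})

test_that("transitive orthology agrees with exhaustive chain enumeration on ladder trees", {
  set.seed(41)
  n_checked <- 0L
  for (rep in 1:20) {
    n_sp <- sample(3:5, 1L)
    species <- paste0("L", seq_len(n_sp))
    nwk <- paste0(
      paste(rep("(", n_sp - 1L), collapse = ""),
      species[1L],
      paste(vapply(species[-1L], function(s) paste0(",", s, ")"), ""), collapse = ""),
      ";"
    )
    tree <- parse_newick(nwk)
    genes <- lapply(species, function(s) paste0(s, "_", 1:3))
    names(genes) <- species
    rows <- list()
    for (i in seq_len(n_sp - 1L)) for (j in (i + 1L):n_sp) {
      for (g1 in genes[[i]]) for (g2 in genes[[j]]) {
        if (stats::runif(1) < 0.4) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            gene_source = g1, sp_source = species[i], gene_target = g2,
            sp_target = species[j], db = "oma", inpara_s = 1, inpara_t = 1,
            boot_s = 1, boot_t = 1, seq_identity = 0.5
          )
        }
      }
    }
    if (!length(rows)) next
    recs <- dplyr::bind_rows(rows)
    mapping <- ortholog_mapping(recs)
    has_rec <- function(g1, s1, g2, s2) {
      any((recs$sp_source == s1 & recs$gene_source == g1 &
             recs$sp_target == s2 & recs$gene_target == g2) |
            (recs$sp_source == s2 & recs$gene_source == g2 &
               recs$sp_target == s1 & recs$gene_target == g1))
    }
    ## oracle: exhaustive recursive enumeration of all gene chains through
    ## the intermediate species list
    oracle_chain <- function(i, j, g_src, g_tgt) {
      mids <- intermediate_species(tree, species[i], species[j])
      seqs <- c(species[i], mids, species[j])
      reach <- function(level, g) {
        if (level == length(seqs)) return(g == g_tgt)
        any(vapply(genes[[seqs[level + 1L]]], function(nxt) {
          has_rec(g, seqs[level], nxt, seqs[level + 1L]) &&
            reach(level + 1L, nxt)
        }, TRUE))
      }
      reach(1L, g_src)
    }
    for (k in 1:5) {
      ij <- sort(sample(n_sp, 2L))
      g1 <- sample(genes[[ij[1L]]], 1L)
      g2 <- sample(genes[[ij[2L]]], 1L)
      expect_equal(
        transitive_ortholog(tree, mapping, species[ij[1L]], species[ij[2L]], g1, g2),
        oracle_chain(ij[1L], ij[2L], g1, g2),
        info = sprintf("rep %d case %d", rep, k)
      )
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 90L)
})

test_that("feature sets expand Table-style cells with the right counts and types", {
  expect_length(feature_set_columns("full"), 43L)
  expect_length(feature_set_columns("reduced"), 38L)
  expect_length(feature_set_columns("network"), 4L)
  expect_length(feature_set_columns("go"), 16L)
  expect_length(feature_set_columns("general"), 5L)
  expect_length(feature_set_columns("ortholog"), 18L)
  expect_setequal(
    setdiff(feature_set_columns("full"), feature_set_columns("reduced")),
    c("network_overlap_S", "network_overlap_T", "net_go_S", "net_go_T", "expr_corr_T")
  )
  ## the category sets partition the full set
  expect_setequal(
    c(feature_set_columns("network"), feature_set_columns("go"),
      feature_set_columns("general"), feature_set_columns("ortholog")),
    feature_set_columns("full")
  )
  sc <- feature_schema("full")
  expect_equal(sum(sc$kind == "categorical"), 8L)
  expect_error(feature_set_columns("bogus"))
})

test_that("the feature table fills all cells and degrades to missing in production mode", {
  w <- world_fixture("tiny")
  tr <- world_transfers(w, "AllI")
  ft <- build_feature_table(tr, world_context(w), "full")
  expect_equal(nrow(ft), nrow(tr))
  expect_setequal(setdiff(names(ft), c(".t_a", ".t_b", ".src_species", ".label")),
                  feature_set_columns("full"))
  ## reduced is a column subset of full on identical instances
  red <- build_feature_table(tr, world_context(w), "reduced")
  expect_equal(as.data.frame(red[feature_set_columns("reduced")]),
               as.data.frame(ft[feature_set_columns("reduced")]),
               ignore_attr = TRUE)
  ## column subsetting of the full table gives the same reduced table
  sub <- subset_feature_set(ft, "reduced")
  expect_equal(as.data.frame(sub), as.data.frame(red), ignore_attr = TRUE)
  expect_identical(attr(sub, "schema"), attr(red, "schema"))
  ## hand-checked values on the first instance (b1, b2 from a1, a2)
  i <- which(ft$.t_a == "b1" & ft$ortho_source_O1 == "inparanoid")[1L]
  expect_equal(ft$token_sim_O1[i], 1 / 3)
  expect_equal(ft$domain_sim_O1[i], 0.5)
  expect_equal(ft$expr_corr_T[i], 1)
  expect_equal(ft$edge_support_S[i], 2L)
  expect_equal(ft$ortho_support_O1[i], 2L)
  expect_equal(ft$phylo_dist_O1[i], 2)
  expect_equal(ft$seq_identity_O1[i], 0.8)
  expect_true(ft$kegg_shared_O1[i])
  ## total support: the pair is transferred from a single source network
  expect_equal(ft$total_support_T[i], 0L)
  ## production mode: (T) network features missing, table still valid
  prod <- build_feature_table(tr, world_context(w, production = TRUE), "full")
  expect_true(all(is.na(prod$network_overlap_T)))
  expect_true(all(is.na(prod$net_go_T)))
  expect_equal(prod$go_global_T, ft$go_global_T) # annotation features remain
})

test_that("neighborhood GO similarity equals the exhaustive pair mean", {
  set.seed(51)
  for (rep in 1:15) {
    fx <- random_go_fixture(n_terms = 7L, n_prot = 6L)
    ic <- build_ic_table(fx$dag, fx$ann, "B")
    oic <- oracle_ic(fx$parents, fx$terms, fx$go_ann, fx$terms[1L])
    prots <- paste0("p", 1:6)
    edges <- list(c("hubA", prots[1L]), c("hubA", prots[2L]),
                  c("hubB", prots[3L]), c("hubB", prots[4L]))
    net <- pair_net(edges)
    got <- network_go_similarity(net, "hubA", "hubB", ic, fx$dag, fx$ann)
    vals <- c()
    for (u in prots[1:2]) for (v in prots[3:4]) {
      vals <- c(vals, oracle_protein_sim(fx$parents, oic, fx$go_ann, u, v))
    }
    vals <- vals[!is.na(vals)]
    if (!length(vals)) expect_true(is.na(got)) else expect_equal(got, mean(vals))
  }
  ## empty neighborhood is missing
  fx <- random_go_fixture()
  ic <- build_ic_table(fx$dag, fx$ann, "B")
  net <- pair_net(list(c("hubA", "p1")))
  expect_true(is.na(network_go_similarity(net, "hubA", "lonely", ic, fx$dag, fx$ann)))
})

test_that("pairwise similarity features are symmetric", {
  w <- world_fixture("tiny")
  ic <- build_ic_tables(w$dag, w$ann)$global
  for (pair in list(c("a1", "b1"), c("a2", "b2"), c("b1", "b2"))) {
    expect_equal(token_similarity(w$ann, pair[1L], pair[2L]),
                 token_similarity(w$ann, pair[2L], pair[1L]))
    expect_equal(domain_similarity(w$ann, pair[1L], pair[2L]),
                 domain_similarity(w$ann, pair[2L], pair[1L]))
    expect_equal(protein_go_similarity(ic, w$dag, w$ann, pair[1L], pair[2L]),
                 protein_go_similarity(ic, w$dag, w$ann, pair[2L], pair[1L]))
  }
})

test_that("the Porter stemmer and token pipeline behave on known words", {
  expect_equal(
    porter_stem(c("kinases", "serine", "threonine", "binding", "caresses",
                  "ponies", "cats", "agreed", "motoring", "happy", "relational",
                  "rational", "troubling")),
    c("kinas", "serin", "threonin", "bind", "caress", "poni", "cat", "agre",
      "motor", "happi", "relat", "ration", "troubl")
  )
  toks <- tokenize_descriptions(c(
    k1 = "Serine/threonine-protein kinase and the ATP binding",
    k2 = "Serine kinases with ATP"
  ), max_doc_frac = 1)
  expect_true(all(c("serin", "kinas", "atp") %in% toks$k1))
  expect_false("the" %in% toks$k1) # stop word
  expect_false("and" %in% toks$k1)
  ## corpus filter removes tokens present in too many proteins
  many <- tokenize_descriptions(
    stats::setNames(paste("ribosome protein", paste0("unique", 1:12)),
                    paste0("p", 1:12)),
    max_doc_frac = 0.5
  )
  expect_false(any(vapply(many, function(s) "ribosom" %in% s, TRUE)))
  expect_true("unique3" %in% many$p3)
})
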