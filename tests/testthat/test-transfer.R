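make_net <- function(edges, species = "Src") {
  interaction_network(
    tibble::tibble(
      id_a = vapply(edges, `[[`, "", 1L), id_b = vapply(edges, `[[`, "", 2L),
      itype = vapply(edges, function(e) if (length(e) > 2L) e[[3L]] else "physical", ""),
      source_db = "db", pubmed_ids = rep(list(character()), length(edges))
    ),
    species = species
  )
}

make_map <- function(...) {
  pairs <- list(...)
  ortholog_mapping(tibble::tibble(
    gene_source = vapply(pairs, `[[`, "", 1L), sp_source = "Src",
    gene_target = vapply(pairs, `[[`, "", 2L), sp_target = "Tgt",
    db = vapply(pairs, function(p) if (length(p) > 2L) p[[3L]] else "oma", ""),
    inpara_s = 1, inpara_t = 1, boot_s = 1, boot_t = 1, seq_identity = 0.5
  ))
}

test_that("direct transfer expands ortholog combinations and drops self-pairs", {
  net <- make_net(list(c("s1", "s2")))
  ## s1 -> {t1, t1b}, s2 -> {t2}: two instances
  tr <- direct_transfer(net, make_map(c("s1", "t1"), c("s1", "t1b"), c("s2", "t2")), "Tgt")
  expect_equal(nrow(tr), 2L)
  expect_setequal(paste(tr$t_a, tr$t_b), c("t1 t2", "t1b t2"))
  ## missing ortholog on one endpoint: no instances
  tr0 <- direct_transfer(net, make_map(c("s1", "t1")), "Tgt")
  expect_equal(nrow(tr0), 0L)
  ## both endpoints mapping to the same target protein: dropped
  trs <- direct_transfer(net, make_map(c("s1", "t1"), c("s2", "t1")), "Tgt")
  expect_equal(nrow(trs), 0L)
  ## unknown species pair: empty with a warning, not an error
  expect_warning(out <- direct_transfer(net, make_map(c("s1", "t1")), "Other"),
                 "no ortholog")
  expect_equal(nrow(out), 0L)
})

test_that("transfer instance count matches the brute-force nested-loop oracle", {
  set.seed(11)
  for (rep in 1:25) {
    genes_s <- paste0("s", 1:6)
    genes_t <- paste0("t", 1:6)
    n_rec <- sample(4:10, 1L)
    recs <- tibble::tibble(
      gene_source = sample(genes_s, n_rec, replace = TRUE),
      sp_source = "Src",
      gene_target = sample(genes_t, n_rec, replace = TRUE),
      sp_target = "Tgt",
      db = sample(c("oma", "inparanoid"), n_rec, replace = TRUE),
      inpara_s = 1, inpara_t = 1, boot_s = 1, boot_t = 1, seq_identity = 0.4
    )
    recs <- dplyr::distinct(recs, gene_source, gene_target, db, .keep_all = TRUE)
    n_edge <- sample(2:5, 1L)
    epairs <- unique(replicate(n_edge, sort(sample(genes_s, 2L)), simplify = FALSE))
    net <- make_net(epairs)
    mapping <- ortholog_mapping(recs)
    ## oracle: exhaustive loop over edges x record pairs
    expected <- 0L
    for (e in epairs) {
      r1 <- which(recs$gene_source == e[1L])
      r2 <- which(recs$gene_source == e[2L])
      for (i in r1) for (j in r2) {
        if (recs$gene_target[i] != recs$gene_target[j]) expected <- expected + 1L
      }
    }
    tr <- direct_transfer(net, mapping, "Tgt")
    expect_equal(nrow(tr), expected)
  }
})

test_that("transfer is monotone in the ortholog mapping", {
  set.seed(21)
  net <- make_net(list(c("s1", "s2"), c("s2", "s3")))
  base <- make_map(c("s1", "t1"), c("s2", "t2"), c("s3", "t3"))
  more <- ortholog_mapping(dplyr::bind_rows(
    tibble::as_tibble(base),
    tibble::tibble(gene_source = "s2", sp_source = "Src", gene_target = "t2b",
                   sp_target = "Tgt", db = "oma", inpara_s = 1, inpara_t = 1,
                   boot_s = 1, boot_t = 1, seq_identity = 0.5)
  ))
  key <- function(tr) paste(tr$t_a, tr$t_b, tr$src_a, tr$src_b, tr$o1_db, tr$o2_db)
  expect_true(all(key(direct_transfer(net, base, "Tgt")) %in%
                    key(direct_transfer(net, more, "Tgt"))))
})

test_that("labeling follows the three experimental settings", {
  net <- make_net(list(c("s1", "s2", "physical"), c("s3", "s4", "genetic"),
                       c("s5", "s6", "other")))
  mapping <- make_map(c("s1", "t1"), c("s2", "t2"), c("s3", "t3"),
                      c("s4", "t4"), c("s5", "t5"), c("s6", "t6"))
  gold <- interaction_network(tibble::tibble(
    id_a = c("t1", "t3"), id_b = c("t2", "t4"),
    itype = c("genetic", "genetic"), source_db = "gold",
    pubmed_ids = list(character(), character())
  ), species = "Tgt")
  tr <- direct_transfer(net, mapping, "Tgt")

  alli <- label_against_gold(tr, gold, "AllI")
  expect_equal(nrow(alli), 3L) # AllI keeps every instance
  ## occurrence with any type counts under AllI
  expect_equal(alli$label[alli$t_a == "t1"], "consistent")
  ## PhyI: physical transfer present in gold only as genetic -> inconsistent
  phyi <- label_against_gold(tr, gold, "PhyI")
  expect_equal(nrow(phyi), 1L)
  expect_equal(phyi$label, "inconsistent")
  ## GenI restricts to genetic source edges and matches type
  geni <- label_against_gold(tr, gold, "GenI")
  expect_equal(nrow(geni), 1L)
  expect_equal(geni$itype, "genetic")
  expect_equal(geni$label, "consistent")
  ## PhyI + GenI + untyped remainder partition the AllI instance set
  expect_equal(nrow(phyi) + nrow(geni) + sum(tr$itype == "other"), nrow(alli))
  ## no gold network: production mode leaves everything unlabeled
  expect_true(all(label_against_gold(tr, NULL, "AllI")$label == "unlabeled"))
})

test_that("dedupe keeps one edge per pair with the maximum score", {
  tr <- world_transfers(world_fixture("tiny"), "AllI")
  tr$score <- c(0.3, 0.8, 0.2, 0.5, 0.4)
  net <- dedupe_network(tr)
  expect_equal(nrow(net), 4L) # 5 instances, 4 distinct pairs
  expect_equal(net$score[net$t_a == "b1" & net$t_b == "b2"], 0.8)
  expect_equal(net$n_instances[net$t_a == "b1" & net$t_b == "b2"], 2L)
  disjoint <- tr[3:5, ]
  expect_equal(nrow(dedupe_network(disjoint)), 3L)
  expect_equal(nrow(dedupe_network(tr[0, ])), 0L)
})

test_that("tiny fixture matches the hand enumeration", {
  w <- world_fixture("tiny")
  tr <- world_transfers(w, "AllI")
  ## hand count: edge (a1,a2): 2 db records for a1 -> 2 instances of (b1,b2);
  ## (a3,a4): a3 -> {b3, b3x} -> 2 instances; (a2,a5): 1; (a6,a7): a6 unmapped -> 0
  expect_equal(nrow(tr), 5L)
  expect_equal(sum(tr$label == "consistent"), 3L)
  expect_equal(transfer_precision(tr), 3 / 5)
  ## planted truth agrees with AllI labeling
  lab <- dplyr::left_join(tr, w$truth, by = c("t_a", "t_b"))
  expect_equal(lab$label == "consistent", lab$conserved)
  ## transfer table round-trips through its TSV format
  path <- withr::local_tempfile(fileext = ".tsv")
  write_transfer_table(tr, path)
  expect_equal(nrow(readr::read_tsv(path, show_col_types = FALSE)), 5L)
})
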