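SYNTH_BLOCKS <- c("go", "seq", "ortho", "tokens", "domains", "pathways",
                  "expression", "general")
ORTHO_DBS <- c("inparanoid", "oma", "homologene")
INTERACTION_DBS <- c("biogrid", "intact", "dip", "mint")

#' Configuration for a synthetic multi-species world
#'
#' Defines the study conditions the generator emulates: a target species
#' with a near-complete gold network plus several source species whose
#' interactions are transferred onto it through scored n:m ortholog
#' clusters. Conservation is planted per family pair: a source edge is
#' copied into the gold target network with probability `conservation_rate`
#' (consistently across source species), and every ortholog-combination
#' target pair of a conserved edge enters the gold network, so at
#' `conservation_rate = 1` a direct transfer is perfectly consistent.
#'
#' @param n_species total species; the first is the transfer target.
#' @param genes_per_species number of gene families (each species carries one
#'   or two members per family, per `cluster_size_probs`).
#' @param tree Newick string for the species tree; default is a ladder over
#'   `S1..Sn`.
#' @param ortholog_coverage probability that a family has ortholog records
#'   for a given species pair.
#' @param cluster_size_probs probabilities of the ortholog-cluster shapes
#'   `1:1`, `1:2` (two members in source species) and `2:2`.
#' @param edges_per_species interactions planted in each source network.
#' @param conservation_rate probability `c` that a source edge is conserved
#'   (copied into the gold network).
#' @param feature_signal planted feature-signal strength in \[0,1\]: either a
#'   scalar or a named vector over the blocks
#'   `r paste(SYNTH_BLOCKS, collapse = ", ")`. At 0 every feature is
#'   independent of conservation.
#' @param annotation_coverage probability that a protein carries GO
#'   annotations.
#' @param db_redundancy probability that an ortholog relation is listed by
#'   each additional database beyond its first (0 gives exactly one record
#'   per gene pair, so every transfer instance is a distinct target pair in
#'   1:1 worlds).
#' @param rewired_fraction fraction of non-conserved edges that place a
#'   rewired (partner-swapped) edge in the gold network, creating hard
#'   negatives.
#' @param n_conditions gene-expression conditions for target genes.
#' @param seed integer seed; the whole world is reproducible from it.
#' @return list of class `world_config`.
#' @export
world_config <- function(n_species = 5L, genes_per_species = 1200L, tree = NULL,
                         ortholog_coverage = 0.85,
                         cluster_size_probs = c("1:1" = 0.7, "1:2" = 0.2, "2:2" = 0.1),
                         edges_per_species = 250L, conservation_rate = 0.25,
                         feature_signal = 0.9, annotation_coverage = 0.9,
                         db_redundancy = 0.15, rewired_fraction = 0,
                         n_conditions = 20L, seed = 1L) {
  fracs <- c(ortholog_coverage, conservation_rate, annotation_coverage,
             db_redundancy, rewired_fraction)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1]")
  if (abs(sum(cluster_size_probs) - 1) > 1e-8) {
    abort("cluster_size_probs must sum to 1")
  }
  if (!all(names(cluster_size_probs) %in% c("1:1", "1:2", "2:2"))) {
    abort("cluster_size_probs names must be 1:1, 1:2, 2:2")
  }
  if (is.null(names(feature_signal))) {
    feature_signal <- stats::setNames(rep(feature_signal[1L], length(SYNTH_BLOCKS)),
                                      SYNTH_BLOCKS)
  } else {
    full <- stats::setNames(rep(0, length(SYNTH_BLOCKS)), SYNTH_BLOCKS)
    full[names(feature_signal)] <- feature_signal
    feature_signal <- full
  }
  if (any(feature_signal < 0 | feature_signal > 1)) {
    abort("feature_signal must lie in [0, 1]")
  }
  structure(
    list(
      n_species = n_species, genes_per_species = genes_per_species, tree = tree,
      ortholog_coverage = ortholog_coverage,
      cluster_size_probs = cluster_size_probs,
      edges_per_species = edges_per_species,
      conservation_rate = conservation_rate, feature_signal = feature_signal,
      annotation_coverage = annotation_coverage, db_redundancy = db_redundancy,
      rewired_fraction = rewired_fraction, n_conditions = n_conditions,
      seed = seed
    ),
    class = "world_config"
  )
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Generate a synthetic multi-species world
#'
#' Builds gene families along a species tree, samples scored ortholog pairs,
#' plants source networks and copies each source edge into the gold target
#' network with probability `conservation_rate`, then annotates proteins
#' (GO DAG, description tokens, domains, pathways, expression) so that the
#' conserved interologs carry feature signal proportional to
#' `feature_signal`. See [world_config()] for the knobs.
#'
#' @param config a [world_config()].
#' @return list of class `world` with elements `networks` (named list; the
#'   target species' network is the gold standard), `target_species`,
#'   `source_species`, `mapping`, `dag`, `ann`, `tree`, `truth`
#'   (tibble of transferable target pairs with their planted conservation)
#'   and `config`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed)
  sig <- config$feature_signal
  n_fam <- config$genes_per_species

  ## species + tree
  if (is.null(config$tree)) {
    species <- paste0("S", seq_len(config$n_species))
    nwk <- Reduce(function(acc, s) paste0("(", s, ",", acc, ")"),
                  rev(species[-length(species)]),
                  species[length(species)])
    tree <- parse_newick(paste0(nwk, ";"))
  } else {
    tree <- parse_newick(config$tree)
    species <- tree$tip.label
  }
  target <- species[1L]
  sources <- species[-1L]

  ## family shapes and members
  shapes <- sample(names(config$cluster_size_probs), n_fam, replace = TRUE,
                   prob = config$cluster_size_probs)
  n_members <- function(f, sp) {
    if (shapes[f] == "2:2") return(2L)
    if (shapes[f] == "1:2" && sp != target) return(2L)
    1L
  }
  members <- function(f, sp) paste0(sp, "_g", f, letters[seq_len(n_members(f, sp))])

  ## source networks + per-family-pair conservation (consistent across species)
  pair_conserved <- new.env(parent = emptyenv())
  conserved_of <- function(f1, f2) {
    key <- paste(min(f1, f2), max(f1, f2))
    v <- pair_conserved[[key]]
    if (is.null(v)) {
      v <- stats::runif(1) < config$conservation_rate
      pair_conserved[[key]] <- v
    }
    v
  }
  edge_rows <- list()
  for (sp in sources) {
    pairs_seen <- character()
    k <- 0L
    while (k < config$edges_per_species) {
      fs <- sample.int(n_fam, 2L)
      key <- paste(min(fs), max(fs))
      if (key %in% pairs_seen) next
      pairs_seen <- c(pairs_seen, key)
      k <- k + 1L
      f1 <- fs[1L]; f2 <- fs[2L]
      g1 <- sample(members(f1, sp), 1L)
      g2 <- sample(members(f2, sp), 1L)
      cons <- conserved_of(f1, f2)
      itype <- sample(c("physical", "genetic", "other"), 1L,
                      prob = c(0.45, 0.35, 0.2))
      n_pm <- 1L + stats::rpois(1L, 0.5 + 1.5 * sig[["general"]] * cons)
      edge_rows[[length(edge_rows) + 1L]] <- tibble(
        species = sp, f1 = f1, f2 = f2, id_a = g1, id_b = g2, itype = itype,
        source_db = sample(INTERACTION_DBS, 1L),
        pubmed_ids = list(as.character(sample.int(99999L, n_pm))),
        conserved = cons
      )
    }
  }
  edges <- bind_rows(edge_rows)

  ## family conservation indicator (touches >= 1 conserved edge)
  z_fam <- rep(FALSE, n_fam)
  z_fam[unique(c(edges$f1[edges$conserved], edges$f2[edges$conserved]))] <- TRUE

  networks <- lapply(sources, function(sp) {
    e <- edges %>% filter(.data$species == sp)
    interaction_network(
      tibble(id_a = e$id_a, id_b = e$id_b, itype = e$itype,
             source_db = e$source_db, pubmed_ids = e$pubmed_ids),
      species = sp
    )
  })
  names(networks) <- sources

  ## gold network: all member-combination target pairs of conserved edges
  gold_rows <- list()
  truth_rows <- list()
  for (i in seq_len(nrow(edges))) {
    ta <- members(edges$f1[i], target)
    tb <- members(edges$f2[i], target)
    combos <- tidyr::expand_grid(a = ta, b = tb)
    truth_rows[[i]] <- tibble(
      t_a = pmin(combos$a, combos$b), t_b = pmax(combos$a, combos$b),
      conserved = edges$conserved[i]
    )
    if (edges$conserved[i]) {
      gold_rows[[length(gold_rows) + 1L]] <- tibble(
        id_a = combos$a, id_b = combos$b, itype = edges$itype[i],
        source_db = "gold", pubmed_ids = list(character())
      )
    } else if (config$rewired_fraction > 0 &&
               stats::runif(1) < config$rewired_fraction) {
      ## hard negative: attach one endpoint family to a random other family
      f3 <- sample(setdiff(seq_len(n_fam), c(edges$f1[i], edges$f2[i])), 1L)
      gold_rows[[length(gold_rows) + 1L]] <- tibble(
        id_a = sample(ta, 1L), id_b = sample(members(f3, target), 1L),
        itype = edges$itype[i], source_db = "gold", pubmed_ids = list(character())
      )
    }
  }
  gold <- interaction_network(
    if (length(gold_rows)) bind_rows(gold_rows) else NULL, species = target
  )
  truth <- bind_rows(truth_rows) %>%
    group_by(.data$t_a, .data$t_b) %>%
    summarise(conserved = any(.data$conserved), .groups = "drop")

  ## ortholog mapping over all species pairs
  sp_pairs <- utils::combn(species, 2L, simplify = FALSE)
  orth_rows <- list()
  for (sp2 in sp_pairs) {
    covered <- stats::runif(n_fam) < config$ortholog_coverage
    for (f in which(covered)) {
      m1 <- members(f, sp2[1L]); m2 <- members(f, sp2[2L])
      dbs <- c(sample(ORTHO_DBS, 1L),
               ORTHO_DBS[stats::runif(3L) < config$db_redundancy])
      dbs <- unique(dbs)
      combos <- tidyr::expand_grid(g1 = m1, g2 = m2, db = dbs)
      nr <- nrow(combos)
      boost_seq <- 0.12 * sig[["seq"]] * z_fam[f]
      boost_ortho <- sig[["ortho"]] * z_fam[f]
      boot_na <- stats::runif(nr) < 0.08
      orth_rows[[length(orth_rows) + 1L]] <- tibble(
        gene_source = combos$g1, sp_source = sp2[1L],
        gene_target = combos$g2, sp_target = sp2[2L], db = combos$db,
        inpara_s = clip01(stats::rnorm(nr, 0.82 + 0.08 * boost_ortho, 0.10)),
        inpara_t = clip01(stats::rnorm(nr, 0.82 + 0.08 * boost_ortho, 0.10)),
        boot_s = ifelse(boot_na, NA,
                        clip01(stats::rnorm(nr, 0.70 + 0.15 * boost_ortho, 0.15))),
        boot_t = ifelse(boot_na, NA,
                        clip01(stats::rnorm(nr, 0.70 + 0.15 * boost_ortho, 0.15))),
        seq_identity = clip01(stats::rnorm(nr, 0.35 + boost_seq, 0.13))
      )
    }
  }
  mapping <- ortholog_mapping(bind_rows(orth_rows))

  ## GO DAG: three categories, root -> 6 mid -> 30 leaves (20% diamond)
  terms <- character(); parents <- list(); category <- character()
  leaves <- list()
  for (cat in c("B", "C", "M")) {
    root <- sprintf("GO:%s000", cat)
    mids <- sprintf("GO:%s0%02d", cat, 1:6)
    lfs <- sprintf("GO:%s1%02d", cat, 1:30)
    terms <- c(terms, root, mids, lfs)
    parents[[root]] <- character()
    for (m in mids) parents[[m]] <- root
    for (l in lfs) {
      p <- sample(mids, 1L)
      if (stats::runif(1) < 0.2) p <- unique(c(p, sample(mids, 1L)))
      parents[[l]] <- p
    }
    category <- c(category,
                  stats::setNames(rep(cat, 1L + 6L + 30L), c(root, mids, lfs)))
    leaves[[cat]] <- lfs
  }
  dag <- go_dag(terms, parents, category)

  ## family home leaves; conserved edge partners share them w.p. feature_signal
  home <- lapply(c(B = "B", C = "C", M = "M"), function(cat) {
    sample(leaves[[cat]], n_fam, replace = TRUE)
  })
  cons_edges <- edges %>% filter(.data$conserved) %>% distinct(.data$f1, .data$f2)
  for (i in seq_len(nrow(cons_edges))) {
    for (cat in c("B", "C", "M")) {
      if (stats::runif(1) < sig[["go"]]) {
        home[[cat]][cons_edges$f2[i]] <- home[[cat]][cons_edges$f1[i]]
      }
    }
  }

  ## per-protein annotations
  token_pool <- sprintf("tok%03d", 1:400)
  domain_pool <- c(sprintf("IPR%03d", 1:150), sprintf("PF%03d", 1:50))
  pathway_pool <- sprintf("path%02d", 1:50)
  fam_tokens <- lapply(seq_len(n_fam), function(f) sample(token_pool, 6L))
  fam_domains <- lapply(seq_len(n_fam), function(f) sample(domain_pool, 3L))
  fam_pathways <- lapply(seq_len(n_fam), function(f) {
    sample(pathway_pool, sample(1:2, 1L))
  })

  go_ann <- list(); tok_ann <- list(); dom_ann <- list(); path_ann <- list()
  for (sp in species) {
    for (f in seq_len(n_fam)) {
      for (g in members(f, sp)) {
        if (stats::runif(1) < config$annotation_coverage) {
          gt <- unlist(lapply(c("B", "C", "M"), function(cat) {
            if (stats::runif(1) < 0.8) home[[cat]][f] else character()
          }))
          if (stats::runif(1) < 0.3) {
            cat <- sample(c("B", "C", "M"), 1L)
            gt <- c(gt, sample(leaves[[cat]], 1L))
          }
          if (length(gt)) go_ann[[g]] <- unique(gt)
        }
        keep_tok <- 0.55 + 0.35 * sig[["tokens"]] * z_fam[f]
        tk <- fam_tokens[[f]][stats::runif(6L) < keep_tok]
        tk <- unique(c(tk, sample(token_pool, 2L)))
        tok_ann[[g]] <- sort(tk)
        keep_dom <- 0.70 + 0.25 * sig[["domains"]] * z_fam[f]
        dm <- fam_domains[[f]][stats::runif(3L) < keep_dom]
        if (stats::runif(1) < 0.2) dm <- c(dm, sample(domain_pool, 1L))
        if (length(dm)) dom_ann[[g]] <- sort(unique(dm))
        keep_path <- 0.55 + 0.40 * sig[["pathways"]] * z_fam[f]
        pw <- fam_pathways[[f]][stats::runif(length(fam_pathways[[f]])) < keep_path]
        if (length(pw)) path_ann[[g]] <- sort(pw)
      }
    }
  }

  ## expression for target genes: conserved gold pairs share a latent profile
  nc <- config$n_conditions
  expr <- list()
  rho <- 0.9 * sig[["expression"]]
  for (i in which(edges$conserved)) {
    latent <- stats::rnorm(nc)
    for (g in c(members(edges$f1[i], target), members(edges$f2[i], target))) {
      if (is.null(expr[[g]])) {
        expr[[g]] <- rho * latent + sqrt(1 - rho^2) * stats::rnorm(nc)
      }
    }
  }
  for (f in seq_len(n_fam)) {
    for (g in members(f, target)) {
      if (is.null(expr[[g]])) expr[[g]] <- stats::rnorm(nc)
    }
  }

  ann <- annotation_store(go = go_ann, tokens = tok_ann, domains = dom_ann,
                          pathways = path_ann, expression = expr, dag = dag)

  networks[[target]] <- gold
  structure(
    list(networks = networks, target_species = target, source_species = sources,
         mapping = mapping, dag = dag, ann = ann, tree = tree, truth = truth,
         config = config),
    class = "world"
  )
}

#' @export
print.world <- function(x, ...) {
  cat(sprintf(
    "<world> target=%s  %d source species, %d ortholog records, gold %d edges\n",
    x$target_species, length(x$source_species), nrow(x$mapping),
    nrow(x$networks[[x$target_species]])
  ))
  invisible(x)
}

#' Direct transfer of all of a world's source networks onto its target
#'
#' @param world a [generate_world()] result.
#' @param setting experimental setting for labeling against the world's gold
#'   network (see [label_against_gold()]); `NULL` leaves instances
#'   unlabeled.
#' @return a labeled `transfer_table`.
#' @export
world_transfers <- function(world, setting = "AllI") {
  transfers <- bind_transfers(lapply(world$source_species, function(sp) {
    direct_transfer(world$networks[[sp]], world$mapping, world$target_species)
  }))
  if (is.null(setting)) return(transfers)
  label_against_gold(transfers, world$networks[[world$target_species]], setting)
}

#' Feature-layer context of a world
#' @param world a `world`.
#' @param production drop the target network (all (T) network features
#'   missing), as when transferring to a species without experimental data.
#' @return a [transfer_context()].
#' @export
world_context <- function(world, production = FALSE) {
  transfer_context(
    source_nets = world$networks[world$source_species],
    mapping = world$mapping, dag = world$dag, ann = world$ann,
    tree = world$tree,
    target_net = if (production) NULL else world$networks[[world$target_species]]
  )
}

#' Named deterministic fixture worlds
#'
#' `tiny` is a hand-built two-species world small enough to enumerate
#' transfers by hand; `signal` plants strong feature signal
#' (`feature_signal = 0.9`) for classifier tests; `noise` is the null world
#' (`feature_signal = 0`) where every feature is independent of
#' conservation. The null world additionally uses 1:1 clusters and
#' single-database ortholog records so that each transfer instance is a
#' distinct target pair: sibling instances of one pair share their label and
#' most feature values, which plain instance-level cross-validation does not
#' control, and a permutation-null AUROC of 0.5 is only meaningful when no
#' such siblings exist. Its classifier tests also score in production
#' context (no target network), since the (T) network-structure features are
#' computed on the gold network that defines the labels and therefore carry
#' label information by construction even at zero planted signal.
#'
#' @param name which fixture.
#' @return a `world`.
#' @export
world_fixture <- function(name = c("tiny", "signal", "noise")) {
  name <- match.arg(name)
  if (name == "tiny") return(tiny_world())
  generate_world(world_fixture_config(name))
}

#' Configuration of a named fixture world
#'
#' The study conditions of the `signal` and `noise` fixtures, optionally
#' under a different seed (the planted structure is the same; only the
#' random draws change).
#'
#' @param name `"signal"` or `"noise"`.
#' @param seed optional seed override.
#' @return a [world_config()].
#' @export
world_fixture_config <- function(name = c("signal", "noise"), seed = NULL) {
  name <- match.arg(name)
  cfg <- switch(name,
    signal = world_config(seed = 7L, feature_signal = 0.9,
                          edges_per_species = 350L),
    noise = world_config(
      seed = 13L, feature_signal = 0, edges_per_species = 700L,
      cluster_size_probs = c("1:1" = 1, "1:2" = 0, "2:2" = 0),
      db_redundancy = 0
    )
  )
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

tiny_world <- function() {
  tree <- parse_newick("(Src,Tgt);")
  src_net <- interaction_network(tibble(
    id_a = c("a1", "a3", "a2", "a6"),
    id_b = c("a2", "a4", "a5", "a7"),
    itype = c("physical", "genetic", "physical", "other"),
    source_db = "dbX",
    pubmed_ids = list(c("11", "12"), "21", "31", "41")
  ), species = "Src")
  mapping <- ortholog_mapping(tibble(
    gene_source = c("a1", "a1", "a2", "a3", "a3", "a4", "a5", "a7"),
    sp_source = "Src",
    gene_target = c("b1", "b1", "b2", "b3", "b3x", "b4", "b5", "b7"),
    sp_target = "Tgt",
    db = c("inparanoid", "oma", "inparanoid", "inparanoid", "inparanoid",
           "inparanoid", "inparanoid", "oma"),
    inpara_s = 1, inpara_t = 1,
    boot_s = c(1, 1, 1, 0.8, 0.6, 1, NA, 1),
    boot_t = c(1, 0.9, 1, 0.8, 0.6, 1, 0.5, 1),
    seq_identity = c(0.8, 0.8, 0.6, 0.5, 0.3, 0.7, 0.4, 0.9)
  ))
  gold <- interaction_network(tibble(
    id_a = c("b1", "b3"), id_b = c("b2", "b4"),
    itype = c("physical", "physical"), source_db = "gold",
    pubmed_ids = list(character(), character())
  ), species = "Tgt")
  dag <- go_dag(
    terms = c("B:root", "B:1", "B:2", "B:1a", "B:1b"),
    parents = list("B:root" = character(), "B:1" = "B:root", "B:2" = "B:root",
                   "B:1a" = "B:1", "B:1b" = "B:1"),
    category = c("B:root" = "B", "B:1" = "B", "B:2" = "B", "B:1a" = "B",
                 "B:1b" = "B")
  )
  ann <- annotation_store(
    go = list(a1 = "B:1a", a2 = "B:1a", b1 = "B:1a", b2 = "B:1b",
              a3 = "B:2", b3 = "B:2", b4 = "B:1", a4 = "B:1"),
    tokens = list(a1 = c("kinas", "serin"), b1 = c("kinas", "threonin"),
                  a2 = c("bind", "dna"), b2 = c("bind", "dna")),
    domains = list(a1 = c("IPR001", "PF001"), b1 = "IPR001",
                   a2 = "IPR002", b2 = "IPR002"),
    pathways = list(a1 = "path01", b1 = "path01", a2 = "path02", b2 = "path03"),
    expression = list(b1 = c(1, 2, 3, 4), b2 = c(2, 4, 6, 8),
                      b3 = c(1, 1, 2, 1), b4 = c(4, 3, 2, 1)),
    dag = dag
  )
  structure(
    list(networks = list(Src = src_net, Tgt = gold), target_species = "Tgt",
         source_species = "Src", mapping = mapping, dag = dag, ann = ann,
         tree = tree,
         truth = tibble(t_a = c("b1", "b2", "b3", "b3x"),
                        t_b = c("b2", "b5", "b4", "b4"),
                        conserved = c(TRUE, FALSE, TRUE, FALSE)),
         config = NULL),
    class = "world"
  )
}

#' Write a world as its standard file set
#'
#' Emits one interaction TSV per species, the ortholog TSV, the GO DAG as
#' OBO, the annotation TSV, the species tree as Newick, the target-species
#' expression TSV and the planted-truth TSV.
#'
#' @param world a `world`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(world$networks)) {
    write_interaction_table(world$networks[[sp]],
                            file.path(dir, paste0("net_", sp, ".tsv")))
  }
  write_ortholog_table(world$mapping, file.path(dir, "orthologs.tsv"))
  write_obo(world$dag, file.path(dir, "ontology.obo"))
  write_annotation_table(world$ann, file.path(dir, "annotations.tsv"))
  write_newick(world$tree, file.path(dir, "species_tree.nwk"))
  write_expression_table(world$ann$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(world$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Write a GO DAG as minimal OBO
#' @param dag a [go_dag()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  ns <- names(GO_NAMESPACES)
  lines <- c("format-version: 1.2", "")
  for (t in dag$terms) {
    lines <- c(
      lines, "[Term]", paste0("id: ", t),
      paste0("namespace: ", ns[match(dag$category[[t]], GO_NAMESPACES)]),
      paste0("is_a: ", dag$parents[[t]]), ""
    )
  }
  writeLines(lines, path)
  invisible(path)
}
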