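#' Jaccard neighborhood overlap of two proteins in a network
#'
#' `|N(a) n N(b)| / |N(a) u N(b)|` over direct neighbors, with `a` and `b`
#' removed from each other's neighbor sets first. Missing (`NA`) when the
#' union is empty or either protein is absent from the network: an empty
#' neighborhood is absence of evidence, not evidence of dissimilarity.
#'
#' @param net an [interaction_network()].
#' @param a,b protein ids.
#' @return value in \[0,1\] or `NA`.
#' @export
network_overlap <- function(net, a, b) {
  prots <- c(net$id_a, net$id_b)
  if (!a %in% prots || !b %in% prots) return(NA_real_)
  na <- setdiff(network_neighbors(net, a), b)
  nb <- setdiff(network_neighbors(net, b), a)
  jaccard(na, nb)
}

#' Average neighborhood GO similarity of two proteins
#'
#' The mean Resnik GO similarity (global table) over all pairs of direct
#' neighbors `N(a) x N(b)`, skipping pairs with undefined similarity.
#' Missing when either neighborhood is empty or all pairs are undefined.
#'
#' @param net an [interaction_network()].
#' @param a,b protein ids.
#' @param ic a global [build_ic_table()] result.
#' @param dag a [go_dag()].
#' @param ann an [annotation_store()].
#' @return non-negative mean similarity or `NA`.
#' @export
network_go_similarity <- function(net, a, b, ic, dag, ann) {
  na <- network_neighbors(net, a)
  nb <- network_neighbors(net, b)
  if (!length(na) || !length(nb)) return(NA_real_)
  vals <- as.vector(outer(na, nb, Vectorize(function(u, v) {
    protein_go_similarity(ic, dag, ann, u, v)
  })))
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Harmonic mean of two ortholog sequence identities
#'
#' `2 a b / (a + b)`, the joint sequence identity of the two ortholog pairs
#' of a transfer; 0 when both identities are 0, `NA` when either is missing.
#'
#' @param id1,id2 sequence-identity fractions in \[0,1\] (vectorized).
#' @return fraction in \[0,1\] or `NA`.
#' @export
harmonic_sequence_similarity <- function(id1, id2) {
  out <- ifelse(id1 + id2 == 0, 0, 2 * id1 * id2 / (id1 + id2))
  out[is.na(id1) | is.na(id2)] <- NA_real_
  out
}

#' Token (synonym) similarity of two proteins
#'
#' Jaccard index of the proteins' descriptive token sets (see
#' [tokenize_descriptions()]); `NA` when either set is empty.
#'
#' @param ann an [annotation_store()].
#' @param p1,p2 protein ids.
#' @return value in \[0,1\] or `NA`.
#' @export
token_similarity <- function(ann, p1, p2) {
  jaccard(ann$tokens[[p1]], ann$tokens[[p2]])
}

#' Domain/family similarity of two proteins
#'
#' Jaccard index of the proteins' combined InterPro + PFAM id sets; `NA`
#' when either set is empty.
#'
#' @inheritParams token_similarity
#' @return value in \[0,1\] or `NA`.
#' @export
domain_similarity <- function(ann, p1, p2) {
  jaccard(ann$domains[[p1]], ann$domains[[p2]])
}

#' Shared-pathway indicator for two proteins
#'
#' `TRUE` iff the pathway-id sets of the two proteins intersect; `NA` when
#' either set is empty.
#'
#' @inheritParams token_similarity
#' @return logical or `NA`.
#' @export
pathway_shared <- function(ann, p1, p2) {
  s1 <- ann$pathways[[p1]]; s2 <- ann$pathways[[p2]]
  if (is.null(s1) || is.null(s2) || !length(s1) || !length(s2)) return(NA)
  length(intersect(s1, s2)) > 0L
}

#' Gene-expression Pearson correlation of two proteins
#'
#' Pearson correlation over the shared condition vector; `NA` when either
#' vector is absent, shorter than 3 conditions, or constant.
#'
#' @inheritParams token_similarity
#' @return value in \[-1,1\] or `NA`.
#' @export
expression_correlation <- function(ann, p1, p2) {
  x <- ann$expression[[p1]]; y <- ann$expression[[p2]]
  if (is.null(x) || is.null(y)) return(NA_real_)
  if (length(x) != length(y)) abort("expression vectors differ in length")
  if (length(x) < 3L) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' InParanoid-style ortholog score
#'
#' Combines each gene's inparalog score `i` and bootstrap score `b` into
#' `(i_s b_s + i_t b_t) / 2`; `NA` when any of the four components is
#' missing.
#'
#' @param inpara_s,inpara_t,boot_s,boot_t fractions in \[0,1\] (vectorized).
#' @return fraction in \[0,1\] or `NA`.
#' @export
ortholog_score <- function(inpara_s, inpara_t, boot_s, boot_t) {
  (inpara_s * boot_s + inpara_t * boot_t) / 2
}

#' Ortholog support of a gene pair
#'
#' The number of distinct ortholog databases listing the same relation
#' between two genes.
#'
#' @param mapping an [ortholog_mapping()].
#' @param g1,g2 gene ids (any order).
#' @return integer >= 1; error when the pair has no record (the feature is
#'   only defined on transfer provenance).
#' @export
ortholog_support <- function(mapping, g1, g2) {
  hit <- (mapping$gene_source == g1 & mapping$gene_target == g2) |
    (mapping$gene_source == g2 & mapping$gene_target == g1)
  if (!any(hit)) abort(sprintf("no ortholog record for gene pair %s / %s", g1, g2))
  dplyr::n_distinct(mapping$db[hit])
}

#' Phylogenetic distance between two species
#'
#' Sum of branch lengths on the unique tree path between the two leaves
#' (edge count when the tree carries no lengths); 0 iff the species
#' coincide.
#'
#' @param tree a rooted `phylo` object whose tips are species ids.
#' @param s1,s2 species ids (must be leaves).
#' @return non-negative distance.
#' @export
phylo_distance <- function(tree, s1, s2) {
  for (s in c(s1, s2)) {
    if (!s %in% tree$tip.label) abort(sprintf("species not a leaf of the tree: %s", s))
  }
  if (s1 == s2) return(0)
  t2 <- tree
  if (is.null(t2$edge.length)) t2$edge.length <- rep(1, nrow(t2$edge))
  d <- ape::dist.nodes(t2)
  i <- match(s1, tree$tip.label); j <- match(s2, tree$tip.label)
  unname(d[i, j])
}

#' Intermediate species between two leaves of a species tree
#'
#' For each inner node on the unique tree path between the two species, the
#' closest leaf is taken (fewest edges; among ties, species other than the
#' two query species are preferred, then lexicographic order), duplicates
#' are removed preserving order, and the query species themselves are
#' dropped, giving the species "between" the source and the target.
#'
#' @inheritParams phylo_distance
#' @return character vector of species ids "between" `s1` and `s2` (possibly
#'   empty).
#' @export
intermediate_species <- function(tree, s1, s2) {
  for (s in c(s1, s2)) {
    if (!s %in% tree$tip.label) abort(sprintf("species not a leaf of the tree: %s", s))
  }
  if (s1 == s2) return(character())
  ntip <- length(tree$tip.label)
  path <- ape::nodepath(tree, match(s1, tree$tip.label), match(s2, tree$tip.label))
  inner <- path[path > ntip]
  if (!length(inner)) return(character())
  t2 <- tree
  t2$edge.length <- rep(1, nrow(t2$edge))
  d <- ape::dist.nodes(t2)
  closest <- vapply(inner, function(nd) {
    dist_to_tips <- d[nd, seq_len(ntip)]
    cand <- tree$tip.label[dist_to_tips == min(dist_to_tips)]
    ## among equally close leaves prefer species other than the endpoints,
    ## then lexicographic order
    non <- setdiff(cand, c(s1, s2))
    if (length(non)) sort(non)[1L] else sort(cand)[1L]
  }, "")
  setdiff(unique(closest), c(s1, s2))
}

#' Transitive-orthology consistency of an ortholog pair
#'
#' Tests whether the direct ortholog relation `g_src` (in `src_sp`) to
#' `g_tgt` (in `tgt_sp`) can also be reached transitively: following pairwise
#' ortholog records through the intermediate species on the tree path
#' between the two species (see [intermediate_species()]), in order. A hop
#' with no connecting record breaks the chain and yields `FALSE`; with no
#' intermediate species the relation is trivially transitively consistent.
#'
#' @param tree species tree (`phylo`).
#' @param mapping an [ortholog_mapping()].
#' @param src_sp,tgt_sp distinct species ids (leaves).
#' @param g_src,g_tgt the directly related genes.
#' @return logical.
#' @export
transitive_ortholog <- function(tree, mapping, src_sp, tgt_sp, g_src, g_tgt) {
  stopifnot(src_sp != tgt_sp)
  mids <- intermediate_species(tree, src_sp, tgt_sp)
  chain_reaches(mapping, c(src_sp, mids, tgt_sp), g_src, g_tgt)
}

chain_reaches <- function(mapping, species_seq, g_src, g_tgt) {
  cur <- g_src
  for (i in seq_len(length(species_seq) - 1L)) {
    recs <- ortholog_pairs_between(mapping, species_seq[i], species_seq[i + 1L])
    cur <- unique(recs$gene_target[recs$gene_source %in% cur])
    if (!length(cur)) return(FALSE)
  }
  g_tgt %in% cur
}

## ---- feature sets -----------------------------------------------------------

GO_CATS <- c("global", "b", "c", "m")

full_feature_columns <- function() {
  o <- function(k) paste0(
    c("go_global", "go_b", "go_c", "go_m", "seq_identity", "token_sim",
      "domain_sim", "kegg_shared", "ortho_source", "ortho_score",
      "ortho_support", "transitive", "phylo_dist"), "_O", k
  )
  c(
    paste0("network_overlap_", c("S", "T")),
    paste0("net_go_", c("S", "T")),
    paste0("go_", rep(GO_CATS, each = 2L), "_", c("S", "T")),
    "source_db_S", "edge_support_S", "source_type_S",
    "total_support_T", "expr_corr_T",
    o(1L), o(2L)
  )
}

#' Columns of a named feature set
#'
#' The six feature-set configurations: `full` (all 43 feature cells over the
#' pairings S, T, O1, O2), `reduced` (`full` minus the network-structure
#' features and the expression correlation, i.e. the features available for
#' most species), and the four per-category sets `network`, `go`, `general`,
#' `ortholog`.
#'
#' @param name feature-set name.
#' @return character vector of feature column names.
#' @export
feature_set_columns <- function(name = c("full", "reduced", "network", "go",
                                         "general", "ortholog")) {
  name <- match.arg(name)
  full <- full_feature_columns()
  switch(name,
    full = full,
    reduced = setdiff(full, c("network_overlap_S", "network_overlap_T",
                              "net_go_S", "net_go_T", "expr_corr_T")),
    network = c("network_overlap_S", "network_overlap_T", "net_go_S", "net_go_T"),
    go = grep("^go_", full, value = TRUE),
    general = c("source_db_S", "edge_support_S", "source_type_S",
                "total_support_T", "expr_corr_T"),
    ortholog = grep("^(seq_identity|token_sim|domain_sim|kegg_shared|ortho_source|ortho_score|ortho_support|transitive|phylo_dist)_O[12]$",
                    full, value = TRUE)
  )
}

#' Feature schema: column names and kinds for a feature set
#' @param name feature-set name (see [feature_set_columns()]).
#' @return tibble with columns `feature`, `kind` (`numeric` or
#'   `categorical`).
#' @export
feature_schema <- function(name = "full") {
  cols <- feature_set_columns(name)
  categorical <- c(
    "source_db_S", "source_type_S", "ortho_source_O1", "ortho_source_O2",
    "kegg_shared_O1", "kegg_shared_O2", "transitive_O1", "transitive_O2"
  )
  tibble(
    feature = cols,
    kind = ifelse(cols %in% categorical, "categorical", "numeric")
  )
}

#' Bundle the inputs the feature layer needs
#'
#' @param source_nets named list of [interaction_network()]s, keyed by
#'   species id.
#' @param mapping an [ortholog_mapping()].
#' @param dag a [go_dag()].
#' @param ann an [annotation_store()].
#' @param tree species tree (`phylo`).
#' @param target_net the target-species network for (T) network features, or
#'   `NULL` in production mode (all (T) network features become missing).
#' @param ic_tables optional precomputed [build_ic_tables()] result.
#' @return list of class `transfer_context`.
#' @export
transfer_context <- function(source_nets, mapping, dag, ann, tree,
                             target_net = NULL, ic_tables = NULL) {
  if (is.null(ic_tables)) ic_tables <- build_ic_tables(dag, ann)
  structure(
    list(source_nets = source_nets, mapping = mapping, dag = dag, ann = ann,
         tree = tree, target_net = target_net, ic_tables = ic_tables),
    class = "transfer_context"
  )
}

#' Compute the feature table for a batch of transfer instances
#'
#' One row per transfer instance; feature columns as given by
#' [feature_set_columns()] for the requested set, plus the bookkeeping
#' columns `.t_a`, `.t_b`, `.src_species`, `.label`. Unavailable inputs
#' produce the missing marker `NA`; in production mode (no target network)
#' all (T) network-structure features are missing but the vector is still
#' valid.
#'
#' @param transfers a (labeled) `transfer_table`.
#' @param context a [transfer_context()].
#' @param feature_set feature-set name.
#' @return tibble of class `feature_table` with attribute `schema`.
#' @export
build_feature_table <- function(transfers, context, feature_set = "full") {
  schema <- feature_schema(feature_set)
  tt <- as_tibble(transfers)
  n <- nrow(tt)
  dag <- context$dag; ann <- context$ann; mapping <- context$mapping
  gosim <- make_gosim_fun(context$ic_tables, dag, ann)

  ## --- per-pair helpers -------------------------------------------------
  net_of <- function(sp) context$source_nets[[sp]]
  ov_cache <- new.env(parent = emptyenv())
  overlap_fun <- function(net, tag, a, b) {
    if (is.null(net)) return(NA_real_)
    key <- paste(tag, pmin(a, b), pmax(a, b))
    v <- ov_cache[[key]]
    if (is.null(v)) {
      v <- network_overlap(net, a, b)
      ov_cache[[key]] <- v
    }
    v
  }
  ng_cache <- new.env(parent = emptyenv())
  netgo_fun <- function(net, tag, a, b) {
    if (is.null(net) || is.null(context$ic_tables$global)) return(NA_real_)
    key <- paste(tag, pmin(a, b), pmax(a, b))
    v <- ng_cache[[key]]
    if (is.null(v)) {
      na <- network_neighbors(net, a); nb <- network_neighbors(net, b)
      if (!length(na) || !length(nb)) {
        v <- NA_real_
      } else {
        vals <- unlist(lapply(na, function(u) {
          vapply(nb, function(w) gosim("global", u, w), 0)
        }), use.names = FALSE)
        vals <- vals[!is.na(vals)]
        v <- if (length(vals)) mean(vals) else NA_real_
      }
      ng_cache[[key]] <- v
    }
    v
  }

  ## ortholog support lookup over unordered gene pairs
  supp_key <- paste(
    pmin(mapping$gene_source, mapping$gene_target),
    pmax(mapping$gene_source, mapping$gene_target)
  )
  supp_tab <- tapply(mapping$db, supp_key, function(d) length(unique(d)))
  support_fun <- function(g1, g2) {
    v <- supp_tab[[paste(pmin(g1, g2), pmax(g1, g2))]]
    if (is.null(v)) NA_integer_ else as.integer(v)
  }

  ## phylogenetic distance per species pair
  sp_pairs <- unique(tt$src_species)
  tgt_sp <- if (n) tt$target_species[1L] else NA_character_
  pd <- vapply(sp_pairs, function(s) phylo_distance(context$tree, s, tgt_sp), 0)
  names(pd) <- sp_pairs

  ## transitive orthology, memoized per (source species, gene pair)
  mids_by_sp <- lapply(sp_pairs, function(s) intermediate_species(context$tree, s, tgt_sp))
  names(mids_by_sp) <- sp_pairs
  trans_cache <- new.env(parent = emptyenv())
  trans_fun <- function(sp, g_src, g_tgt) {
    key <- paste(sp, g_src, g_tgt)
    v <- trans_cache[[key]]
    if (is.null(v)) {
      v <- chain_reaches(mapping, c(sp, mids_by_sp[[sp]], tgt_sp), g_src, g_tgt)
      trans_cache[[key]] <- v
    }
    v
  }

  ## total support: distinct source species per target pair, minus own
  pair_key <- paste(tt$t_a, tt$t_b)
  sp_per_pair <- tapply(tt$src_species, pair_key, function(s) length(unique(s)))

  num <- function(f) vapply(seq_len(n), f, 0)
  lgl <- function(f) vapply(seq_len(n), f, NA)

  out <- tibble(
    .t_a = tt$t_a, .t_b = tt$t_b, .src_species = tt$src_species,
    .label = tt$label
  )

  out$network_overlap_S <- num(function(i) {
    overlap_fun(net_of(tt$src_species[i]), tt$src_species[i], tt$src_a[i], tt$src_b[i])
  })
  out$network_overlap_T <- num(function(i) {
    overlap_fun(context$target_net, "(T)", tt$t_a[i], tt$t_b[i])
  })
  out$net_go_S <- num(function(i) {
    netgo_fun(net_of(tt$src_species[i]), tt$src_species[i], tt$src_a[i], tt$src_b[i])
  })
  out$net_go_T <- num(function(i) {
    netgo_fun(context$target_net, "(T)", tt$t_a[i], tt$t_b[i])
  })
  for (cat in GO_CATS) {
    out[[paste0("go_", cat, "_S")]] <- num(function(i) gosim(cat, tt$src_a[i], tt$src_b[i]))
    out[[paste0("go_", cat, "_T")]] <- num(function(i) gosim(cat, tt$t_a[i], tt$t_b[i]))
  }
  out$source_db_S <- tt$source_db
  out$edge_support_S <- vapply(tt$pubmed_ids, length, 0L)
  out$source_type_S <- tt$itype
  out$total_support_T <- as.integer(sp_per_pair[pair_key] - 1L)
  out$expr_corr_T <- num(function(i) expression_correlation(ann, tt$t_a[i], tt$t_b[i]))

  for (k in 1:2) {
    src_gene <- if (k == 1L) tt$src_a else tt$src_b
    tgt_gene <- if (k == 1L) tt$t_a else tt$t_b
    pre <- function(nm) paste0("o", k, "_", nm)
    suf <- function(nm) paste0(nm, "_O", k)
    for (cat in GO_CATS) {
      out[[paste0("go_", cat, "_O", k)]] <- num(function(i) gosim(cat, src_gene[i], tgt_gene[i]))
    }
    out[[suf("seq_identity")]] <- tt[[pre("seq_identity")]]
    out[[suf("token_sim")]] <- num(function(i) {
      v <- token_similarity(ann, src_gene[i], tgt_gene[i]); if (is.null(v)) NA_real_ else v
    })
    out[[suf("domain_sim")]] <- num(function(i) {
      v <- domain_similarity(ann, src_gene[i], tgt_gene[i]); if (is.null(v)) NA_real_ else v
    })
    out[[suf("kegg_shared")]] <- lgl(function(i) pathway_shared(ann, src_gene[i], tgt_gene[i]))
    out[[suf("ortho_source")]] <- tt[[pre("db")]]
    out[[suf("ortho_score")]] <- ortholog_score(
      tt[[pre("inpara_s")]], tt[[pre("inpara_t")]], tt[[pre("boot_s")]], tt[[pre("boot_t")]]
    )
    out[[suf("ortho_support")]] <- num(function(i) support_fun(src_gene[i], tgt_gene[i]))
    out[[suf("transitive")]] <- lgl(function(i) {
      trans_fun(tt$src_species[i], src_gene[i], tgt_gene[i])
    })
    out[[suf("phylo_dist")]] <- if (n) unname(pd[tt$src_species]) else numeric()
  }

  out <- out[, c(".t_a", ".t_b", ".src_species", ".label", schema$feature)]
  structure(out, schema = schema, feature_set = feature_set,
            class = c("feature_table", class(out)))
}

#' Restrict a feature table to a smaller feature set
#'
#' Column subsetting of an already computed table (every named set is a
#' subset of `full`), avoiding recomputation of the expensive GO and
#' network features.
#'
#' @param features a `feature_table` built with the `full` set.
#' @param feature_set target feature-set name.
#' @return a `feature_table` with the target schema.
#' @export
subset_feature_set <- function(features, feature_set) {
  schema <- feature_schema(feature_set)
  missing_cols <- setdiff(schema$feature, names(features))
  if (length(missing_cols)) {
    abort(sprintf("features lack column(s) %s; build from the full set",
                  paste(missing_cols, collapse = ", ")))
  }
  meta <- intersect(c(".t_a", ".t_b", ".src_species", ".label"), names(features))
  out <- features[, c(meta, schema$feature)]
  structure(out, schema = schema, feature_set = feature_set,
            class = unique(c("feature_table", class(out))))
}

#' Baseline filter scores for a transfer batch
#'
#' The two classical single-feature filters used as comparison baselines: the
#' harmonic mean of the two ortholog sequence identities, and the mean
#' InParanoid-style [ortholog_score()] of the two ortholog pairs. `NA` where
#' the underlying scores are missing.
#'
#' @param transfers a `transfer_table`.
#' @return tibble with columns `harmonic_seq` and `ortho_score`.
#' @export
baseline_scores <- function(transfers) {
  tt <- as_tibble(transfers)
  o1 <- ortholog_score(tt$o1_inpara_s, tt$o1_inpara_t, tt$o1_boot_s, tt$o1_boot_t)
  o2 <- ortholog_score(tt$o2_inpara_s, tt$o2_inpara_t, tt$o2_boot_s, tt$o2_boot_t)
  tibble(
    harmonic_seq = harmonic_sequence_similarity(tt$o1_seq_identity, tt$o2_seq_identity),
    ortho_score = (o1 + o2) / 2
  )
}

#' Write a feature table with its schema sidecar
#' @param features a `feature_table`.
#' @param path output TSV path; the schema is written to `<path>.schema.json`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  readr::write_tsv(as_tibble(features), path, na = "NA")
  schema <- attr(features, "schema")
  jsonlite::write_json(
    list(feature_set = attr(features, "feature_set"),
         features = schema$feature, kinds = schema$kind),
    paste0(path, ".schema.json")
  )
  invisible(path)
}

## pairwise Resnik similarity with per-protein ancestor caching
make_gosim_fun <- function(ic_tables, dag, ann) {
  anc_cache <- new.env(parent = emptyenv())
  sim_cache <- new.env(parent = emptyenv())
  anc_get <- function(cat, p) {
    key <- paste0(cat, "\r", p)
    v <- anc_cache[[key]]
    if (is.null(v)) {
      v <- protein_ancestor_set(ic_tables[[cat]], dag, ann, p)
      if (is.null(v)) v <- NA_character_
      anc_cache[[key]] <- v
    }
    v
  }
  function(cat, p1, p2) {
    if (cat %in% c("b", "c", "m")) cat <- toupper(cat)
    tab <- ic_tables[[cat]]
    if (is.null(tab)) return(NA_real_)
    if (p1 > p2) { tmp <- p1; p1 <- p2; p2 <- tmp }
    key <- paste0(cat, "\r", p1, "\r", p2)
    v <- sim_cache[[key]]
    if (!is.null(v)) return(v)
    a1 <- anc_get(cat, p1); a2 <- anc_get(cat, p2)
    v <- if (anyNA(a1) || anyNA(a2)) {
      NA_real_
    } else {
      common <- intersect(a1, a2)
      if (!length(common)) 0 else max(tab$ic[common])
    }
    sim_cache[[key]] <- v
    v
  }
}

jaccard <- function(s1, s2) {
  if (is.null(s1) || is.null(s2) || !length(s1) || !length(s2)) return(NA_real_)
  u <- length(union(s1, s2))
  if (!u) return(NA_real_)
  length(intersect(s1, s2)) / u
}
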