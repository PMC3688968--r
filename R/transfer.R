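#' Direct interolog transfer of a source network onto a target species
#'
#' For every source edge (s1, s2) and every combination of ortholog records
#' s1 -> t1 and s2 -> t2 connecting the source species to `target_species`,
#' one transfer instance is emitted. Combinations mapping both endpoints to
#' the same target protein are dropped. The same target pair may occur in
#' several instances with different provenance (different source edges,
#' ortholog records, or ortholog databases); duplicates over
#' (target pair, source edge, ortholog records) are emitted once.
#'
#' Each row retains full provenance: the source edge (`src_a`, `src_b`,
#' `src_species`, `itype`, `source_db`, `pubmed_ids`) and the two ortholog
#' records (`o1_*` maps `src_a` -> `t_a`, `o2_*` maps `src_b` -> `t_b`; the
#' pairing is preserved when canonicalization swaps `t_a`/`t_b`).
#'
#' @param source_net an [interaction_network()].
#' @param mapping an [ortholog_mapping()].
#' @param target_species species id to transfer onto.
#' @return tibble of class `transfer_table`, one row per transfer instance,
#'   with `label = "unlabeled"` and `score = NA`. Empty (with a warning) when
#'   the mapping holds no records for the species pair.
#' @export
direct_transfer <- function(source_net, mapping, target_species) {
  src_sp <- network_species(source_net)
  orth <- ortholog_pairs_between(mapping, src_sp, target_species)
  if (!nrow(orth) || !nrow(source_net)) {
    if (!nrow(orth)) {
      warn(sprintf(
        "no ortholog records between %s and %s: empty transfer", src_sp, target_species
      ))
    }
    return(empty_transfer_table(src_sp, target_species))
  }
  orth <- orth %>% mutate(.rec = seq_len(nrow(orth)))
  edges <- as_tibble(source_net) %>% mutate(.edge = seq_len(nrow(source_net)))

  a_side <- edges %>%
    inner_join(orth, by = c(id_a = "gene_source"), relationship = "many-to-many")
  both <- a_side %>%
    inner_join(orth, by = c(id_b = "gene_source"), suffix = c("_o1", "_o2"),
               relationship = "many-to-many") %>%
    filter(.data$gene_target_o1 != .data$gene_target_o2)
  if (!nrow(both)) return(empty_transfer_table(src_sp, target_species))

  out <- tibble(
    t_a = both$gene_target_o1, t_b = both$gene_target_o2,
    src_a = both$id_a, src_b = both$id_b,
    src_species = src_sp, target_species = target_species,
    itype = both$itype, source_db = both$source_db, pubmed_ids = both$pubmed_ids,
    o1_db = both$db_o1, o1_inpara_s = both$inpara_s_o1, o1_inpara_t = both$inpara_t_o1,
    o1_boot_s = both$boot_s_o1, o1_boot_t = both$boot_t_o1,
    o1_seq_identity = both$seq_identity_o1,
    o2_db = both$db_o2, o2_inpara_s = both$inpara_s_o2, o2_inpara_t = both$inpara_t_o2,
    o2_boot_s = both$boot_s_o2, o2_boot_t = both$boot_t_o2,
    o2_seq_identity = both$seq_identity_o2,
    .edge = both$.edge, .rec1 = both$.rec_o1, .rec2 = both$.rec_o2
  )
  ## canonical target order, keeping ortholog/source pairing aligned with t_a/t_b
  swap <- out$t_a > out$t_b
  if (any(swap)) {
    o1 <- c("t_a", "src_a", "o1_db", "o1_inpara_s", "o1_inpara_t", "o1_boot_s",
            "o1_boot_t", "o1_seq_identity", ".rec1")
    o2 <- c("t_b", "src_b", "o2_db", "o2_inpara_s", "o2_inpara_t", "o2_boot_s",
            "o2_boot_t", "o2_seq_identity", ".rec2")
    tmp <- out[swap, o1]
    out[swap, o1] <- stats::setNames(out[swap, o2], o1)
    out[swap, o2] <- stats::setNames(tmp, o2)
  }
  out <- out %>%
    distinct(.data$t_a, .data$t_b, .data$.edge, .data$.rec1, .data$.rec2,
             .keep_all = TRUE) %>%
    select(-".edge", -".rec1", -".rec2") %>%
    arrange(.data$t_a, .data$t_b, .data$src_a, .data$src_b, .data$o1_db, .data$o2_db) %>%
    mutate(label = "unlabeled", score = NA_real_)
  as_transfer_table(out)
}

empty_transfer_table <- function(src_sp, target_species) {
  as_transfer_table(tibble(
    t_a = character(), t_b = character(), src_a = character(), src_b = character(),
    src_species = character(), target_species = character(), itype = character(),
    source_db = character(), pubmed_ids = list(),
    o1_db = character(), o1_inpara_s = numeric(), o1_inpara_t = numeric(),
    o1_boot_s = numeric(), o1_boot_t = numeric(), o1_seq_identity = numeric(),
    o2_db = character(), o2_inpara_s = numeric(), o2_inpara_t = numeric(),
    o2_boot_s = numeric(), o2_boot_t = numeric(), o2_seq_identity = numeric(),
    label = character(), score = numeric()
  ))
}

as_transfer_table <- function(x) {
  class(x) <- unique(c("transfer_table", class(x)))
  x
}

#' Combine transfer tables from several source networks
#' @param ... `transfer_table`s (or a single list of them).
#' @return one `transfer_table`.
#' @export
bind_transfers <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) && !inherits(args[[1L]], "data.frame")) {
    args <- args[[1L]]
  }
  as_transfer_table(bind_rows(lapply(args, as_tibble)))
}

#' Label transferred interactions against a gold-standard network
#'
#' Under `AllI` every instance is kept and is `consistent` iff its target
#' pair occurs in the gold network with any interaction type. Under `PhyI`
#' (`GenI`) the instance set is first restricted to transfers whose source
#' interaction type is physical (genetic), and consistency additionally
#' requires the gold edge to carry the matching type.
#'
#' @param transfers a `transfer_table`.
#' @param gold an [interaction_network()] for the target species, or `NULL` to
#'   leave every instance `unlabeled` (production mode).
#' @param setting one of `"AllI"`, `"PhyI"`, `"GenI"`.
#' @return the (possibly restricted) `transfer_table` with `label` filled in.
#' @export
label_against_gold <- function(transfers, gold, setting = c("AllI", "PhyI", "GenI")) {
  setting <- match.arg(setting)
  out <- as_tibble(transfers)
  if (setting == "PhyI") out <- out %>% filter(.data$itype == "physical")
  if (setting == "GenI") out <- out %>% filter(.data$itype == "genetic")
  if (is.null(gold)) {
    out$label <- "unlabeled"
    return(as_transfer_table(out))
  }
  if (nrow(out) && any(out$target_species != network_species(gold))) {
    abort("gold network species does not match the transfers' target species")
  }
  gold_keys <- if (setting == "AllI") {
    unique(paste(gold$id_a, gold$id_b))
  } else {
    type <- if (setting == "PhyI") "physical" else "genetic"
    g <- gold[gold$itype == type, , drop = FALSE]
    unique(paste(g$id_a, g$id_b))
  }
  out$label <- ifelse(paste(out$t_a, out$t_b) %in% gold_keys, "consistent", "inconsistent")
  as_transfer_table(out)
}

#' Collapse transfer instances into a pair-wise interaction network
#'
#' One edge per canonical target pair; the retained score is the maximum over
#' the pair's instances (conserving the best evidence), with the instance
#' count and the supporting source species/databases attached as provenance.
#'
#' @param transfers a scored (or unscored) `transfer_table`.
#' @return tibble of class `transferred_network` with columns `t_a`, `t_b`,
#'   `score`, `n_instances`, `src_species` and `source_dbs` (list-columns).
#' @export
dedupe_network <- function(transfers) {
  tb <- as_tibble(transfers)
  out <- tb %>%
    group_by(.data$t_a, .data$t_b) %>%
    summarise(
      score = if (all(is.na(.data$score))) NA_real_ else max(.data$score, na.rm = TRUE),
      n_instances = dplyr::n(),
      src_species = list(sort(unique(.data$src_species))),
      source_dbs = list(sort(unique(.data$source_db))),
      .groups = "drop"
    ) %>%
    arrange(.data$t_a, .data$t_b)
  class(out) <- unique(c("transferred_network", class(out)))
  out
}

#' Fraction of labeled instances that are consistent
#' @param transfers a labeled `transfer_table`.
#' @return numeric scalar: consistent / (consistent + inconsistent).
#' @export
transfer_precision <- function(transfers) {
  lab <- transfers$label[transfers$label != "unlabeled"]
  if (!length(lab)) abort("no labeled instances")
  mean(lab == "consistent")
}

#' Write a transfer table
#' @param transfers a `transfer_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_transfer_table <- function(transfers, path) {
  fmt <- function(x) ifelse(is.na(x), "NA", format(x, digits = 10, trim = TRUE))
  lines <- c(
    paste(c("t_a", "t_b", "src_a", "src_b", "src_species", "itype", "source_db",
            "ortho_db_a", "ortho_db_b", "label", "score"), collapse = "\t"),
    sprintf(
      "%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
      transfers$t_a, transfers$t_b, transfers$src_a, transfers$src_b,
      transfers$src_species, transfers$itype, transfers$source_db,
      transfers$o1_db, transfers$o2_db, transfers$label, fmt(transfers$score)
    )
  )
  writeLines(lines, path)
  invisible(path)
}
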