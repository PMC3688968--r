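#' Published benchmark counts for interolog transfer to S. cerevisiae
#'
#' Reference counts from a published large-scale interolog transfer
#' benchmark, shipped as a plain-text table: the consistent/inconsistent
#' split of the 19,785 interactions transferable to *S. cerevisiae* under
#' the three experimental settings (AllI: any occurrence in the gold
#' network; PhyI/GenI: occurrence plus interaction-type agreement for
#' physical/genetic source interactions), the sizes of the *S. cerevisiae*
#' gold network, and the production-scale transfer totals.
#'
#' @return tibble with columns `quantity`, `value`.
#' @export
reference_transfer_counts <- function() {
  path <- system.file("extdata", "reference_transfer_counts.tsv",
                      package = "interolog", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    quantity = readr::col_character(), value = readr::col_double()
  ))
}

#' Benchmark arithmetic derived from the reference counts
#'
#' Recomputes the self-contained arithmetic of the benchmark from
#' [reference_transfer_counts()]: direct-transfer precision per setting
#' (consistent / transferred), the percentage of the gold network covered
#' by the consistent transfers, the count-conservation identity between the
#' AllI split and the PhyI + GenI + untyped split, the target network's
#' interactions-per-gene ratio, and the fraction of production-scale
#' transfers removed by filtering.
#'
#' @return tibble with columns `stat`, `value`.
#' @export
reference_transfer_stats <- function() {
  v <- reference_transfer_counts()
  g <- function(q) v$value[v$quantity == q]
  alli_total <- g("transfer_consistent_alli") + g("transfer_inconsistent_alli")
  phyi_total <- g("transfer_consistent_phyi") + g("transfer_inconsistent_phyi")
  geni_total <- g("transfer_consistent_geni") + g("transfer_inconsistent_geni")
  tibble(
    stat = c(
      "precision_alli", "precision_phyi", "precision_geni",
      "coverage_pct_alli", "coverage_pct_phyi", "coverage_pct_geni",
      "transferable_total", "count_identity_gap",
      "interactions_per_gene", "production_filtered_pct"
    ),
    value = c(
      g("transfer_consistent_alli") / alli_total,
      g("transfer_consistent_phyi") / phyi_total,
      g("transfer_consistent_geni") / geni_total,
      100 * g("transfer_consistent_alli") / g("gold_interactions_total"),
      100 * g("transfer_consistent_phyi") / g("gold_interactions_physical"),
      100 * g("transfer_consistent_geni") / g("gold_interactions_genetic"),
      alli_total,
      abs(alli_total - (phyi_total + geni_total + g("transfer_untyped"))),
      g("gold_interactions_total") / g("target_genes"),
      100 * (1 - g("production_filtered_transfers") / g("production_direct_transfers"))
    )
  )
}
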