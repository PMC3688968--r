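GLOBAL_ROOT <- "(global-root)"

#' Build a Resnik information-content table
#'
#' A protein annotated with a term contributes one count to that term and to
#' every ancestor, with set semantics: on diamond paths a protein is counted
#' once per term, never twice. With `p(t) = count(t) / count(root)` the
#' information content is `IC(t) = -log p(t)` (natural log; the base only
#' rescales similarities). The category root has IC 0. `category = "global"`
#' pools all three categories under a virtual super-root, so cross-category
#' term pairs score 0 rather than being skipped.
#'
#' Terms annotated to no protein (directly or via descendants) have no
#' defined IC and are absent from the table.
#'
#' @param dag a [go_dag()].
#' @param annotations an [annotation_store()] (only `$go` is used).
#' @param category `"B"`, `"C"`, `"M"` or `"global"`.
#' @return object of class `ic_table`: list with `counts`, `ic`, `total`,
#'   `category`, `root`.
#' @export
build_ic_table <- function(dag, annotations, category = c("global", "B", "C", "M")) {
  category <- match.arg(category)
  counts <- new_counter()
  n_annotated <- 0L
  for (p in names(annotations$go)) {
    terms <- intersect(annotations$go[[p]], dag$terms)
    if (category != "global") terms <- terms[dag$category[terms] == category]
    if (!length(terms)) next
    n_annotated <- n_annotated + 1L
    anc <- unique(unlist(dag$ancestors[terms], use.names = FALSE))
    if (category == "global") anc <- c(anc, GLOBAL_ROOT)
    counter_add(counts, anc)
  }
  cnt <- counter_values(counts)
  if (!length(cnt) || n_annotated == 0L) {
    abort(sprintf("no annotations for category %s", category))
  }
  root <- if (category == "global") GLOBAL_ROOT else dag$roots[[category]]
  total <- cnt[[root]]
  stopifnot(total == n_annotated)
  ic <- -log(cnt / total)
  ic[ic < 0] <- 0 # guard against -0
  structure(
    list(counts = cnt, ic = ic, total = total, category = category, root = root),
    class = "ic_table"
  )
}

#' @export
print.ic_table <- function(x, ...) {
  cat(sprintf(
    "<ic_table> category=%s  %d terms with counts, %d annotated proteins\n",
    x$category, length(x$counts), x$total
  ))
  invisible(x)
}

#' Export an IC table as a tibble
#' @param x an `ic_table`.
#' @param ... unused.
#' @return tibble with columns `term`, `count`, `ic`.
#' @export
tidy.ic_table <- function(x, ...) {
  tibble(term = names(x$counts), count = as.integer(x$counts), ic = unname(x$ic)) %>%
    arrange(dplyr::desc(.data$ic), .data$term)
}

#' Resnik similarity of two GO terms
#'
#' The information content of the most informative common ancestor (MICA):
#' the maximum IC over the common ancestors of the two terms that have a
#' defined IC. A term is its own ancestor, so `term_similarity(t, t) = IC(t)`.
#' Under a global table two terms from different categories share only the
#' virtual super-root and score 0.
#'
#' @param ic an [build_ic_table()] result.
#' @param dag the [go_dag()] the table was built on.
#' @param t1,t2 term ids present in the DAG.
#' @return non-negative similarity (0 when no scored common ancestor exists).
#' @export
term_similarity <- function(ic, dag, t1, t2) {
  common <- intersect(term_ancestors(dag, t1), term_ancestors(dag, t2))
  common <- common[common %in% names(ic$ic)]
  if (!length(common)) return(0)
  max(ic$ic[common])
}

#' Resnik GO similarity of two proteins
#'
#' The maximum [term_similarity()] over all combinations of the two
#' proteins' GO annotations (restricted to the table's category). Missing
#' (`NA`) when either protein carries no scored annotation in the category,
#' mirroring the missing-value policy of the feature layer.
#'
#' @param ic an `ic_table`.
#' @param dag a `go_dag`.
#' @param ann an [annotation_store()].
#' @param p1,p2 protein ids.
#' @return numeric similarity, or `NA` if undefined.
#' @export
protein_go_similarity <- function(ic, dag, ann, p1, p2) {
  a1 <- protein_ancestor_set(ic, dag, ann, p1)
  a2 <- protein_ancestor_set(ic, dag, ann, p2)
  if (is.null(a1) || is.null(a2)) return(NA_real_)
  ## max over term pairs of the MICA IC equals the max IC over the
  ## intersection of the two ancestor unions
  common <- intersect(a1, a2)
  if (!length(common)) return(0)
  max(ic$ic[common])
}

## ancestor union of a protein's category-restricted annotation terms,
## filtered to terms with defined IC; NULL when the protein has none
protein_ancestor_set <- function(ic, dag, ann, p) {
  terms <- intersect(ann$go[[p]], dag$terms)
  if (ic$category != "global") terms <- terms[dag$category[terms] == ic$category]
  terms <- terms[terms %in% names(ic$ic)]
  if (!length(terms)) return(NULL)
  anc <- unique(unlist(dag$ancestors[terms], use.names = FALSE))
  anc <- anc[anc %in% names(ic$ic)]
  if (ic$category == "global") anc <- c(anc, GLOBAL_ROOT)
  anc
}

#' Build the four IC tables used by the feature layer
#' @param dag a `go_dag`.
#' @param ann an `annotation_store`.
#' @return named list of `ic_table`s (`global`, `B`, `C`, `M`); categories
#'   with no annotated protein are dropped.
#' @export
build_ic_tables <- function(dag, ann) {
  out <- list()
  for (cat in c("global", "B", "C", "M")) {
    tb <- tryCatch(build_ic_table(dag, ann, cat), error = function(e) NULL)
    if (!is.null(tb)) out[[cat]] <- tb
  }
  if (!length(out)) abort("no annotations for any category")
  out
}

## ---- small counting helper (environment-backed) -----------------------------

new_counter <- function() new.env(parent = emptyenv())

counter_add <- function(env, keys) {
  for (k in keys) {
    prev <- env[[k]]
    env[[k]] <- if (is.null(prev)) 1L else prev + 1L
  }
}

counter_values <- function(env) {
  keys <- ls(env, all.names = TRUE)
  stats::setNames(vapply(keys, function(k) env[[k]], 0L), keys)
}
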