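#' @import rlang
#' @importFrom dplyr %>% filter mutate select arrange group_by ungroup summarise
#'   distinct n n_distinct left_join inner_join bind_rows rename across all_of
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data abort warn
NULL

INTERACTION_TYPES <- c("physical", "genetic", "other")

## tokens that denote an untyped/ambiguous interaction collapse to "other"
OTHER_ALIASES <- c("other", "unknown", "ambiguous", "na", "")

#' Construct an interaction network
#'
#' An interaction network is a species-tagged, undirected edge table. Edges are
#' stored once, in canonical order (lexicographically smaller protein id
#' first), with an interaction type, a source database and a set of PubMed
#' evidence ids. Self-interactions are rejected: the neighborhood-based
#' features downstream (Jaccard overlap, neighborhood GO similarity) are
#' degenerate for loops.
#'
#' @param edges tibble with columns `id_a`, `id_b`, `itype`, `source_db` and a
#'   list-column `pubmed_ids` (character vectors, possibly empty).
#' @param species single species identifier tag for the network.
#' @return a tibble of class `interaction_network` with attribute `species`.
#' @export
interaction_network <- function(edges = NULL, species) {
  stopifnot(is.character(species), length(species) == 1L, nzchar(species))
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- tibble(
      id_a = character(), id_b = character(), itype = character(),
      source_db = character(), pubmed_ids = list()
    )
  }
  edges <- as_tibble(edges)
  if (!all(c("id_a", "id_b", "itype", "source_db") %in% names(edges))) {
    abort("edges must have columns id_a, id_b, itype, source_db")
  }
  if (!"pubmed_ids" %in% names(edges)) edges$pubmed_ids <- rep(list(character()), nrow(edges))
  if (any(edges$id_a == edges$id_b)) {
    abort("self-interaction: interactions must connect two distinct proteins")
  }
  bad <- !edges$itype %in% INTERACTION_TYPES
  if (any(bad)) {
    abort(paste0(
      "unknown interaction type(s): ", paste(unique(edges$itype[bad]), collapse = ", "),
      "; allowed: ", paste(INTERACTION_TYPES, collapse = ", ")
    ))
  }
  ## canonical order + collapse duplicates (pair, itype, source_db), union pubmed
  swap <- edges$id_a > edges$id_b
  tmp <- edges$id_a[swap]
  edges$id_a[swap] <- edges$id_b[swap]
  edges$id_b[swap] <- tmp
  edges <- edges %>%
    group_by(.data$id_a, .data$id_b, .data$itype, .data$source_db) %>%
    summarise(
      pubmed_ids = list(sort(unique(unlist(.data$pubmed_ids)))),
      .groups = "drop"
    ) %>%
    arrange(.data$id_a, .data$id_b, .data$itype, .data$source_db)
  structure(
    edges,
    species = species,
    class = c("interaction_network", class(edges))
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf(
    "<interaction_network> species=%s  %d edges, %d proteins\n",
    attr(x, "species"), nrow(x), length(network_proteins(x))
  ))
  NextMethod()
}

#' Species tag of a network
#' @param net an `interaction_network`.
#' @return single character species id.
#' @export
network_species <- function(net) attr(net, "species")

#' Proteins of a network
#' @param net an `interaction_network`.
#' @return sorted character vector of distinct endpoint ids.
#' @export
network_proteins <- function(net) sort(unique(c(net$id_a, net$id_b)))

#' Direct neighbors of a protein
#' @param net an `interaction_network`.
#' @param p protein id.
#' @return character vector of proteins sharing an edge with `p` (empty when
#'   `p` is isolated or absent).
#' @export
network_neighbors <- function(net, p) {
  sort(unique(c(net$id_b[net$id_a == p], net$id_a[net$id_b == p])))
}

#' Test whether a pair is an edge of a network
#' @param net an `interaction_network`.
#' @param a,b protein ids (any order).
#' @param itype optional interaction type that must also match.
#' @return logical scalar.
#' @export
network_has_edge <- function(net, a, b, itype = NULL) {
  ca <- pmin(a, b); cb <- pmax(a, b)
  hit <- net$id_a == ca & net$id_b == cb
  if (!is.null(itype)) hit <- hit & net$itype == itype
  any(hit)
}

#' Read a tab-separated interaction table
#'
#' Expects the header `idA idB itype source_db pubmed_ids` (tab-separated).
#' `pubmed_ids` is a pipe-separated list, possibly empty. Rows are
#' canonicalized; duplicate (pair, itype, source_db) rows are collapsed with
#' their PubMed sets unioned. Interaction type tokens other than
#' `physical`/`genetic` that denote an untyped or ambiguous interaction
#' (`other`, `unknown`, `ambiguous`) collapse to `other`; anything else is an
#' error listing the allowed tokens.
#'
#' @param file path, connection, or literal text (with embedded newlines).
#' @param species species id to tag the network with.
#' @return an [interaction_network()].
#' @export
parse_interaction_table <- function(file, species) {
  lines <- read_text_lines(file)
  header <- c("idA", "idB", "itype", "source_db", "pubmed_ids")
  check_header(lines, header, "interaction table")
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (!length(body)) return(interaction_network(NULL, species))
  parts <- stringr::str_split(body, "\t")
  nf <- lengths(parts)
  if (any(nf != 5L)) {
    abort(sprintf(
      "malformed interaction row at line %d: expected 5 tab-separated fields, got %d",
      which(nf != 5L)[1L] + 1L, nf[nf != 5L][1L]
    ))
  }
  m <- do.call(rbind, parts)
  itype <- tolower(m[, 3L])
  itype[itype %in% OTHER_ALIASES] <- "other"
  bad <- !itype %in% INTERACTION_TYPES
  if (any(bad)) {
    abort(sprintf(
      "unknown interaction type '%s' at line %d; allowed tokens: %s",
      m[bad, 3L][1L], which(bad)[1L] + 1L,
      paste(c("physical", "genetic", "other (unknown/ambiguous)"), collapse = ", ")
    ))
  }
  selfs <- m[, 1L] == m[, 2L]
  if (any(selfs)) {
    abort(sprintf("self-interaction at line %d: '%s'", which(selfs)[1L] + 1L, m[selfs, 1L][1L]))
  }
  pm <- lapply(m[, 5L], function(s) {
    v <- strsplit(s, "|", fixed = TRUE)[[1L]]
    v[nzchar(v)]
  })
  interaction_network(
    tibble(id_a = m[, 1L], id_b = m[, 2L], itype = itype, source_db = m[, 4L], pubmed_ids = pm),
    species = species
  )
}

#' Write an interaction table
#' @param net an `interaction_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(net, path) {
  lines <- c(
    "idA\tidB\titype\tsource_db\tpubmed_ids",
    sprintf(
      "%s\t%s\t%s\t%s\t%s",
      net$id_a, net$id_b, net$itype, net$source_db,
      vapply(net$pubmed_ids, paste, "", collapse = "|")
    )
  )
  writeLines(lines, path)
  invisible(path)
}

ORTHOLOG_COLS <- c(
  "gene_source", "sp_source", "gene_target", "sp_target", "db",
  "inpara_s", "inpara_t", "boot_s", "boot_t", "seq_identity"
)

#' Read a scored ortholog-pair table
#'
#' Expects the tab-separated header
#' `gene_source sp_source gene_target sp_target db inpara_s inpara_t boot_s
#' boot_t seq_identity`. The numeric columns hold InParanoid-style inparalog
#' and bootstrap confidences and the ortholog sequence identity, each in
#' \[0,1\] or `NA` (missing). n:m relations are allowed; the same gene pair
#' listed by several ortholog databases yields several records (its
#' ortholog-support count downstream). Duplicate (gene pair, db) rows are an
#' error, as is a score outside \[0,1\] or a within-species pair.
#'
#' @param file path, connection, or literal text.
#' @return tibble of class `ortholog_mapping`.
#' @export
parse_ortholog_table <- function(file) {
  lines <- read_text_lines(file)
  check_header(lines, ORTHOLOG_COLS, "ortholog table")
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (!length(body)) return(ortholog_mapping(NULL))
  parts <- stringr::str_split(body, "\t")
  nf <- lengths(parts)
  if (any(nf != 10L)) {
    abort(sprintf("malformed ortholog row at line %d", which(nf != 10L)[1L] + 1L))
  }
  m <- do.call(rbind, parts)
  num <- function(j) {
    v <- m[, j]
    out <- suppressWarnings(as.numeric(ifelse(v == "NA", NA, v)))
    bad <- !is.na(out) & (out < 0 | out > 1)
    if (any(bad)) {
      abort(sprintf(
        "score out of range [0,1] in column %s at line %d: %s",
        ORTHOLOG_COLS[j], which(bad)[1L] + 1L, v[bad][1L]
      ))
    }
    out
  }
  tb <- tibble(
    gene_source = m[, 1L], sp_source = m[, 2L],
    gene_target = m[, 3L], sp_target = m[, 4L], db = m[, 5L],
    inpara_s = num(6L), inpara_t = num(7L), boot_s = num(8L), boot_t = num(9L),
    seq_identity = num(10L)
  )
  ortholog_mapping(tb)
}

#' Construct an ortholog mapping
#'
#' @param pairs tibble with the columns of [parse_ortholog_table()]. Lookup is
#'   symmetric: records can be queried from either species side.
#' @return tibble of class `ortholog_mapping`.
#' @export
ortholog_mapping <- function(pairs = NULL) {
  if (is.null(pairs) || nrow(pairs) == 0L) {
    pairs <- tibble(
      gene_source = character(), sp_source = character(),
      gene_target = character(), sp_target = character(), db = character(),
      inpara_s = numeric(), inpara_t = numeric(), boot_s = numeric(),
      boot_t = numeric(), seq_identity = numeric()
    )
  }
  pairs <- as_tibble(pairs)
  stopifnot(all(ORTHOLOG_COLS %in% names(pairs)))
  if (any(pairs$sp_source == pairs$sp_target)) {
    abort("ortholog pair within a single species is not allowed")
  }
  ## duplicate (unordered gene pair, db) records rejected
  key <- paste(
    pmin(pairs$gene_source, pairs$gene_target),
    pmax(pairs$gene_source, pairs$gene_target), pairs$db
  )
  if (anyDuplicated(key)) {
    abort(sprintf(
      "duplicate ortholog record for gene pair in the same database: %s",
      key[duplicated(key)][1L]
    ))
  }
  structure(pairs[ORTHOLOG_COLS], class = c("ortholog_mapping", class(pairs)))
}

#' Ortholog records for one species pair, oriented source -> target
#'
#' Returns all records connecting `sp_from` and `sp_to`, re-oriented so that
#' `gene_source`/`sp_source` is the `sp_from` side (records stored the other
#' way around have their gene, inparalog and bootstrap columns swapped).
#'
#' @param mapping an `ortholog_mapping`.
#' @param sp_from,sp_to species ids.
#' @return tibble with the mapping columns.
#' @export
ortholog_pairs_between <- function(mapping, sp_from, sp_to) {
  fwd <- mapping %>% filter(.data$sp_source == sp_from, .data$sp_target == sp_to)
  rev <- mapping %>% filter(.data$sp_source == sp_to, .data$sp_target == sp_from)
  if (nrow(rev)) {
    rev <- tibble(
      gene_source = rev$gene_target, sp_source = rev$sp_target,
      gene_target = rev$gene_source, sp_target = rev$sp_source, db = rev$db,
      inpara_s = rev$inpara_t, inpara_t = rev$inpara_s,
      boot_s = rev$boot_t, boot_t = rev$boot_s, seq_identity = rev$seq_identity
    )
  }
  bind_rows(as_tibble(fwd), rev)
}

#' Write an ortholog table
#' @param mapping an `ortholog_mapping`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ortholog_table <- function(mapping, path) {
  fmt <- function(x) ifelse(is.na(x), "NA", format(x, digits = 15, scientific = FALSE, trim = TRUE))
  lines <- c(
    paste(ORTHOLOG_COLS, collapse = "\t"),
    sprintf(
      "%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
      mapping$gene_source, mapping$sp_source, mapping$gene_target,
      mapping$sp_target, mapping$db,
      fmt(mapping$inpara_s), fmt(mapping$inpara_t),
      fmt(mapping$boot_s), fmt(mapping$boot_t), fmt(mapping$seq_identity)
    )
  )
  writeLines(lines, path)
  invisible(path)
}

GO_NAMESPACES <- c(
  biological_process = "B", cellular_component = "C", molecular_function = "M"
)

#' Parse an OBO ontology into a GO DAG
#'
#' Consumes only `id`, `namespace`, `is_a` and `is_obsolete` from `[Term]`
#' stanzas. Obsolete terms are dropped (together with edges that point at
#' them). Namespaces are mapped to the three GO categories B (biological
#' process), C (cellular component), M (molecular function). The resulting
#' `is_a` closure must be acyclic and each category must have exactly one
#' root; ancestry never crosses categories.
#'
#' @param file path, connection, or literal OBO text.
#' @return object of class `go_dag`: list with `terms`, `parents` (named list),
#'   `category` (named character), `roots` (named by category) and `ancestors`
#'   (named list of ancestor sets, each including the term itself).
#' @export
parse_obo <- function(file) {
  lines <- read_text_lines(file)
  term_starts <- which(lines == "[Term]")
  if (!length(term_starts)) abort("no [Term] stanzas found in OBO input")
  block_of <- cumsum(lines == "[Term]" | grepl("^\\[", lines))
  ids <- character(); ns <- character(); obs <- logical(); parents <- list()
  for (s in term_starts) {
    b <- block_of[s]
    stanza <- lines[block_of == b][-1L]
    stanza <- stanza[nzchar(stanza)]
    get1 <- function(key) {
      v <- stanza[startsWith(stanza, paste0(key, ": "))]
      if (length(v)) sub(paste0("^", key, ": "), "", v[1L]) else NA_character_
    }
    id <- get1("id")
    if (is.na(id)) abort("OBO [Term] stanza without id")
    isa <- stanza[startsWith(stanza, "is_a: ")]
    isa <- sub("^is_a: ", "", isa)
    isa <- trimws(sub("!.*$", "", isa))
    ids <- c(ids, id)
    ns <- c(ns, get1("namespace"))
    obs <- c(obs, identical(get1("is_obsolete"), "true"))
    parents[[id]] <- isa
  }
  keep <- !obs & !duplicated(ids)
  ids <- ids[keep]; ns <- ns[keep]
  parents <- parents[ids]
  parents <- lapply(parents, function(p) p[p %in% ids])
  category <- unname(GO_NAMESPACES[ns])
  if (anyNA(category)) {
    abort(sprintf("term with missing or unknown namespace: %s", ids[is.na(category)][1L]))
  }
  names(category) <- ids
  go_dag(ids, parents, category)
}

#' Construct a GO DAG from term, parent and category vectors
#'
#' @param terms character vector of term ids.
#' @param parents named list: term -> character vector of `is_a` parents.
#' @param category named character: term -> one of "B", "C", "M".
#' @return `go_dag` object; errors on cycles, multiple roots per category, or
#'   parents in a different category.
#' @export
go_dag <- function(terms, parents, category) {
  stopifnot(length(terms) > 0L, all(terms %in% names(category)))
  parents <- parents[terms]
  names(parents) <- terms
  parents <- lapply(parents, function(p) unique(p[!is.na(p)]))
  unknown <- setdiff(unlist(parents), terms)
  if (length(unknown)) abort(sprintf("is_a parent not among terms: %s", unknown[1L]))
  ## topological order; detects cycles
  indeg <- vapply(parents, length, 0L)
  children <- split(
    rep(terms, times = indeg),
    unlist(parents, use.names = FALSE)
  )
  order <- character(0)
  frontier <- terms[indeg == 0L]
  remaining <- indeg
  while (length(frontier)) {
    t <- frontier[1L]; frontier <- frontier[-1L]
    order <- c(order, t)
    for (ch in children[[t]]) {
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) frontier <- c(frontier, ch)
    }
  }
  if (length(order) < length(terms)) {
    abort(sprintf(
      "cycle in is_a relations involving terms: %s",
      paste(setdiff(terms, order), collapse = ", ")
    ))
  }
  ## category consistency + single root per category
  for (t in terms) {
    for (p in parents[[t]]) {
      if (category[[p]] != category[[t]]) {
        abort(sprintf("is_a edge crosses categories: %s -> %s", t, p))
      }
    }
  }
  root_terms <- terms[vapply(parents, length, 0L) == 0L]
  roots <- character()
  for (cat in unique(category[terms])) {
    r <- root_terms[category[root_terms] == cat]
    if (length(r) != 1L) {
      abort(sprintf("category %s must have exactly one root, found %d", cat, length(r)))
    }
    roots[[cat]] <- r
  }
  ## ancestor closure (including self), computed in topological order
  anc <- vector("list", length(terms))
  names(anc) <- terms
  for (t in order) {
    anc[[t]] <- unique(c(t, unlist(anc[parents[[t]]], use.names = FALSE)))
  }
  structure(
    list(terms = terms, parents = parents, category = category,
         roots = roots, ancestors = anc),
    class = "go_dag"
  )
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf(
    "<go_dag> %d terms (%s)\n", length(x$terms),
    paste(sprintf("%s: %d", names(x$roots), table(x$category)[names(x$roots)]), collapse = ", ")
  ))
  invisible(x)
}

#' Ancestors of a GO term (including the term itself)
#' @param dag a `go_dag`.
#' @param term term id.
#' @return character vector of ancestor term ids.
#' @export
term_ancestors <- function(dag, term) {
  a <- dag$ancestors[[term]]
  if (is.null(a)) abort(sprintf("unknown GO term: %s", term))
  a
}

#' Parse a rooted Newick species tree
#'
#' Thin wrapper around [ape::read.tree()]. Unnamed inner nodes are auto-named
#' `N1`, `N2`, ... in the order ape stores them, so repeated parses of the
#' same string name nodes identically.
#'
#' @param file path, connection, or literal Newick text.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
parse_newick <- function(file) {
  txt <- if (is.character(file) && length(file) == 1L &&
             grepl("[();]", file) && !file.exists(file)) {
    file # literal Newick text
  } else {
    paste(read_text_lines(file), collapse = "")
  }
  tree <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) abort(paste0("Newick parse error: ", conditionMessage(e))),
    warning = function(w) abort(paste0("Newick parse error: ", conditionMessage(w)))
  )
  if (is.null(tree)) abort("Newick parse error: no tree in input")
  if (is.null(tree$node.label) || !length(tree$node.label)) {
    tree$node.label <- rep("", tree$Nnode)
  }
  blank <- !nzchar(tree$node.label) | is.na(tree$node.label)
  tree$node.label[blank] <- paste0("N", which(blank))
  tree
}

#' Write a tree as Newick text
#' @param tree a `phylo` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Construct an annotation store
#'
#' Per-protein annotation sets used by the feature layer: GO terms,
#' lowercase description tokens, InterPro/PFAM domain ids, pathway ids, and
#' optional expression vectors (equal length within a species).
#'
#' @param go,tokens,domains,pathways named lists: protein id -> character set.
#' @param expression named list: protein id -> numeric vector.
#' @param dag optional `go_dag`; when given, every annotated GO term must be a
#'   term of the DAG.
#' @return object of class `annotation_store`.
#' @export
annotation_store <- function(go = list(), tokens = list(), domains = list(),
                             pathways = list(), expression = list(), dag = NULL) {
  tokens <- lapply(tokens, tolower)
  if (!is.null(dag)) {
    unknown <- setdiff(unique(unlist(go)), dag$terms)
    if (length(unknown)) {
      abort(sprintf("annotation references GO term absent from DAG: %s", unknown[1L]))
    }
  }
  structure(
    list(go = go, tokens = tokens, domains = domains,
         pathways = pathways, expression = expression),
    class = "annotation_store"
  )
}

#' @export
print.annotation_store <- function(x, ...) {
  cat(sprintf(
    "<annotation_store> go:%d tokens:%d domains:%d pathways:%d expression:%d proteins\n",
    length(x$go), length(x$tokens), length(x$domains), length(x$pathways), length(x$expression)
  ))
  invisible(x)
}

#' Read a protein annotation table
#'
#' Tab-separated with header
#' `protein go_terms tokens domains pathways`; each set column is
#' pipe-separated, `NA` for an absent block.
#'
#' @param file path, connection, or literal text.
#' @param dag optional `go_dag` for term validation.
#' @param expression optional named list of expression vectors to attach.
#' @return an [annotation_store()].
#' @export
read_annotation_table <- function(file, dag = NULL, expression = list()) {
  lines <- read_text_lines(file)
  check_header(lines, c("protein", "go_terms", "tokens", "domains", "pathways"),
               "annotation table")
  body <- lines[-1L]
  body <- body[nzchar(body)]
  split_sets <- function(v) {
    lapply(v, function(s) {
      if (s == "NA" || !nzchar(s)) character() else {
        x <- strsplit(s, "|", fixed = TRUE)[[1L]]
        x[nzchar(x)]
      }
    })
  }
  if (!length(body)) return(annotation_store(dag = dag, expression = expression))
  parts <- stringr::str_split(body, "\t")
  if (any(lengths(parts) != 5L)) {
    abort(sprintf("malformed annotation row at line %d", which(lengths(parts) != 5L)[1L] + 1L))
  }
  m <- do.call(rbind, parts)
  prot <- m[, 1L]
  nm <- function(l) stats::setNames(l, prot)
  keep_nonempty <- function(l) l[lengths(l) > 0L]
  annotation_store(
    go = keep_nonempty(nm(split_sets(m[, 2L]))),
    tokens = keep_nonempty(nm(split_sets(m[, 3L]))),
    domains = keep_nonempty(nm(split_sets(m[, 4L]))),
    pathways = keep_nonempty(nm(split_sets(m[, 5L]))),
    expression = expression,
    dag = dag
  )
}

#' Write a protein annotation table
#' @param ann an `annotation_store`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(ann, path) {
  prots <- sort(unique(c(
    names(ann$go), names(ann$tokens), names(ann$domains), names(ann$pathways)
  )))
  fmt <- function(l, p) {
    v <- l[[p]]
    if (is.null(v) || !length(v)) "NA" else paste(v, collapse = "|")
  }
  lines <- c(
    "protein\tgo_terms\ttokens\tdomains\tpathways",
    vapply(prots, function(p) {
      paste(p, fmt(ann$go, p), fmt(ann$tokens, p), fmt(ann$domains, p),
            fmt(ann$pathways, p), sep = "\t")
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix
#'
#' Tab-separated, header `protein v1 v2 ...`; one row per protein.
#'
#' @param file path, connection, or literal text.
#' @return named list: protein id -> numeric vector.
#' @export
read_expression_table <- function(file) {
  lines <- read_text_lines(file)
  if (!length(lines) || !startsWith(lines[1L], "protein")) {
    abort("expression table must start with a 'protein\\tv1\\t...' header")
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  out <- list()
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L) abort(sprintf("malformed expression row at line %d", i + 1L))
    out[[f[1L]]] <- as.numeric(f[-1L])
  }
  out
}

#' Write an expression matrix
#' @param expression named list of numeric vectors (equal lengths).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expression, path) {
  n <- if (length(expression)) length(expression[[1L]]) else 0L
  lines <- c(
    paste(c("protein", paste0("v", seq_len(n))), collapse = "\t"),
    vapply(names(expression), function(p) {
      paste(c(p, format(expression[[p]], digits = 10, trim = TRUE)), collapse = "\t")
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

## ---- internal helpers -------------------------------------------------------

read_text_lines <- function(file) {
  if (inherits(file, "connection")) return(readLines(file, warn = FALSE))
  stopifnot(is.character(file), length(file) == 1L)
  ## literal text (embedded newlines or tabs) versus a file path
  if (grepl("[\n\t]", file)) {
    strsplit(file, "\n", fixed = TRUE)[[1L]]
  } else if (file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    abort(sprintf("file not found: %s", file))
  }
}

check_header <- function(lines, expected, what) {
  if (!length(lines)) abort(sprintf("empty %s", what))
  got <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(got, expected)) {
    abort(sprintf(
      "%s header must be '%s', got '%s'",
      what, paste(expected, collapse = "\\t"), lines[1L]
    ))
  }
  invisible(TRUE)
}
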