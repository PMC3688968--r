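# Shared fixtures (computed once per test run) and independent brute-force
# oracles used by the property and acceptance tests.

.fixtures <- new.env(parent = emptyenv())

fixture_cached <- function(name, fn) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fn()
  .fixtures[[name]]
}

signal_bundle <- function() {
  fixture_cached("signal", function() {
    w <- world_fixture("signal")
    tr <- world_transfers(w, "AllI")
    list(world = w, transfers = tr, ctx = world_context(w))
  })
}

signal_features <- function(set = "full") {
  fixture_cached(paste0("signal_ft_", set), function() {
    if (set == "full") {
      b <- signal_bundle()
      build_feature_table(b$transfers, b$ctx, "full")
    } else {
      subset_feature_set(signal_features("full"), set)
    }
  })
}

signal_cv <- function(set = "full") {
  fixture_cached(paste0("signal_cv_", set), function() {
    rff_cross_validate(signal_features(set), folds = 10L, seed = 1L, n_trees = 300L)
  })
}

noise_bundle <- function() {
  fixture_cached("noise", function() {
    w <- world_fixture("noise")
    tr <- world_transfers(w, "AllI")
    ft <- build_feature_table(tr, world_context(w, production = TRUE), "full")
    list(world = w, transfers = tr, features = ft)
  })
}

noise_cv <- function() {
  fixture_cached("noise_cv", function() {
    rff_cross_validate(noise_bundle()$features, folds = 10L, seed = 1L,
                       n_trees = 300L)
  })
}

# small labeled feature table with a planted linear signal, for forest tests
make_planted_features <- function(n = 200L, n_junk = 4L, seed = 42L,
                                  signal_sd = 0.1) {
  set.seed(seed)
  lab <- rep(c(TRUE, FALSE), length.out = n)
  cols <- list(signal = as.numeric(lab) + rnorm(n, sd = signal_sd))
  for (j in seq_len(n_junk)) cols[[paste0("junk", j)]] <- rnorm(n)
  tb <- tibble::as_tibble(cols)
  tb$.label <- ifelse(lab, "consistent", "inconsistent")
  schema <- tibble::tibble(feature = setdiff(names(tb), ".label"),
                           kind = "numeric")
  structure(tb, schema = schema, feature_set = "custom",
            class = c("feature_table", class(tb)))
}

as_feature_table <- function(tb, categorical = character()) {
  schema <- tibble::tibble(
    feature = setdiff(names(tb), grep("^\\.", names(tb), value = TRUE)),
    kind = "numeric"
  )
  schema$kind[schema$feature %in% categorical] <- "categorical"
  structure(tb, schema = schema, feature_set = "custom",
            class = c("feature_table", class(tb)))
}

## ---- GO oracles (independent of the package's DAG machinery) ---------------

oracle_ancestors <- function(parents, t) {
  out <- t
  frontier <- parents[[t]]
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- setdiff(unique(unlist(parents[frontier])), out)
  }
  unique(out)
}

oracle_ic <- function(parents, terms, go_ann, root) {
  counts <- vapply(terms, function(t) {
    desc <- terms[vapply(terms, function(x) t %in% oracle_ancestors(parents, x), TRUE)]
    sum(vapply(go_ann, function(s) any(s %in% desc), TRUE))
  }, 0)
  ic <- -log(counts / counts[[root]])
  ic[counts == 0] <- NA_real_
  ic
}

oracle_term_sim <- function(parents, ic, t1, t2) {
  common <- intersect(oracle_ancestors(parents, t1), oracle_ancestors(parents, t2))
  common <- common[!is.na(ic[common])]
  if (!length(common)) 0 else max(ic[common])
}

oracle_protein_sim <- function(parents, ic, go_ann, p1, p2) {
  t1 <- go_ann[[p1]]; t2 <- go_ann[[p2]]
  t1 <- t1[!is.na(ic[t1])]; t2 <- t2[!is.na(ic[t2])]
  if (is.null(t1) || is.null(t2) || !length(t1) || !length(t2)) return(NA_real_)
  max(outer(t1, t2, Vectorize(function(a, b) oracle_term_sim(parents, ic, a, b))))
}

# random single-category DAG with diamonds plus random annotations
random_go_fixture <- function(n_terms = 8L, n_prot = 6L) {
  terms <- paste0("t", seq_len(n_terms))
  parents <- list()
  parents[[terms[1L]]] <- character()
  for (i in 2:n_terms) {
    k <- sample(1:min(2L, i - 1L), 1L)
    parents[[terms[i]]] <- sample(terms[seq_len(i - 1L)], k)
  }
  go_ann <- list()
  for (p in paste0("p", seq_len(n_prot))) {
    k <- sample(0:3, 1L)
    if (k > 0) go_ann[[p]] <- sample(terms[-1L], k)
  }
  if (!length(go_ann)) go_ann[["p1"]] <- terms[2L]
  list(
    terms = terms, parents = parents,
    category = stats::setNames(rep("B", n_terms), terms),
    go_ann = go_ann,
    dag = go_dag(terms, parents, stats::setNames(rep("B", n_terms), terms)),
    ann = annotation_store(go = go_ann)
  )
}
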