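#' Train a Random-Forest-Filter on labeled feature vectors
#'
#' Fits a probability forest predicting the consistent/inconsistent outcome
#' of transfer instances. Preprocessing recorded in the model and replayed
#' at scoring time: numeric features are imputed with the training median,
#' categorical features with the training mode and one-hot encoded (levels
#' unseen in training map to a reserved `__other__` column), and every
#' feature with any missing training value gains a binary missing-indicator
#' column, so informative missingness stays visible to the trees.
#'
#' @param features a [build_feature_table()] result with a filled `.label`
#'   column (both classes present).
#' @param n_trees number of trees.
#' @param m_features number of features tried per split; default
#'   `floor(sqrt(d))` over the encoded design matrix.
#' @param seed integer seed; given the same data and seed, training and
#'   scoring are deterministic.
#' @return object of class `rff_model`.
#' @export
rff_train <- function(features, n_trees = 500L, m_features = NULL, seed = 1L) {
  schema <- attr(features, "schema")
  if (is.null(schema)) abort("features must carry a schema (use build_feature_table)")
  lab <- normalize_labels(features$.label)
  if (length(unique(lab)) < 2L) abort("training needs both classes present")
  if (min(sum(lab), sum(!lab)) < 2L) abort("training needs >= 2 instances of each class")
  prep <- fit_preprocessor(features, schema)
  x <- apply_preprocessor(prep, features)
  if (is.null(m_features)) m_features <- max(1L, floor(sqrt(ncol(x))))
  m_features <- min(m_features, ncol(x))
  forest <- ranger::ranger(
    x = x, y = factor(ifelse(lab, "consistent", "inconsistent"),
                      levels = c("inconsistent", "consistent")),
    num.trees = n_trees, mtry = m_features, probability = TRUE,
    seed = seed, num.threads = 1L, importance = "impurity"
  )
  structure(
    list(forest = forest, schema = schema,
         feature_set = attr(features, "feature_set"),
         preprocessor = prep,
         hyperparams = list(n_trees = n_trees, m_features = m_features),
         seed = seed),
    class = "rff_model"
  )
}

#' @export
print.rff_model <- function(x, ...) {
  cat(sprintf(
    "<rff_model> feature_set=%s  %d trees, mtry=%d, seed=%d, oob=%.4f\n",
    x$feature_set %||% "?", x$hyperparams$n_trees, x$hyperparams$m_features,
    x$seed, x$forest$prediction.error
  ))
  invisible(x)
}

#' Variable importance of a fitted filter
#' @param x an `rff_model`.
#' @param ... unused.
#' @return tibble with `term`, `importance` (impurity decrease), sorted.
#' @export
tidy.rff_model <- function(x, ...) {
  imp <- ranger::importance(x$forest)
  tibble(term = names(imp), importance = unname(imp)) %>%
    arrange(dplyr::desc(.data$importance))
}

#' One-row model summary
#' @param x an `rff_model`.
#' @param ... unused.
#' @return tibble with hyperparameters and out-of-bag error.
#' @export
glance.rff_model <- function(x, ...) {
  tibble(
    n_trees = x$hyperparams$n_trees, m_features = x$hyperparams$m_features,
    seed = x$seed, oob_error = x$forest$prediction.error
  )
}

#' Score transfer instances with a trained filter
#'
#' Returns the forest's probability for the `consistent` class, the
#' confidence score in \[0,1\] used for filtering. The feature table must
#' match the schema the model was trained on.
#'
#' @param model an [rff_train()] model.
#' @param features a feature table with the model's schema.
#' @return numeric vector of scores in \[0,1\].
#' @export
rff_score <- function(model, features) {
  schema <- attr(features, "schema")
  if (!is.null(schema) && !identical(schema$feature, model$schema$feature)) {
    abort("schema mismatch: features were built with a different feature set")
  }
  missing_cols <- setdiff(model$schema$feature, names(features))
  if (length(missing_cols)) {
    abort(sprintf("schema mismatch: missing feature column(s) %s",
                  paste(missing_cols, collapse = ", ")))
  }
  x <- apply_preprocessor(model$preprocessor, features)
  p <- stats::predict(model$forest, data = x, num.threads = 1L)$predictions
  unname(p[, "consistent"])
}

#' Stratified cross-validation of the Random-Forest-Filter
#'
#' Instances are assigned to folds at random within each class (stratified;
#' fold sizes differ by at most one per class), and each instance is scored
#' by the model trained on the remaining folds. Fold assignment and training
#' are deterministic given the seed.
#'
#' @param features labeled feature table.
#' @param folds number of folds (default 10).
#' @param seed integer seed.
#' @param n_trees,m_features forwarded to [rff_train()].
#' @return tibble of class `rff_cv` with columns `.fold`, `.score`, `.label`
#'   (plus the instance bookkeeping columns), in the input row order.
#' @export
rff_cross_validate <- function(features, folds = 10L, seed = 1L,
                               n_trees = 500L, m_features = NULL) {
  stopifnot(folds >= 2L)
  lab <- normalize_labels(features$.label)
  n_min <- min(sum(lab), sum(!lab))
  if (n_min < folds) {
    abort(sprintf(
      "smallest class has %d instances, fewer than %d folds; use fewer folds",
      n_min, folds
    ))
  }
  set.seed(seed)
  fold <- integer(length(lab))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(lab == cls)
    fold[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  score <- rep(NA_real_, length(lab))
  for (k in seq_len(folds)) {
    train_rows <- fold != k
    model <- rff_train(features[train_rows, , drop = FALSE],
                       n_trees = n_trees, m_features = m_features,
                       seed = seed + k)
    score[!train_rows] <- rff_score(model, features[!train_rows, , drop = FALSE])
  }
  meta <- intersect(c(".t_a", ".t_b", ".src_species"), names(features))
  out <- dplyr::bind_cols(
    as_tibble(features)[, meta, drop = FALSE],
    tibble(.fold = fold, .score = score, .label = features$.label)
  )
  structure(out, folds = folds, seed = seed,
            class = c("rff_cv", class(out)))
}

#' Out-of-fold curve and summary for a cross-validation
#' @param x an `rff_cv` result.
#' @param ... unused.
#' @return tibble with per-fold AUPRC/AUROC plus a pooled row.
#' @export
glance.rff_cv <- function(x, ...) {
  per_fold <- lapply(sort(unique(x$.fold)), function(k) {
    sel <- x$.fold == k
    cv <- transfer_curve(x$.score[sel], x$.label[sel])
    tibble(fold = k, auprc = cv$auprc, auroc = cv$auroc, n = sum(sel))
  })
  pooled <- transfer_curve(x$.score, x$.label)
  bind_rows(
    bind_rows(per_fold),
    tibble(fold = NA_integer_, auprc = pooled$auprc, auroc = pooled$auroc, n = nrow(x))
  )
}

#' Grid search over forest hyperparameters
#'
#' Evaluates each (n_trees, m_features) cell by stratified cross-validation
#' and selects the cell with the highest mean per-fold AUPRC; ties are
#' broken toward smaller `n_trees`, then smaller `m_features`.
#'
#' @param features labeled feature table.
#' @param n_trees_grid,m_features_grid candidate values.
#' @param folds CV folds per cell.
#' @param seed integer seed (same folds across cells).
#' @return list with `best` (n_trees, m_features), `results` tibble.
#' @export
rff_grid_search <- function(features, n_trees_grid = c(50L, 100L, 250L, 500L),
                            m_features_grid = NULL, folds = 5L, seed = 1L) {
  stopifnot(length(n_trees_grid) >= 1L)
  if (is.null(m_features_grid)) {
    d <- nrow(attr(features, "schema"))
    m_features_grid <- unique(pmax(1L, c(floor(sqrt(d)), floor(log2(d)) + 1L, floor(d / 3))))
  }
  grid <- tidyr::expand_grid(n_trees = sort(n_trees_grid),
                             m_features = sort(m_features_grid))
  res <- purrr::pmap(grid, function(n_trees, m_features) {
    cv <- rff_cross_validate(features, folds = folds, seed = seed,
                             n_trees = n_trees, m_features = m_features)
    g <- glance(cv)
    tibble(n_trees = n_trees, m_features = m_features,
           mean_auprc = mean(g$auprc[!is.na(g$fold)]),
           mean_auroc = mean(g$auroc[!is.na(g$fold)]))
  }) %>% bind_rows()
  best <- res %>%
    arrange(dplyr::desc(.data$mean_auprc), .data$n_trees, .data$m_features) %>%
    dplyr::slice(1L)
  list(best = list(n_trees = best$n_trees, m_features = best$m_features),
       results = res)
}

#' Choose a score threshold from cross-validated scores
#'
#' Either the smallest threshold whose cross-validated precision meets a
#' target, or the threshold retaining a requested number of instances.
#'
#' @param cv an [rff_cross_validate()] result (or any tibble with `.score`
#'   and `.label`).
#' @param precision_target desired precision in \[0,1\].
#' @param retained_count desired number of retained instances.
#' @return list with `threshold`, `precision`, `relative_recall`, `retained`.
#' @export
choose_threshold <- function(cv, precision_target = NULL, retained_count = NULL) {
  if (is.null(precision_target) == is.null(retained_count)) {
    abort("give exactly one of precision_target or retained_count")
  }
  scores <- cv$.score; lab <- normalize_labels(cv$.label)
  curve <- transfer_curve(scores, lab)$points
  if (!is.null(retained_count)) {
    retained_count <- min(retained_count, length(scores))
    thr <- sort(scores, decreasing = TRUE)[retained_count]
    if (retained_count == length(scores)) thr <- 0
  } else {
    ok <- curve$precision >= precision_target
    if (!any(ok)) {
      abort(sprintf(
        "precision target %.3f unreachable; maximum achievable is %.3f",
        precision_target, max(curve$precision)
      ))
    }
    thr <- min(curve$threshold[ok])
  }
  sel <- scores >= thr
  list(
    threshold = thr,
    precision = mean(lab[sel]),
    relative_recall = sum(lab[sel]) / sum(lab),
    retained = sum(sel)
  )
}

#' Score a production batch with per-setting filters
#'
#' In production transfer, three filters are employed: the PhyI model for
#' physical source interactions, the GenI model for genetic ones, and the
#' AllI model for the remaining (untyped/ambiguous) interactions. Each
#' instance is scored by the filter matching its source interaction type.
#'
#' @param models named list with elements `AllI`, `PhyI`, `GenI`, each an
#'   [rff_train()] model sharing one feature schema.
#' @param transfers the `transfer_table` being scored (supplies the source
#'   interaction types; rows aligned with `features`).
#' @param features the feature table for `transfers`.
#' @return numeric vector of scores in \[0,1\].
#' @export
rff_score_dispatch <- function(models, transfers, features) {
  stopifnot(all(c("AllI", "PhyI", "GenI") %in% names(models)),
            nrow(transfers) == nrow(features))
  setting <- dplyr::case_match(transfers$itype,
    "physical" ~ "PhyI", "genetic" ~ "GenI", .default = "AllI"
  )
  scores <- rep(NA_real_, nrow(features))
  for (s in unique(setting)) {
    rows <- setting == s
    scores[rows] <- rff_score(models[[s]], features[rows, , drop = FALSE])
  }
  scores
}

#' Save / load a Random-Forest-Filter model
#'
#' Serializes the model (forest, schema, imputation statistics,
#' hyperparameters, seed) to a single file.
#'
#' @param model an `rff_model`.
#' @param path file path.
#' @return `path` invisibly; `rff_load` returns the model.
#' @export
rff_save <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname rff_save
#' @export
rff_load <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "rff_model")) abort("file does not contain an rff_model")
  model
}

## ---- preprocessing ----------------------------------------------------------

fit_preprocessor <- function(features, schema) {
  stats <- list()
  for (i in seq_len(nrow(schema))) {
    nm <- schema$feature[i]
    v <- features[[nm]]
    if (schema$kind[i] == "numeric") {
      med <- stats::median(v, na.rm = TRUE)
      if (is.na(med)) med <- 0
      stats[[nm]] <- list(kind = "numeric", median = med, any_missing = anyNA(v))
    } else {
      ch <- as.character(v)
      tab <- table(ch[!is.na(ch)])
      mode_lev <- if (length(tab)) names(tab)[which.max(tab)] else "__other__"
      levels <- sort(unique(ch[!is.na(ch)]))
      stats[[nm]] <- list(kind = "categorical", mode = mode_lev,
                          levels = levels, any_missing = anyNA(ch))
    }
  }
  stats
}

apply_preprocessor <- function(prep, features) {
  cols <- list()
  for (nm in names(prep)) {
    st <- prep[[nm]]
    v <- features[[nm]]
    if (st$kind == "numeric") {
      miss <- is.na(v)
      v[miss] <- st$median
      cols[[nm]] <- as.numeric(v)
      if (st$any_missing) cols[[paste0(nm, "__missing")]] <- as.numeric(miss)
    } else {
      ch <- as.character(v)
      miss <- is.na(ch)
      ch[miss] <- st$mode
      ch[!ch %in% st$levels] <- "__other__"
      for (lev in c(st$levels, "__other__")) {
        cols[[paste0(nm, "=", lev)]] <- as.numeric(ch == lev)
      }
      if (st$any_missing) cols[[paste0(nm, "__missing")]] <- as.numeric(miss)
    }
  }
  as.data.frame(cols, check.names = FALSE, optional = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
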