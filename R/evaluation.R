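#' Precision / relative-recall / recall curve for scored transfers
#'
#' At each distinct score value `s` (descending), the instances with score
#' `>= s` are retained and the curve records precision `TP/(TP+FP)`,
#' relative recall `TP / relative_denominator` (the fraction of the
#' correctly transferable interactions still retained), regular recall
#' `TP / gold_size` when a gold-network size is supplied, and the false
#' positive rate. The area under the precision-(relative) recall curve uses
#' Davis-Goadrich interpolation; the AUROC is the rank statistic with ties
#' averaged.
#'
#' @param scores numeric scores in \[0,1\].
#' @param labels `"consistent"` / `"inconsistent"` labels (or a logical
#'   vector, `TRUE` = consistent).
#' @param relative_denominator number of consistent instances under direct
#'   (unfiltered) transfer; must be positive.
#' @param gold_size optional size of the gold network, for regular recall.
#' @return object of class `transfer_curve`: list with `points` (tibble),
#'   `auprc`, `auroc`.
#' @export
transfer_curve <- function(scores, labels, relative_denominator = NULL,
                           gold_size = NULL) {
  lab <- normalize_labels(labels)
  stopifnot(length(scores) == length(lab), !anyNA(scores))
  if (is.null(relative_denominator)) relative_denominator <- sum(lab)
  if (relative_denominator <= 0) abort("relative_denominator must be positive")
  thresholds <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(lab); n_neg <- sum(!lab)
  ## cumulative TP/FP over instances sorted by decreasing score
  ord <- order(scores, decreasing = TRUE)
  cs <- scores[ord]; cl <- lab[ord]
  tp_cum <- cumsum(cl); fp_cum <- cumsum(!cl)
  idx <- findInterval(-thresholds, -cs) # last instance with score >= threshold
  tp <- tp_cum[idx]; fp <- fp_cum[idx]
  points <- tibble(
    threshold = thresholds,
    tp = tp, fp = fp,
    precision = tp / (tp + fp),
    relative_recall = tp / relative_denominator,
    recall = if (is.null(gold_size)) NA_real_ else tp / gold_size,
    fpr = if (n_neg) fp / n_neg else NA_real_
  )
  structure(
    list(
      points = points,
      auprc = auprc_davis_goadrich(tp, fp, relative_denominator),
      auroc = if (n_pos && n_neg) auroc(scores, lab) else NA_real_
    ),
    class = "transfer_curve"
  )
}

#' @export
print.transfer_curve <- function(x, ...) {
  cat(sprintf(
    "<transfer_curve> %d thresholds  AUPRC=%.4f  AUROC=%.4f\n",
    nrow(x$points), x$auprc, x$auroc
  ))
  invisible(x)
}

#' Curve points as a tibble
#' @param x a `transfer_curve`.
#' @param ... unused.
#' @return the `points` tibble.
#' @export
tidy.transfer_curve <- function(x, ...) x$points

#' One-row curve summary
#' @param x a `transfer_curve`.
#' @param ... unused.
#' @return tibble with `auprc`, `auroc`, `n_thresholds`.
#' @export
glance.transfer_curve <- function(x, ...) {
  tibble(auprc = x$auprc, auroc = x$auroc, n_thresholds = nrow(x$points))
}

#' Precision-(relative) recall plot of a curve
#' @param object a `transfer_curve`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.transfer_curve <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$relative_recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "relative recall", y = "precision",
      subtitle = sprintf("AUPRC = %.3f, AUROC = %.3f", object$auprc, object$auroc)
    ) +
    ggplot2::theme_minimal()
}

#' Area under the PR curve by Davis-Goadrich interpolation
#'
#' Interpolates between achievable (TP, FP) points in unit TP steps, with FP
#' varying linearly in TP (the correct non-linear interpolation in PR
#' space), and integrates precision over the recall axis
#' (`recall = TP / denominator`). Between recall 0 and the first achievable
#' point, precision is held at the first point's value.
#'
#' @param tp,fp integer vectors of retained true/false positives per
#'   threshold (any order).
#' @param denominator recall denominator (> 0).
#' @return area in \[0,1\].
#' @export
auprc_davis_goadrich <- function(tp, fp, denominator) {
  stopifnot(denominator > 0, length(tp) == length(fp))
  ord <- order(tp, fp)
  tp <- tp[ord]; fp <- fp[ord]
  keep <- tp > 0
  tp <- tp[keep]; fp <- fp[keep]
  if (!length(tp)) return(0)
  first <- !duplicated(tp) # per TP level, the smallest achievable FP
  tp <- tp[first]; fp <- fp[first]
  area <- (tp[1L] / denominator) * (tp[1L] / (tp[1L] + fp[1L]))
  if (length(tp) > 1L) {
    for (i in seq_len(length(tp) - 1L)) {
      dtp <- tp[i + 1L] - tp[i]
      slope <- (fp[i + 1L] - fp[i]) / dtp
      x <- seq(tp[i], tp[i + 1L]) # unit TP steps
      prec <- x / (x + fp[i] + slope * (x - tp[i]))
      area <- area + sum((prec[-1L] + prec[-length(prec)]) / 2) / denominator
    }
  }
  area
}

#' Area under the ROC curve (rank statistic)
#'
#' The normalized Wilcoxon rank-sum statistic: the probability that a random
#' consistent instance outscores a random inconsistent one, with ties
#' counted 1/2.
#'
#' @param scores numeric scores.
#' @param labels consistency labels (see [transfer_curve()]).
#' @return AUROC in \[0,1\]; errors when a class is absent.
#' @export
auroc <- function(scores, labels) {
  lab <- normalize_labels(labels)
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (!n_pos || !n_neg) abort("AUROC needs at least one instance of each class")
  r <- rank(scores) # ties averaged
  (sum(r[lab]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Information Gain of a feature for the consistency labeling
#'
#' Entropy reduction (base 2) of the consistent/inconsistent labeling when
#' partitioning by the feature's values: `H(D) - sum_v |D_v|/|D| H(D_v)`.
#' Continuous features are discretized into `bins` equal-frequency bins
#' computed on the non-missing values; missing values form their own
#' partition cell, so informative missingness is credited.
#'
#' @param x feature values (numeric, character, logical or factor).
#' @param labels consistency labels.
#' @param bins number of equal-frequency bins for numeric features.
#' @return non-negative IG in bits.
#' @export
information_gain <- function(x, labels, bins = 10L) {
  lab <- normalize_labels(labels)
  stopifnot(length(x) == length(lab), length(lab) >= 1L)
  v <- discretize_feature(x, bins)
  h <- entropy2(lab)
  cond <- 0
  for (lev in unique(v)) {
    sel <- v == lev
    cond <- cond + mean(sel) * entropy2(lab[sel])
  }
  max(0, h - cond)
}

discretize_feature <- function(x, bins) {
  if (is.numeric(x)) {
    out <- rep("__missing__", length(x))
    ok <- !is.na(x)
    if (any(ok)) {
      qs <- unique(stats::quantile(x[ok], probs = seq(0, 1, length.out = bins + 1L),
                                   names = FALSE, type = 7))
      if (length(qs) < 2L) {
        out[ok] <- "bin1"
      } else {
        out[ok] <- paste0("bin", cut(x[ok], breaks = qs, include.lowest = TRUE,
                                     labels = FALSE))
      }
    }
    out
  } else {
    x <- as.character(x)
    x[is.na(x)] <- "__missing__"
    x
  }
}

entropy2 <- function(lab) {
  if (!length(lab)) return(0)
  p <- mean(lab)
  part <- function(q) if (q == 0) 0 else -q * log2(q)
  part(p) + part(1 - p)
}

#' Rank features by Information Gain
#'
#' IG per feature column of a feature table, sorted descending (ties broken
#' lexicographically by feature name). With `average_ortholog_pairs = TRUE`
#' the per-ortholog-pair features (suffixes `_O1`/`_O2`) are reported once
#' with the average IG of the two partners.
#'
#' @param features a [build_feature_table()] result (or any tibble with a
#'   `.label` column).
#' @param feature_cols columns to rank; defaults to the table's schema.
#' @param bins equal-frequency bin count for numeric features.
#' @param average_ortholog_pairs collapse O1/O2 feature pairs to their mean IG.
#' @return tibble of class `feature_ranking` with columns `feature`, `ig`,
#'   `rank`.
#' @export
rank_features <- function(features, feature_cols = NULL, bins = 10L,
                          average_ortholog_pairs = FALSE) {
  if (is.null(feature_cols)) {
    schema <- attr(features, "schema")
    feature_cols <- if (!is.null(schema)) schema$feature else {
      setdiff(names(features), grep("^\\.", names(features), value = TRUE))
    }
  }
  lab <- features$.label
  ig <- vapply(feature_cols, function(cl) information_gain(features[[cl]], lab, bins), 0)
  out <- tibble(feature = feature_cols, ig = unname(ig))
  if (average_ortholog_pairs) {
    out <- out %>%
      mutate(feature = sub("_O[12]$", "_O", .data$feature)) %>%
      group_by(.data$feature) %>%
      summarise(ig = mean(.data$ig), .groups = "drop")
  }
  out <- out %>%
    arrange(dplyr::desc(.data$ig), .data$feature) %>%
    mutate(rank = dplyr::row_number())
  class(out) <- unique(c("feature_ranking", class(out)))
  out
}

#' Information-Gain bar plot of a feature ranking
#' @param object a [rank_features()] result.
#' @param top show at most this many features.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.feature_ranking <- function(object, top = 25L, ...) {
  d <- utils::head(as_tibble(object), top)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ig,
                                  y = stats::reorder(.data$feature, .data$ig))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Information Gain (bits)", y = NULL) +
    ggplot2::theme_minimal()
}

normalize_labels <- function(labels) {
  if (is.logical(labels)) {
    if (anyNA(labels)) abort("labels must not be NA")
    return(labels)
  }
  if (!all(labels %in% c("consistent", "inconsistent"))) {
    abort("labels must be 'consistent'/'inconsistent' (or logical)")
  }
  labels == "consistent"
}
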