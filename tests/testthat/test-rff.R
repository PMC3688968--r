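test_that("training is deterministic given a seed and separates planted signal", {
  ft <- make_planted_features(n = 200L)
  m1 <- rff_train(ft, n_trees = 100L, seed = 5L)
  m2 <- rff_train(ft, n_trees = 100L, seed = 5L)
  expect_identical(rff_score(m1, ft), rff_score(m2, ft))
  ## near-separable signal: out-of-bag accuracy above 0.95
  expect_lt(m1$forest$prediction.error, 0.05)
  ## votes for clear positives/negatives approach the extremes
  s <- rff_score(m1, ft)
  expect_gte(min(s[ft$.label == "consistent"]), 0.5)
  expect_gte(mean(s[ft$.label == "consistent"] >= 0.9), 0.8)
  expect_true(all(s >= 0 & s <= 1))
})

test_that("training rejects degenerate inputs and scoring rejects schema mismatch", {
  ft <- make_planted_features(n = 40L)
  ft_one <- ft
  ft_one$.label <- "consistent"
  expect_error(rff_train(ft_one), "class")
  model <- rff_train(ft, n_trees = 50L, seed = 1L)
  other <- as_feature_table(tibble::tibble(bogus = rnorm(5), .label = "consistent"))
  expect_error(rff_score(model, other), "schema mismatch")
})

test_that("missing values are imputed with indicator columns and survive scoring", {
  set.seed(71)
  n <- 120L
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  tb <- tibble::tibble(
    ## missingness itself carries the signal here
    informative = ifelse(lab, NA_real_, rnorm(n)),
    cat = sample(c("u", "v"), n, replace = TRUE),
    .label = ifelse(lab, "consistent", "inconsistent")
  )
  ft <- as_feature_table(tb, categorical = "cat")
  model <- rff_train(ft, n_trees = 100L, seed = 2L)
  s <- rff_score(model, ft)
  expect_gt(auroc(s, ft$.label), 0.95)
  ## unseen categorical level at scoring time maps to the reserved bucket
  ft2 <- ft
  ft2$cat[1L] <- "never-seen"
  expect_no_error(rff_score(model, ft2))
})

test_that("cross-validation folds are stratified, exhaustive and reproducible", {
  ft <- make_planted_features(n = 120L, seed = 9L)
  cv <- rff_cross_validate(ft, folds = 5L, seed = 3L, n_trees = 60L)
  expect_equal(nrow(cv), nrow(ft))
  expect_false(anyNA(cv$.score))
  for (cls in c("consistent", "inconsistent")) {
    sizes <- table(cv$.fold[cv$.label == cls])
    expect_lte(diff(range(sizes)), 1)
  }
  cv2 <- rff_cross_validate(ft, folds = 5L, seed = 3L, n_trees = 60L)
  expect_identical(cv$.score, cv2$.score)
  ## scores are invariant to instance order within the batch
  perm <- sample(nrow(ft))
  model <- rff_train(ft, n_trees = 60L, seed = 4L)
  expect_equal(rff_score(model, ft[perm, ]), rff_score(model, ft)[perm])
  expect_error(rff_cross_validate(make_planted_features(n = 12L), folds = 10L),
               "folds")
})

test_that("grid search picks the best cell deterministically", {
  ft <- make_planted_features(n = 150L, n_junk = 30L, seed = 12L,
                              signal_sd = 0.6)
  ## with 30 junk features, mtry = 1 rarely sees the informative one
  gs <- rff_grid_search(ft, n_trees_grid = 100L, m_features_grid = c(1L, 12L),
                        folds = 3L, seed = 5L)
  expect_equal(gs$best$m_features, 12L)
  gs2 <- rff_grid_search(ft, n_trees_grid = 100L, m_features_grid = c(1L, 12L),
                         folds = 3L, seed = 5L)
  expect_identical(gs$results, gs2$results)
  ## single-cell grid returns that cell
  one <- rff_grid_search(ft, n_trees_grid = 50L, m_features_grid = 3L,
                         folds = 3L, seed = 5L)
  expect_equal(one$best, list(n_trees = 50L, m_features = 3L))
})

test_that("threshold selection honors precision and retained-count targets", {
  scores <- c(0.95, 0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2)
  labels <- c("consistent", "consistent", "inconsistent", "consistent",
              "inconsistent", "inconsistent", "consistent", "inconsistent")
  cv <- tibble::tibble(.score = scores, .label = labels)
  ## a perfect prefix: target precision 1.0 reaches the top two scores
  got <- choose_threshold(cv, precision_target = 1)
  expect_equal(got$threshold, 0.9)
  expect_equal(got$precision, 1)
  ## keep-everything retained count gives threshold 0
  all_in <- choose_threshold(cv, retained_count = length(scores))
  expect_equal(all_in$threshold, 0)
  expect_equal(all_in$relative_recall, 1)
  expect_error(choose_threshold(cv, precision_target = 0.99, retained_count = 1))
  expect_error(choose_threshold(cv), "exactly one")
  ## unreachable target reports the maximum achievable
  cv2 <- tibble::tibble(.score = c(0.9, 0.8),
                        .label = c("inconsistent", "consistent"))
  expect_error(choose_threshold(cv2, precision_target = 0.99), "unreachable|achievable")
  ## monotonicity: higher targets never lower the threshold
  set.seed(72)
  for (rep in 1:20) {
    n <- 40L
    rcv <- tibble::tibble(
      .score = runif(n),
      .label = sample(c("consistent", "inconsistent"), n, replace = TRUE)
    )
    pmax_achievable <- max(transfer_curve(rcv$.score, rcv$.label)$points$precision)
    targets <- sort(runif(3, 0, pmax_achievable))
    thr <- vapply(targets, function(t) {
      choose_threshold(rcv, precision_target = t)$threshold
    }, 0)
    expect_true(all(diff(thr) >= 0))
  }
})

test_that("models round-trip through serialization", {
  ft <- make_planted_features(n = 60L)
  model <- rff_train(ft, n_trees = 50L, seed = 8L)
  path <- withr::local_tempfile(fileext = ".rds")
  rff_save(model, path)
  expect_identical(rff_score(rff_load(path), ft), rff_score(model, ft))
  expect_equal(glance(model)$n_trees, 50L)
  expect_true("importance" %in% names(tidy(model)))
})

test_that("production scoring dispatches each instance to its setting's filter", {
  w <- world_fixture("tiny")
  tr <- world_transfers(w, NULL)
  ft <- build_feature_table(tr, world_context(w, production = TRUE), "reduced")
  ## three distinguishable filters trained on shared-schema data
  labeled <- ft
  labeled$.label <- rep(c("consistent", "inconsistent"), length.out = nrow(ft))
  models <- list(
    AllI = rff_train(labeled, n_trees = 30L, seed = 1L),
    PhyI = rff_train(labeled, n_trees = 30L, seed = 2L),
    GenI = rff_train(labeled, n_trees = 30L, seed = 3L)
  )
  s <- rff_score_dispatch(models, tr, labeled)
  expect_length(s, nrow(tr))
  expect_true(all(s >= 0 & s <= 1))
  ## physical instances carry the PhyI model's scores, genetic the GenI's
  phys <- tr$itype == "physical"
  expect_equal(s[phys], rff_score(models$PhyI, labeled[phys, ]))
  gen <- tr$itype == "genetic"
  expect_equal(s[gen], rff_score(models$GenI, labeled[gen, ]))
})
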