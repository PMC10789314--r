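test_that("stratified folds balance classes and are deterministic", {
  labels <- rep(c("a", "b"), each = 5)
  f <- make_cv_folds(10, labels, n_folds = 5, seed = 1)
  for (k in 1:5) expect_equal(sort(labels[f == k]), c("a", "b"))
  expect_identical(f, make_cv_folds(10, labels, n_folds = 5, seed = 1))
  expect_false(identical(f, make_cv_folds(10, labels, n_folds = 5, seed = 2)))
  expect_error(make_cv_folds(3, n_folds = 5), "fewer rows")
  expect_warning(make_cv_folds(12, c(rep("a", 10), "b", "b"), n_folds = 5),
                 "unstratified")
  # folds never disturb the global RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(make_cv_folds(10, labels, seed = 3))
  expect_identical(rnorm(1), before)
})

small_screen <- function(seed, n = 150, p = 24) {
  sc <- generate_screen_dataset(screen_sim_config(
    n_enzymes = n, n_columns = p, stereo_switch_column = 5,
    reactivity_switch_column = 15, seed = seed))
  build_feature_matrix(sc$alignment, labels = sc$labels)
}

test_that("ensemble training beats the majority baseline on planted screens", {
  fm <- small_screen(31)
  b <- suppressWarnings(
    train_ensemble(fm, "stereochemistry", n_folds = 3, nrounds = 40))
  baseline <- max(table(fm$labels$stereochemistry)) /
    nrow(fm$aa)
  for (alg in b$algorithms) {
    acc <- mean(bundle_heldout_predictions(b, alg) ==
                  as.character(fm$labels$stereochemistry))
    expect_gt(acc, baseline)
  }
  # every row predicted exactly once per algorithm
  expect_length(bundle_heldout_predictions(b, "gbt"), nrow(fm$aa))
})

test_that("a constant feature matrix collapses to the majority class", {
  fm <- small_screen(32)
  fm$aa[] <- "A"
  b <- suppressWarnings(
    train_ensemble(fm, "reactivity", n_folds = 3, nrounds = 10))
  pred <- bundle_heldout_predictions(b, "gbt")
  expect_length(unique(pred), 1L)
  imp <- suppressWarnings(shap_consensus_importance(b))
  expect_true(all(imp$importance < 1e-8))
})

test_that("a single-algorithm run carries exactly n_folds fitted models", {
  fm <- small_screen(33)
  b <- train_ensemble(fm, "reactivity", algorithms = "gbt", n_folds = 4,
                      nrounds = 20)
  expect_equal(b$algorithms, "gbt")
  expect_length(b$fits$gbt$models, 4L)
  expect_length(b$fits$gbt$shap, 4L)
  expect_error(bundle_heldout_predictions(b, "rf"), "no fitted backend")
  expect_error(suppressWarnings(
    train_ensemble(fm, "reactivity", algorithms = "nope")),
    "all tree backends failed")
})

# Hand-built two-fold bundle for the normalization arithmetic.
fake_bundle <- function(shap_by_fold, aa_col, fold, classes = c(0, 1)) {
  structure(list(
    target = "reactivity", algorithms = "gbt", classes = classes,
    n_folds = length(shap_by_fold), seed = 1, fold = fold,
    feature_names = dimnames(shap_by_fold[[1]])[[3]][
      -dim(shap_by_fold[[1]])[3]],
    residues = NA_integer_, aa = aa_col, labels = classes[1],
    fits = list(gbt = list(shap = shap_by_fold))), class = "model_bundle")
}

test_that("consensus importance min-max normalizes per fold then averages", {
  # one fold with raw mean-|SHAP| importances (2, 1, 0)
  arr1 <- array(0, c(1, 1, 4),
                dimnames = list(NULL, NULL, c("res1", "res2", "res3", "BIAS")))
  arr1[1, 1, 1:3] <- c(2, -1, 0)
  b1 <- fake_bundle(list(arr1), aa_col = matrix("A", 1, 3), fold = c(1L))
  imp <- shap_consensus_importance(b1)
  expect_equal(imp$importance[match(c("res1", "res2", "res3"), imp$feature)],
               c(1, 0.5, 0))
  # two folds normalized (1, 0) and (0, 1) average to (0.5, 0.5)
  a1 <- array(0, c(1, 1, 3), dimnames = list(NULL, NULL, c("r1", "r2", "BIAS")))
  a2 <- a1
  a1[1, 1, 1] <- 3; a2[1, 1, 2] <- 5
  b2 <- fake_bundle(list(a1, a2), aa_col = matrix("A", 2, 2),
                    fold = c(1L, 2L))
  imp2 <- shap_consensus_importance(b2)
  expect_equal(unname(imp2$importance), c(0.5, 0.5))
})

test_that("dependence values are scaled by the residue's fold maximum", {
  arr <- array(0, c(2, 1, 2), dimnames = list(NULL, NULL, c("res9", "BIAS")))
  arr[, 1, 1] <- c(2, -1)
  b <- fake_bundle(list(arr), aa_col = matrix(c("F", "Y"), 2, 1,
                                              dimnames = list(NULL, "res9")),
                   fold = c(1L, 1L))
  dep <- shap_dependence(b, 9)
  expect_equal(dep$shap, c(1.0, -0.5))
  expect_equal(dep$amino_acid, c("F", "Y"))
  zero <- b
  zero$fits$gbt$shap[[1]][, 1, 1] <- 0
  expect_equal(shap_dependence(zero, 9)$shap, c(0, 0))
  expect_error(shap_dependence(b, 123), "not among retained")
})

test_that("planted switch alleles split the dependence profile by sign", {
  fm <- small_screen(35, n = 200)
  b <- suppressWarnings(
    train_ensemble(fm, "stereochemistry", algorithms = c("gbt", "rf"),
                   n_folds = 3, nrounds = 40))
  dep <- shap_dependence(b, 5, class_of_interest = 1)  # the R class
  means <- tapply(dep$shap, dep$amino_acid, mean)
  # F codes S, Y codes R: opposite pull on the R class
  expect_lt(means[["F"]], 0)
  expect_gt(means[["Y"]], 0)
})

test_that("consensus importance ignores algorithm and fold ordering", {
  fm <- small_screen(36)
  b1 <- suppressWarnings(train_ensemble(fm, "reactivity",
                                        algorithms = c("gbt", "rf"),
                                        n_folds = 3, nrounds = 30))
  b2 <- suppressWarnings(train_ensemble(fm, "reactivity",
                                        algorithms = c("rf", "gbt"),
                                        n_folds = 3, nrounds = 30))
  i1 <- shap_consensus_importance(b1)
  i2 <- shap_consensus_importance(b2)
  expect_equal(i1[order(i1$feature), c("feature", "importance")],
               i2[order(i2$feature), c("feature", "importance")],
               ignore_attr = TRUE)
})

test_that("metrics match hand-computed confusion matrices", {
  perfect <- evaluate_predictions(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$macro_f1, 1)
  # binary TP=2 TN=3 FP=1 FN=1 -> MCC = 5/12
  obs <- c(rep("pos", 3), rep("neg", 4))
  pred <- c("pos", "pos", "neg", "pos", "neg", "neg", "neg")
  m <- evaluate_predictions(pred, obs)
  expect_equal(m$mcc, 5 / 12, tolerance = 1e-12)
  expect_equal(m$accuracy, 5 / 7)
  expect_equal(sum(m$confusion), 7)
  expect_equal(unname(rowSums(m$confusion)),
               unname(as.vector(table(factor(obs, levels = c("neg", "pos"))))))
})

test_that("MCC and macro F1 agree with independent implementations", {
  set.seed(77)
  for (i in 1:40) {
    k <- sample(2:5, 1)
    classes <- letters[1:k]
    n <- sample(20:200, 1)
    obs <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    got <- suppressWarnings(evaluate_predictions(pred, obs, classes))
    want_mcc <- oracle_mcc(obs, pred, classes)
    if (is.na(want_mcc)) {
      expect_true(is.na(got$mcc))
    } else {
      expect_equal(got$mcc, want_mcc, tolerance = 1e-12)
    }
    expect_equal(got$macro_f1, oracle_macro_f1(obs, pred, classes),
                 tolerance = 1e-12)
  }
})

test_that("random balanced predictions give near-zero MCC and a warning on one class", {
  set.seed(5)
  obs <- sample(c("a", "b", "c"), 10000, replace = TRUE)
  pred <- sample(c("a", "b", "c"), 10000, replace = TRUE)
  expect_lt(abs(evaluate_predictions(pred, obs)$mcc), 0.05)
  expect_warning(one <- evaluate_predictions(c("a", "a"), c("a", "a")),
                 "MCC undefined")
  expect_true(is.na(one$mcc))
  expect_equal(one$accuracy, 1)
})
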