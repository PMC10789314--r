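#' Deterministic (optionally stratified) cross-validation folds
#'
#' @param n_rows number of rows to partition.
#' @param labels class labels used for stratification (optional).
#' @param n_folds number of folds (>= 2).
#' @param stratified stratify on `labels`; falls back to an unstratified
#'   partition with a warning when some class has fewer members than folds.
#' @param seed RNG seed; the global RNG state is left untouched.
#' @return integer vector of fold ids in `1:n_folds`, one per row.
#' @export
make_cv_folds <- function(n_rows, labels = NULL, n_folds = 5,
                          stratified = TRUE, seed = 17) {
  if (n_folds < 2L) stop("n_folds must be at least 2", call. = FALSE)
  if (n_rows < n_folds) {
    stop("fewer rows (", n_rows, ") than folds (", n_folds, ")", call. = FALSE)
  }
  if (stratified && is.null(labels)) stratified <- FALSE
  if (stratified) {
    counts <- table(labels)
    if (any(counts < n_folds)) {
      warning("class(es) smaller than n_folds; falling back to unstratified ",
              "folds", call. = FALSE)
      stratified <- FALSE
    }
  }
  withr::with_seed(seed, {
    fold <- integer(n_rows)
    if (stratified) {
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        fold[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    } else {
      fold <- sample(rep_len(seq_len(n_folds), n_rows))
    }
    fold
  })
}

# xgboost parameter sets for the three tree backends: depth-wise boosting,
# loss-guided (histogram) boosting, and single-round bagged forest.
backend_params <- function(algorithm, objective, num_class, seed) {
  base <- list(objective = objective, nthread = 1, seed = seed)
  if (!is.null(num_class)) base$num_class <- num_class
  extra <- switch(algorithm,
    gbt = list(eta = 0.3, max_depth = 5, subsample = 0.9,
               colsample_bytree = 0.9, min_child_weight = 1),
    gbt_lg = list(eta = 0.15, tree_method = "hist", grow_policy = "lossguide",
                  max_leaves = 31, max_depth = 0, subsample = 0.9,
                  colsample_bytree = 0.9),
    rf = list(eta = 1, num_parallel_tree = 200, subsample = 0.632,
              colsample_bynode = 0.7, max_depth = 8),
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  )
  c(base, extra)
}

backend_nrounds <- function(algorithm, nrounds) {
  if (algorithm == "rf") 1L else nrounds
}

#' Train the cross-validated tree-ensemble sequence-function models
#'
#' For every requested algorithm and fold, fits a tree model on the in-fold
#' rows, predicts the held-out rows, and computes exact tree-path SHAP values
#' for the held-out rows. The three built-in backends (all through xgboost)
#' are depth-wise gradient boosting (`"gbt"`), loss-guided histogram boosting
#' (`"gbt_lg"`), and a single-round bagged random forest (`"rf"`). A backend
#' that fails to fit is skipped with a warning; at least one must succeed.
#'
#' @param features a [build_feature_matrix()] result carrying the target
#'   label column.
#' @param target `"stereochemistry"` or `"reactivity"`.
#' @param algorithms subset of `c("gbt", "gbt_lg", "rf")`.
#' @param n_folds,seed cross-validation policy (see [make_cv_folds()]).
#' @param nrounds boosting rounds for the boosted backends.
#' @return object of class `model_bundle` holding per-(algorithm, fold)
#'   fitted models, held-out class predictions and probabilities, and SHAP
#'   arrays (`rows x classes x features+bias`).
#' @export
train_ensemble <- function(features, target = c("stereochemistry",
                                                "reactivity"),
                           algorithms = c("gbt", "gbt_lg", "rf"),
                           n_folds = 5, seed = 17, nrounds = 60) {
  target <- match.arg(target)
  if (is.null(features$labels) || is.null(features$labels[[target]])) {
    stop("feature matrix carries no ", target, " labels", call. = FALSE)
  }
  y_raw <- features$labels[[target]]
  classes <- sort(unique(y_raw))
  if (length(classes) < 2L) {
    stop("target has a single class; nothing to learn", call. = FALSE)
  }
  y <- match(y_raw, classes) - 1L
  k <- length(classes)
  multi <- k > 2L
  objective <- if (multi) "multi:softprob" else "binary:logistic"
  x <- encode_features(features)
  fold <- make_cv_folds(nrow(x), labels = y_raw, n_folds = n_folds,
                        seed = seed)
  p <- ncol(x)
  fitted <- list()
  for (alg in algorithms) {
    res <- tryCatch({
      models <- vector("list", n_folds)
      shap <- vector("list", n_folds)
      pred <- integer(nrow(x))
      prob <- matrix(NA_real_, nrow(x), k)
      for (f in seq_len(n_folds)) {
        tr <- fold != f; te <- !tr
        # seed depends on the algorithm identity, not its position, so the
        # bundle is invariant to algorithm ordering
        alg_off <- match(alg, c("gbt", "gbt_lg", "rf"))
        if (is.na(alg_off)) alg_off <- sum(utf8ToInt(alg)) %% 97L
        par <- backend_params(alg, objective, if (multi) k else NULL,
                              seed = seed + 1000L * alg_off + f)
        dtr <- xgboost::xgb.DMatrix(x[tr, , drop = FALSE], label = y[tr])
        bst <- xgboost::xgb.train(params = par, data = dtr,
                                  nrounds = backend_nrounds(alg, nrounds),
                                  verbose = 0)
        dte <- xgboost::xgb.DMatrix(x[te, , drop = FALSE])
        pr <- predict(bst, dte)
        if (multi) {
          pr <- matrix(pr, ncol = k, byrow = FALSE)
          if (is.null(dim(pr)) || ncol(pr) != k) {
            pr <- matrix(predict(bst, dte), ncol = k)
          }
        } else {
          pr <- cbind(1 - pr, pr)
        }
        prob[te, ] <- pr
        pred[te] <- max.col(pr) - 1L
        ct <- predict(bst, dte, predcontrib = TRUE)
        if (length(dim(ct)) == 2L) {
          ct <- array(ct, dim = c(nrow(ct), 1L, ncol(ct)),
                      dimnames = list(NULL, NULL, colnames(ct)))
        }
        models[[f]] <- bst
        shap[[f]] <- ct
      }
      list(models = models, shap = shap, pred = pred, prob = prob)
    }, error = function(e) {
      warning("backend '", alg, "' failed and was skipped: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(res)) fitted[[alg]] <- res
  }
  if (length(fitted) == 0L) {
    stop("all tree backends failed; no model trained", call. = FALSE)
  }
  structure(list(
    target = target, algorithms = names(fitted), classes = classes,
    n_folds = n_folds, seed = seed, fold = fold,
    feature_names = colnames(x), residues = features$residues,
    aa = features$aa, labels = y_raw, fits = fitted
  ), class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf(
    "<model_bundle> target %s: %d classes, %d features, %s x %d folds\n",
    x$target, length(x$classes), length(x$feature_names),
    paste(x$algorithms, collapse = "/"), x$n_folds))
  invisible(x)
}

#' Held-out predictions of one algorithm in a bundle
#'
#' Every row is predicted exactly once, by the fold that held it out.
#'
#' @param bundle a [train_ensemble()] result.
#' @param algorithm one of `bundle$algorithms`.
#' @return vector of predicted labels on the original label scale.
#' @export
bundle_heldout_predictions <- function(bundle, algorithm) {
  if (!algorithm %in% bundle$algorithms) {
    stop("no fitted backend '", algorithm, "' in bundle", call. = FALSE)
  }
  bundle$classes[bundle$fits[[algorithm]]$pred + 1L]
}

#' Consensus SHAP residue importance
#'
#' Within each (algorithm, fold): the importance of a feature is the mean
#' absolute SHAP value over held-out rows (and classes, for multiclass
#' models); fold importances are min-max normalized to \[0, 1\]. The
#' consensus importance is the mean of the normalized fold importances over
#' all (algorithm, fold) pairs, ranked descending.
#'
#' @param bundle a [train_ensemble()] result.
#' @return data.frame with `feature`, `residue`, `importance`, `rank`,
#'   ordered by rank.
#' @export
shap_consensus_importance <- function(bundle) {
  p <- length(bundle$feature_names)
  acc <- matrix(0, 0, p)
  for (alg in bundle$algorithms) {
    for (f in seq_len(bundle$n_folds)) {
      arr <- bundle$fits[[alg]]$shap[[f]]
      raw <- apply(abs(arr[, , seq_len(p), drop = FALSE]), 3L, mean)
      rng <- range(raw)
      if (rng[2L] - rng[1L] < .Machine$double.eps) {
        warning("fold with constant SHAP importances normalized to zeros",
                call. = FALSE)
        norm <- rep(0, p)
      } else {
        norm <- (raw - rng[1L]) / (rng[2L] - rng[1L])
      }
      acc <- rbind(acc, norm)
    }
  }
  cons <- colMeans(acc)
  out <- data.frame(feature = bundle$feature_names,
                    residue = bundle$residues,
                    importance = cons, stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$feature), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' SHAP dependence profile of one residue
#'
#' Within each (algorithm, fold), the residue's held-out SHAP values for the
#' class of interest are divided by the fold's maximum absolute value for
#' that residue, mapping them into \[-1, 1\] while preserving sign. Values
#' are grouped by the amino acid the row carries at the residue and pooled
#' across folds and algorithms.
#'
#' @param bundle a [train_ensemble()] result.
#' @param residue reference residue number (matched against `res<k>` feature
#'   names) or a feature name.
#' @param class_of_interest which class's SHAP matrix to use for multiclass
#'   models (on the original label scale, e.g. `1` for the R class); ignored
#'   for binary models.
#' @return data.frame of class `dependence_profile` with `algorithm`, `fold`,
#'   `amino_acid`, `shap`.
#' @export
shap_dependence <- function(bundle, residue, class_of_interest = NULL) {
  fname <- if (is.numeric(residue)) {
    cand <- paste0(c("res", "col"), residue)
    cand[cand %in% bundle$feature_names][1L] %||% paste0("res", residue)
  } else residue
  j <- match(fname, bundle$feature_names)
  if (is.na(j)) stop("residue not among retained features: ", fname,
                     call. = FALSE)
  k <- dim(bundle$fits[[bundle$algorithms[1L]]]$shap[[1L]])[2L]
  if (k > 1L) {
    if (is.null(class_of_interest)) {
      stop("class_of_interest required for multiclass models", call. = FALSE)
    }
    ci <- match(class_of_interest, bundle$classes)
    if (is.na(ci)) stop("unknown class: ", class_of_interest, call. = FALSE)
  } else {
    ci <- 1L
  }
  rows <- list()
  for (alg in bundle$algorithms) {
    for (f in seq_len(bundle$n_folds)) {
      held <- which(bundle$fold == f)
      s <- bundle$fits[[alg]]$shap[[f]][, ci, j]
      m <- max(abs(s))
      norm <- if (m < .Machine$double.eps) rep(0, length(s)) else s / m
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm = alg, fold = f,
        amino_acid = bundle$aa[held, j],
        shap = norm, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("dependence_profile", "data.frame")
  out
}

#' Classification metrics: accuracy, multiclass MCC, macro F1
#'
#' The Matthews correlation coefficient uses the generalized multiclass
#' (Gorodkin R_K) form, which reduces to the familiar binary formula for two
#' classes. Macro F1 is the unweighted mean of per-class F1 scores (a class
#' never predicted and never observed contributes 0).
#'
#' @param predicted,observed equal-length label vectors.
#' @param classes label universe (default: sorted union of both vectors).
#' @return object of class `metrics_report`: list with `accuracy`, `mcc`,
#'   `macro_f1`, and the `confusion` matrix (rows = observed,
#'   columns = predicted).
#' @export
evaluate_predictions <- function(predicted, observed, classes = NULL) {
  stopifnot(length(predicted) == length(observed))
  predicted <- as.character(predicted); observed <- as.character(observed)
  if (is.null(classes)) classes <- sort(unique(c(predicted, observed)))
  classes <- as.character(classes)
  cm <- table(factor(observed, levels = classes),
              factor(predicted, levels = classes))
  cm <- unclass(cm)
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  t_k <- rowSums(cm)  # observed class counts
  p_k <- colSums(cm)  # predicted class counts
  num <- n * sum(diag(cm)) - sum(t_k * p_k)
  den <- sqrt(n^2 - sum(p_k^2)) * sqrt(n^2 - sum(t_k^2))
  if (den == 0) {
    warning("MCC undefined (single observed or predicted class)",
            call. = FALSE)
    mcc <- NA_real_
  } else {
    mcc <- num / den
  }
  f1 <- vapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    denom <- 2 * tp + (p_k[i] - tp) + (t_k[i] - tp)
    if (denom == 0) 0 else 2 * tp / denom
  }, numeric(1))
  structure(list(accuracy = acc, mcc = mcc, macro_f1 = mean(f1),
                 confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> accuracy %.3f, MCC %s, macro-F1 %.3f\n",
              x$accuracy,
              if (is.na(x$mcc)) "NA" else sprintf("%.3f", x$mcc),
              x$macro_f1))
  print(x$confusion)
  invisible(x)
}
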