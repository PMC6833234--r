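#' False-negative cost from training-fold class imbalance
#'
#' The false-negative cost is the exact ratio of negative to positive label
#' counts over the training folds; the false-positive cost is 1 and the costs
#' of correct decisions are 0. Training with these costs keeps a model from
#' collapsing onto the majority (non-hypoglycemic) class.
#'
#' @param labels 0/1 vector of training labels.
#' @return An object of class `cost_spec` with fields `cost_fn`, `cost_fp`,
#'   `cost_tp`, `cost_tn`, `n_pos`, `n_neg`.
#' @export
compute_fn_cost <- function(labels) {
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L) {
    stop("training folds contain no positive label; re-split the folds",
         call. = FALSE)
  }
  structure(
    list(cost_fn = n_neg / n_pos, cost_fp = 1, cost_tp = 0, cost_tn = 0,
         n_pos = n_pos, n_neg = n_neg),
    class = "cost_spec"
  )
}

#' Cross-subject fold assignment
#'
#' Patients (not series) are the cross-validation unit: patients are shuffled
#' by the seed and dealt round-robin into `k` groups, and every series is
#' placed in its patient's fold, so no subject contributes to both sides of
#' any split.
#'
#' @param series_meta Data.frame with columns `series_id`, `patient_id`.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the patient shuffle.
#' @return A list of `k` fold splits, each a list with `fold`,
#'   `test_patients`, `train_patients`, `test_series`, `train_series`.
#' @export
cross_subject_folds <- function(series_meta, k = 5L, seed = 1L) {
  stopifnot(all(c("series_id", "patient_id") %in% names(series_meta)))
  patients <- unique(series_meta$patient_id)
  if (length(patients) < k) {
    stop("need at least k = ", k, " distinct patients, got ",
         length(patients), call. = FALSE)
  }
  set.seed(seed)
  shuffled <- sample(patients)
  group <- ((seq_along(shuffled) - 1L) %% k) + 1L
  lapply(seq_len(k), function(q) {
    test_pat <- shuffled[group == q]
    test_ser <- series_meta$series_id[series_meta$patient_id %in% test_pat]
    list(
      fold = q,
      test_patients = test_pat,
      train_patients = setdiff(patients, test_pat),
      test_series = test_ser,
      train_series = setdiff(series_meta$series_id, test_ser)
    )
  })
}

#' Default hyperparameter grids
#'
#' One data.frame of candidate settings per family. `max_depth = 0` means
#' unlimited tree depth; the logistic-regression `C` is an inverse
#' regularization strength (larger C, weaker ridge penalty).
#'
#' @return Named list of data.frames keyed by family
#'   (`rf`, `svm_ln`, `svm_rbf`, `knn`, `lr`).
#' @export
default_grids <- function() {
  list(
    rf = expand.grid(num_trees = c(100L, 300L), max_depth = c(4L, 8L, 0L)),
    svm_ln = data.frame(C = c(0.1, 1, 10)),
    svm_rbf = expand.grid(C = c(0.1, 1, 10), gamma = c(0.01, 0.1, 1)),
    knn = data.frame(k = c(5L, 15L, 31L)),
    lr = data.frame(C = c(0.1, 1, 10))
  )
}

#' Grid search by inner cross-subject validation
#'
#' Every grid point is scored by subject-grouped inner cross-validation on
#' the training series: the loss is the cost-weighted misclassification rate
#' `(cost_fn * FN + cost_fp * FP) / n`, averaged over the inner folds. The
#' grid point with the lowest mean loss wins; ties break in declared grid
#' order. A single-point grid is returned immediately without inner fits.
#'
#' @param family One of `"rf"`, `"svm_ln"`, `"svm_rbf"`, `"knn"`, `"lr"`.
#' @param samples Training feature samples ([build_dataset()] rows).
#' @param series_meta Data.frame `series_id`, `patient_id` covering the
#'   training series (used for subject grouping).
#' @param grid Data.frame of candidate hyperparameter rows.
#' @param cost A `cost_spec` from [compute_fn_cost()] (computed on `samples`
#'   when `NULL`).
#' @param inner_k Number of inner folds (default 3).
#' @param seed Seed for the inner fold shuffle and any stochastic learner.
#' @param feature_subset `"all"` or `"cgm_grc"`.
#' @return The winning grid row (one-row data.frame) with attribute
#'   `inner_loss` holding the mean loss per grid point.
#' @export
grid_search <- function(family, samples, series_meta, grid, cost = NULL,
                        inner_k = 3L, seed = 1L, feature_subset = "all") {
  stopifnot(nrow(grid) >= 1L)
  if (nrow(grid) == 1L) return(grid[1, , drop = FALSE])
  if (is.null(cost)) cost <- compute_fn_cost(samples$label)
  meta <- series_meta[series_meta$series_id %in% samples$series_id, ,
                      drop = FALSE]
  folds <- cross_subject_folds(meta, k = inner_k, seed = seed)
  losses <- vapply(seq_len(nrow(grid)), function(gidx) {
    fold_loss <- vapply(folds, function(f) {
      tr <- samples[samples$series_id %in% f$train_series, , drop = FALSE]
      te <- samples[samples$series_id %in% f$test_series, , drop = FALSE]
      if (nrow(te) == 0L || length(unique(tr$label)) < 2L) return(NA_real_)
      model <- train_model(family, tr, cost, grid[gidx, , drop = FALSE],
                           feature_subset = feature_subset, seed = seed)
      pred <- predict(model, te)
      fn <- sum(te$label == 1 & pred$label == 0)
      fp <- sum(te$label == 0 & pred$label == 1)
      (cost$cost_fn * fn + cost$cost_fp * fp) / nrow(te)
    }, 0)
    mean(fold_loss, na.rm = TRUE)
  }, 0)
  best <- which.min(losses)   # ties: earliest grid row
  out <- grid[best, , drop = FALSE]
  attr(out, "inner_loss") <- losses
  out
}

feature_columns <- function(feature_subset) {
  switch(feature_subset,
         all = c("cgm", "rig", "grc"),
         cgm_grc = c("cgm", "grc"),
         stop("unknown feature_subset '", feature_subset, "'", call. = FALSE))
}

#' Train one cost-sensitive classifier
#'
#' Fits the min-max scaler on the training samples, then the requested family
#' with the false-negative cost entering as a positive-class weight: case
#' weights for the random forest, class weights for the SVMs, observation
#' weights for the ridge logistic regression, and a vote multiplier on
#' positive neighbors for the KNN. All models expose a continuous score in
#' \[0, 1\] for the positive class; SVM scores are the logistic transform of
#' the decision value, whose 0.5 cut coincides with the class-weighted
#' decision boundary.
#'
#' @inheritParams grid_search
#' @param hyper One-row data.frame of hyperparameters (see
#'   [default_grids()]).
#' @param cost A `cost_spec`; `cost_fn = 1` reproduces cost-insensitive
#'   training.
#' @return An object of class `pphypo_model`.
#' @export
train_model <- function(family, samples, cost, hyper,
                        feature_subset = "all", seed = 1L) {
  family <- match.arg(family, c("rf", "svm_ln", "svm_rbf", "knn", "lr"))
  stopifnot(inherits(cost, "cost_spec"), nrow(samples) > 0L)
  feats <- feature_columns(feature_subset)
  scaler <- fit_scaler(samples, features = feats)
  scaled <- apply_scaler(scaler, samples)
  X <- as.matrix(scaled[, feats, drop = FALSE])
  y <- factor(samples$label, levels = c(0, 1))
  w <- ifelse(samples$label == 1, cost$cost_fn, cost$cost_fp)

  fit <- switch(
    family,
    rf = {
      md <- hyper$max_depth
      ranger::ranger(
        x = X, y = y, num.trees = hyper$num_trees,
        max.depth = if (is.null(md) || md == 0L) NULL else md,
        probability = TRUE, case.weights = w,
        seed = seed, num.threads = 1L
      )
    },
    svm_ln = e1071::svm(
      x = X, y = y, kernel = "linear", cost = hyper$C,
      class.weights = c("0" = cost$cost_fp, "1" = cost$cost_fn),
      scale = FALSE
    ),
    svm_rbf = e1071::svm(
      x = X, y = y, kernel = "radial", cost = hyper$C, gamma = hyper$gamma,
      class.weights = c("0" = cost$cost_fp, "1" = cost$cost_fn),
      scale = FALSE
    ),
    knn = list(X = X, y = samples$label, k = hyper$k),
    lr = {
      # C is an inverse regularization strength; glmnet penalizes by lambda
      lambda <- 1 / (hyper$C * nrow(X))
      glmnet::glmnet(X, y, family = "binomial", weights = w, alpha = 0,
                     lambda = lambda)
    }
  )
  structure(
    list(family = family, hyper = hyper, cost = cost, scaler = scaler,
         fit = fit, feature_subset = feature_subset, features = feats),
    class = "pphypo_model"
  )
}

#' @export
print.pphypo_model <- function(x, ...) {
  cat(sprintf(
    "<pphypo_model %s | features: %s | cost_fn = %.2f | %s>\n",
    x$family, paste(x$features, collapse = "+"), x$cost$cost_fn,
    paste(sprintf("%s=%s", names(x$hyper), unlist(x$hyper)), collapse = ", ")
  ))
  invisible(x)
}

#' Predict hypoglycemia scores and hard labels
#'
#' Applies the model's own fitted scaler to the samples and returns a
#' continuous score in \[0, 1\] for the positive class together with the hard
#' label `score >= 0.5`.
#'
#' @param object A [train_model()] fit.
#' @param newdata Data.frame of feature samples carrying the model's feature
#'   columns.
#' @param ... Unused.
#' @return A data.frame with columns `score` and `label`.
#' @export
predict.pphypo_model <- function(object, newdata, ...) {
  feats <- object$features
  missing_cols <- setdiff(feats, names(newdata))
  if (length(missing_cols)) {
    stop("samples lack feature column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(newdata) == 0L) {
    return(data.frame(score = numeric(), label = integer()))
  }
  scaled <- apply_scaler(object$scaler, newdata)
  X <- as.matrix(scaled[, feats, drop = FALSE])
  score <- switch(
    object$family,
    rf = {
      p <- stats::predict(object$fit, data = X, num.threads = 1L)$predictions
      p[, "1"]
    },
    svm_ln = ,
    svm_rbf = {
      pr <- stats::predict(object$fit, X, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # libsvm labels the decision value by "first/second" class; flip so that
      # larger means more positive ("1")
      sgn <- if (colnames(dv)[1] == "1/0") 1 else -1
      stats::plogis(sgn * dv[, 1])
    },
    knn = knn_scores(object$fit, X, cost_fn = object$cost$cost_fn),
    lr = as.numeric(stats::predict(object$fit, newx = X, type = "response"))
  )
  data.frame(score = unname(score), label = as.integer(score >= 0.5))
}

# Cost-weighted K-nearest-neighbor scores: positive neighbor votes are
# multiplied by cost_fn, and the score is the weighted positive vote fraction
# cost_fn * n_pos / (cost_fn * n_pos + n_neg). Neighbor ties at the k-th
# distance break by training-set order. Distances are computed in chunks to
# bound memory.
knn_scores <- function(fit, X, cost_fn, chunk = 500L) {
  train <- fit$X
  ytr <- fit$y
  k <- min(fit$k, nrow(train))
  tr_sq <- rowSums(train^2)
  out <- numeric(nrow(X))
  for (from in seq(1L, nrow(X), by = chunk)) {
    to <- min(from + chunk - 1L, nrow(X))
    Xc <- X[from:to, , drop = FALSE]
    d2 <- outer(rowSums(Xc^2), tr_sq, "+") - 2 * tcrossprod(Xc, train)
    for (i in seq_len(nrow(Xc))) {
      nn <- order(d2[i, ])[seq_len(k)]
      npos <- sum(ytr[nn] == 1)
      nneg <- k - npos
      out[from + i - 1L] <- cost_fn * npos / (cost_fn * npos + nneg)
    }
  }
  out
}
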