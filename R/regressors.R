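#' Hyperparameter grid for model selection
#'
#' The default grid searched by [fit_potency_model()]: SVR cost values
#' `C in {1, 10, 100, 1000}`; random forest number of trees
#' `{50, 100, 200}`, minimum samples to split a node `{2, 3, 5, 10}`,
#' minimum samples per leaf `{1, 2, 5, 10}`, and `sqrt`/`log2` feature
#' subsampling.
#'
#' @param svr_C SVR cost values.
#' @param rfr_num_trees,rfr_min_node_size,rfr_min_bucket,rfr_max_features
#'   Random forest grid dimensions (`min_node_size` = minimum samples to
#'   attempt a split, `min_bucket` = minimum samples per leaf).
#' @return A named list with class `hyperparam_grid`.
#' @export
default_grid <- function(svr_C = c(1, 10, 100, 1000),
                         rfr_num_trees = c(50L, 100L, 200L),
                         rfr_min_node_size = c(2L, 3L, 5L, 10L),
                         rfr_min_bucket = c(1L, 2L, 5L, 10L),
                         rfr_max_features = c("sqrt", "log2")) {
  stopifnot(length(svr_C) > 0, length(rfr_num_trees) > 0,
            length(rfr_min_node_size) > 0, length(rfr_min_bucket) > 0,
            length(rfr_max_features) > 0)
  structure(list(svr_C = svr_C, rfr_num_trees = rfr_num_trees,
                 rfr_min_node_size = rfr_min_node_size,
                 rfr_min_bucket = rfr_min_bucket,
                 rfr_max_features = match.arg(rfr_max_features,
                                              c("sqrt", "log2"),
                                              several.ok = TRUE)),
            class = "hyperparam_grid")
}

#' A condensed grid for fast scaled-down runs
#'
#' Keeps the full SVR `C` search but condenses the random forest search to
#' the corners of the tree-shape range (100 trees; split at 2 or 10; leaf
#' size 1 or 5; sqrt features), so cross-validation can still trade tree
#' depth against training-set size at a fraction of the full grid's cost.
#' Used by the packaged scaled-down experiments.
#'
#' @return A `hyperparam_grid`.
#' @export
reduced_grid <- function() {
  default_grid(rfr_num_trees = 100L, rfr_min_node_size = c(2L, 10L),
               rfr_min_bucket = c(1L, 5L), rfr_max_features = "sqrt")
}

mtry_of <- function(rule, p) {
  switch(rule, sqrt = max(1L, floor(sqrt(p))), log2 = max(1L, floor(log2(p))),
         stop("unknown max_features rule: ", rule, call. = FALSE))
}

# Fold assignment for cross-validation; stratified by sub-range when asked.
# Falls back to a single 50/50 train/validation split when folds would be
# degenerate (< 2 compounds per fold).
make_folds <- function(n, k, strata = NULL, stratify = FALSE) {
  if (n < 2L * k) {
    half <- sample.int(n, ceiling(n / 2))
    return(list(fold_of = replace(rep(1L, n), half, 2L), k = 1L,
                single_split = TRUE))
  }
  fold_of <- integer(n)
  if (stratify && !is.null(strata)) {
    # cycle fold labels across strata so every fold is populated even when
    # strata are smaller than k (e.g. 2 compounds per sub-range, 3 folds)
    pos <- 0L
    for (s in unique(strata)) {
      idx <- which(strata == s)
      labels <- ((pos + seq_along(idx) - 1L) %% k) + 1L
      fold_of[idx] <- sample(labels)
      pos <- pos + length(idx)
    }
  } else {
    fold_of <- sample(rep_len(seq_len(k), n))
  }
  list(fold_of = fold_of, k = k, single_split = FALSE)
}

# Mean validation cost over folds; `fit_fun(train_idx)` returns a closure
# predicting on indices. cost "MAE" is minimised; cost "R2" (coefficient of
# determination) is maximised, handled as its negation.
cv_cost <- function(y, folds, fit_predict, cost) {
  ks <- if (folds$single_split) 2L else seq_len(folds$k)
  vals <- vapply(ks, function(f) {
    val_idx <- which(folds$fold_of == f)
    trn_idx <- which(folds$fold_of != f)
    if (folds$single_split && f == 2L) {
      trn_idx <- which(folds$fold_of == 1L)
    }
    if (length(val_idx) == 0L || length(trn_idx) == 0L) {
      return(NA_real_)
    }
    pred <- fit_predict(trn_idx, val_idx)
    if (cost == "MAE") {
      mae(y[val_idx], pred)
    } else {
      if (stats::sd(y[val_idx]) == 0) NA_real_ else -r2_determination(y[val_idx], pred)
    }
  }, numeric(1))
  if (all(is.na(vals))) Inf else mean(vals, na.rm = TRUE)
}

svr_fit <- function(K, y, C, epsilon) {
  # a training set constant to within the epsilon tube has the all-zero dual
  # solution; represent it directly instead of relying on the optimiser
  fit <- if (stats::sd(y) == 0) NULL else {
    tryCatch(kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "eps-svr",
                           C = C, epsilon = epsilon),
             error = function(e) NULL)
  }
  if (is.null(fit) || length(kernlab::SVindex(fit)) == 0L) {
    return(structure(list(constant = stats::median(y)), class = "svr_constant"))
  }
  fit
}

svr_predict <- function(fit, K_new_train) {
  if (inherits(fit, "svr_constant")) {
    return(rep(fit$constant, nrow(K_new_train)))
  }
  as.numeric(kernlab::predict(
    fit, kernlab::as.kernelMatrix(K_new_train[, kernlab::SVindex(fit),
                                              drop = FALSE])))
}

rfr_fit <- function(X, y, params, seed) {
  ranger::ranger(x = X, y = y, num.trees = params$num_trees,
                 min.node.size = params$min_node_size,
                 min.bucket = params$min_bucket,
                 mtry = mtry_of(params$max_features, ncol(X)),
                 seed = seed, num.threads = 1L, verbose = FALSE)
}

#' Fit a potency regression model
#'
#' Fits one of the five methods of the benchmark to a training set of
#' fingerprinted compounds:
#' \describe{
#'   \item{SVR}{Epsilon-insensitive support vector regression on the
#'     precomputed Tanimoto kernel; `C` selected by grid search with 3-fold
#'     cross-validation (stratified by potency sub-range when the training
#'     set is sub-range balanced), minimising MAE or maximising the
#'     coefficient of determination.}
#'   \item{RFR}{Random forest regression on the raw fingerprint bits, grid
#'     searched the same way.}
#'   \item{1NN, 3NN}{No fitting: test compounds receive the potency of the
#'     most Tanimoto-similar training compound, or the unweighted mean of the
#'     top 3. Similarity ties are broken by the first compound in a seeded
#'     shuffle of the training set.}
#'   \item{MR}{Median regression, the null control: every prediction is the
#'     training-set median potency.}
#' }
#' Training sets too small for the requested folds fall back to a single
#' 50/50 train/validation split. Grid ties are broken toward the smaller /
#' simpler setting. All randomness (fold assignment, tree seeds, tie
#' shuffles) derives from `seed`.
#'
#' @param train Training tibble with `pic50`, `fingerprint`, `subrange`
#'   columns.
#' @param method One of `"SVR"`, `"RFR"`, `"1NN"`, `"3NN"`, `"MR"`.
#' @param grid A [default_grid()]-style grid.
#' @param cost Selection cost: `"MAE"` (default) or `"R2"`.
#' @param seed Integer seed.
#' @param cv_folds Number of cross-validation folds (default 3).
#' @param epsilon SVR epsilon-insensitive tube width (default 0.1).
#' @param stratify_cv Stratify CV folds by sub-range; default `NULL`
#'   auto-detects a sub-range-balanced training set.
#' @return A `potency_model` object with [predict()][predict.potency_model],
#'   [generics::tidy()] and [generics::glance()] methods.
#' @export
#' @examples
#' cls <- generate_activity_class(synth_config(n_compounds = 120,
#'                                             min_per_subrange = 10))
#' m <- fit_potency_model(cls[1:60, ], "MR")
#' predict(m, cls[61:80, ])
fit_potency_model <- function(train, method = c("SVR", "RFR", "1NN", "3NN", "MR"),
                              grid = default_grid(), cost = c("MAE", "R2"),
                              seed = 1L, cv_folds = 3L, epsilon = 0.1,
                              stratify_cv = NULL) {
  method <- match.arg(method)
  cost <- match.arg(cost)
  check_columns(train, c("pic50", "fingerprint"), "train")
  n <- nrow(train)
  if (n == 0L) {
    stop("empty training set", call. = FALSE)
  }
  y <- train$pic50
  model <- list(method = method, cost = cost, seed = seed, n_train = n,
                train_y = y,
                train_ids = if ("compound_id" %in% names(train)) train$compound_id else NULL,
                median = stats::median(y), params = NULL, cv = NULL,
                fit = NULL, k = NA_integer_)
  if (method == "MR") {
    return(structure(model, class = "potency_model"))
  }

  X <- fp_matrix(train)
  model$train_fp <- X
  if (method %in% c("1NN", "3NN")) {
    k <- if (method == "1NN") 1L else 3L
    if (k > n) {
      stop(sprintf("%s requires at least %d training compounds", method, k),
           call. = FALSE)
    }
    model$k <- k
    model$tie_rank <- with_seed(derive_seed(seed, "knn-ties"), sample.int(n))
    return(structure(model, class = "potency_model"))
  }

  balanced <- if (is.null(stratify_cv)) {
    "subrange" %in% names(train) &&
      length(unique(table(factor(train$subrange,
                                 levels = c("LOW", "MID", "HIGH"))))) == 1L
  } else {
    stratify_cv
  }
  folds <- with_seed(derive_seed(seed, "cv-folds"),
                     make_folds(n, cv_folds,
                                strata = if ("subrange" %in% names(train)) train$subrange,
                                stratify = balanced))

  if (method == "SVR") {
    K <- tanimoto_matrix(X)
    costs <- vapply(grid$svr_C, function(C) {
      cv_cost(y, folds, function(trn, val) {
        fit <- svr_fit(K[trn, trn, drop = FALSE], y[trn], C, epsilon)
        svr_predict(fit, K[val, trn, drop = FALSE])
      }, cost)
    }, numeric(1))
    best <- which.min(costs) # first minimum: smallest C wins ties
    model$cv <- tibble::tibble(C = grid$svr_C, cv_cost = costs)
    model$params <- list(C = grid$svr_C[best], epsilon = epsilon)
    model$fit <- svr_fit(K, y, grid$svr_C[best], epsilon)
    model$train_K <- K
  } else { # RFR
    colnames(X) <- paste0("b", seq_len(ncol(X)))
    model$train_fp <- X
    combos <- expand.grid(min_bucket = sort(grid$rfr_min_bucket),
                          min_node_size = sort(grid$rfr_min_node_size),
                          num_trees = sort(grid$rfr_num_trees),
                          max_features = grid$rfr_max_features,
                          stringsAsFactors = FALSE)
    # order so that ties resolve toward fewer trees / simpler trees
    combos <- combos[order(combos$num_trees, combos$min_node_size,
                           combos$min_bucket), , drop = FALSE]
    costs <- vapply(seq_len(nrow(combos)), function(i) {
      prm <- as.list(combos[i, ])
      cv_cost(y, folds, function(trn, val) {
        fit <- rfr_fit(X[trn, , drop = FALSE], y[trn], prm,
                       derive_seed(seed, "rfr-cv", i))
        stats::predict(fit, data = X[val, , drop = FALSE],
                       num.threads = 1L)$predictions
      }, cost)
    }, numeric(1))
    best <- which.min(costs)
    model$cv <- dplyr::bind_cols(tibble::as_tibble(combos),
                                 tibble::tibble(cv_cost = costs))
    model$params <- as.list(combos[best, ])
    model$fit <- rfr_fit(X, y, model$params, derive_seed(seed, "rfr-final"))
  }
  structure(model, class = "potency_model")
}

#' Predict potency for test compounds
#'
#' @param object A `potency_model`.
#' @param newdata Test tibble with a `fingerprint` column (and `pic50`,
#'   `subrange`, `compound_id` when available, which are carried into the
#'   result).
#' @param ... Unused.
#' @return A tibble with one row per test compound: `compound_id`, `y_true`,
#'   `y_pred`, `subrange`, `method`.
#' @export
predict.potency_model <- function(object, newdata, ...) {
  out_ids <- if ("compound_id" %in% names(newdata)) {
    newdata$compound_id
  } else {
    as.character(seq_len(nrow(newdata)))
  }
  result <- tibble::tibble(
    compound_id = out_ids,
    y_true = if ("pic50" %in% names(newdata)) newdata$pic50 else NA_real_,
    y_pred = NA_real_,
    subrange = if ("subrange" %in% names(newdata)) {
      newdata$subrange
    } else if ("pic50" %in% names(newdata)) {
      assign_subrange(newdata$pic50)
    } else {
      factor(NA, levels = c("LOW", "MID", "HIGH"))
    },
    method = object$method
  )
  if (nrow(newdata) == 0L) {
    return(result)
  }
  if (object$method == "MR") {
    result$y_pred <- rep(object$median, nrow(newdata))
    return(result)
  }
  X_new <- fp_matrix(newdata)
  if (ncol(X_new) != ncol(object$train_fp)) {
    stop("test fingerprint length differs from training", call. = FALSE)
  }
  if (object$method %in% c("1NN", "3NN")) {
    S <- tanimoto_matrix(X_new, object$train_fp)
    y <- object$train_y
    k <- object$k
    result$y_pred <- vapply(seq_len(nrow(S)), function(i) {
      ord <- order(-S[i, ], object$tie_rank)
      mean(y[ord[seq_len(k)]])
    }, numeric(1))
  } else if (object$method == "SVR") {
    K_new <- tanimoto_matrix(X_new, object$train_fp)
    result$y_pred <- svr_predict(object$fit, K_new)
  } else {
    colnames(X_new) <- colnames(object$train_fp)
    result$y_pred <- stats::predict(object$fit, data = X_new,
                                    num.threads = 1L)$predictions
  }
  result
}

#' @export
print.potency_model <- function(x, ...) {
  cat(sprintf("<potency_model> %s, n_train = %d, cost = %s\n", x$method,
              x$n_train, x$cost))
  if (!is.null(x$params)) {
    cat("  selected:", paste(names(x$params), unlist(x$params), sep = " = ",
                             collapse = ", "), "\n")
  }
  if (x$method == "MR") {
    cat(sprintf("  training median pIC50 = %.4f\n", x$median))
  }
  invisible(x)
}

#' Tidy method for potency models
#'
#' `tidy()` returns the hyperparameter grid with cross-validation costs (one
#' row per candidate; empty for methods without a search); `glance()` returns
#' a one-row model summary.
#'
#' @param x A `potency_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy potency_model
#' @export
tidy.potency_model <- function(x, ...) {
  if (is.null(x$cv)) {
    return(tibble::tibble())
  }
  x$cv
}

#' @rdname tidy.potency_model
#' @method glance potency_model
#' @export
glance.potency_model <- function(x, ...) {
  tibble::tibble(
    method = x$method, n_train = x$n_train, cost = x$cost,
    train_median = x$median,
    selected = if (is.null(x$params)) NA_character_ else {
      paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
    },
    seed = x$seed
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
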