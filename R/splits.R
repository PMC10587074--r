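#' Training-set ladder sizes
#'
#' The fixed sequence of balanced training-set sizes used in the
#' increasing-training-set experiments: 6 compounds (two per potency
#' sub-range) up to 330 (110 per sub-range).
#'
#' @return `c(6, 12, 18, 30, 48, 78, 126, 204, 330)`.
#' @export
ladder_sizes <- function() {
  c(6L, 12L, 18L, 30L, 48L, 78L, 126L, 204L, 330L)
}

new_split_plan <- function(class_id, trial, protocol, seed, size, train_ids,
                           test_ids) {
  tibble::tibble(
    class_id = class_id, trial = trial, protocol = protocol, seed = seed,
    ladder_size = size, train_ids = list(train_ids), test_ids = list(test_ids)
  )
}

split_one_class <- function(classes, f) {
  check_columns(classes, c("class_id", "compound_id", "subrange"), "classes")
  if (anyDuplicated(classes$compound_id)) {
    stop("compound_ids are not unique within the input", call. = FALSE)
  }
  classes |>
    dplyr::group_by(.data$class_id) |>
    dplyr::group_split() |>
    purrr::map(f) |>
    dplyr::bind_rows()
}

#' Random 50/50 train/test splits
#'
#' For each class, `n_trials` independent random partitions into 50% training
#' and 50% test compounds, with no stratification by potency sub-range. For
#' odd class sizes the training set receives the extra compound. Plans are
#' fully reproducible from the master seed.
#'
#' @param classes Compound tibble (one or more classes) with `class_id`,
#'   `compound_id`, `subrange` columns.
#' @param n_trials Number of independent trials (default 10).
#' @param seed Master seed.
#' @return A tibble of split plans: `class_id`, `trial`, `protocol`, `seed`,
#'   `ladder_size` (`NA` here), and list-columns `train_ids`, `test_ids`.
#' @export
#' @examples
#' cls <- generate_activity_class(synth_config(n_compounds = 100,
#'                                             min_per_subrange = 0))
#' plans <- random_5050_splits(cls, n_trials = 3, seed = 42)
random_5050_splits <- function(classes, n_trials = 10L, seed = 1L) {
  split_one_class(classes, function(cls) {
    n <- nrow(cls)
    if (n < 2L) {
      stop(sprintf("class %s has fewer than 2 compounds", cls$class_id[1]),
           call. = FALSE)
    }
    purrr::map(seq_len(n_trials) - 1L, function(trial) {
      s <- derive_seed(seed, cls$class_id[1], trial, "RANDOM_5050")
      with_seed(s, {
        perm <- sample.int(n)
        n_train <- ceiling(n / 2)
        new_split_plan(cls$class_id[1], trial, "RANDOM_5050", s, NA_integer_,
                       cls$compound_id[perm[seq_len(n_train)]],
                       cls$compound_id[perm[(n_train + 1L):n]])
      })
    }) |>
      dplyr::bind_rows()
  })
}

#' Sub-range-balanced training-set ladders
#'
#' For each class and trial, builds nested training sets at every ladder size
#' with exactly `size/3` compounds sampled uniformly from each potency
#' sub-range, plus one fixed test set per trial drawn from the compounds left
#' after removing the largest (330-compound) training pool. The test set is
#' balanced with respect to the HIGH (9--11) sub-range: each sub-range
#' contributes as many compounds as remain in HIGH.
#'
#' @inheritParams random_5050_splits
#' @param sizes Ladder of total training-set sizes; each must be divisible by
#'   3 (default [ladder_sizes()]).
#' @param nested If `TRUE` (default) each training set extends the previous
#'   one within a trial; otherwise each size is drawn independently.
#' @return A tibble of split plans, one row per (class, trial, ladder size);
#'   within a trial all rows share the same `test_ids`.
#' @export
balanced_ladder_splits <- function(classes, n_trials = 10L, seed = 1L,
                                   sizes = ladder_sizes(), nested = TRUE) {
  stopifnot(all(sizes %% 3L == 0L), all(diff(sizes) > 0L))
  per_sub <- sizes %/% 3L
  pool_n <- max(per_sub)
  split_one_class(classes, function(cls) {
    by_sub <- split(cls$compound_id, cls$subrange)
    counts <- lengths(by_sub)
    short <- names(counts)[counts < pool_n + 1L]
    if (length(short) > 0L) {
      stop(sprintf("class %s: sub-range %s has %d compounds; the balanced ladder needs at least %d (%d training + 1 test)",
                   cls$class_id[1], short[1], counts[[short[1]]], pool_n + 1L,
                   pool_n), call. = FALSE)
    }
    purrr::map(seq_len(n_trials) - 1L, function(trial) {
      s <- derive_seed(seed, cls$class_id[1], trial, "BALANCED_LADDER")
      with_seed(s, {
        perms <- lapply(by_sub, sample)
        pool <- lapply(perms, utils::head, pool_n)
        remaining <- lapply(names(perms), function(sr) {
          setdiff(perms[[sr]], pool[[sr]])
        })
        names(remaining) <- names(perms)
        n_test_per_sub <- length(remaining$HIGH)
        deficient <- names(remaining)[lengths(remaining) < n_test_per_sub]
        if (length(deficient) > 0L) {
          stop(sprintf("class %s: sub-range %s has only %d compounds left for the balanced test set; %d required",
                       cls$class_id[1], deficient[1],
                       lengths(remaining)[[deficient[1]]], n_test_per_sub),
               call. = FALSE)
        }
        test_ids <- unlist(lapply(remaining, function(ids) {
          ids[sample.int(length(ids), n_test_per_sub)]
        }), use.names = FALSE)
        purrr::map(seq_along(sizes), function(k) {
          train_ids <- if (nested) {
            unlist(lapply(pool, utils::head, per_sub[k]), use.names = FALSE)
          } else {
            unlist(lapply(by_sub, function(ids) {
              ids[sample.int(length(ids), per_sub[k])]
            }), use.names = FALSE)
          }
          new_split_plan(cls$class_id[1], trial, "BALANCED_LADDER", s,
                         sizes[k], train_ids, test_ids)
        }) |>
          dplyr::bind_rows()
      })
    }) |>
      dplyr::bind_rows()
  })
}

#' Imbalanced training-set ladders (control)
#'
#' Same total training-set sizes as [balanced_ladder_splits()] but sampled
#' uniformly from the whole class without sub-range quotas; the fixed test
#' set of a trial is everything outside the largest training pool
#' (imbalanced, mirroring the class composition).
#'
#' @inheritParams balanced_ladder_splits
#' @return A tibble of split plans.
#' @export
imbalanced_ladder_splits <- function(classes, n_trials = 10L, seed = 1L,
                                     sizes = ladder_sizes(), nested = TRUE) {
  stopifnot(all(diff(sizes) > 0L))
  pool_n <- max(sizes)
  split_one_class(classes, function(cls) {
    n <- nrow(cls)
    if (n < pool_n + 3L) {
      stop(sprintf("class %s has %d compounds; the imbalanced ladder needs at least %d",
                   cls$class_id[1], n, pool_n + 3L), call. = FALSE)
    }
    purrr::map(seq_len(n_trials) - 1L, function(trial) {
      s <- derive_seed(seed, cls$class_id[1], trial, "IMBALANCED_LADDER")
      with_seed(s, {
        perm <- sample(cls$compound_id)
        pool <- perm[seq_len(pool_n)]
        test_ids <- perm[(pool_n + 1L):n]
        purrr::map(seq_along(sizes), function(k) {
          train_ids <- if (nested) {
            pool[seq_len(sizes[k])]
          } else {
            pool[sample.int(pool_n, sizes[k])]
          }
          new_split_plan(cls$class_id[1], trial, "IMBALANCED_LADDER", s,
                         sizes[k], train_ids, test_ids)
        }) |>
          dplyr::bind_rows()
      })
    }) |>
      dplyr::bind_rows()
  })
}

#' Serialise split plans as JSON
#'
#' Writes the full description of each plan (class, trial, protocol, seed,
#' ladder size, train/test compound ids) so an experiment can be replayed
#' exactly or audited without regenerating it.
#'
#' @param plans Plan tibble from one of the split constructors.
#' @param path JSON file path.
#' @return `write_split_plans` returns `path` invisibly; `read_split_plans`
#'   returns the plan tibble.
#' @export
write_split_plans <- function(plans, path) {
  payload <- purrr::map(seq_len(nrow(plans)), function(i) {
    list(class_id = plans$class_id[i], trial = plans$trial[i],
         protocol = plans$protocol[i], seed = plans$seed[i],
         ladder_size = if (is.na(plans$ladder_size[i])) NULL else plans$ladder_size[i],
         train_ids = plans$train_ids[[i]], test_ids = plans$test_ids[[i]])
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname write_split_plans
#' @export
read_split_plans <- function(path) {
  payload <- jsonlite::read_json(path)
  purrr::map(payload, function(p) {
    tibble::tibble(
      class_id = p$class_id, trial = as.integer(p$trial),
      protocol = p$protocol, seed = as.integer(p$seed),
      ladder_size = if (is.null(p$ladder_size)) NA_integer_ else as.integer(p$ladder_size),
      train_ids = list(unlist(p$train_ids, use.names = FALSE)),
      test_ids = list(unlist(p$test_ids, use.names = FALSE))
    )
  }) |>
    dplyr::bind_rows()
}
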