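#' Training-protocol configuration
#'
#' Bundles the knobs of the screening-model training protocol: the held-out
#' test fraction, the number of cross-validation folds, the hyperparameter
#' grid per model family, the fold-selection metric, the seed, and (for the
#' neural network) whether to balance classes by oversampling actives.
#'
#' The protocol is: split molecules 80/20 into training set L and test set
#' T (stratified by label); 5-fold cross-validate every grid point on L;
#' pick the grid point with the best mean validation score; refit on all of
#' L; evaluate on T. Splits are always at molecule level - all conformers
#' of a molecule stay on one side - because conformers of one molecule are
#' near-duplicates and a conformer-level split would leak.
#'
#' @param test_fraction Fraction of molecules held out as T (default 0.2).
#' @param cv_folds Number of CV folds on L (default 5, >= 2).
#' @param grids Named list of hyperparameter tibbles per family; defaults
#'   to [default_grids()].
#' @param selection_metric `"roc_auc"` (default; stabler on small folds) or
#'   `"ef1"` (enrichment factor at 1%).
#' @param seed Integer master seed; every downstream random step derives
#'   its own child seed from it.
#' @param balance_by_oversampling ANN only: oversample actives to 1:1.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(test_fraction = 0.2, cv_folds = 5,
                            grids = default_grids(),
                            selection_metric = c("roc_auc", "ef1"),
                            seed = 1, balance_by_oversampling = FALSE) {
  selection_metric <- match.arg(selection_metric)
  if (!(test_fraction > 0 && test_fraction < 1)) abort("`test_fraction` must be in (0, 1).")
  cv_folds <- as.integer(cv_folds)
  if (cv_folds < 2L) abort("`cv_folds` must be >= 2.")
  structure(
    list(test_fraction = test_fraction, cv_folds = cv_folds, grids = grids,
         selection_metric = selection_metric, seed = as.integer(seed),
         balance_by_oversampling = isTRUE(balance_by_oversampling)),
    class = "protocol_config"
  )
}

#' Default hyperparameter grids
#'
#' GMM: number of components in {1, 2, 4, 8, 16} (full covariance, 1e-6
#' diagonal regularization). Isolation forest: 100 or 200 trees, subsample
#' 256. ANN: hidden layer of 100 or 500 nodes.
#'
#' @return Named list of tibbles.
#' @export
default_grids <- function() {
  list(
    gmm = tibble::tibble(n_components = c(1, 2, 4, 8, 16)),
    iforest = tibble::tibble(n_trees = c(100, 200), subsample_size = 256),
    ann = tibble::tibble(hidden_size = c(100, 500))
  )
}

screen_families <- c("gmm", "iforest", "ann")

#' Molecule-level stratified train/test split
#'
#' Splits a labeled descriptor table into training and test partitions at
#' the molecule level: all conformers of a molecule land on the same side,
#' and the label proportions are preserved. Deterministic given the seed.
#'
#' @param descriptors Descriptor tibble with `mol_id` and `label` columns.
#' @param test_fraction Fraction of molecules per label class in the test
#'   set (default 0.2; at least one molecule per class is always held out).
#' @param seed Integer seed.
#' @return List with tibbles `train` and `test`.
#' @export
split_train_test <- function(descriptors, test_fraction = 0.2, seed = 1) {
  check_labeled_descriptors(descriptors)
  mols <- dplyr::distinct(descriptors, .data$mol_id, .data$label)
  counts <- dplyr::count(mols, .data$label)
  if (any(counts$n < 2L)) {
    abort("Every label class needs at least 2 molecules to stratify the split.")
  }
  test_ids <- withr::with_seed(seed, {
    unlist(purrr::map(split(mols$mol_id, mols$label), function(ids) {
      n_test <- min(length(ids) - 1L, max(1L, round(test_fraction * length(ids))))
      sample(ids, n_test)
    }), use.names = FALSE)
  })
  list(train = dplyr::filter(descriptors, !(.data$mol_id %in% test_ids)),
       test = dplyr::filter(descriptors, .data$mol_id %in% test_ids))
}

check_labeled_descriptors <- function(descriptors) {
  if (!is.data.frame(descriptors) || nrow(descriptors) == 0L) {
    abort("`descriptors` must be a non-empty descriptor tibble.")
  }
  needed <- c("mol_id", "label")
  if (!all(needed %in% names(descriptors))) {
    abort("`descriptors` needs `mol_id` and `label` columns.")
  }
  invisible(descriptors)
}

# stratified fold assignment at molecule level; returns tibble mol_id/fold
assign_folds <- function(mols, k, seed) {
  withr::with_seed(seed, {
    mols |>
      dplyr::group_by(.data$label) |>
      dplyr::mutate(fold = sample(rep_len(seq_len(k), dplyr::n()))) |>
      dplyr::ungroup()
  })
}

# record the labels of every row handed to a fitting routine, when a
# tracing environment is installed via options(usrml.audit_env = )
audit_training <- function(family, labels) {
  env <- getOption("usrml.audit_env")
  if (is.environment(env)) {
    env$log <- c(env$log, list(list(family = family, labels = labels)))
  }
  invisible(NULL)
}

# fit one model family on a (possibly LEC-reduced) training table.
# One-class families (gmm, iforest) see active conformers only; the ANN
# sees both classes. `hyper` is a named list from the grid.
fit_family <- function(family, train, hyper, mode, config, seed) {
  if (mode == "lec") train <- reduce_to_lec(train)
  if (family %in% c("gmm", "iforest")) {
    act <- dplyr::filter(train, .data$label == "active")
    if (nrow(act) == 0L) abort("No active descriptors available for one-class fitting.")
    audit_training(family, act$label)
    m <- descriptor_matrix(act, unique(train$method))
    if (family == "gmm") {
      fit_gmm(m, n_components = hyper$n_components, seed = seed)
    } else {
      fit_isolation_forest(m, n_trees = hyper$n_trees,
                           subsample_size = hyper$subsample_size %||% 256,
                           seed = seed)
    }
  } else if (family == "ann") {
    audit_training(family, train$label)
    m <- descriptor_matrix(train, unique(train$method))
    fit_ann(m, train$label, hidden_size = hyper$hidden_size,
            balance_by_oversampling = config$balance_by_oversampling,
            seed = seed)
  } else {
    abort(sprintf("Unknown model family '%s'.", family))
  }
}

#' Score descriptors with any fitted screening model
#'
#' Dispatches to [gmm_score()], [if_score()] or [ann_score()]; for a
#' [train_and_screen()] result it unwraps the underlying model. All
#' families share the convention that higher scores are more active-like.
#'
#' @param model A fitted model object.
#' @param x Descriptor vector, matrix or tibble.
#' @return Numeric score vector.
#' @export
screen_score <- function(model, x) UseMethod("screen_score")

#' @export
screen_score.usrml_gmm <- function(model, x) gmm_score(model, x)
#' @export
screen_score.usrml_iforest <- function(model, x) if_score(model, x)
#' @export
screen_score.usrml_ann <- function(model, x) ann_score(model, x)
#' @export
screen_score.usrml_screen_model <- function(model, x) screen_score(model$model, x)

#' Aggregate conformer scores into a molecule score
#'
#' A molecule's score is the maximum of its conformer scores, mirroring
#' the classical max-over-conformer-pairs similarity rule.
#'
#' @param model A fitted model object (any family).
#' @param descriptors Non-empty descriptor tibble of one molecule's
#'   conformers (or a numeric matrix).
#' @return Single numeric score.
#' @export
molecule_score <- function(model, descriptors) {
  if (is.data.frame(descriptors) && nrow(descriptors) == 0L) abort("No descriptors supplied.")
  max(screen_score(model, descriptors))
}

# per-molecule max-aggregated scores for a labeled descriptor table
score_molecules <- function(model, descriptors) {
  m <- descriptor_matrix(descriptors, unique(descriptors$method))
  per_conf <- screen_score(model, m)
  tibble::tibble(mol_id = descriptors$mol_id, label = descriptors$label,
                 score = per_conf) |>
    dplyr::group_by(.data$mol_id, .data$label) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop")
}

#' Cross-validated grid search over model hyperparameters
#'
#' For every grid point, performs molecule-level stratified k-fold
#' cross-validation on the training table: the model is fitted on the
#' in-fold molecules (actives only for the one-class families) and scored
#' on the held-out fold's actives *and* decoys with the selection metric.
#' The grid point with the highest mean validation score wins; ties go to
#' the earlier grid row. Folds whose validation side lacks a class are
#' skipped.
#'
#' @param train Labeled descriptor tibble (the L partition).
#' @param family `"gmm"`, `"iforest"` or `"ann"`.
#' @param config A [protocol_config()].
#' @param mode `"full"` or `"lec"` (LEC reduction of the training side).
#' @return List with `best` (named list of winning hyperparameters) and
#'   `results` (grid tibble with a `mean_score` column).
#' @export
cv_grid_search <- function(train, family, config = protocol_config(),
                           mode = c("full", "lec")) {
  mode <- match.arg(mode)
  check_labeled_descriptors(train)
  grid <- config$grids[[family]]
  if (is.null(grid) || nrow(grid) == 0L) abort(sprintf("Empty grid for family '%s'.", family))
  if (nrow(grid) == 1L) {
    return(list(best = as.list(grid[1L, ]),
                results = dplyr::mutate(grid, mean_score = NA_real_)))
  }
  mols <- dplyr::distinct(train, .data$mol_id, .data$label)
  folds <- assign_folds(mols, config$cv_folds, derive_seed(config$seed, 17))
  scores <- matrix(NA_real_, nrow(grid), config$cv_folds)
  for (g in seq_len(nrow(grid))) {
    hyper <- as.list(grid[g, ])
    for (j in seq_len(config$cv_folds)) {
      val_ids <- folds$mol_id[folds$fold == j]
      fit_tbl <- dplyr::filter(train, !(.data$mol_id %in% val_ids))
      val_tbl <- dplyr::filter(train, .data$mol_id %in% val_ids)
      scores[g, j] <- tryCatch({
        model <- fit_family(family, fit_tbl, hyper, mode, config,
                            seed = derive_seed(config$seed, g, j))
        validation_metric(score_molecules(model, val_tbl), config$selection_metric)
      }, error = function(e) NA_real_)
    }
  }
  mean_score <- rowMeans(scores, na.rm = TRUE)
  if (all(is.nan(mean_score) | is.na(mean_score))) {
    abort("All grid points failed validation scoring.")
  }
  best_idx <- which.max(mean_score)
  list(best = as.list(grid[best_idx, ]),
       results = dplyr::mutate(grid, mean_score = mean_score))
}

validation_metric <- function(scored, metric) {
  if (length(unique(scored$label)) < 2L) return(NA_real_)
  ranked <- rank_scored(scored)
  if (metric == "roc_auc") roc_auc(ranked) else enrichment_factor(ranked, 1)$ef
}

#' Train a screening model and rank the held-out test set
#'
#' Runs the full training protocol end to end: molecule-level stratified
#' 80/20 split, k-fold cross-validated grid search on the training side,
#' final refit with the winning hyperparameters, then scoring and ranking
#' of the held-out test molecules (all their conformers, max-aggregated;
#' ties broken by `mol_id`). In `"lec"` mode the *training* side is reduced
#' to lowest-energy conformers; test molecules are always scored with all
#' available conformers.
#'
#' @param descriptors Labeled descriptor tibble (e.g. from
#'   [make_screening_scenario()] or [compute_descriptors()] joined with
#'   labels; an `energy` column is needed for `"lec"` mode).
#' @param family `"gmm"`, `"iforest"` or `"ann"`.
#' @param mode `"full"` or `"lec"`.
#' @param config A [protocol_config()].
#' @return List with `model` (a `usrml_screen_model`) and `ranking` (test
#'   set ranked by decreasing score).
#' @export
train_and_screen <- function(descriptors, family = screen_families,
                             mode = c("full", "lec"),
                             config = protocol_config()) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  check_labeled_descriptors(descriptors)
  parts <- split_train_test(descriptors, config$test_fraction,
                            derive_seed(config$seed, 1))
  cv <- cv_grid_search(parts$train, family, config, mode)
  model <- fit_family(family, parts$train, cv$best, mode, config,
                      seed = derive_seed(config$seed, 2))
  ranking <- rank_scored(score_molecules(model, parts$test))
  train_mols <- dplyr::distinct(parts$train, .data$mol_id, .data$label)
  wrapped <- structure(
    list(family = family, model = model, hyperparameters = cv$best,
         mode = mode, cv_results = cv$results,
         selection_metric = config$selection_metric, seed = config$seed,
         metadata = list(
           n_train_molecules = nrow(train_mols),
           n_test_molecules = dplyr::n_distinct(parts$test$mol_id),
           train_label_counts = table(train_mols$label)
         )),
    class = "usrml_screen_model"
  )
  list(model = wrapped, ranking = ranking)
}

#' @export
print.usrml_screen_model <- function(x, ...) {
  hp <- paste(names(x$hyperparameters),
              vapply(x$hyperparameters, format, character(1)),
              sep = "=", collapse = ", ")
  cat(sprintf("<usrml_screen_model %s (%s mode): %s; trained on %d molecules>\n",
              x$family, x$mode, hp, x$metadata$n_train_molecules))
  invisible(x)
}
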