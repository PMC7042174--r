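# broom-style tidiers for the fitted objects

#' @export
tidy.usrml_gmm <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$n_components),
    weight = x$weights,
    mean_norm = sqrt(rowSums(x$means^2)),
    mean = asplit(x$means, 1L)
  )
}

#' @export
glance.usrml_gmm <- function(x, ...) {
  tibble::tibble(n_components = x$n_components, dim = x$dim, n = x$n,
                 log_likelihood = x$log_likelihood[x$n_iter],
                 n_iter = x$n_iter, converged = x$converged)
}

#' @export
tidy.usrml_iforest <- function(x, ...) {
  tibble::tibble(
    tree = seq_len(x$n_trees),
    n_nodes = purrr::map_int(x$trees, ~ length(.x$size)),
    n_leaves = purrr::map_int(x$trees, ~ sum(is.na(.x$feature)))
  )
}

#' @export
glance.usrml_iforest <- function(x, ...) {
  tibble::tibble(n_trees = x$n_trees, subsample_size = x$subsample_size,
                 dim = x$dim, normalizer = x$c_psi)
}

#' @export
tidy.usrml_ann <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_trace), validation_loss = x$loss_trace)
}

#' @export
glance.usrml_ann <- function(x, ...) {
  tibble::tibble(hidden_size = x$hidden_size, epochs_run = x$epochs_run,
                 best_epoch = x$best_epoch,
                 best_validation_loss = min(x$loss_trace),
                 oversampled = x$balance_by_oversampling)
}

#' @export
tidy.usrml_screen_model <- function(x, ...) {
  x$cv_results
}

#' @export
glance.usrml_screen_model <- function(x, ...) {
  out <- tibble::tibble(family = x$family, mode = x$mode,
                        selection_metric = x$selection_metric,
                        n_train_molecules = x$metadata$n_train_molecules,
                        n_test_molecules = x$metadata$n_test_molecules)
  for (nm in names(x$hyperparameters)) out[[nm]] <- x$hyperparameters[[nm]]
  out
}

#' @export
tidy.usrml_report <- function(x, ...) {
  x$ef
}

#' @export
glance.usrml_report <- function(x, ...) {
  out <- tibble::tibble(roc_auc = x$roc_auc, n_actives = x$n_actives,
                        n_compounds = x$n_compounds)
  ef1 <- x$ef[x$ef$x_percent == 1, ]
  if (nrow(ef1) == 1L) out$ef1 <- ef1$ef
  if (x$has_baseline && nrow(ef1) == 1L) out$improvement_ratio_ef1 <- ef1$improvement_ratio
  out
}
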