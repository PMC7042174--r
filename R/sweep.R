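#' Training-set fraction sweep
#'
#' Measures how screening performance degrades as the number of known
#' actives shrinks. The molecule-level train/test split is performed once
#' (so the test set is identical across all cells); then, for each
#' conformer mode and each dataset size - the fractions plus one absolute
#' size in molecules - the training actives are subsampled at random, the
#' full protocol (grid search, refit) is rerun, and the held-out test set
#' is re-ranked. With the default 7 fractions plus the absolute size and
#' both modes this yields 16 result rows.
#'
#' One-class families only ever see actives, so only actives are
#' subsampled; for the supervised ANN the decoys are subsampled
#' proportionally so the class ratio is preserved. Cells whose subsample
#' retains no active molecule are reported as unavailable rather than
#' failing the sweep; cells where cross-validation cannot score any fold
#' fall back to the first grid row (flagged in `note`).
#'
#' @param descriptors Labeled descriptor tibble.
#' @param family `"gmm"`, `"iforest"` or `"ann"`.
#' @param fractions Active fractions to sweep (defaults to the classic
#'   100/80/60/50/30/10/5% ladder).
#' @param n_absolute Absolute size cell (default 10 molecules).
#' @param modes Conformer modes to sweep (default both `"full"` and `"lec"`).
#' @param config A [protocol_config()].
#' @return A tibble of class `usrml_sweep` with columns `fraction_label`,
#'   `fraction`, `mode`, `n_active_train`, `ef1`, `auc`, `note`.
#' @export
fraction_sweep <- function(descriptors, family = screen_families,
                           fractions = c(1, 0.8, 0.6, 0.5, 0.3, 0.1, 0.05),
                           n_absolute = 10, modes = c("full", "lec"),
                           config = protocol_config()) {
  family <- match.arg(family)
  modes <- match.arg(modes, c("full", "lec"), several.ok = TRUE)
  check_labeled_descriptors(descriptors)
  if (any(fractions <= 0 | fractions > 1)) abort("`fractions` must lie in (0, 1].")
  if (!is.null(n_absolute) && n_absolute < 1) abort("`n_absolute` must be >= 1.")

  parts <- split_train_test(descriptors, config$test_fraction,
                            derive_seed(config$seed, 1))
  train_mols <- dplyr::distinct(parts$train, .data$mol_id, .data$label)
  act_ids <- train_mols$mol_id[train_mols$label == "active"]
  dec_ids <- train_mols$mol_id[train_mols$label == "decoy"]
  n_act <- length(act_ids)

  sizes <- tibble::tibble(
    fraction_label = c(sprintf("%g%%", 100 * fractions),
                       if (!is.null(n_absolute)) sprintf("%d mols", as.integer(n_absolute))),
    n_keep = c(pmax(1L, as.integer(round(fractions * n_act))),
               if (!is.null(n_absolute)) min(as.integer(n_absolute), n_act))
  )

  cells <- tidyr::expand_grid(mode = modes, sizes)
  rows <- purrr::pmap(
    list(cells$mode, cells$fraction_label, cells$n_keep, seq_len(nrow(cells))),
    function(mode, label, n_keep, cell_idx) {
      out <- tibble::tibble(fraction_label = label,
                            fraction = n_keep / max(1L, n_act),
                            mode = mode, n_active_train = n_keep,
                            ef1 = NA_real_, auc = NA_real_, note = "")
      if (n_keep < 1L || n_act == 0L) {
        out$note <- "unavailable: no actives retained"
        return(out)
      }
      cell_seed <- derive_seed(config$seed, 23, cell_idx)
      keep <- withr::with_seed(cell_seed, {
        keep_act <- sample(act_ids, n_keep)
        if (family == "ann") {
          n_dec_keep <- max(1L, as.integer(round(n_keep / n_act * length(dec_ids))))
          c(keep_act, sample(dec_ids, min(n_dec_keep, length(dec_ids))))
        } else {
          c(keep_act, dec_ids)  # decoys only enter CV validation scoring
        }
      })
      sub_train <- dplyr::filter(parts$train, .data$mol_id %in% keep)
      cell_config <- config
      cell_config$seed <- cell_seed
      cv <- tryCatch(cv_grid_search(sub_train, family, cell_config, mode),
                     error = function(e) NULL)
      if (is.null(cv)) {
        cv <- list(best = as.list(config$grids[[family]][1L, ]))
        out$note <- "cv_fallback: first grid point used"
      }
      fit <- tryCatch(
        fit_family(family, sub_train, cv$best, mode, cell_config,
                   seed = derive_seed(cell_seed, 2)),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        out$note <- "unavailable: model fit failed"
        return(out)
      }
      ranking <- rank_scored(score_molecules(fit, parts$test))
      out$ef1 <- enrichment_factor(ranking, 1)$ef
      out$auc <- roc_auc(ranking)
      out
    }
  )
  out <- dplyr::bind_rows(rows)
  attr(out, "family") <- family
  class(out) <- c("usrml_sweep", class(out))
  out
}
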