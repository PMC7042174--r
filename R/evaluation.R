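#' Enrichment factor of a ranked screen
#'
#' The enrichment factor at `x%` is the ratio of the fraction of actives
#' found in the top `x%` of the ranked list to the fraction expected by
#' chance: `EF = (a_x / c_x) / (a_total / c_total)`. The top-`x%` window
#' holds `c_x = ceiling(x/100 * c_total)` compounds (never fewer than one);
#' ties at the window boundary are resolved by the deterministic order of
#' the input list.
#'
#' @param ranked Tibble with columns `score` and `label`
#'   (`"active"`/`"decoy"`), sorted by non-increasing score (as produced by
#'   [screen_baseline()] or [train_and_screen()]).
#' @param x_percent Percentage(s) of the list to inspect, in `(0, 100]`.
#' @return A tibble with one row per `x_percent` and columns `x_percent`,
#'   `a_x`, `c_x`, `a_total`, `c_total`, `ef`.
#' @examples
#' ranked <- tibble::tibble(
#'   score = seq(1, 0, length.out = 100),
#'   label = rep(c("active", "decoy"), c(10, 90))[sample(100)]
#' )
#' enrichment_factor(dplyr::arrange(ranked, dplyr::desc(score)), 10)
#' @export
enrichment_factor <- function(ranked, x_percent = 1) {
  check_ranked(ranked)
  if (any(!is.finite(x_percent)) || any(x_percent <= 0) || any(x_percent > 100)) {
    abort("`x_percent` must lie in (0, 100].")
  }
  c_total <- nrow(ranked)
  a_total <- sum(ranked$label == "active")
  if (a_total == 0L) abort("Enrichment factor is undefined without actives.")
  purrr::map_dfr(x_percent, function(x) {
    c_x <- max(1L, as.integer(ceiling(x / 100 * c_total)))
    a_x <- sum(ranked$label[seq_len(c_x)] == "active")
    tibble::tibble(x_percent = x, a_x = a_x, c_x = c_x,
                   a_total = a_total, c_total = c_total,
                   ef = (a_x / c_x) / (a_total / c_total))
  })
}

check_ranked <- function(ranked) {
  if (!is.data.frame(ranked) || nrow(ranked) == 0L) abort("`ranked` must be a non-empty tibble.")
  if (!all(c("score", "label") %in% names(ranked))) {
    abort("`ranked` needs `score` and `label` columns.")
  }
  if (is.unsorted(-ranked$score)) {
    abort("`ranked` must be sorted by non-increasing score.")
  }
  invisible(ranked)
}

#' ROC AUC of a scored screen
#'
#' The probability that a randomly chosen active outscores a randomly
#' chosen decoy, with tied scores counted as one half (the Mann-Whitney
#' construction).
#'
#' @param scored Tibble with columns `score` and `label` (both labels must
#'   be present); order is irrelevant.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(tibble::tibble(score = c(0.9, 0.8, 0.7, 0.6),
#'                        label = c("active", "decoy", "active", "decoy")))
#' @export
roc_auc <- function(scored) {
  if (!is.data.frame(scored) || !all(c("score", "label") %in% names(scored))) {
    abort("`scored` needs `score` and `label` columns.")
  }
  act <- scored$label == "active"
  n_a <- sum(act)
  n_d <- sum(scored$label == "decoy")
  if (n_a == 0L || n_d == 0L) abort("ROC AUC needs both actives and decoys.")
  r <- rank(scored$score)
  (sum(r[act]) - n_a * (n_a + 1) / 2) / (n_a * n_d)
}

#' Improvement ratio over a baseline enrichment factor
#'
#' Expresses a model's enrichment factor as a percentage of a baseline's:
#' `100 * ef_model / ef_baseline`. 100 means equal performance. A zero
#' baseline makes the ratio unavailable (`NA` with a warning) rather than
#' infinite.
#'
#' @param ef_model,ef_baseline Enrichment factors (vectorized).
#' @return Percentage ratio(s).
#' @examples
#' improvement_ratio(8.6, 2)  # 430
#' @export
improvement_ratio <- function(ef_model, ef_baseline) {
  if (any(ef_baseline < 0, na.rm = TRUE) || any(ef_model < 0, na.rm = TRUE)) {
    abort("Enrichment factors must be non-negative.")
  }
  out <- 100 * ef_model / ef_baseline
  zero <- !is.na(ef_baseline) & ef_baseline == 0
  if (any(zero)) {
    warn("Baseline EF of 0: improvement ratio reported as unavailable (NA).")
    out[zero] <- NA_real_
  }
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Unpaired rank-sum comparison of two groups. For a combined sample size
#' of at most `exact_limit` the null distribution of the rank sum is
#' enumerated exhaustively over all group assignments (ties handled through
#' midranks); above it a normal approximation with tie correction is used.
#' The statistic reported is the rank sum of the first group.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param exact_limit Largest combined size for the exact branch (default 10).
#' @return One-row tibble with `statistic`, `p_value`, `method`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))  # exact p = 1/3
#' @export
wilcoxon_rank_sum <- function(group_a, group_b, exact_limit = 10) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    abort("Both groups must be non-empty.")
  }
  if (!all(is.finite(c(group_a, group_b)))) abort("Groups must be finite numeric.")
  n1 <- length(group_a)
  n2 <- length(group_b)
  n <- n1 + n2
  r <- rank(c(group_a, group_b))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  if (n <= exact_limit) {
    sums <- colSums(matrix(r[utils::combn(n, n1)], nrow = n1))
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      p <- min(1, 2 * pnorm(-abs(w - mu) / sqrt(sigma2)))
    }
    method <- "normal_approx"
  }
  tibble::tibble(statistic = w, p_value = p, method = method)
}

#' Summarize a ranked screen into an evaluation report
#'
#' Bundles the enrichment factors at the configured percentages, the ROC
#' AUC, and (when a baseline ranking or baseline EF values are supplied)
#' the percentage improvement ratios into one JSON-serializable report.
#'
#' @param ranked Ranked tibble (see [enrichment_factor()]).
#' @param ef_percent Percentages at which to report EF (default 1 and 0.25).
#' @param baseline Optional: either a ranked tibble for the baseline method
#'   or a numeric vector of baseline EF values aligned with `ef_percent`.
#' @return An object of class `usrml_report`.
#' @export
evaluate_screen <- function(ranked, ef_percent = c(1, 0.25), baseline = NULL) {
  ef <- enrichment_factor(ranked, ef_percent)
  auc <- roc_auc(ranked)
  baseline_ef <- NULL
  baseline_auc <- NULL
  if (!is.null(baseline)) {
    if (is.data.frame(baseline)) {
      baseline_ef <- enrichment_factor(baseline, ef_percent)$ef
      baseline_auc <- roc_auc(baseline)
    } else if (is.numeric(baseline) && length(baseline) == length(ef_percent)) {
      baseline_ef <- as.double(baseline)
    } else {
      abort("`baseline` must be a ranked tibble or EF values aligned with `ef_percent`.")
    }
    ef$baseline_ef <- baseline_ef
    ef$improvement_ratio <- improvement_ratio(ef$ef, baseline_ef)
  }
  structure(
    list(ef = ef, roc_auc = auc,
         n_actives = ef$a_total[[1L]], n_compounds = ef$c_total[[1L]],
         baseline_auc = baseline_auc,
         has_baseline = !is.null(baseline_ef)),
    class = "usrml_report"
  )
}

#' @export
print.usrml_report <- function(x, ...) {
  cat(sprintf("<usrml_report: %d actives / %d compounds>\n", x$n_actives, x$n_compounds))
  cat(sprintf("  ROC AUC: %.4f\n", x$roc_auc))
  for (r in seq_len(nrow(x$ef))) {
    line <- sprintf("  EF %.4g%%: %.3f", x$ef$x_percent[[r]], x$ef$ef[[r]])
    if (x$has_baseline) {
      line <- paste0(line, sprintf(" (baseline %.3f, ratio %s%%)",
                                   x$ef$baseline_ef[[r]],
                                   format(round(x$ef$improvement_ratio[[r]]))))
    }
    cat(line, "\n")
  }
  invisible(x)
}

#' Serialize / restore an evaluation report
#'
#' @param report A `usrml_report`.
#' @param path File path for the JSON document.
#' @return `report_to_json()` returns `path` invisibly; `report_from_json()`
#'   returns the restored `usrml_report`.
#' @export
report_to_json <- function(report, path) {
  stopifnot(inherits(report, "usrml_report"))
  payload <- list(ef = report$ef, roc_auc = report$roc_auc,
                  n_actives = report$n_actives, n_compounds = report$n_compounds,
                  baseline_auc = report$baseline_auc,
                  has_baseline = report$has_baseline)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname report_to_json
#' @export
report_from_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(ef = tibble::as_tibble(payload$ef), roc_auc = payload$roc_auc,
         n_actives = payload$n_actives, n_compounds = payload$n_compounds,
         baseline_auc = payload$baseline_auc,
         has_baseline = isTRUE(payload$has_baseline)),
    class = "usrml_report"
  )
}
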