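ranked_with <- function(labels, scores = NULL) {
  n <- length(labels)
  tibble::tibble(score = scores %||% seq(1, 0, length.out = n), label = labels) |>
    dplyr::arrange(dplyr::desc(score))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("enrichment factor reproduces the direct arithmetic", {
  # 100 compounds, 10 actives, 5 of them in the top 10 -> EF10 = 5
  labels <- rep("decoy", 100)
  labels[c(1, 3, 5, 7, 9, 60, 70, 80, 90, 100)] <- "active"
  ef <- enrichment_factor(ranked_with(labels), 10)
  expect_equal(ef$a_x, 5L)
  expect_equal(ef$c_x, 10L)
  expect_equal(ef$ef, 5)
  # perfect ranking of 10/1000 at 1% -> maximum EF 100
  labels <- rep(c("active", "decoy"), c(10, 990))
  ef <- enrichment_factor(ranked_with(labels), 1)
  expect_equal(ef$ef, 100)
  # window floor: tiny list, tiny percentage still inspects one compound
  ef <- enrichment_factor(ranked_with(c("active", "decoy")), 0.25)
  expect_equal(ef$c_x, 1L)
  expect_error(enrichment_factor(ranked_with(rep("decoy", 5))), "without actives")
  unsorted <- tibble::tibble(score = c(0.1, 0.9), label = c("decoy", "active"))
  expect_error(enrichment_factor(unsorted, 10), "sorted")
})

test_that("random rankings enrich at about chance level", {
  labels <- rep(c("active", "decoy"), c(10, 90))
  efs <- withr::with_seed(77, {
    vapply(1:300, function(i) {
      enrichment_factor(ranked_with(sample(labels)), 10)$ef
    }, numeric(1))
  })
  expect_gt(mean(efs), 0.8)
  expect_lt(mean(efs), 1.2)
})

test_that("ROC AUC matches the Mann-Whitney construction", {
  scored <- tibble::tibble(score = c(0.9, 0.8, 0.7, 0.6),
                           label = c("active", "decoy", "active", "decoy"))
  expect_equal(roc_auc(scored), 0.75)
  perfect <- tibble::tibble(score = c(3, 2, 1), label = c("active", "active", "decoy"))
  expect_equal(roc_auc(perfect), 1)
  ties <- tibble::tibble(score = rep(1, 6), label = rep(c("active", "decoy"), 3))
  expect_equal(roc_auc(ties), 0.5)
  expect_error(roc_auc(tibble::tibble(score = 1, label = "active")), "both")
})

test_that("AUC equals brute-force pair counting on random inputs", {
  withr::with_seed(31, {
    for (i in 1:10) {
      n <- sample(20:200, 1)
      scored <- tibble::tibble(
        score = sample(round(rnorm(n), 2)),  # rounding forces ties
        label = sample(c("active", "decoy"), n, replace = TRUE,
                       prob = c(0.3, 0.7))
      )
      if (length(unique(scored$label)) < 2) next
      expect_equal(roc_auc(scored), naive_auc(scored$score, scored$label),
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC agrees with pROC on a clean case", {
  skip_if_not_installed("pROC")
  withr::with_seed(8, {
    scored <- tibble::tibble(score = rnorm(100),
                             label = rep(c("active", "decoy"), c(30, 70)))
    scored$score[scored$label == "active"] <- scored$score[scored$label == "active"] + 1
    ref <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(scored$label, scored$score, levels = c("decoy", "active"),
                          direction = "<"))
    ))
    expect_equal(roc_auc(scored), ref, tolerance = 1e-12)
  })
})

test_that("improvement ratios follow the percentage convention", {
  expect_equal(improvement_ratio(2, 2), 100)
  expect_equal(improvement_ratio(8.6, 2), 430)
  expect_equal(improvement_ratio(0, 2), 0)
  expect_warning(r <- improvement_ratio(3, 0), "unavailable")
  expect_true(is.na(r))
})

test_that("rank-sum test: exact branch, null symmetry and large shifts", {
  res <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(res$method, "exact")
  same <- wilcoxon_rank_sum(c(1, 2), c(1, 2))
  expect_equal(same$p_value, 1)
  withr::with_seed(40, {
    a <- rnorm(20)
    shifted <- wilcoxon_rank_sum(a, a + 10)
    expect_lt(shifted$p_value, 0.01)
    expect_equal(shifted$method, "normal_approx")
  })
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("exact branch matches exhaustive enumeration, ties included", {
  withr::with_seed(52, {
    for (i in 1:15) {
      n1 <- sample(1:4, 1)
      n2 <- sample(1:4, 1)
      a <- sample(1:4, n1, replace = TRUE)  # small support forces ties
      b <- sample(1:4, n2, replace = TRUE)
      expect_equal(wilcoxon_rank_sum(a, b)$p_value, enum_wilcoxon_p(a, b),
                   tolerance = 1e-12)
    }
  })
})

test_that("approximate branch tracks wilcox.test without continuity correction", {
  withr::with_seed(63, {
    a <- rnorm(15)
    b <- rnorm(12) + 0.8
    ours <- wilcoxon_rank_sum(a, b)
    ref <- suppressWarnings(stats::wilcox.test(a, b, correct = FALSE, exact = FALSE))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  })
})

test_that("ROC and enrichment curves build as ggplots", {
  ranked <- ranked_with(rep(c("active", "decoy"), c(5, 45)))
  expect_s3_class(plot_roc(ranked), "ggplot")
  expect_s3_class(plot_enrichment(ranked), "ggplot")
  report <- evaluate_screen(ranked)
  expect_s3_class(autoplot(report), "ggplot")
})

test_that("evaluation reports bundle EF, AUC and ratios and survive JSON", {
  labels <- rep(c("active", "decoy"), c(10, 190))
  withr::with_seed(3, {
    model_rank <- ranked_with(sample(labels), scores = NULL)
    model_rank$score[model_rank$label == "active"] <-
      model_rank$score[model_rank$label == "active"] + 1
    model_rank <- dplyr::arrange(model_rank, dplyr::desc(score))
    base_rank <- ranked_with(sample(labels))
  })
  # the shuffled baseline may score zero at EF 0.25%, in which case the
  # ratio is reported unavailable with a warning
  report <- suppressWarnings(
    evaluate_screen(model_rank, ef_percent = c(1, 0.25), baseline = base_rank)
  )
  expect_s3_class(report, "usrml_report")
  expect_true(report$has_baseline)
  expect_equal(nrow(tidy(report)), 2L)
  expect_true("improvement_ratio" %in% names(tidy(report)))
  g <- glance(report)
  expect_equal(g$n_actives, 10)
  expect_equal(g$roc_auc, roc_auc(model_rank))
  path <- withr::local_tempfile(fileext = ".json")
  report_to_json(report, path)
  back <- report_from_json(path)
  expect_equal(back$ef$ef, report$ef$ef, tolerance = 1e-12)
  expect_equal(back$roc_auc, report$roc_auc, tolerance = 1e-12)
  # missing baseline: ratios omitted, flag unset
  bare <- evaluate_screen(model_rank)
  expect_false(bare$has_baseline)
  expect_false("improvement_ratio" %in% names(tidy(bare)))
})
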