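small_scenario <- function(seed = 5, n_actives = 20, n_decoys = 100) {
  make_screening_scenario(scenario_config(
    n_actives = n_actives, n_decoys = n_decoys, n_conformers_per_mol = 3,
    active_modes = 2, separation = 8, noise_sd = 1, seed = seed
  ))$descriptors
}

test_that("the split is stratified, molecule-level and deterministic", {
  desc <- small_scenario(n_actives = 10, n_decoys = 90)
  parts <- split_train_test(desc, test_fraction = 0.2, seed = 3)
  test_mols <- dplyr::distinct(parts$test, mol_id, label)
  expect_equal(nrow(test_mols), 20L)
  expect_equal(sum(test_mols$label == "active"), 2L)
  expect_length(intersect(parts$train$mol_id, parts$test$mol_id), 0L)
  # all conformers of a molecule stay on one side
  expect_equal(nrow(parts$test), 20L * 3L)
  again <- split_train_test(desc, test_fraction = 0.2, seed = 3)
  expect_identical(parts$test$mol_id, again$test$mol_id)
  tiny <- dplyr::filter(desc, mol_id %in% c("act0001", "dec0001", "dec0002"))
  expect_error(split_train_test(tiny), "at least 2")
})

multimodal_train <- function(seed = 9) {
  # four tight active clusters on orthogonal axes with decoys at the
  # centroid of the cluster centers: one Gaussian centred between the
  # clusters scores the decoys high, four Gaussians do not
  d <- 12
  withr::with_seed(seed, {
    centers <- matrix(0, 4, d)
    for (k in 1:4) centers[k, k] <- 10
    act <- centers[rep(1:4, each = 8), ] + matrix(rnorm(32 * d, sd = 0.5), 32, d)
    dec <- matrix(rnorm(48 * d, sd = 0.5), 48, d)
    dec <- sweep(dec, 2, colMeans(centers), "+")
    out <- tibble::tibble(
      mol_id = c(sprintf("a%02d", 1:32), sprintf("d%02d", 1:48)),
      conf_id = 0L, method = "usr",
      label = rep(c("active", "decoy"), c(32, 48))
    )
    out[sprintf("m%02d", 1:d)] <- as.data.frame(rbind(act, dec))
    out
  })
}

test_that("cross-validation prefers the component count that matches the modes", {
  cfg <- protocol_config(seed = 2, grids = list(gmm = tibble::tibble(n_components = c(1, 4))))
  cv <- cv_grid_search(multimodal_train(), "gmm", cfg)
  expect_equal(cv$best$n_components, 4)
  expect_equal(nrow(cv$results), 2L)
  expect_gt(cv$results$mean_score[2], cv$results$mean_score[1])
})

test_that("a single grid point short-circuits and score ties keep grid order", {
  cfg1 <- protocol_config(seed = 2, grids = list(gmm = tibble::tibble(n_components = 2)))
  cv1 <- cv_grid_search(small_scenario(), "gmm", cfg1)
  expect_equal(cv1$best$n_components, 2)
  # duplicated grid point: identical mean scores, first row wins
  cfg2 <- protocol_config(seed = 2, grids = list(gmm = tibble::tibble(
    n_components = c(3, 3), tag = c("first", "second")
  )))
  cv2 <- cv_grid_search(small_scenario(), "gmm", cfg2)
  expect_equal(cv2$best$tag, "first")
})

test_that("train_and_screen ranks exactly the held-out molecules, reproducibly", {
  desc <- small_scenario()
  cfg <- protocol_config(seed = 4, grids = list(gmm = tibble::tibble(n_components = c(1, 2))))
  run1 <- train_and_screen(desc, "gmm", config = cfg)
  run2 <- train_and_screen(desc, "gmm", config = cfg)
  expect_identical(run1$ranking, run2$ranking)
  parts <- split_train_test(desc, 0.2, usrml:::derive_seed(4, 1))
  expect_setequal(run1$ranking$mol_id, unique(parts$test$mol_id))
  expect_true(all(diff(run1$ranking$score) <= 1e-12))
  expect_s3_class(run1$model, "usrml_screen_model")
  expect_equal(glance(run1$model)$family, "gmm")
})

test_that("molecule scores aggregate conformer scores by max", {
  desc <- small_scenario()
  act <- dplyr::filter(desc, label == "active")
  fit <- fit_gmm(usrml:::descriptor_matrix(act), 1, seed = 1)
  one_mol <- dplyr::filter(desc, mol_id == "act0001")
  expect_equal(molecule_score(fit, one_mol),
               max(gmm_score(fit, usrml:::descriptor_matrix(one_mol))))
  scored <- usrml:::score_molecules(fit, desc)
  expect_equal(nrow(scored), dplyr::n_distinct(desc$mol_id))
})

test_that("one-class fits see only active rows; the ANN sees both classes", {
  desc <- small_scenario(n_actives = 12, n_decoys = 40)
  audit <- new.env()
  withr::local_options(usrml.audit_env = audit)
  cfg <- protocol_config(seed = 6, grids = list(
    gmm = tibble::tibble(n_components = 1),
    iforest = tibble::tibble(n_trees = 20, subsample_size = 64),
    ann = tibble::tibble(hidden_size = 8)
  ))
  for (fam in c("gmm", "iforest")) {
    audit$log <- list()
    train_and_screen(desc, fam, config = cfg)
    expect_gt(length(audit$log), 0)
    for (entry in audit$log) {
      expect_true(all(entry$labels == "active"))
    }
  }
  audit$log <- list()
  train_and_screen(desc, "ann", config = cfg)
  seen <- unique(unlist(purrr::map(audit$log, "labels")))
  expect_setequal(seen, c("active", "decoy"))
})

test_that("LEC mode trains on one conformer per molecule", {
  desc <- small_scenario(n_actives = 12, n_decoys = 40)
  audit <- new.env()
  withr::local_options(usrml.audit_env = audit)
  cfg <- protocol_config(seed = 6, grids = list(gmm = tibble::tibble(n_components = 1)))
  audit$log <- list()
  res_lec <- train_and_screen(desc, "gmm", mode = "lec", config = cfg)
  n_act_train <- res_lec$model$metadata$train_label_counts[["active"]]
  # final fit (last audit entry) received exactly one row per training active
  expect_equal(length(audit$log[[length(audit$log)]]$labels), n_act_train)
  audit$log <- list()
  res_full <- train_and_screen(desc, "gmm", mode = "full", config = cfg)
  expect_equal(length(audit$log[[length(audit$log)]]$labels), n_act_train * 3L)
  # both modes still rank all test molecules
  expect_setequal(res_lec$ranking$mol_id, res_full$ranking$mol_id)
})

test_that("ranking-convention uniformity: cluster centers beat far points", {
  sc <- make_screening_scenario(scenario_config(
    n_actives = 20, n_decoys = 100, n_conformers_per_mol = 3,
    active_modes = 1, separation = 8, noise_sd = 1, seed = 5
  ))
  desc <- sc$descriptors
  act <- dplyr::filter(desc, label == "active")
  m <- usrml:::descriptor_matrix(act)
  center <- sc$centers[1, ]
  far <- center - 10 * center / sqrt(sum(center^2))  # 10 sigma into decoy space
  models <- list(
    fit_gmm(m, 1, seed = 1),
    fit_isolation_forest(m, n_trees = 50, seed = 1),
    fit_ann(usrml:::descriptor_matrix(desc), desc$label, hidden_size = 16,
            epochs = 100, seed = 1)
  )
  for (model in models) {
    expect_gt(screen_score(model, center), screen_score(model, far))
  }
})
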