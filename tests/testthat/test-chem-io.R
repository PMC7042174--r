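write_smi <- function(lines) {
  path <- withr::local_tempfile(fileext = ".smi", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("SMILES files parse in order with comments ignored", {
  path <- write_smi(c("# a comment", "CCO mol1", "", "c1ccccc1 mol2"))
  mols <- read_smiles_file(path)
  expect_equal(mols$mol_id, c("mol1", "mol2"))
  expect_equal(mols$label, c("unknown", "unknown"))
  expect_equal(attr(mols, "n_skipped"), 0L)
})

test_that("unparseable SMILES are skipped with a warning and counted", {
  path <- write_smi(c("CCO mol1", "not_a_smiles molX"))
  expect_warning(mols <- read_smiles_file(path), "unparseable")
  expect_equal(mols$mol_id, "mol1")
  expect_equal(attr(mols, "n_skipped"), 1L)
})

test_that("degenerate SMILES files are fatal", {
  expect_error(read_smiles_file(write_smi(character(0))), "No parseable")
  expect_error(read_smiles_file(tempfile()), "not found")
  expect_error(read_smiles_file(write_smi(c("CCO m1", "CCN m1"))), "Duplicate")
})

test_that("SDF round trips preserve conformers and assign sequential conf_ids", {
  confs <- list(random_point_cloud(5, 1, mol_id = "A"),
                random_point_cloud(6, 2, mol_id = "A"),
                random_point_cloud(4, 3, mol_id = "B"))
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(confs, path)
  back <- read_sdf(path)
  expect_length(back, 3L)
  expect_equal(purrr::map_chr(back, "mol_id"), c("A", "A", "B"))
  expect_equal(purrr::map_int(back, "conf_id"), c(0L, 1L, 0L))
  expect_lt(max(abs(back[[1]]$coords - confs[[1]]$coords)), 1e-4)  # SDF precision
  expect_equal(back[[2]]$charges, confs[[2]]$charges, tolerance = 1e-9)
  expect_equal(back[[3]]$energy, confs[[3]]$energy)
})

test_that("the V2000 reader agrees with ChemmineR on multi-atom entries", {
  skip_if_not_installed("ChemmineR")
  confs <- generate_conformers(tibble::tibble(mol_id = "etoh", smiles = "CCO"),
                               max_conformers = 2, seed = 4)
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(confs, path)
  ours <- read_sdf(path)
  ref <- suppressWarnings(ChemmineR::read.SDFset(path, skipErrors = TRUE))
  for (e in seq_along(ours)) {
    ab <- ChemmineR::atomblock(ref[[e]])
    expect_equal(unname(ours[[e]]$coords), unname(ab[, 1:3]), tolerance = 1e-9)
    expect_equal(ours[[e]]$elements, gsub("_.*$", "", rownames(ab)))
  }
})

test_that("flat (all z = 0) SDF entries raise a 2D-suspect warning", {
  flat <- conformer_record("flat", 0, cbind(matrix(rnorm(6), 3, 2), 0))
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(flat, path)
  expect_warning(back <- read_sdf(path), "2D suspect")
  expect_length(back, 1L)
})

test_that("single-atom SDF entries survive", {
  one <- conformer_record("tiny", 0, matrix(c(0, 0, 1), 1, 3))
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(one, path)
  back <- read_sdf(path)
  expect_equal(nrow(back[[1]]$coords), 1L)
})

test_that("descriptor tables round-trip bit-compatibly at 12 significant digits", {
  desc <- compute_descriptors(purrr::map(1:10, ~ random_point_cloud(8, .x)), "usr")
  path <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_table(desc, path)
  header <- readLines(path, n = 1)
  expect_equal(header, paste(c("mol_id", "conf_id", "method", sprintf("m%02d", 1:15)),
                             collapse = ","))
  back <- read_descriptor_table(path)
  expect_equal(names(back), names(desc))
  expect_equal(usrml:::descriptor_matrix(back), usrml:::descriptor_matrix(desc),
               tolerance = 1e-13)
  # es5d tables keep all 15 columns
  desc5 <- compute_descriptors(purrr::map(1:3, ~ random_point_cloud(8, .x)), "es5d")
  write_descriptor_table(desc5, path)
  expect_equal(ncol(read_descriptor_table(path)), 18L)
})

test_that("malformed descriptor tables are fatal", {
  desc <- compute_descriptors(purrr::map(1:3, ~ random_point_cloud(5, .x)), "usr")
  mixed <- desc
  mixed$method[2] <- "es5d"
  path <- withr::local_tempfile(fileext = ".csv")
  expect_error(write_descriptor_table(mixed, path), "single method")
  # a usr table smuggling a 15-value row is a format error
  write_descriptor_table(desc, path)
  lines <- readLines(path)
  lines[2] <- sub(",,$", ",2.5,3.5", lines[2])  # fill m14/m15 of a usr row
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, bad)
  expect_error(read_descriptor_table(bad), "beyond m12")
  other <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mol_id,conf_id,wrong_header", "x,0,usr"), other)
  expect_error(read_descriptor_table(other), "header")
})

test_that("empty descriptor tables round-trip as header-only files", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_table(usrml:::empty_descriptor_table("usr"), path)
  expect_length(readLines(path), 1L)
  expect_equal(nrow(read_descriptor_table(path)), 0L)
})

test_that("target datasets label by file membership and track missing conformers", {
  actives <- write_smi(c("CCO act1", "CCN act2"))
  decoys <- write_smi(c("CCC dec1", "CCCC dec2", "c1ccccc1 dec3"))
  sdf <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(list(random_point_cloud(4, 1, mol_id = "act1"),
                 random_point_cloud(4, 2, mol_id = "dec1")), sdf)
  ds <- assemble_target_dataset(actives, decoys, sdf, target_id = "toy")
  expect_equal(nrow(ds$molecules), 5L)
  expect_equal(sum(ds$molecules$label == "active"), 2L)
  expect_equal(sum(ds$molecules$label == "decoy"), 3L)
  expect_equal(ds$n_missing_conformers, 3L)
  expect_named(ds$conformers, c("act1", "dec1"))
  # manifest round trip preserves the label partition
  mpath <- withr::local_tempfile(fileext = ".json")
  write_dataset_manifest(ds, mpath)
  m <- read_dataset_manifest(mpath)
  expect_setequal(m$actives, c("act1", "act2"))
  expect_setequal(m$decoys, c("dec1", "dec2", "dec3"))
})

test_that("overlapping active/decoy identifiers are a consistency error", {
  actives <- write_smi("CCO both1")
  decoys <- write_smi(c("CCC both1", "CCCC dec2"))
  expect_error(assemble_target_dataset(actives, decoys), "both actives and decoys")
})
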